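make_ref <- function(seqs, species = "spX") {
  nm <- sprintf("gene%02d|tx%02d|%s", seq_along(seqs), seq_along(seqs),
                species)
  Biostrings::DNAStringSet(setNames(seqs, nm))
}

test_that("index contains L - k + 1 forward positions and skips N k-mers", {
  idx <- build_index(make_ref("ACGTACGT"), k = 4)
  st <- index_size(idx)
  expect_equal(st$n_positions, 5)

  idx_n <- build_index(make_ref(c("NNNNNNNNNN", "ACGTACGTAC")), k = 4)
  expect_equal(index_size(idx_n)$n_positions, 7)

  expect_warning(build_index(make_ref(c("ACG", "ACGTACGTACGTACGTACGT")),
                             k = 16), "shorter than k")
})

test_that("every indexed k-mer is relocatable by brute-force string search", {
  set.seed(7)
  s <- random_dna(1000)
  idx <- build_index(make_ref(s), k = 16)
  for (start in sample(1:(1000 - 15), 25)) {
    kmer <- substr(s, start, start + 15)
    hits <- index_lookup(idx, kmer)
    # oracle: all exact occurrences via gregexpr
    occ <- gregexpr(kmer, s, fixed = TRUE)[[1]]
    expect_true((start - 1) %in% hits$pos)
    expect_setequal(hits$pos, as.integer(occ) - 1L)
  }
})

test_that("exact substrings map with zero mismatches at the true position", {
  set.seed(11)
  ref <- make_ref(replicate(3, random_dna(500)))
  seqs <- as.character(ref)
  r <- substr(seqs[2], 101, 150)
  res <- map_read(c(read1 = r), build_index(ref), mapper_config())
  expect_equal(res$status, "mapped")
  expect_equal(res$pos, 100)
  expect_equal(res$mismatches, 0)
  expect_equal(res$transcript, "tx02")
  expect_equal(res$strand, "+")
  # reverse-complement read maps to the same locus on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
  res_rc <- map_read(c(read1 = rc), build_index(ref), mapper_config())
  expect_equal(res_rc$pos, 100)
  expect_equal(res_rc$strand, "-")
})

test_that("a substituted read maps to its origin and matches the Hamming oracle", {
  set.seed(13)
  ref <- make_ref(replicate(3, random_dna(500)))
  seqs <- as.character(ref)
  r <- strsplit(substr(seqs[1], 201, 250), "")[[1]]
  r[c(10, 30)] <- vapply(r[c(10, 30)],
                         function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  read <- paste(r, collapse = "")
  cfg <- mapper_config()
  res <- map_read(c(x = read), build_index(ref), cfg)
  expect_equal(res$status, "mapped")
  expect_equal(res$mismatches, 2)
  expect_equal(res$pos, 200)
  orc <- oracle_scan(read, seqs, budget = ceiling(0.06 * 50))
  expect_equal(res$mismatches, orc$min_dist)
})

test_that("minimum-distance ties across genes follow the ambiguity policy", {
  set.seed(17)
  core <- random_dna(60)
  ref <- make_ref(c(paste0(random_dna(50), core, random_dna(50)),
                    paste0(random_dna(80), core, random_dna(20))))
  read <- substr(core, 6, 55)
  res_d <- map_read(c(r = read), build_index(ref),
                    mapper_config(ambiguity = "discard"))
  expect_equal(res_d$status, "ambiguous")
  res_f <- map_read(c(r = read), build_index(ref),
                    mapper_config(ambiguity = "first_best"))
  expect_equal(res_f$status, "mapped")
  expect_equal(res_f$transcript, "tx01")  # lexicographic tie-break
})

test_that("the cascade assigns reads to the earliest mappable stage", {
  set.seed(19)
  shared <- random_dna(300)
  only3 <- random_dna(300)
  refs <- list(sp1 = make_ref(shared, "sp1"),
               sp2 = make_ref(shared, "sp2"),
               sp3 = make_ref(c(shared, only3), "sp3"))
  names(refs$sp3) <- c("gene01|tx01|sp3", "gene99|tx99|sp3")
  reads <- list(s1 = c(a = substr(shared, 11, 60),    # present in all stages
                       b = substr(only3, 101, 150)))  # stage-3 exclusive
  wf <- run_waterfall(reads, refs, mapper_config())
  stages <- setNames(wf$alignments$stage, wf$alignments$read_id)
  expect_equal(unname(stages["a"]), 1L)
  expect_equal(unname(stages["b"]), 3L)
  expect_equal(sum(wf$summary$stage_counts), 2)
  expect_equal(unname(wf$summary$fraction_mapped["s1"]), 1)
})

test_that("an empty read set yields zero totals and fraction 0", {
  refs <- list(sp1 = make_ref(random_dna(100), "sp1"))
  wf <- run_waterfall(list(s1 = character(0)), refs, mapper_config())
  expect_equal(nrow(wf$alignments), 0)
  expect_equal(unname(wf$summary$total["s1"]), 0L)
  expect_equal(unname(wf$summary$fraction_mapped["s1"]), 0)
})

test_that("a missing reference named in stage_order is a hard error", {
  refs <- list(sp1 = make_ref(random_dna(100), "sp1"))
  expect_error(run_waterfall(list(s1 = c(r = random_dna(50))), refs,
                             mapper_config(stage_order = c("sp1", "sp9"))),
               "sp9")
})

test_that("mapper decisions agree with the exhaustive scan oracle", {
  # k = 12 guarantees seed discovery for any locus within the budget of a
  # 50-mer (3 mismatches split the read into gaps of >= 12 clean bases)
  set.seed(23)
  txs <- replicate(5, random_dna(5000))
  ref <- make_ref(txs)
  idx <- build_index(ref, k = 12)
  cfg <- mapper_config(k = 12)
  budget <- ceiling(0.06 * 50)
  reads <- character(80)
  for (i in seq_along(reads)) {
    t <- sample(5, 1); st <- sample(5000 - 49, 1)
    r <- strsplit(substr(txs[t], st, st + 49), "")[[1]]
    nmut <- sample(0:5, 1)  # some reads deliberately exceed the budget
    if (nmut > 0) {
      at <- sample(50, nmut)
      r[at] <- vapply(r[at],
                      function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                         1), "")
    }
    if (runif(1) < 0.5)
      r <- rev(chartr("ACGT", "TGCA", r))
    reads[i] <- paste(r, collapse = "")
  }
  names(reads) <- paste0("r", seq_along(reads))
  res <- map_read(reads, idx, cfg)
  for (i in seq_along(reads)) {
    orc <- oracle_scan(reads[i], txs, budget)
    expect_equal(res$status[i] == "mapped", orc$mapped, info = paste("read", i))
    if (res$status[i] == "mapped")
      expect_equal(res$mismatches[i], orc$min_dist, info = paste("read", i))
  }
})

test_that("increasing the mismatch budget never decreases the mapped fraction", {
  cfg <- sim_config(seed = 29, n_genes = 15, depth = 600,
                    transcript_len = 250)
  d <- simulate_dataset(cfg)
  fractions <- vapply(c(0.02, 0.04, 0.06, 0.1), function(rate) {
    wf <- run_waterfall(d$reads[1], d$refs$references,
                        mapper_config(budget_rate = rate))
    sum(wf$summary$mapped) / sum(wf$summary$total)
  }, numeric(1))
  expect_true(all(diff(fractions) >= 0))
})

test_that("stage exclusivity: mapped stages plus unmapped partition the reads", {
  cfg <- sim_config(seed = 37, n_genes = 20, depth = 1000,
                    transcript_len = 300)
  d <- simulate_dataset(cfg)
  wf <- run_waterfall(d$reads, d$refs$references, mapper_config())
  expect_equal(anyDuplicated(wf$alignments$read_id), 0L)
  expect_equal(nrow(wf$alignments) + nrow(wf$unmapped),
               sum(wf$summary$total))
  expect_equal(unname(rowSums(wf$summary$stage_counts) +
                        (wf$summary$total - wf$summary$mapped)),
               unname(wf$summary$total))
})
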