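test_that("config validation rejects degenerate parameters", {
  expect_error(sim_config(species_divergence = 0.8), "degenerate")
  expect_error(sim_config(seq_error = -0.1), "probabilities")
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(read_len = 600, transcript_len = 500),
               "read_len")
  expect_error(sim_config(dispersion = -1), "dispersion")
})

test_that("zero divergence reproduces the focal transcriptome in every species", {
  cfg <- sim_config(seed = 5, n_genes = 12, transcript_len = 120,
                    species_divergence = 0, orphan_fraction = 0)
  rs <- simulate_references(cfg)
  focal <- as.character(rs$focal)
  for (sp in names(rs$references)) {
    ref <- as.character(rs$references[[sp]])
    expect_equal(unname(ref), unname(focal))
  }
})

test_that("per-transcript divergence matches the binomial expectation", {
  cfg <- sim_config(seed = 9, n_genes = 50, transcripts_per_gene = 2,
                    transcript_len = 1000, species_divergence = 0.03,
                    orphan_fraction = 0)
  rs <- simulate_references(cfg)
  focal <- as.character(rs$focal)
  for (sp in names(rs$references)) {
    ref <- as.character(rs$references[[sp]])
    # brute-force site-wise mismatch count per transcript
    mm <- mapply(function(a, b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, focal, ref)
    expected <- 1000 * 0.03
    s <- sqrt(1000 * 0.03 * 0.97)
    expect_true(all(abs(mm - expected) <= 4 * s))
    # and the pooled mean must be much tighter
    expect_lt(abs(mean(mm) - expected), 4 * s / sqrt(length(mm)))
  }
})

test_that("the same configuration reproduces byte-identical FASTA", {
  cfg <- sim_config(seed = 21, n_genes = 10, transcript_len = 150)
  r1 <- simulate_references(cfg)
  r2 <- simulate_references(cfg)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(r1$references$sp1, f1)
  write_fasta(r2$references$sp1, f2)
  expect_identical(readLines(f1), readLines(f2))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$reads, d2$reads)
  expect_identical(d1$counts_focal, d2$counts_focal)
  expect_identical(as.character(d1$proteins), as.character(d2$proteins))
})

test_that("NB count moments match a Monte-Carlo oracle", {
  cfg <- sim_config(seed = 31, n_genes = 10000, de_fraction = 0,
                    dispersion = 0.1, depth = 1e6, expr_sdlog = 0,
                    n_replicates = 2)
  # every gene at mu = depth/n_genes = 100; pool one sample's draws
  sc <- simulate_counts(cfg)
  x <- sc$counts[, 1]
  # independent Monte-Carlo oracle at 10x replication
  set.seed(123)
  mc <- rnbinom(1e5, mu = 100, size = 1 / 0.1)
  se_mean <- sd(mc) / sqrt(length(x))
  expect_lt(abs(mean(x) - mean(mc)), 4 * se_mean)
  # sampling sd of the variance estimated from MC batches
  vb <- vapply(split(mc, rep(1:10, each = 1e4)), var, numeric(1))
  se_var <- sd(vb) * sqrt(1e4 / length(x))
  expect_lt(abs(var(x) - mean(vb)), 4 * se_var)
  expect_gt(var(x), 100 + 0.5 * 0.1 * 100^2)  # clearly overdispersed
})

test_that("de_fraction 0 yields all-null labels and fold 1 is indistinguishable", {
  cfg <- sim_config(seed = 3, n_genes = 100, de_fraction = 0)
  sc <- simulate_counts(cfg)
  expect_true(all(sc$labels$label == "null"))

  cfg2 <- sim_config(seed = 3, n_genes = 400, de_fraction = 0.5, de_fold = 1,
                     expr_sdlog = 0, depth = 40000)
  sc2 <- simulate_counts(cfg2)
  lab <- setNames(sc2$labels$label, sc2$labels$gene)
  m <- rowMeans(sc2$counts)
  p <- t.test(m[lab[rownames(sc2$counts)] != "null"],
              m[lab[rownames(sc2$counts)] == "null"])$p.value
  expect_gt(p, 0.01)
})

test_that("reads conserve counts and carry exact origin truth", {
  cfg <- sim_config(seed = 13, n_genes = 20, depth = 400,
                    transcript_len = 200, seq_error = 0)
  d <- simulate_dataset(cfg)
  total_reads <- sum(vapply(d$reads, length, integer(1)))
  expect_equal(total_reads, sum(d$counts_focal))
  expect_equal(nrow(d$origins), total_reads)
  expect_false(anyDuplicated(d$origins$read_id) > 0)
  # per-gene conservation in one sample
  s1 <- colnames(d$counts_focal)[1]
  per_gene <- table(d$origins$gene[d$origins$sample == s1])
  cnt <- d$counts_focal[, s1]
  expect_true(all(per_gene[names(cnt)[cnt > 0]] == cnt[cnt > 0]))

  # with seq_error 0 every read is an exact substring of its origin (or its
  # reverse complement), verified by brute-force search
  focal <- setNames(as.character(d$refs$focal),
                    parse_ids_for_test(names(d$refs$focal)))
  org <- d$origins[sample.int(nrow(d$origins), 50), ]
  rd <- unlist(lapply(d$reads, as.character))
  names(rd) <- unlist(lapply(d$reads, names))
  for (i in seq_len(nrow(org))) {
    r <- rd[[org$read_id[i]]]
    if (org$strand[i] == "-")
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    tx_seq <- focal[[org$transcript[i]]]
    expect_identical(substr(tx_seq, org$pos[i] + 1, org$pos[i] + nchar(r)), r)
    expect_true(grepl(r, tx_seq, fixed = TRUE))
  }
})

test_that("zero counts yield empty read sets", {
  cfg <- sim_config(seed = 2, n_genes = 5, transcript_len = 100, depth = 10)
  rs <- simulate_references(cfg)
  counts <- matrix(0L, 5, 2,
                   dimnames = list(sprintf("g%04d", 1:5), c("TG_1", "DRG_1")))
  rd <- simulate_reads(counts, rs$focal, cfg)
  expect_true(all(lengths(rd$reads) == 0))
  expect_equal(nrow(rd$origins), 0)
})

test_that("planted TM segments are strongly hydrophobic; truth empty when disabled", {
  cfg0 <- sim_config(seed = 17, n_genes = 30, tm_fraction = 0,
                     sp_fraction = 0)
  pr0 <- simulate_proteins(cfg0)
  expect_true(all(vapply(pr0$truth$tm, nrow, integer(1)) == 0))
  expect_true(all(is.na(pr0$truth$sp)))

  cfg1 <- sim_config(seed = 18, n_genes = 60, tm_fraction = 1,
                     sp_fraction = 0.5)
  pr1 <- simulate_proteins(cfg1)
  kd <- kd_hydropathy()
  for (id in names(pr1$truth$tm)) {
    segs <- pr1$truth$tm[[id]]
    expect_gt(nrow(segs), 0)
    seq <- as.character(pr1$proteins[[id]])
    for (s in seq_len(nrow(segs))) {
      frag <- substr(seq, segs$start[s] + 1, segs$end[s])
      expect_gte(segs$end[s] - segs$start[s], 19)
      expect_lte(segs$end[s] - segs$start[s], 23)
      # direct hydropathy oracle on the planted segment
      h <- mean(kd[strsplit(frag, "")[[1]]])
      expect_gt(h, 1.6)
    }
  }
  # planted signal peptides sit within the first 35 residues
  sp_pos <- pr1$truth$sp[!is.na(pr1$truth$sp)]
  expect_true(all(sp_pos >= 15 & sp_pos <= 35))
})

test_that("a constructed pure-hydrophobic 21-mer passes the hydropathy bar", {
  seg <- paste(sample(c("L", "I", "V", "F"), 21, replace = TRUE),
               collapse = "")
  h <- mean(kd_hydropathy()[strsplit(seg, "")[[1]]])
  expect_gt(h, 1.6)
})
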