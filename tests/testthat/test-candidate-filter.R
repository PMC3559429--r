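make_de <- function(gene, fold, padj, conditions = c("TG", "DRG")) {
  out <- data.frame(gene = gene, base_mean = 100, fold_change = fold,
                    log2fc = log2(fold), pval = padj, padj = padj,
                    enriched_in = ifelse(padj <= 0.05,
                                         ifelse(fold > 1, conditions[2],
                                                conditions[1]), "none"),
                    stringsAsFactors = FALSE)
  attr(out, "conditions") <- conditions
  out
}

test_that("enriched-gene selection is inclusive at the threshold boundary", {
  de <- make_de(c("a", "b", "c", "d"),
                fold = c(0.5, 2.0, 0.4, 3.0),
                padj = c(0.049, 0.05, 0.051, 0.2))
  expect_setequal(select_enriched(de, "TG", 0.05), "a")    # fold < 1 = TG
  expect_setequal(select_enriched(de, "DRG", 0.05), "b")   # 0.05 inclusive
  expect_equal(select_enriched(de[0, ], "TG", 0.05), character(0))
  expect_error(select_enriched(de, "liver", 0.05), "direction")
})

test_that("selection equals a brute-force filter on random fixtures", {
  set.seed(5)
  de <- make_de(sprintf("g%03d", 1:100),
                fold = exp(rnorm(100)),
                padj = runif(100))
  got <- select_enriched(de, "DRG", 0.05)
  expect_setequal(got, de$gene[de$padj <= 0.05 & de$fold_change > 1])
  got_tg <- select_enriched(de, "TG", 0.05)
  expect_setequal(got_tg, de$gene[de$padj <= 0.05 & de$fold_change < 1])
})

test_that("cross-species sharing is a plain harmonized intersection", {
  expect_equal(shared_across_species(c("C1", "C2", "C3"), c("C3", "C1")),
               c("C1", "C3"))
  expect_equal(shared_across_species(c("C1"), c("C9")), character(0))
  set.seed(7)
  a <- sample(sprintf("C%02d", 1:40), 20)
  b <- sample(sprintf("C%02d", 1:40), 20)
  expect_setequal(shared_across_species(a, b), intersect(a, b))
})

test_that("a gene enriched in both species is shared but excluded from candidates", {
  # printed-value fixture: DRG/TG fold 4.76 at padj 9.26e-5 in the focal
  # species and fold 1.5 at padj 0.034 in the cross species
  de_focal <- make_de(c("Hoxd1", "other"), fold = c(4.76, 1.2),
                      padj = c(9.26e-5, 0.5))
  de_cross <- make_de(c("Hoxd1", "other"), fold = c(1.5, 1.0),
                      padj = c(0.034, 0.9))
  shared <- shared_across_species(select_enriched(de_focal, "DRG", 0.05),
                                  select_enriched(de_cross, "DRG", 0.05))
  expect_true("Hoxd1" %in% shared)

  membrane <- data.frame(protein = c("Hoxd1", "other"), sp_trimmed = 0,
                         m1_segments = "", m2_segments = "", m3_segments = "",
                         votes = 3L, is_membrane = TRUE,
                         stringsAsFactors = FALSE)
  cand <- candidate_transducers(de_focal, de_cross, membrane,
                                filter_criteria(direction = "DRG"))
  expect_false("Hoxd1" %in% cand$gene)  # cross-species DE at 0.034 <= 0.05
})

test_that("the cascade equals a brute-force three-way set computation", {
  set.seed(11)
  genes <- sprintf("g%02d", 1:40)
  de_f <- make_de(genes, fold = exp(rnorm(40, 0, 1)), padj = runif(40))
  de_c <- make_de(sample(genes, 30), fold = exp(rnorm(30)),
                  padj = runif(30))
  mem <- data.frame(protein = genes, sp_trimmed = 0, m1_segments = "",
                    m2_segments = "", m3_segments = "",
                    votes = sample(0:3, 40, replace = TRUE),
                    stringsAsFactors = FALSE)
  mem$is_membrane <- mem$votes >= 2
  cand <- candidate_transducers(de_f, de_c, mem,
                                filter_criteria(direction = "DRG"))
  cross_padj <- setNames(de_c$padj, de_c$gene)
  brute <- genes[
    de_f$padj <= 0.05 & de_f$fold_change > 1 &
      (is.na(cross_padj[genes]) | cross_padj[genes] > 0.05) &
      mem$is_membrane]
  expect_setequal(cand$gene, brute)
  # every surviving row re-satisfies its predicate
  expect_true(all(cand$padj <= 0.05 & cand$fold_enrichment > 1))
  expect_true(all(is.na(cand$cross_padj) | cand$cross_padj > 0.05))
  expect_true(all(cand$is_membrane))
  # sorted by fold enrichment descending
  expect_true(all(diff(cand$fold_enrichment) <= 0))
})

test_that("relaxing any single criterion yields a superset", {
  set.seed(13)
  genes <- sprintf("g%02d", 1:50)
  de_f <- make_de(genes, fold = exp(rnorm(50)), padj = runif(50))
  de_c <- make_de(genes, fold = exp(rnorm(50)), padj = runif(50))
  mem <- data.frame(protein = genes, votes = sample(0:3, 50, TRUE),
                    stringsAsFactors = FALSE)
  mem$is_membrane <- mem$votes >= 2
  full <- candidate_transducers(de_f, de_c, mem,
                                filter_criteria(direction = "DRG"))
  no_mem <- candidate_transducers(de_f, de_c, mem,
                                  filter_criteria(direction = "DRG",
                                                  require_membrane = FALSE))
  no_cross <- candidate_transducers(de_f, de_c, mem,
                                    filter_criteria(direction = "DRG",
                                                    exclude_cross_de = FALSE))
  wider <- candidate_transducers(de_f, de_c, mem,
                                 filter_criteria(padj_threshold = 0.2,
                                                 direction = "DRG"))
  expect_true(all(full$gene %in% no_mem$gene))
  expect_true(all(full$gene %in% no_cross$gene))
  # raising the focal threshold admits more focal genes but also excludes
  # more cross-DE genes, so compare with the cross exclusion held fixed
  wider_noc <- candidate_transducers(de_f, de_c, mem,
                                     filter_criteria(padj_threshold = 0.2,
                                                     direction = "DRG",
                                                     exclude_cross_de = FALSE))
  expect_true(all(no_cross$gene %in% wider_noc$gene))
  expect_s3_class(wider, "candidate_table")
})

test_that("missing membrane predictions warn and are kept with NA votes", {
  de_f <- make_de(c("a", "b"), fold = c(3, 4), padj = c(0.01, 0.01))
  mem <- data.frame(protein = "a", votes = 3L, is_membrane = TRUE,
                    stringsAsFactors = FALSE)
  expect_warning(
    cand <- candidate_transducers(de_f, NULL, mem,
                                  filter_criteria(direction = "DRG")),
    "no membrane prediction")
  expect_setequal(cand$gene, c("a", "b"))
  expect_true(is.na(cand$votes[cand$gene == "b"]))
  expect_error(
    suppressWarnings(
      candidate_transducers(de_f, NULL, mem,
                            filter_criteria(direction = "DRG",
                                            strict = TRUE))),
    "no membrane prediction")
})

test_that("category tallies cover all candidates, with unannotated fallback", {
  cand <- data.frame(gene = c("a", "b", "c"), direction = "TG",
                     fold_enrichment = c(3, 2, 1.5),
                     stringsAsFactors = FALSE)
  ann <- data.frame(gene = c("a", "b"), category = c("receptor", "receptor"),
                    stringsAsFactors = FALSE)
  tal <- tally_categories(cand, ann)
  expect_equal(sum(tal$n), 3)
  expect_equal(tal$n[tal$category == "receptor"], 2)
  expect_equal(tal$n[tal$category == "unannotated"], 1)
  expect_equal(nrow(tally_categories(cand[0, ], ann)), 0)

  set.seed(17)
  cand2 <- data.frame(gene = sprintf("g%02d", 1:30),
                      direction = sample(c("TG", "DRG"), 30, TRUE),
                      fold_enrichment = runif(30, 1, 5),
                      stringsAsFactors = FALSE)
  ann2 <- data.frame(gene = sprintf("g%02d", 1:20),
                     category = sample(letters[1:4], 20, TRUE),
                     stringsAsFactors = FALSE)
  tal2 <- tally_categories(cand2, ann2)
  cat_of <- setNames(ann2$category, ann2$gene)[cand2$gene]
  cat_of[is.na(cat_of)] <- "unannotated"
  orc <- table(cand2$direction, cat_of)
  for (i in seq_len(nrow(tal2)))
    expect_equal(tal2$n[i], unname(orc[tal2$direction[i], tal2$category[i]]))
})

test_that("channel ranking sorts by fold enrichment with stable gene-id ties", {
  cand <- data.frame(gene = c("chB", "chA", "x", "chC"), direction = "TG",
                     fold_enrichment = c(2, 2, 9, 5),
                     stringsAsFactors = FALSE)
  ch <- data.frame(gene = c("chA", "chB", "chC"), is_channel = TRUE,
                   conductance = c("K+", "Na+", "Ca2+"),
                   stringsAsFactors = FALSE)
  rk <- rank_channels(cand, ch)
  expect_equal(rk$gene, c("chC", "chA", "chB"))
  expect_equal(rk$conductance, c("Ca2+", "K+", "Na+"))
  expect_equal(nrow(rank_channels(cand[cand$gene == "x", ], ch)), 0)
})
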