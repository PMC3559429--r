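#' Generate a complete synthetic study with planted ground truth
#'
#' Orchestrates the four generators into one coherent dataset: references and
#' homology, focal-species ("mole-like") counts and reads, an independently
#' labelled cross-species ("mouse-like") count table for the exclusion
#' filter, one representative protein per collapsed gene entity, and
#' category/channel annotation tables. A configurable number of genes per
#' direction are deliberately planted to satisfy the full candidate cascade
#' (enriched in the focal species, null in the cross species, transmembrane,
#' channel), and the emergent set of genes whose ground truth satisfies the
#' cascade is recorded in `truth$candidates`.
#'
#' Per-gene relative expression is shared between the focal and cross
#' species (expression levels are conserved; only the differential labels
#' differ). The cross-species table contains only genes present in the last
#' reference species; focal-only orphans are therefore untestable in the
#' cross species, as in a real cross-species exclusion filter.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_dataset`; see Details in the package
#'   vignette. Key elements: `refs` (a `reference_set`), `counts_focal`,
#'   `counts_cross`, `reads`, `origins`, `proteins`, `protein_truth`,
#'   `annotation`, `channels`, `truth` (labels, planted candidates,
#'   entity map).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  refs <- simulate_references(config)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  entity <- setNames(refs$truth$entity$entity, refs$truth$entity$gene)
  cross_sp <- sprintf("sp%d", config$n_species)
  cross_genes <- unique(
    refs$gene_model$gene[refs$gene_model$species == cross_sp])

  lab <- with_seed(derive_seed(config$seed, "labels"), {
    focal <- draw_de_labels(genes, config$de_fraction)
    cross <- draw_de_labels(cross_genes, config$de_fraction_cross)
    tm <- runif(length(genes)) < config$tm_fraction
    sp <- runif(length(genes)) < config$sp_fraction
    channel <- runif(length(genes)) < config$channel_fraction
    names(tm) <- names(sp) <- names(channel) <- genes

    # plant full-cascade candidates: focal-enriched, cross-null, TM, channel
    flab <- setNames(focal$label, focal$gene)
    clab <- setNames(cross$label, cross$gene)
    planted <- character(0)
    for (dir in TISSUES) {
      pool <- genes[flab == dir & genes %in% cross_genes]
      pick <- head(sample(pool), config$n_planted_channels)
      clab[pick] <- "null"
      tm[pick] <- TRUE
      channel[pick] <- TRUE
      planted <- c(planted, pick)
    }
    cross$label <- unname(clab[cross$gene])
    list(focal = focal, cross = cross, tm = tm, sp = sp,
         channel = channel, planted = planted)
  })

  rho <- with_seed(derive_seed(config$seed, "expression"),
                   setNames(stats::rlnorm(length(genes), 0, config$expr_sdlog),
                            genes))

  cf <- simulate_counts(config, genes = genes, labels = lab$focal, rho = rho,
                        n_replicates = config$n_replicates,
                        seed_stage = "counts_focal")
  cc <- simulate_counts(config, genes = cross_genes,
                        labels = lab$cross, rho = rho[cross_genes],
                        n_replicates = config$n_replicates_cross,
                        seed_stage = "counts_cross")

  rd <- simulate_reads(cf$counts, refs$focal, config)

  prot <- simulate_proteins(config, ids = unname(entity[genes]),
                            tm = unname(lab$tm[genes]),
                            sp = unname(lab$sp[genes]))

  ann <- with_seed(derive_seed(config$seed, "annotations"), {
    category <- ifelse(lab$channel[genes], "ion channel",
                       sample(ANNOTATION_CATEGORIES, length(genes),
                              replace = TRUE))
    covered <- runif(length(genes)) < config$annotation_coverage
    conductance <- sample(CONDUCTANCE_CLASSES, length(genes), replace = TRUE)
    list(annotation = data.frame(gene = unname(entity[genes[covered]]),
                                 category = category[covered],
                                 stringsAsFactors = FALSE),
         channels = data.frame(gene = unname(entity[genes[lab$channel]]),
                               is_channel = TRUE,
                               conductance = conductance[lab$channel[genes]],
                               stringsAsFactors = FALSE))
  })

  flab <- setNames(lab$focal$label, lab$focal$gene)
  clab <- setNames(lab$cross$label, lab$cross$gene)
  cross_null <- !(genes %in% cross_genes) | clab[genes] == "null"
  cross_null[is.na(cross_null)] <- TRUE
  is_cand <- flab[genes] != "null" & lab$tm[genes] & lab$channel[genes] &
    cross_null
  candidates <- data.frame(gene = genes[is_cand],
                           entity = unname(entity[genes[is_cand]]),
                           direction = unname(flab[genes[is_cand]]),
                           stringsAsFactors = FALSE)

  out <- list(
    config = config,
    refs = refs,
    counts_focal = cf$counts,
    counts_cross = cc$counts,
    reads = rd$reads,
    origins = rd$origins,
    proteins = prot$proteins,
    protein_truth = prot$truth,
    annotation = ann$annotation,
    channels = ann$channels,
    truth = list(
      de_labels = lab$focal,
      cross_de_labels = lab$cross,
      tm_flag = lab$tm,
      sp_flag = lab$sp,
      channel_flag = lab$channel,
      planted = lab$planted,
      candidates = candidates,
      entity = refs$truth$entity,
      orphans = refs$truth$orphans))
  class(out) <- "sim_dataset"
  out
}

ANNOTATION_CATEGORIES <- c(
  "receptor", "transporter", "enzyme", "cytoskeleton",
  "vesicle trafficking", "myelin", "transcription factor",
  "cell adhesion", "extracellular matrix", "unknown function")

CONDUCTANCE_CLASSES <- c("Na+", "K+", "Ca2+", "Cl-", "nonselective cation")

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", x$config$n_genes, "genes,",
      length(x$reads), "focal samples,",
      sum(vapply(x$reads, length, integer(1))), "reads,",
      nrow(x$truth$candidates), "ground-truth cascade candidates\n")
  invisible(x)
}
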