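#' Configuration for the synthetic ground-truth generator
#'
#' Bundles every knob of the synthetic study: a focal-species ("mole-like")
#' transcriptome with no usable reference of its own, an ordered set of
#' related reference transcriptomes it can be mapped against, negative
#' binomial counts for two ganglia (TG, DRG) with a planted fraction of
#' enriched genes, single-end reads drawn from the focal transcriptome, and
#' proteins with planted transmembrane helices and signal peptides.
#'
#' Defaults encode the study conditions the pipeline is meant to emulate:
#' three mappable reference species each diverged 3% per site from the focal
#' transcriptome, 50 bp single-end reads at 1% sequencing error, three focal
#' replicates per ganglion and two for the cross-check ("mouse-like")
#' species, 4-fold planted enrichment, and NB dispersion 0.1.
#'
#' @param seed integer global seed; all stages derive child seeds from it.
#' @param n_genes number of ancestral genes.
#' @param transcripts_per_gene isoforms per gene.
#' @param transcript_len transcript length in bases.
#' @param n_species number of reference transcriptomes (mapping stages).
#' @param species_divergence per-site substitution probability between the
#'   focal transcriptome and each reference; recycled to `n_species`.
#' @param orphan_fraction fraction of genes present in only one reference
#'   species (and in no homology cluster).
#' @param read_len single-end read length, bases.
#' @param seq_error per-base sequencing error probability.
#' @param depth expected reads per sample for a library of null genes.
#' @param n_replicates focal-species replicates per ganglion.
#' @param n_replicates_cross cross-species replicates per ganglion.
#' @param de_fraction fraction of genes differentially expressed in the focal
#'   species (split evenly between TG- and DRG-enriched).
#' @param de_fraction_cross same, for the independent cross-species labels.
#' @param de_fold true fold change of enriched genes.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param expr_sdlog log-normal spread of per-gene relative expression.
#' @param protein_len protein length, residues.
#' @param tm_fraction fraction of proteins given planted TM helices.
#' @param sp_fraction fraction of proteins given planted signal peptides.
#' @param channel_fraction fraction of genes flagged as ion channels.
#' @param annotation_coverage fraction of genes covered by the category
#'   annotation table (the rest tally as "unannotated").
#' @param n_planted_channels per direction, number of genes deliberately
#'   planted to satisfy the full candidate cascade (enriched in the focal
#'   species, null in the cross species, membrane, channel).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 250L,
                       transcripts_per_gene = 2L,
                       transcript_len = 500L,
                       n_species = 3L,
                       species_divergence = 0.03,
                       orphan_fraction = 0.1,
                       read_len = 50L,
                       seq_error = 0.01,
                       depth = 8000L,
                       n_replicates = 3L,
                       n_replicates_cross = 2L,
                       de_fraction = 0.2,
                       de_fraction_cross = 0.2,
                       de_fold = 4,
                       dispersion = 0.1,
                       expr_sdlog = 0.6,
                       protein_len = 300L,
                       tm_fraction = 0.3,
                       sp_fraction = 0.2,
                       channel_fraction = 0.15,
                       annotation_coverage = 0.9,
                       n_planted_channels = 12L) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    transcripts_per_gene = as.integer(transcripts_per_gene),
    transcript_len = as.integer(transcript_len),
    n_species = as.integer(n_species),
    species_divergence = rep_len(as.numeric(species_divergence),
                                 as.integer(n_species)),
    orphan_fraction = as.numeric(orphan_fraction),
    read_len = as.integer(read_len),
    seq_error = as.numeric(seq_error),
    depth = as.numeric(depth),
    n_replicates = as.integer(n_replicates),
    n_replicates_cross = as.integer(n_replicates_cross),
    de_fraction = as.numeric(de_fraction),
    de_fraction_cross = as.numeric(de_fraction_cross),
    de_fold = as.numeric(de_fold),
    dispersion = as.numeric(dispersion),
    expr_sdlog = as.numeric(expr_sdlog),
    protein_len = as.integer(protein_len),
    tm_fraction = as.numeric(tm_fraction),
    sp_fraction = as.numeric(sp_fraction),
    channel_fraction = as.numeric(channel_fraction),
    annotation_coverage = as.numeric(annotation_coverage),
    n_planted_channels = as.integer(n_planted_channels)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$species_divergence, cfg$orphan_fraction, cfg$seq_error,
             cfg$de_fraction, cfg$de_fraction_cross, cfg$tm_fraction,
             cfg$sp_fraction, cfg$channel_fraction, cfg$annotation_coverage)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (any(cfg$species_divergence > 0.75))
    stop("species_divergence > 0.75: the uniform substitution model is ",
         "degenerate beyond 3/4")
  counts <- c(cfg$n_genes, cfg$transcripts_per_gene, cfg$transcript_len,
              cfg$n_species, cfg$read_len, cfg$n_replicates,
              cfg$n_replicates_cross, cfg$protein_len)
  if (any(counts <= 0)) stop("counts and lengths must be positive")
  if (cfg$depth < 0) stop("depth must be non-negative")
  if (cfg$dispersion < 0) stop("NB dispersion must be >= 0")
  if (cfg$de_fold <= 0) stop("de_fold must be positive")
  if (cfg$read_len > cfg$transcript_len)
    stop("read_len exceeds transcript_len")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes x", x$transcripts_per_gene,
      "isoforms,", x$n_species, "reference species (divergence",
      paste(x$species_divergence, collapse = "/"), ")\n")
  cat("  reads:", x$read_len, "bp, error", x$seq_error,
      ", depth", x$depth, "per sample\n")
  cat("  design:", x$n_replicates, "v", x$n_replicates,
      "(focal),", x$n_replicates_cross, "v", x$n_replicates_cross,
      "(cross); de_fraction", x$de_fraction, "fold", x$de_fold,
      "dispersion", x$dispersion, "\n")
  invisible(x)
}

# Tissue labels used throughout: the two somatosensory ganglia contrasted.
TISSUES <- c("TG", "DRG")
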