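#' Simulate negative-binomial gene counts for a two-ganglion design
#'
#' Draws a gene x sample integer count matrix under the NB model the
#' differential-expression test assumes: counts ~ NB(mu, variance
#' mu + alpha * mu^2), with mu = depth x (relative expression) and the
#' planted fold change applied to enriched genes in their ganglion.
#'
#' When `labels`, `rho` or `genes` are not supplied they are drawn from the
#' configuration: per-gene relative expression is log-normal with spread
#' `expr_sdlog`, and a `de_fraction` of genes is enriched (half toward each
#' ganglion, at fold `de_fold`).
#'
#' @param config a [sim_config()].
#' @param genes character vector of gene ids (default `g0001`...).
#' @param labels optional data.frame `(gene, label)` with label in
#'   `"TG"`, `"DRG"`, `"null"`.
#' @param rho optional named per-gene relative expression (normalized to sum
#'   to 1 internally).
#' @param n_replicates replicates per ganglion (default from config).
#' @param depth expected null-library size (default from config).
#' @param seed_stage stage name used for seed derivation, so the focal and
#'   cross-species tables draw independent streams.
#' @return list with `counts` (integer matrix, genes x samples, with a
#'   `tissue` attribute naming each sample's ganglion) and `labels`.
#' @export
simulate_counts <- function(config, genes = NULL, labels = NULL, rho = NULL,
                            n_replicates = config$n_replicates,
                            depth = config$depth,
                            seed_stage = "counts") {
  validate_sim_config(config)
  if (n_replicates < 2) stop("need >= 2 replicates per condition")
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(config$n_genes))
  with_seed(derive_seed(config$seed, seed_stage), {
    if (is.null(labels)) labels <- draw_de_labels(genes, config$de_fraction)
    if (is.null(rho)) {
      rho <- stats::rlnorm(length(genes), meanlog = 0,
                           sdlog = config$expr_sdlog)
      names(rho) <- genes
    }
    rho <- rho[genes] / sum(rho[genes])

    tissue <- rep(TISSUES, each = n_replicates)
    samples <- paste0(tissue, "_", rep(seq_len(n_replicates), times = 2))
    lab <- setNames(labels$label, labels$gene)[genes]

    mu <- outer(depth * rho, rep(1, length(samples)))
    for (j in seq_along(samples))
      mu[lab == tissue[j], j] <- mu[lab == tissue[j], j] * config$de_fold

    counts <- draw_nb(mu, config$dispersion)
    dimnames(counts) <- list(genes, samples)
    attr(counts, "tissue") <- setNames(tissue, samples)
    list(counts = counts, labels = labels)
  })
}

draw_de_labels <- function(genes, de_fraction) {
  n_de <- round(de_fraction * length(genes))
  de <- if (n_de > 0) sample(genes, n_de) else character(0)
  lab <- setNames(rep("null", length(genes)), genes)
  half <- floor(n_de / 2)
  lab[de[seq_len(half)]] <- "TG"
  lab[de[setdiff(seq_len(n_de), seq_len(half))]] <- "DRG"
  data.frame(gene = genes, label = unname(lab[genes]),
             stringsAsFactors = FALSE)
}

# NB draws at matrix mu; alpha = 0 degenerates to Poisson.
draw_nb <- function(mu, alpha) {
  if (alpha < 0) stop("NB dispersion must be >= 0")
  n <- length(mu)
  x <- if (alpha == 0) rpois(n, lambda = as.vector(mu))
       else rnbinom(n, mu = as.vector(mu), size = 1 / alpha)
  matrix(as.integer(x), nrow = nrow(mu))
}
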