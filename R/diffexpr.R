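#' Median-of-ratios size factors
#'
#' For sample `j`, the size factor is the median over genes (restricted to
#' genes with a positive count in every sample) of the ratio of the gene's
#' count in `j` to the gene's geometric mean across samples. This is the
#' classic count-based normalization for comparing libraries of different
#' depth under the assumption that most genes are not differentially
#' expressed.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return named positive numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has a positive count in every sample; filter or ",
         "aggregate counts before normalization")
  k <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(k)))   # per-gene geometric mean across samples
  sf <- apply(k / geo, 2, median)
  setNames(sf, colnames(counts))
}

#' Method-of-moments NB dispersion with a parametric trend
#'
#' Raw per-gene dispersions come from the method of moments on normalized
#' counts pooled within conditions: `alpha_i = max(0, (v_i - mu_i) / mu_i^2)`
#' where `v_i` is the mean within-condition sample variance and `mu_i` the
#' overall mean. A parametric trend `alpha(mu) = a0 + a1/mu` is fitted by
#' least squares over genes with positive raw dispersion, and the final
#' dispersion is the conservative `max(raw, trend(mu_i), alpha_min)` — a
#' closed-form analogue of the shared-information max-rule used by NB
#' differential-expression packages.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors from [estimate_size_factors()].
#' @param condition factor/character of length `ncol(counts)`; at least one
#'   condition needs >= 2 replicates.
#' @param alpha_min dispersion floor (default 1e-8).
#' @return list of class `dispersion_model`: `raw`, `fitted`, `final`
#'   (per-gene), `trend` (`a0`, `a1`), `mu` (per-gene normalized mean).
#' @export
estimate_dispersions <- function(counts, size_factors, condition,
                                 alpha_min = 1e-8) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (length(condition) != ncol(counts))
    stop("condition length must match the number of samples")
  reps <- table(condition)
  if (!any(reps >= 2)) stop("need >= 2 replicates in at least one condition")
  q <- sweep(counts, 2, size_factors, "/")
  mu <- rowMeans(q)

  use <- levels(condition)[reps >= 2]
  vlist <- vapply(use, function(cc)
    apply(q[, condition == cc, drop = FALSE], 1, var), numeric(nrow(q)))
  v <- if (is.matrix(vlist)) rowMeans(vlist) else vlist
  if (all(v == 0, na.rm = TRUE)) stop("all genes have zero variance")

  raw <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  fit_genes <- which(raw > 0 & mu > 0)
  trend <- c(a0 = alpha_min, a1 = 0)
  if (length(fit_genes) >= 2 &&
      length(unique(round(1 / mu[fit_genes], 12))) >= 2) {
    fit <- tryCatch(lm(raw[fit_genes] ~ I(1 / mu[fit_genes])),
                    error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(coef(fit))))
      trend <- c(a0 = unname(coef(fit)[1]), a1 = unname(coef(fit)[2]))
  } else if (length(fit_genes) >= 1) {
    trend <- c(a0 = mean(raw[fit_genes]), a1 = 0)
  }
  fitted <- ifelse(mu > 0, trend[["a0"]] + trend[["a1"]] / mu, alpha_min)
  final <- pmax(raw, fitted, alpha_min)
  structure(list(raw = raw, fitted = fitted, final = final,
                 trend = trend, mu = mu, alpha_min = alpha_min),
            class = "dispersion_model")
}

#' Two-sided NB exact test on condition totals
#'
#' Conditions on the observed overall total `K = k_A + k_B` and sums, over
#' all splits `(a, b)` with `a + b = K`, the joint NB probabilities no
#' larger than that of the observed split, normalized by the total over all
#' splits. Each condition total is modelled as a single NB whose mean is the
#' pooled normalized mean times the condition's summed size factors and
#' whose variance adds the dispersion term `alpha * q0^2 * sum(s_j^2)`
#' (moment-matching the sum of the per-sample NBs). As `alpha -> 0` the
#' test converges to the binomial-conditional (Poisson exact) test.
#'
#' @param k named/unnamed integer vector of one gene's counts across samples.
#' @param size_factors per-sample size factors.
#' @param alpha NB dispersion for this gene.
#' @param condition two-level factor/character over the samples.
#' @return two-sided p-value in `[0, 1]` (1 when `K = 0`).
#' @export
nb_exact_test <- function(k, size_factors, alpha, condition) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("exact test needs exactly two conditions")
  A <- condition == levels(condition)[1]
  kA <- sum(k[A]); kB <- sum(k[!A])
  K <- kA + kB
  if (K == 0) return(1)
  sA <- size_factors[A]; sB <- size_factors[!A]
  q0 <- K / sum(size_factors)
  mA <- q0 * sum(sA); mB <- q0 * sum(sB)
  vA <- mA + alpha * q0^2 * sum(sA^2)
  vB <- mB + alpha * q0^2 * sum(sB^2)
  a <- 0:K
  pr <- dcount(a, mA, vA) * dcount(K - a, mB, vB)
  tot <- sum(pr)
  if (tot == 0) return(1)
  pobs <- pr[kA + 1]
  # relative tie tolerance: splits mathematically tied with the observed one
  # must be included regardless of last-ulp rounding differences
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]) / tot)
}

# NB pmf parameterized by mean and variance; degenerates to Poisson when
# the variance does not exceed the mean (within rounding).
dcount <- function(x, mean, varv) {
  if (mean <= 0) return(ifelse(x == 0, 1, 0))
  if (varv <= mean * (1 + 1e-12)) return(dpois(x, lambda = mean))
  size <- mean^2 / (varv - mean)
  dnbinom(x, mu = mean, size = size)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `p_adj(i) = min_{j >= i} min(1, m * p_(j) / j)`
#' over the `m` sorted p-values.
#'
#' @param p numeric vector of p-values.
#' @return vector of adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-condition differential expression on a collapsed count table
#'
#' Runs the full from-scratch pipeline: median-of-ratios size factors,
#' method-of-moments dispersions with the parametric-trend max rule, a
#' per-gene two-sided NB exact test, and Benjamini-Hochberg adjustment over
#' all tested genes. Genes with zero total count are excluded before testing
#' (and from the BH denominator). The fold change is
#' `(normalized mean of condition 2) / (normalized mean of condition 1)`
#' with a +0.5 pseudocount applied to both means when either is zero; it is
#' reported but never thresholded — enrichment calls use `padj` only.
#'
#' @param counts integer matrix, genes x samples.
#' @param condition two-level factor over samples; the first level is the
#'   reference (fold changes are level2 / level1).
#' @param threshold adjusted-p significance threshold (default 0.05,
#'   inclusive).
#' @param alpha_min dispersion floor.
#' @return data.frame of class `de_result`: `gene, base_mean, fold_change,
#'   log2fc, pval, padj, enriched_in` (`enriched_in` is the condition name
#'   or `"none"`). Attributes: `size_factors`, `dispersion`, `conditions`,
#'   `threshold`.
#' @export
run_de <- function(counts, condition, threshold = 0.05, alpha_min = 1e-8) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("need exactly two conditions")
  lev <- levels(condition)
  sf <- estimate_size_factors(counts)
  keep <- rowSums(counts) > 0
  k <- counts[keep, , drop = FALSE]
  disp <- estimate_dispersions(k, sf, condition, alpha_min = alpha_min)
  q <- sweep(k, 2, sf, "/")
  mean1 <- rowMeans(q[, condition == lev[1], drop = FALSE])
  mean2 <- rowMeans(q[, condition == lev[2], drop = FALSE])
  zero <- mean1 == 0 | mean2 == 0
  fc <- ifelse(zero, (mean2 + 0.5) / (mean1 + 0.5), mean2 / mean1)
  pval <- vapply(seq_len(nrow(k)), function(i)
    nb_exact_test(k[i, ], sf, disp$final[i], condition), numeric(1))
  padj <- bh_adjust(pval)
  enriched <- ifelse(padj <= threshold & fc > 1, lev[2],
                     ifelse(padj <= threshold & fc < 1, lev[1], "none"))
  out <- data.frame(gene = rownames(k), base_mean = rowMeans(q),
                    fold_change = fc, log2fc = log2(fc), pval = pval,
                    padj = padj, enriched_in = enriched,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "size_factors") <- sf
  attr(out, "dispersion") <- disp
  attr(out, "conditions") <- lev
  attr(out, "threshold") <- threshold
  class(out) <- c("de_result", "data.frame")
  out
}
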