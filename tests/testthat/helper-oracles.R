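# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: alignment by exhaustive all-position scanning through
# Biostrings, normalization/BH/exact-test by direct transcription of the
# defining formulas.

# Exhaustive Hamming scan of one read against every position and strand of
# every transcript. Returns the global minimum distance and whether any
# locus is within budget.
oracle_scan <- function(read, ref_seqs, budget) {
  L <- nchar(read)
  best <- Inf
  pat_f <- Biostrings::DNAString(read)
  pat_r <- Biostrings::reverseComplement(pat_f)
  for (s in ref_seqs) {
    subj <- Biostrings::DNAString(s)
    n <- nchar(s)
    if (n < L) next
    starts <- seq_len(n - L + 1)
    for (pat in list(pat_f, pat_r)) {
      d <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                       with.indels = FALSE)
      best <- min(best, min(d))
    }
  }
  list(min_dist = best, mapped = is.finite(best) && best <= budget)
}

# Median-of-ratios, written as the formula reads: per gene the geometric
# mean across samples, per sample the median ratio over all-positive genes.
oracle_size_factors <- function(counts) {
  m <- ncol(counts)
  keep <- apply(counts, 1, function(r) all(r > 0))
  k <- counts[keep, , drop = FALSE]
  geo <- apply(k, 1, function(r) prod(r)^(1 / m))
  out <- numeric(m)
  for (j in seq_len(m)) out[j] <- median(k[, j] / geo)
  setNames(out, colnames(counts))
}

# Benjamini-Hochberg by the direct definition: for each p_i with rank r_i,
# the minimum over all j with rank >= r_i of min(1, m * p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  out <- numeric(m)
  ord <- order(p)
  for (i in seq_len(m)) {
    js <- which(seq_len(m) >= r[i])
    out[i] <- min(1, min(m * p[ord][js] / js))
  }
  out
}

# NB exact test by exhaustive split enumeration in log space, using the
# (size, prob) parameterization and lgamma arithmetic rather than dnbinom.
oracle_exact_p <- function(k, size_factors, alpha, condition) {
  condition <- as.factor(condition)
  A <- condition == levels(condition)[1]
  kA <- sum(k[A]); kB <- sum(k[!A]); K <- kA + kB
  if (K == 0) return(1)
  sA <- size_factors[A]; sB <- size_factors[!A]
  q0 <- K / sum(size_factors)
  lp_one <- function(x, mean, varv) {
    if (varv <= mean * (1 + 1e-12)) return(x * log(mean) - mean - lgamma(x + 1))
    r <- mean^2 / (varv - mean)
    pr <- r / (r + mean)
    lgamma(x + r) - lgamma(r) - lgamma(x + 1) + r * log(pr) +
      x * log(1 - pr)
  }
  mA <- q0 * sum(sA); mB <- q0 * sum(sB)
  vA <- mA + alpha * q0^2 * sum(sA^2)
  vB <- mB + alpha * q0^2 * sum(sB^2)
  a <- 0:K
  lp <- vapply(a, function(x) lp_one(x, mA, vA) + lp_one(K - x, mB, vB),
               numeric(1))
  pr <- exp(lp - max(lp))
  pobs <- pr[kA + 1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]) / sum(pr))
}

# Direct group-by recomputation of a count aggregation.
oracle_groupby <- function(values, groups) {
  tapply(values, groups, sum)
}

# Random DNA / hydrophilic protein helpers for fixtures.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
parse_ids_for_test <- function(nm)
  vapply(strsplit(nm, "|", fixed = TRUE), `[[`, "", 2L)
hydrophilic_stretch <- function(n)
  paste(rep(c("D", "E", "K", "N", "S", "T", "Q", "R"), length.out = n),
        collapse = "")
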