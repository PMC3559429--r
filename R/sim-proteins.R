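#' Simulate proteins with planted transmembrane helices and signal peptides
#'
#' Background residues are drawn from a hydrophilic-biased composition, so a
#' random protein almost never contains a membrane-like stretch. Planted TM
#' segments are 19-23-mers drawn from a hydrophobic-biased composition (1-3
#' per TM protein, placed after residue 45 with >= 20-residue spacing).
#' Planted signal peptides follow the classical architecture: Met, an
#' n-region of 2-4 residues containing a positive charge, a hydrophobic
#' h-region of 9-12 residues, and a short polar c-region ending in an
#' A-X-A motif, with the cleavage site inside the first 35 residues.
#'
#' @param config a [sim_config()].
#' @param ids protein ids (default `g0001`... matching the gene universe).
#' @param tm optional logical vector: which proteins get planted TM helices
#'   (default: Bernoulli `tm_fraction`).
#' @param sp optional logical vector for signal peptides (default:
#'   Bernoulli `sp_fraction`).
#' @return list with `proteins` ([Biostrings::AAStringSet]) and `truth`
#'   (list `tm`: per-protein data.frame of 0-based half-open `(start, end)`
#'   segments; `sp`: named integer cleavage positions, `NA` when absent).
#' @export
simulate_proteins <- function(config, ids = NULL, tm = NULL, sp = NULL) {
  validate_sim_config(config)
  if (is.null(ids)) ids <- sprintf("g%04d", seq_len(config$n_genes))
  n <- length(ids)
  with_seed(derive_seed(config$seed, "proteins"), {
    if (is.null(tm)) tm <- runif(n) < config$tm_fraction
    if (is.null(sp)) sp <- runif(n) < config$sp_fraction
    len <- config$protein_len

    seqs <- character(n)
    tm_truth <- vector("list", n)
    sp_truth <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      x <- sample(names(BG_AA_FREQ), len, replace = TRUE, prob = BG_AA_FREQ)
      if (sp[i]) {
        pre <- build_signal_peptide()
        x[seq_along(pre)] <- pre
        sp_truth[i] <- length(pre)  # 0-based index of first mature residue
      }
      segs <- NULL
      if (tm[i]) {
        n_seg <- sample.int(3L, 1L)
        starts <- integer(0)
        for (s in seq_len(n_seg)) {
          st <- 45L + (s - 1L) * 60L + sample.int(21L, 1L) - 1L
          sl <- sample(19:23, 1L)
          if (st + sl + 5L > len) break
          x[(st + 1):(st + sl)] <- sample(names(TM_AA_FREQ), sl,
                                          replace = TRUE, prob = TM_AA_FREQ)
          starts <- c(starts, st)
          segs <- rbind(segs, c(st, st + sl))
        }
      }
      tm_truth[[i]] <- if (is.null(segs)) {
        data.frame(start = integer(0), end = integer(0))
      } else {
        data.frame(start = as.integer(segs[, 1]), end = as.integer(segs[, 2]))
      }
      seqs[i] <- paste(x, collapse = "")
    }
    proteins <- Biostrings::AAStringSet(setNames(seqs, ids))
    names(tm_truth) <- ids
    names(sp_truth) <- ids
    list(proteins = proteins,
         truth = list(tm = tm_truth, sp = sp_truth))
  })
}

# Hydrophilic-biased background composition (soluble-protein-like, with
# hydrophobics downweighted so random 19-mers essentially never look TM).
BG_AA_FREQ <- c(A = 0.06, C = 0.01, D = 0.08, E = 0.09, F = 0.02,
                G = 0.07, H = 0.03, I = 0.02, K = 0.09, L = 0.04,
                M = 0.01, N = 0.06, P = 0.06, Q = 0.06, R = 0.07,
                S = 0.09, T = 0.07, V = 0.03, W = 0.01, Y = 0.03)

# Hydrophobic-biased composition for planted membrane-spanning segments.
TM_AA_FREQ <- c(L = 0.28, I = 0.18, V = 0.18, F = 0.12,
                A = 0.10, M = 0.08, W = 0.03, C = 0.03)

# Met + n-region (2-4, one K/R guaranteed in the first positions) +
# h-region (9-12 hydrophobic) + polar c-region ending A-X-A; total 15-22
# residues, so the cleavage site always falls in [15, 35].
build_signal_peptide <- function() {
  n_len <- sample(2:4, 1L)
  n_reg <- sample(c("K", "R", "N", "S", "T"), n_len, replace = TRUE)
  n_reg[1] <- sample(c("K", "R"), 1L)
  h_len <- sample(9:12, 1L)
  h_reg <- sample(c("L", "I", "V", "F", "A"), h_len, replace = TRUE,
                  prob = c(0.35, 0.2, 0.2, 0.15, 0.1))
  c_mid <- sample(c("S", "T", "N", "Q", "G"), 1L)
  pre <- c("M", n_reg, h_reg, "A", c_mid, "A")
  if (length(pre) < 15) pre <- c("M", n_reg, h_reg,
                                 rep("S", 15 - length(pre)), "A", c_mid, "A")
  pre
}
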