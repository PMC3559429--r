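#' Heuristic signal-peptide trimming
#'
#' A signal peptide is called iff, within the first 35 residues: (a) at
#' least one positively charged residue (K/R) occurs in positions 0-5, and
#' (b) a window of >= 8 residues with mean Kyte-Doolittle hydropathy > 1.6
#' starts somewhere in positions 5-25. The cleavage site is the position
#' `c` in residues 15-35 with a small residue (A/G/S) at `c - 1` that
#' maximizes the mean hydropathy of the 8 residues preceding `c` (the
#' h-region should immediately precede the cleavage site); ties take the
#' smallest `c`, and if no eligible position exists the default is 25.
#' Proteins shorter than 40 residues are never called.
#'
#' All coordinates are 0-based; the returned `cleavage` is the index of the
#' first mature residue.
#'
#' @param protein one amino-acid sequence (character string).
#' @return list: `sp_called` (logical), `cleavage` (integer, 0 if no SP),
#'   `trimmed` (mature sequence).
#' @export
trim_signal_peptide <- function(protein) {
  protein <- toupper(as.character(protein))
  n <- nchar(protein)
  no_sp <- list(sp_called = FALSE, cleavage = 0L, trimmed = protein)
  if (n < 40) return(no_sp)
  kd <- residue_hydropathy(protein, kd_hydropathy())
  head36 <- substring(protein, 1, 36)
  aa <- strsplit(head36, "", fixed = TRUE)[[1]]

  has_positive <- any(aa[1:6] %in% c("K", "R"))
  if (!has_positive) return(no_sp)

  # windows of length >= 8 reduce to: some 8-window starting in 5..25
  # (0-based) with mean KD > 1.6 -- a longer qualifying window contains one
  starts <- 5:25
  win_ok <- vapply(starts, function(s0)
    mean(kd[(s0 + 1):(s0 + 8)]) > 1.6, logical(1))
  if (!any(win_ok)) return(no_sp)

  cand <- 15:35
  small <- aa[cand] %in% c("A", "G", "S")   # residue at position c-1 is aa[c]
  cand <- cand[small]
  cleavage <- if (length(cand) == 0) 25L else {
    score <- vapply(cand, function(cc) mean(kd[(cc - 7):cc]), numeric(1))
    as.integer(cand[which.max(score)])
  }
  list(sp_called = TRUE, cleavage = cleavage,
       trimmed = substring(protein, cleavage + 1, n))
}

# Merge overlapping/adjacent qualifying window start positions into segments
# [start, start + w) and cap each merged segment at max_len residues.
merge_windows <- function(ok_starts, w, max_len = 35L) {
  if (length(ok_starts) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  # two qualifying windows overlap (or touch) iff their starts differ by <= w
  runs <- split(ok_starts, cumsum(c(1, diff(ok_starts) > w)))
  segs <- lapply(runs, function(r) {
    st <- r[1]
    en <- r[length(r)] + w
    c(st, min(en, st + max_len))
  })
  m <- do.call(rbind, segs)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

#' TM predictor 1: sliding-window Kyte-Doolittle hydropathy
#'
#' 19-residue windows whose mean Kyte-Doolittle hydropathy exceeds 1.6
#' qualify; overlapping qualifying windows are merged and merged segments
#' are capped at 35 residues. Coordinates are 0-based half-open.
#'
#' @param protein one amino-acid sequence.
#' @param threshold window-mean hydropathy threshold.
#' @param window window length, residues.
#' @return data.frame `(start, end, score)`; `score` is the maximum window
#'   mean inside the segment.
#' @export
predict_tm_hydropathy <- function(protein, threshold = 1.6, window = 19L) {
  protein <- toupper(as.character(protein))
  n <- nchar(protein)
  if (n < window) return(data.frame(start = integer(0), end = integer(0),
                                    score = numeric(0)))
  kd <- residue_hydropathy(protein, kd_hydropathy())
  wm <- window_means(kd, window)
  ok <- which(wm > threshold) - 1L   # 0-based starts
  segs <- merge_windows(ok, window)
  segs$score <- vapply(seq_len(nrow(segs)), function(i) {
    s <- segs$start[i] + 1L
    max(wm[s:min(segs$end[i] - window + 1L, length(wm))])
  }, numeric(1))
  segs
}

#' TM predictor 2: GES hydropathy with an amphiphilicity filter
#'
#' Same windowing as predictor 1 but with 18-residue windows on the GES
#' scale (threshold 1.0); a candidate segment is rejected if its normalized
#' alpha-helical hydrophobic moment exceeds `moment_cap`, excluding
#' amphipathic surface helices that are hydrophobic on one face only.
#'
#' @inheritParams predict_tm_hydropathy
#' @param moment_cap maximum allowed normalized hydrophobic moment.
#' @return data.frame `(start, end, score)`; `score` is the segment's
#'   normalized hydrophobic moment (lower = more uniformly hydrophobic).
#' @export
predict_tm_amphiphilic <- function(protein, threshold = 1.0, window = 18L,
                                   moment_cap = 0.35) {
  protein <- toupper(as.character(protein))
  n <- nchar(protein)
  if (n < window) return(data.frame(start = integer(0), end = integer(0),
                                    score = numeric(0)))
  ges <- residue_hydropathy(protein, ges_hydropathy())
  wm <- window_means(ges, window)
  ok <- which(wm > threshold) - 1L
  segs <- merge_windows(ok, window)
  if (nrow(segs) == 0) return(cbind(segs, score = numeric(0)))
  segs$score <- vapply(seq_len(nrow(segs)), function(i)
    hydrophobic_moment(substring(protein, segs$start[i] + 1, segs$end[i])),
    numeric(1))
  segs[segs$score <= moment_cap, , drop = FALSE]
}

window_means <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' TM predictor 3: two-state Viterbi decoding
#'
#' A two-state (membrane/loop) model with fixed emissions — membrane
#' emissions proportional to `exp(KD/2)`, loop emissions proportional to
#' `exp(-KD/4)` (a mildly hydrophilic-biased near-uniform distribution) —
#' and fixed transitions (self-transition 0.95, initial loop probability
#' 0.95). The most probable state path is decoded and membrane runs of at
#' least `min_len` residues are reported.
#'
#' @param protein one amino-acid sequence.
#' @param min_len minimum reported membrane run, residues.
#' @param self_transition probability of staying in the current state.
#' @return data.frame `(start, end, score)`; `score` is the run's mean
#'   membrane-vs-loop log emission odds.
#' @export
predict_tm_hmm <- function(protein, min_len = 15L, self_transition = 0.95) {
  protein <- toupper(as.character(protein))
  n <- nchar(protein)
  if (n < min_len) return(data.frame(start = integer(0), end = integer(0),
                                     score = numeric(0)))
  path <- viterbi_two_state(protein, self_transition)
  runs <- rle(path)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values == "M" & runs$lengths >= min_len
  if (!any(keep)) return(data.frame(start = integer(0), end = integer(0),
                                    score = numeric(0)))
  lo <- tm_hmm_log_odds(protein)
  data.frame(start = as.integer(starts[keep]),
             end = as.integer(ends[keep]),
             score = vapply(which(keep), function(i)
               mean(lo[(starts[i] + 1):ends[i]]), numeric(1)))
}

tm_hmm_emissions <- function() {
  kd <- kd_hydropathy()[1:20]
  list(M = log(exp(kd / 2) / sum(exp(kd / 2))),
       L = log(exp(-kd / 4) / sum(exp(-kd / 4))))
}

tm_hmm_log_odds <- function(protein) {
  em <- tm_hmm_emissions()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  lm <- em$M[aa]; ll <- em$L[aa]
  lm[is.na(lm)] <- log(1 / 20); ll[is.na(ll)] <- log(1 / 20)
  unname(lm - ll)
}

viterbi_two_state <- function(protein, self_transition = 0.95,
                              init_loop = 0.95) {
  em <- tm_hmm_emissions()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(aa)
  eM <- em$M[aa]; eL <- em$L[aa]
  eM[is.na(eM)] <- log(1 / 20); eL[is.na(eL)] <- log(1 / 20)
  lself <- log(self_transition); lswitch <- log(1 - self_transition)
  vM <- numeric(n); vL <- numeric(n)
  bM <- integer(n); bL <- integer(n)   # backpointer: 1 = from M, 2 = from L
  vM[1] <- log(1 - init_loop) + eM[1]
  vL[1] <- log(init_loop) + eL[1]
  for (i in seq_len(n)[-1]) {
    fromM <- vM[i - 1] + lself; fromL <- vL[i - 1] + lswitch
    if (fromM >= fromL) { vM[i] <- fromM + eM[i]; bM[i] <- 1L }
    else { vM[i] <- fromL + eM[i]; bM[i] <- 2L }
    fromM2 <- vM[i - 1] + lswitch; fromL2 <- vL[i - 1] + lself
    if (fromL2 >= fromM2) { vL[i] <- fromL2 + eL[i]; bL[i] <- 2L }
    else { vL[i] <- fromM2 + eL[i]; bL[i] <- 1L }
  }
  path <- character(n)
  state <- if (vM[n] >= vL[n]) 1L else 2L
  for (i in rev(seq_len(n))) {
    path[i] <- c("M", "L")[state]
    if (i > 1) state <- if (state == 1L) bM[i] else bL[i]
  }
  path
}

#' 2-of-3 membrane vote
#'
#' @param m1,m2,m3 logical: did each predictor report at least one segment?
#' @return list `votes` (0-3) and `is_membrane` (`votes >= 2`).
#' @export
vote_membrane <- function(m1, m2, m3) {
  votes <- as.integer(m1) + as.integer(m2) + as.integer(m3)
  list(votes = votes, is_membrane = votes >= 2L)
}

#' Consensus membrane-protein classification
#'
#' For each protein: trim the predicted signal peptide, run the three
#' independent TM predictors on the mature sequence, and call the protein a
#' membrane protein iff at least two of the three predict at least one
#' transmembrane segment.
#'
#' @param proteins [Biostrings::AAStringSet] or named character vector.
#' @param moment_cap passed to [predict_tm_amphiphilic()].
#' @return data.frame of class `consensus_result`: `protein, sp_trimmed`
#'   (residues removed from the N-terminus, 0 if none), `m1_segments,
#'   m2_segments, m3_segments` (0-based half-open `start-end` lists joined
#'   by `;`, empty string if none), `votes`, `is_membrane`. Segment
#'   coordinates refer to the trimmed sequence.
#' @export
tm_consensus <- function(proteins, moment_cap = 0.35) {
  if (inherits(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  ids <- names(proteins) %||% as.character(seq_along(proteins))
  rows <- lapply(seq_along(proteins), function(i) {
    tr <- trim_signal_peptide(proteins[[i]])
    s1 <- predict_tm_hydropathy(tr$trimmed)
    s2 <- predict_tm_amphiphilic(tr$trimmed, moment_cap = moment_cap)
    s3 <- predict_tm_hmm(tr$trimmed)
    v <- vote_membrane(nrow(s1) > 0, nrow(s2) > 0, nrow(s3) > 0)
    data.frame(protein = ids[i],
               sp_trimmed = if (tr$sp_called) tr$cleavage else 0L,
               m1_segments = format_segments(s1),
               m2_segments = format_segments(s2),
               m3_segments = format_segments(s3),
               votes = v$votes, is_membrane = v$is_membrane,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("consensus_result", "data.frame")
  out
}

format_segments <- function(segs) {
  if (nrow(segs) == 0) return("")
  paste(sprintf("%d-%d", segs$start, segs$end), collapse = ";")
}
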