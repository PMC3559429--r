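#' Amino-acid hydropathy scales
#'
#' Residue-level hydropathy values used by the transmembrane predictors and
#' the signal-peptide trimmer. `kd_hydropathy()` returns the Kyte-Doolittle
#' scale; `ges_hydropathy()` returns the Goldman-Engelman-Steitz (GES)
#' water-to-membrane transfer scale (kcal/mol, hydrophobic positive). The
#' unknown residue `X` scores 0 on both scales.
#'
#' @return a named numeric vector over the 20 amino acids plus `X`.
#' @export
kd_hydropathy <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
    X =  0.0)
}

#' @rdname kd_hydropathy
#' @export
ges_hydropathy <- function() {
  c(F =  3.7, M =  3.4, I =  3.1, L =  2.8, V =  2.6,
    C =  2.0, W =  1.9, A =  1.6, T =  1.2, G =  1.0,
    S =  0.6, P = -0.2, Y = -0.7, H = -3.0, Q = -4.1,
    N = -4.8, E = -8.2, K = -8.8, D = -9.2, R = -12.3,
    X =  0.0)
}

# Per-residue hydropathy of a sequence under a scale; unknown letters score 0.
residue_hydropathy <- function(seq, scale) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  h <- unname(scale[aa])
  h[is.na(h)] <- 0
  h
}

#' Normalized alpha-helical hydrophobic moment
#'
#' Eisenberg-style hydrophobic moment of a residue stretch at helical
#' periodicity (100 degrees per residue), normalized by the summed absolute
#' hydropathies so the value lies in `[0, 1]`. Amphipathic surface helices
#' score high; uniformly hydrophobic membrane-spanning segments score near 0.
#'
#' @param seq character amino-acid sequence (one string).
#' @param scale named hydropathy scale, default GES.
#' @param period helical twist per residue, degrees.
#' @return numeric scalar in `[0, 1]` (0 for an all-zero-hydropathy stretch).
#' @export
hydrophobic_moment <- function(seq, scale = ges_hydropathy(), period = 100) {
  h <- residue_hydropathy(seq, scale)
  if (sum(abs(h)) == 0) return(0)
  ang <- (seq_along(h) - 1) * period * pi / 180
  m <- sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2)
  m / sum(abs(h))
}
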