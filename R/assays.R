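#' Classify a calcium trace as stimulus-responsive
#'
#' A cell is responsive iff the maximum of the 340/380 ratio over the
#' stimulus window is strictly greater than 1.10 times the mean over the
#' baseline window (an increase of more than 10% above baseline; the
#' boundary case is negative).
#'
#' @param trace numeric vector of ratio values.
#' @param baseline integer indices of the baseline window.
#' @param stimulus integer indices of the stimulus window.
#' @return logical flag.
#' @export
classify_responsive <- function(trace, baseline, stimulus) {
  if (length(baseline) == 0) stop("baseline window is empty")
  if (length(stimulus) == 0) stop("stimulus window is empty")
  if (length(intersect(baseline, stimulus)) > 0)
    stop("baseline and stimulus windows must be disjoint")
  if (max(c(baseline, stimulus)) > length(trace) ||
      min(c(baseline, stimulus)) < 1)
    stop("window indices outside the trace")
  max(trace[stimulus]) > 1.10 * mean(trace[baseline])
}

#' Classify a cell as marker-positive
#'
#' Positive iff the cell's mean intensity is strictly greater than 1.30
#' times the field background (more than 30% above background).
#'
#' @param intensity cell mean intensity (RFU), non-negative.
#' @param background field background intensity (RFU), strictly positive.
#' @return logical vector (vectorized over cells).
#' @export
classify_marker_positive <- function(intensity, background) {
  if (any(background <= 0)) stop("background intensity must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  intensity > 1.30 * background
}

#' Percent positive cells per field, with group mean and s.e.m.
#'
#' Computes the percent of positive cells within each imaging field, then
#' the mean and standard error (sd/sqrt(n) over fields) per group. A group
#' with a single field reports `NA` s.e.m.
#'
#' @param positive logical per-cell flags.
#' @param field field id per cell.
#' @param group optional grouping per cell (e.g. tissue); defaults to one
#'   group. Must be constant within a field.
#' @return data.frame `(group, n_fields, mean_percent, sem_percent)`.
#' @export
summarize_percent_positive <- function(positive, field, group = NULL) {
  if (is.null(group)) group <- rep("all", length(positive))
  stopifnot(length(positive) == length(field),
            length(group) == length(positive))
  g_of_field <- tapply(as.character(group), field,
                       function(g) unique(g))
  if (any(lengths(g_of_field) > 1))
    stop("a field spans multiple groups")
  pct <- tapply(positive, field, function(p) 100 * mean(p))
  grp <- unlist(g_of_field)[names(pct)]
  out <- do.call(rbind, lapply(split(pct, grp), function(v)
    data.frame(n_fields = length(v), mean_percent = mean(v),
               sem_percent = if (length(v) > 1) sd(v) / sqrt(length(v))
                             else NA_real_)))
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' qPCR fold expression under 100% efficiency
#'
#' Per (sample, run, gene), the Ct is the mean over wells; per (sample,
#' run), `dCt = Ct(target) - Ct(reference)`; dCt values are averaged over
#' runs within a sample and then over biological replicates within a
#' tissue; finally `fold(tissue) = 2^(dCt(baseline) - dCt(tissue))` —
#' doubling per cycle, i.e. 100% amplification efficiency.
#'
#' @param records long data.frame `(sample, tissue, run, gene, well, ct)`.
#' @param target target gene name.
#' @param reference reference (housekeeping) gene name.
#' @param baseline_tissue tissue whose fold is 1 by construction.
#' @return data.frame `(tissue, mean_dct, fold)`.
#' @export
qpcr_fold_expression <- function(records, target, reference,
                                 baseline_tissue) {
  need <- c("sample", "tissue", "run", "gene", "well", "ct")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$ct <= 0)) stop("Ct values must be positive")
  if (!all(c(target, reference) %in% records$gene))
    stop("missing target or reference gene in records")
  rec <- records[records$gene %in% c(target, reference), ]

  well_mean <- stats::aggregate(ct ~ sample + tissue + run + gene,
                                data = rec, FUN = mean)
  wide <- merge(
    well_mean[well_mean$gene == target,
              c("sample", "tissue", "run", "ct")],
    well_mean[well_mean$gene == reference,
              c("sample", "tissue", "run", "ct")],
    by = c("sample", "tissue", "run"), suffixes = c("_t", "_r"))
  if (nrow(wide) == 0 ||
      !setequal(unique(rec$sample), unique(wide$sample)))
    stop("reference gene missing for at least one sample/run")
  wide$dct <- wide$ct_t - wide$ct_r
  per_sample <- stats::aggregate(dct ~ sample + tissue, data = wide,
                                 FUN = mean)
  per_tissue <- stats::aggregate(dct ~ tissue, data = per_sample, FUN = mean)
  if (!baseline_tissue %in% per_tissue$tissue)
    stop("baseline tissue not present: ", baseline_tissue)
  base <- per_tissue$dct[per_tissue$tissue == baseline_tissue]
  data.frame(tissue = per_tissue$tissue, mean_dct = per_tissue$dct,
             fold = 2^(base - per_tissue$dct), stringsAsFactors = FALSE)
}
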