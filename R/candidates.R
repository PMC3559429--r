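#' Criteria for the candidate-transducer filter cascade
#'
#' @param padj_threshold adjusted-p significance threshold (inclusive).
#' @param direction which ganglion the candidates must be enriched in.
#' @param require_membrane keep only consensus membrane proteins.
#' @param exclude_cross_de drop genes differentially expressed in the
#'   cross-check species at the same threshold. Genes untested in the cross
#'   species count as not differentially expressed (flagged via
#'   `cross_tested`).
#' @param strict error (rather than warn) when a surviving gene has no
#'   membrane prediction.
#' @return an object of class `filter_criteria`.
#' @export
filter_criteria <- function(padj_threshold = 0.05,
                            direction = c("TG", "DRG"),
                            require_membrane = TRUE,
                            exclude_cross_de = TRUE,
                            strict = FALSE) {
  direction <- match.arg(direction)
  if (padj_threshold <= 0 || padj_threshold >= 1)
    stop("padj_threshold must lie in (0, 1)")
  structure(list(padj_threshold = padj_threshold, direction = direction,
                 require_membrane = require_membrane,
                 exclude_cross_de = exclude_cross_de, strict = strict),
            class = "filter_criteria")
}

#' Genes significantly enriched in one condition
#'
#' The threshold is inclusive (`padj <= threshold`), and the direction is
#' read off the fold change (`> 1` means enriched in the second condition
#' of the contrast).
#'
#' @param de a [run_de()] result (needs `gene`, `padj`, `fold_change`).
#' @param direction condition name; must be one of the contrast's levels
#'   when the DE table carries them.
#' @param threshold inclusive adjusted-p threshold.
#' @return character vector of gene ids.
#' @export
select_enriched <- function(de, direction, threshold = 0.05) {
  lev <- attr(de, "conditions") %||% TISSUES
  if (!direction %in% lev)
    stop("direction must be one of: ", paste(lev, collapse = ", "))
  right_dir <- if (direction == lev[2]) de$fold_change > 1
               else de$fold_change < 1
  sel <- de$padj <= threshold & right_dir
  de$gene[!is.na(sel) & sel]
}

#' Genes enriched in the same direction in both species
#'
#' Plain intersection of harmonized gene sets; identifiers must already be
#' in the shared (cluster-level) namespace, e.g. via [harmonize_genes()].
#'
#' @param focal_set,cross_set character vectors of harmonized gene ids.
#' @return sorted character vector.
#' @export
shared_across_species <- function(focal_set, cross_set) {
  sort(intersect(focal_set, cross_set))
}

#' The candidate-transducer filter cascade
#'
#' Selects genes that are (a) significantly enriched in the requested
#' ganglion in the focal species, (b) not differentially expressed between
#' the cross-check species' ganglia at the same threshold (genes untested
#' there pass, flagged), and (c) predicted membrane proteins by the 2-of-3
#' consensus. Rows are sorted by fold enrichment toward the requested
#' direction, descending, with ties broken by gene id.
#'
#' @param de_focal focal-species [run_de()] table (gene ids in the collapsed
#'   entity namespace).
#' @param de_cross cross-species DE table harmonized to the same namespace,
#'   or `NULL` (every gene then counts as untested).
#' @param membrane a [tm_consensus()] table keyed like the DE genes, or
#'   `NULL` when `require_membrane` is off.
#' @param criteria a [filter_criteria()].
#' @param annotation optional data.frame `(gene, category)` to attach.
#' @param channels optional data.frame `(gene, is_channel, conductance)`.
#' @return data.frame of class `candidate_table`: `gene, direction,
#'   fold_enrichment, log2fc, padj, cross_padj, cross_tested, votes,
#'   is_membrane` plus `category`/`is_channel`/`conductance` when provided.
#' @export
candidate_transducers <- function(de_focal, de_cross = NULL, membrane = NULL,
                                  criteria = filter_criteria(),
                                  annotation = NULL, channels = NULL) {
  thr <- criteria$padj_threshold
  dir <- criteria$direction
  lev <- attr(de_focal, "conditions") %||% TISSUES

  sel <- select_enriched(de_focal, dir, thr)
  tab <- de_focal[de_focal$gene %in% sel, , drop = FALSE]
  # fold enrichment toward the requested direction
  fe <- if (dir == lev[2]) tab$fold_change else 1 / tab$fold_change
  out <- data.frame(gene = tab$gene,
                    direction = rep(dir, nrow(tab)),
                    fold_enrichment = fe, log2fc = tab$log2fc,
                    padj = tab$padj, stringsAsFactors = FALSE)

  if (!is.null(de_cross)) {
    cross_padj <- setNames(de_cross$padj, de_cross$gene)
    out$cross_padj <- unname(cross_padj[out$gene])
  } else {
    out$cross_padj <- rep(NA_real_, nrow(out))
  }
  out$cross_tested <- !is.na(out$cross_padj)
  if (criteria$exclude_cross_de)
    out <- out[!(out$cross_tested & out$cross_padj <= thr), , drop = FALSE]

  out$votes <- rep(NA_integer_, nrow(out))
  out$is_membrane <- rep(NA, nrow(out))
  if (!is.null(membrane)) {
    vmap <- setNames(membrane$votes, membrane$protein)
    mmap <- setNames(membrane$is_membrane, membrane$protein)
    out$votes <- unname(vmap[out$gene])
    out$is_membrane <- unname(mmap[out$gene])
  }
  if (criteria$require_membrane) {
    miss <- is.na(out$is_membrane)
    if (any(miss)) {
      msg <- paste0(sum(miss), " surviving gene(s) have no membrane ",
                    "prediction; kept with votes = NA")
      if (criteria$strict) stop(msg) else warning(msg)
    }
    out <- out[miss | out$is_membrane, , drop = FALSE]
  }

  if (!is.null(annotation)) {
    cat_map <- setNames(annotation$category, annotation$gene)
    out$category <- unname(cat_map[out$gene])
    out$category[is.na(out$category)] <- "unannotated"
  }
  if (!is.null(channels)) {
    ch <- setNames(channels$is_channel, channels$gene)
    cond <- setNames(channels$conductance, channels$gene)
    out$is_channel <- !is.na(ch[out$gene]) & unname(ch[out$gene])
    out$conductance <- unname(cond[out$gene])
  }

  out <- out[order(-out$fold_enrichment, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Tally candidate genes by annotation category
#'
#' Genes missing from the annotation map count as `"unannotated"`; the
#' counts sum to the number of candidates per direction.
#'
#' @param candidates a [candidate_transducers()] table.
#' @param annotation data.frame `(gene, category)`.
#' @return data.frame `(direction, category, n)`, sorted by direction then
#'   decreasing count.
#' @export
tally_categories <- function(candidates, annotation) {
  if (nrow(candidates) == 0)
    return(data.frame(direction = character(0), category = character(0),
                      n = integer(0)))
  cat_map <- setNames(annotation$category, annotation$gene)
  category <- unname(cat_map[candidates$gene])
  category[is.na(category)] <- "unannotated"
  agg <- as.data.frame(table(direction = candidates$direction,
                             category = category),
                       stringsAsFactors = FALSE)
  agg <- agg[agg$Freq > 0, ]
  agg <- agg[order(agg$direction, -agg$Freq, agg$category), ]
  rownames(agg) <- NULL
  names(agg)[3] <- "n"
  agg
}

#' Rank candidate channels by fold enrichment
#'
#' Restricts the candidate table to annotated ion channels and sorts by
#' fold enrichment toward the candidate's direction, descending; ties are
#' broken by gene id (stable).
#'
#' @param candidates a [candidate_transducers()] table.
#' @param channels data.frame `(gene, is_channel, conductance)`.
#' @return data.frame `(gene, fold_enrichment, direction, conductance)`.
#' @export
rank_channels <- function(candidates, channels) {
  ch <- channels[channels$is_channel, , drop = FALSE]
  out <- candidates[candidates$gene %in% ch$gene, , drop = FALSE]
  cond <- setNames(ch$conductance, ch$gene)
  out <- data.frame(gene = out$gene, fold_enrichment = out$fold_enrichment,
                    direction = out$direction,
                    conductance = unname(cond[out$gene]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$direction, -out$fold_enrichment, out$gene), ]
  rownames(out) <- NULL
  out
}
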