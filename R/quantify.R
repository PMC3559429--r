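#' Count alignments per transcript and sample
#'
#' Each read contributes at most one alignment, so the transcript count is
#' simply the number of alignment records per (species-qualified transcript,
#' sample). A duplicated read id within a sample violates that contract and
#' is a hard error.
#'
#' @param alignments alignment data.frame from [run_waterfall()].
#' @param samples optional character vector fixing the column universe
#'   (samples with zero alignments still get a column).
#' @return integer matrix, rows `species:transcript`, columns samples.
#' @export
count_per_transcript <- function(alignments, samples = NULL) {
  samples <- samples %||% sort(unique(alignments$sample))
  if (nrow(alignments) == 0)
    return(matrix(0L, nrow = 0, ncol = length(samples),
                  dimnames = list(character(0), samples)))
  dup <- duplicated(alignments[, c("sample", "read_id")])
  if (any(dup))
    stop("duplicate read id(s) in alignments: ",
         paste(head(unique(alignments$read_id[dup]), 5), collapse = ", "))
  key <- paste0(alignments$species, ":", alignments$transcript)
  tab <- table(factor(key, levels = sort(unique(key))),
               factor(alignments$sample, levels = samples))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Sum transcript counts into per-species gene counts
#'
#' The read count for a gene is the sum of reads aligning to its
#' transcript(s). Transcripts absent from the gene model are a hard error
#' listing the offenders.
#'
#' @param tx_counts matrix from [count_per_transcript()] (rows
#'   `species:transcript`).
#' @param gene_model data.frame `(species, transcript, gene)`.
#' @return integer matrix, rows `species:gene`, columns samples.
#' @export
aggregate_to_genes <- function(tx_counts, gene_model) {
  if (nrow(tx_counts) == 0)
    return(matrix(0L, 0, ncol(tx_counts),
                  dimnames = list(character(0), colnames(tx_counts))))
  model_key <- paste0(gene_model$species, ":", gene_model$transcript)
  n_assign <- tapply(gene_model$gene, model_key,
                     function(g) length(unique(g)))
  if (any(n_assign > 1))
    stop("gene model conflict: transcript(s) assigned to multiple genes: ",
         paste(head(names(n_assign)[n_assign > 1], 5), collapse = ", "))
  gene_model <- gene_model[!duplicated(model_key), ]
  model_key <- paste0(gene_model$species, ":", gene_model$transcript)
  gene_of <- setNames(paste0(gene_model$species, ":", gene_model$gene),
                      model_key)
  missing <- setdiff(rownames(tx_counts), names(gene_of))
  if (length(missing))
    stop("transcript(s) absent from gene model: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  g <- gene_of[rownames(tx_counts)]
  out <- rowsum(tx_counts, group = g, reorder = TRUE)
  storage.mode(out) <- "integer"
  out
}

#' Collapse per-species gene counts over homolog clusters
#'
#' A collapsed gene entity's count is the sum over its member
#' (species, gene) counts; genes belonging to no cluster are retained as
#' orphan rows keyed `species:gene` rather than dropped.
#'
#' @param gene_counts matrix from [aggregate_to_genes()] (rows
#'   `species:gene`).
#' @param homology data.frame `(cluster, species, gene)`; a (species, gene)
#'   pair may belong to at most one cluster.
#' @return integer matrix, rows = cluster ids and orphan `species:gene`
#'   keys, columns samples; a `tissue` attribute is carried over if present.
#' @export
collapse_homologs <- function(gene_counts, homology) {
  key <- paste0(homology$species, ":", homology$gene)
  if (anyDuplicated(key))
    stop("homology table assigns a (species, gene) pair to multiple clusters")
  cluster_of <- setNames(homology$cluster, key)
  grp <- cluster_of[rownames(gene_counts)]
  grp[is.na(grp)] <- rownames(gene_counts)[is.na(grp)]  # orphan rows
  out <- rowsum(gene_counts, group = unname(grp), reorder = TRUE)
  storage.mode(out) <- "integer"
  attr(out, "tissue") <- attr(gene_counts, "tissue")
  out
}

#' Map per-species gene ids to collapsed entity keys
#'
#' Harmonizes gene identifiers from one species into the row universe of a
#' collapsed count table: the homolog cluster id where one exists, otherwise
#' the orphan key `species:gene`.
#'
#' @param genes character vector of gene ids.
#' @param homology homology data.frame `(cluster, species, gene)`.
#' @param species the species the ids belong to.
#' @return character vector of entity keys, same length as `genes`.
#' @export
harmonize_genes <- function(genes, homology, species) {
  hit <- homology[homology$species == species, ]
  cluster_of <- setNames(hit$cluster, hit$gene)
  out <- unname(cluster_of[genes])
  out[is.na(out)] <- paste0(species, ":", genes[is.na(out)])
  out
}
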