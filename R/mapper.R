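#' Configuration for the waterfall mapper
#'
#' The mapper is a substitution-tolerant seed-and-extend ungapped aligner:
#' candidate loci come from exact k-mer seed hits (every read offset, both
#' strands), each candidate is scored by full-length Hamming distance, and
#' the minimum-distance locus is accepted iff its distance is within the
#' mismatch budget `ceiling(budget_rate * L)`. The default budget rate 0.06
#' accepts the expected 3% cross-species divergence with headroom for
#' sequencing error.
#'
#' @param k seed k-mer length (default 16). With stride-1 seeding, discovery
#'   of a locus with `d` mismatches is guaranteed when
#'   `k <= ceiling((L - d) / (d + 1))`.
#' @param budget_rate mismatch budget per read base; budget =
#'   `ceiling(budget_rate * L)`.
#' @param stage_order character vector of reference names, in cascade order.
#' @param ambiguity one of `"discard"` (minimum-distance ties across
#'   distinct genes are left unmapped and flagged ambiguous; the default,
#'   conservative choice that prevents double counting) or `"first_best"`
#'   (deterministic lexicographic pick).
#' @return an object of class `mapper_config`.
#' @export
mapper_config <- function(k = 16L, budget_rate = 0.06,
                          stage_order = NULL,
                          ambiguity = c("discard", "first_best")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(k >= 1, k <= 31, budget_rate >= 0, budget_rate < 1)
  structure(list(k = as.integer(k), budget_rate = budget_rate,
                 stage_order = stage_order, ambiguity = ambiguity),
            class = "mapper_config")
}

mismatch_budget <- function(config, L) as.integer(ceiling(config$budget_rate * L))

#' Build an exact k-mer index over a reference transcriptome
#'
#' Indexes every forward k-mer of every transcript (k-mers containing
#' non-ACGT bases are skipped). Reverse-complement placements are found at
#' query time by also seeding from the reverse complement of the read.
#' Transcripts shorter than `k` are left unindexed with a warning.
#'
#' @param reference a [Biostrings::DNAStringSet] with record ids
#'   `gene|transcript|species` (plain ids are accepted and treated as their
#'   own gene).
#' @param k k-mer length.
#' @return an object of class `ref_index`.
#' @export
build_index <- function(reference, k = 16L) {
  if (length(reference) == 0) stop("empty reference")
  seqs <- as.character(reference)
  nm <- names(reference)
  if (is.null(nm)) stop("reference transcripts must be named")
  ids <- tryCatch(parse_fasta_ids(nm),
                  error = function(e) data.frame(
                    gene = nm, transcript = nm, species = NA_character_,
                    stringsAsFactors = FALSE))
  if (any(nchar(seqs) < k))
    warning(sum(nchar(seqs) < k), " transcript(s) shorter than k=", k,
            " left unindexed")
  gene_idx <- as.integer(factor(ids$gene))
  rank <- as.integer(rank(ids$transcript, ties.method = "first"))
  ptr <- .build_index_cpp(seqs, gene_idx, rank, as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k),
                 transcript = ids$transcript, gene = ids$gene,
                 species = ids$species[1], tx_len = nchar(seqs)),
            class = "ref_index")
}

#' Inspect an index
#'
#' `index_size()` reports the number of distinct k-mers and indexed
#' positions; `index_lookup()` returns the (transcript, 0-based offset)
#' placements of one exact k-mer.
#'
#' @param index a [build_index()] result.
#' @return `index_size()`: a list with `k`, `n_kmers`, `n_positions`.
#' @export
index_size <- function(index) .index_stats_cpp(index$ptr)

#' @rdname index_size
#' @param kmer a length-`k` DNA string.
#' @export
index_lookup <- function(index, kmer) {
  hits <- .index_lookup_cpp(index$ptr, as.character(kmer))
  data.frame(transcript = index$transcript[hits$transcript],
             pos = hits$pos, stringsAsFactors = FALSE)
}

#' Map reads against one indexed reference
#'
#' @param reads named character vector (or [Biostrings::DNAStringSet]) of
#'   read sequences.
#' @param index a [build_index()] result.
#' @param config a [mapper_config()].
#' @return data.frame with one row per read: `read_id, status`
#'   (`mapped`/`unmapped`/`ambiguous`), `species, gene, transcript, pos`
#'   (0-based leftmost), `strand`, `mismatches`.
#' @export
map_read <- function(reads, index, config = mapper_config()) {
  if (inherits(reads, "DNAStringSet")) reads <- setNames(as.character(reads),
                                                         names(reads))
  if (length(reads) == 0)
    return(data.frame(read_id = character(0), status = character(0),
                      species = character(0), gene = character(0),
                      transcript = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  L <- nchar(reads)
  if (any(L < index$k)) stop("read shorter than seed length k")
  res <- .map_reads_cpp(index$ptr, unname(reads),
                        mismatch_budget(config, L),
                        as.integer(config$ambiguity == "first_best"))
  data.frame(
    read_id = names(reads) %||% as.character(seq_along(reads)),
    status = c("unmapped", "mapped", "ambiguous")[res$status + 1L],
    species = ifelse(res$status == 1L, index$species, NA_character_),
    gene = ifelse(res$status == 1L, index$gene[res$tx], NA_character_),
    transcript = ifelse(res$status == 1L, index$transcript[res$tx],
                        NA_character_),
    pos = res$pos, strand = res$strand, mismatches = res$mismatches,
    stringsAsFactors = FALSE)
}

#' Run the waterfall mapping cascade
#'
#' Maps every sample's reads against an ordered series of reference
#' transcriptomes: a read is attempted at stage `t` only if it was unmapped
#' (including ambiguous-discarded) at every earlier stage. Ambiguous reads
#' cascade onward and are flagged in the per-read status of their last
#' attempted stage.
#'
#' @param reads named list: sample id -> named character vector (or
#'   `DNAStringSet`) of reads.
#' @param references named list of [Biostrings::DNAStringSet], one per
#'   species named in `config$stage_order`.
#' @param config a [mapper_config()]; `stage_order` defaults to
#'   `names(references)`.
#' @return list of class `waterfall_result` with
#'   \describe{
#'     \item{alignments}{data.frame `read_id, sample, stage, species, gene,
#'       transcript, pos, strand, mismatches` (mapped reads only, one row
#'       per read).}
#'     \item{summary}{a `mapping_summary`: per-sample per-stage mapped
#'       counts, totals, and mapped fractions.}
#'     \item{unmapped}{data.frame `read_id, sample, ambiguous`.}
#'   }
#' @export
run_waterfall <- function(reads, references, config = mapper_config()) {
  order <- config$stage_order %||% names(references)
  if (length(order) == 0) stop("stage_order is empty")
  missing_refs <- setdiff(order, names(references))
  if (length(missing_refs))
    stop("stage_order names missing from references: ",
         paste(missing_refs, collapse = ", "))
  if (is.null(names(reads)))
    names(reads) <- paste0("sample", seq_along(reads))

  indexes <- lapply(order, function(sp) build_index(references[[sp]],
                                                    config$k))
  names(indexes) <- order

  alns <- list()
  unmapped <- list()
  stage_counts <- matrix(0L, nrow = length(reads), ncol = length(order),
                         dimnames = list(names(reads), order))
  totals <- integer(length(reads))
  names(totals) <- names(reads)

  for (s in names(reads)) {
    pending <- reads[[s]]
    if (inherits(pending, "DNAStringSet"))
      pending <- setNames(as.character(pending), names(pending))
    totals[s] <- length(pending)
    ambiguous_ids <- character(0)
    for (t in seq_along(order)) {
      if (length(pending) == 0) break
      res <- map_read(pending, indexes[[t]], config)
      mapped <- res[res$status == "mapped", , drop = FALSE]
      if (nrow(mapped)) {
        mapped$sample <- s
        mapped$stage <- t
        alns[[length(alns) + 1L]] <-
          mapped[, c("read_id", "sample", "stage", "species", "gene",
                     "transcript", "pos", "strand", "mismatches")]
        stage_counts[s, t] <- nrow(mapped)
      }
      ambiguous_ids <- union(ambiguous_ids,
                             res$read_id[res$status == "ambiguous"])
      pending <- pending[res$status != "mapped"]
    }
    if (length(pending))
      unmapped[[length(unmapped) + 1L]] <- data.frame(
        read_id = names(pending), sample = s,
        ambiguous = names(pending) %in% ambiguous_ids,
        stringsAsFactors = FALSE)
  }

  alignments <- if (length(alns)) do.call(rbind, alns) else
    data.frame(read_id = character(0), sample = character(0),
               stage = integer(0), species = character(0),
               gene = character(0), transcript = character(0),
               pos = integer(0), strand = character(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
  rownames(alignments) <- NULL

  mapped_per_sample <- rowSums(stage_counts)
  summary <- structure(list(
    stage_order = order,
    stage_counts = stage_counts,
    total = totals,
    mapped = mapped_per_sample,
    fraction_mapped = ifelse(totals > 0, mapped_per_sample / totals, 0)),
    class = "mapping_summary")

  structure(list(alignments = alignments, summary = summary,
                 unmapped = if (length(unmapped)) do.call(rbind, unmapped)
                            else data.frame(read_id = character(0),
                                            sample = character(0),
                                            ambiguous = logical(0))),
            class = "waterfall_result")
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat("waterfall mapping:", sum(x$total), "reads,",
      sum(x$mapped), sprintf("mapped (%.1f%%)\n",
                             100 * sum(x$mapped) / max(1, sum(x$total))))
  tab <- cbind(x$stage_counts, unmapped = x$total - x$mapped,
               total = x$total)
  print(tab)
  invisible(x)
}

#' Export ungapped transcript alignments as minimal SAM
#'
#' Interoperability shim: emits header `@SQ` lines and one M-only CIGAR
#' record per alignment (1-based POS, NM tag = mismatches). The native
#' format of the package is the alignment TSV; transcript-space ungapped
#' hits need no richer CIGAR.
#'
#' @param alignments alignment data.frame from [run_waterfall()].
#' @param tx_len named integer vector: transcript lengths, names as
#'   `species:transcript`.
#' @param file output path.
#' @export
write_sam <- function(alignments, tx_len, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(tx_len))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, tx_len[[nm]]), con)
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    rname <- paste0(alignments$species, ":", alignments$transcript)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t*\t*\t0\t0\t*\t*\tNM:i:%d",
                       alignments$read_id, flag, rname,
                       alignments$pos + 1L, alignments$mismatches), con)
  }
  invisible(file)
}
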