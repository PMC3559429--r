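#' Simulate single-end reads from a count matrix and a transcriptome
#'
#' Emits exactly `counts[i, j]` reads for gene `i` in sample `j` — no
#' Poisson resampling — so downstream quantification is exactly checkable
#' against the count matrix. For each read the isoform is chosen uniformly
#' among the gene's transcripts, the start position uniformly along the
#' transcript, and the strand uniformly; each base is then flipped to one of
#' the three alternatives with probability `seq_error`. Base qualities are
#' constant (`I`, Phred 40): the pipeline never uses them.
#'
#' @param counts integer gene x sample matrix (rownames = gene ids).
#' @param transcripts [Biostrings::DNAStringSet] of the focal transcriptome,
#'   record ids `gene|transcript|species`.
#' @param config a [sim_config()] (uses `read_len`, `seq_error`, `seed`).
#' @return list with `reads` (named list: sample -> named character vector of
#'   read sequences) and `origins` (data.frame `read_id, sample, gene,
#'   transcript, pos, strand` with 0-based leftmost transcript positions).
#' @export
simulate_reads <- function(counts, transcripts, config) {
  validate_sim_config(config)
  ids <- parse_fasta_ids(names(transcripts))
  seqs <- as.character(transcripts)
  L <- config$read_len
  if (any(nchar(seqs) < L))
    stop("read_len exceeds the length of at least one transcript")
  genes_in <- rownames(counts)
  if (!all(genes_in %in% ids$gene))
    stop("counts contain genes absent from the transcriptome: ",
         paste(head(setdiff(genes_in, ids$gene), 5), collapse = ", "))
  tx_by_gene <- split(seq_along(seqs), ids$gene)

  with_seed(derive_seed(config$seed, "reads"), {
    reads <- list()
    origins <- vector("list", ncol(counts))
    for (j in seq_len(ncol(counts))) {
      sample_id <- colnames(counts)[j]
      cnt <- counts[, j]
      gene_rep <- rep(genes_in, times = cnt)
      n <- length(gene_rep)
      if (n == 0) {
        reads[[sample_id]] <- character(0)
        origins[[j]] <- data.frame(read_id = character(0),
                                   sample = character(0), gene = character(0),
                                   transcript = character(0),
                                   pos = integer(0), strand = character(0),
                                   stringsAsFactors = FALSE)
        next
      }
      tx_idx <- vapply(tx_by_gene[gene_rep], function(ix)
        ix[sample.int(length(ix), 1L)], integer(1))
      tlen <- nchar(seqs)[tx_idx]
      pos <- floor(runif(n) * (tlen - L + 1))  # 0-based start
      strand <- ifelse(runif(n) < 0.5, "+", "-")
      rd <- substring(seqs[tx_idx], pos + 1, pos + L)
      neg <- strand == "-"
      if (any(neg)) rd[neg] <- revcomp_chr(rd[neg])
      rd <- apply_seq_errors(rd, config$seq_error)
      read_id <- sprintf("%s:r%06d", sample_id, seq_len(n))
      names(rd) <- read_id
      reads[[sample_id]] <- rd
      origins[[j]] <- data.frame(
        read_id = read_id, sample = sample_id, gene = gene_rep,
        transcript = ids$transcript[tx_idx], pos = as.integer(pos),
        strand = strand, stringsAsFactors = FALSE)
    }
    list(reads = reads, origins = do.call(rbind, origins))
  })
}

parse_fasta_ids <- function(nm) {
  parts <- strsplit(nm, "|", fixed = TRUE)
  ok <- lengths(parts) == 3L
  if (!all(ok))
    stop("malformed FASTA ids (expected gene|transcript|species): ",
         paste(head(nm[!ok], 3), collapse = ", "))
  data.frame(gene = vapply(parts, `[[`, "", 1L),
             transcript = vapply(parts, `[[`, "", 2L),
             species = vapply(parts, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

apply_seq_errors <- function(reads, p) {
  if (p == 0 || length(reads) == 0) return(reads)
  L <- nchar(reads[1])
  nerr <- rbinom(length(reads), L, p)
  hit <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    x <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    at <- sample.int(L, nerr[i])
    idx <- match(x[at], bases)
    x[at] <- bases[(idx - 1L + sample.int(3L, length(at),
                                          replace = TRUE)) %% 4L + 1L]
    reads[i] <- paste(x, collapse = "")
  }
  reads
}
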