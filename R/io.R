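#' Read and write the package's tabular and sequence formats
#'
#' All TSV outputs begin with comment lines (`# key=value`) carrying the
#' seed and a configuration hash so every file is traceable to the run that
#' produced it; readers skip comment lines. FASTA/FASTQ go through
#' Biostrings; FASTQ qualities are constant `I` (Phred+33, Q40) because the
#' pipeline never uses them.
#'
#' @param x object to write.
#' @param file path.
#' @param header named character/list of `key=value` metadata to stamp.
#' @return the path, invisibly (writers); a data.frame or matrix (readers).
#' @name waterfall_io
NULL

#' @rdname waterfall_io
#' @export
write_tsv <- function(x, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s=%s", names(header),
                       vapply(header, as.character, "")), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname waterfall_io
#' @export
read_tsv <- function(file) {
  read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname waterfall_io
#' @param counts integer matrix with a `tissue` attribute.
#' @export
write_counts <- function(counts, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s=%s", names(header),
                       vapply(header, as.character, "")), con)
  tissue <- attr(counts, "tissue")
  if (!is.null(tissue))
    writeLines(paste0("#tissue\t",
                      paste(tissue[colnames(counts)], collapse = "\t")), con)
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname waterfall_io
#' @export
read_counts <- function(file) {
  lines <- readLines(file)
  tissue_line <- grep("^#tissue\t", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  df <- read.delim(text = body, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  if (length(tissue_line)) {
    tis <- strsplit(sub("^#tissue\t", "", tissue_line[1]), "\t")[[1]]
    attr(m, "tissue") <- setNames(tis, colnames(m))
  }
  m
}

#' @rdname waterfall_io
#' @param seqs a `DNAStringSet`/`AAStringSet` or named character vector.
#' @export
write_fasta <- function(seqs, file) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' @rdname waterfall_io
#' @param reads named character vector of read sequences.
#' @export
write_fastq <- function(reads, file) {
  x <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, file, format = "fastq", qualities = quals)
  invisible(file)
}

#' @rdname waterfall_io
#' @export
read_fastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  setNames(as.character(x), names(x))
}
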