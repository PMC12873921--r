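#' Write reads to FASTQ
#'
#' @param reads Named character vector of sequences.
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ or FASTQ.gz path.
#' @return Named character vector (names are read identifiers up to the
#'   first whitespace).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a count or abundance table as TSV
#'
#' @param table Matrix with barcode rownames and sample colnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(barcode = rownames(table), table, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table TSV written by [write_count_table()]
#' @param path TSV path.
#' @return Matrix with barcode rownames.
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$barcode
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
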