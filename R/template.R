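#' Amplicon read template
#'
#' Describes the conserved structure of the barcode amplicon as it appears in
#' template orientation (i.e. after reverse-complementing raw reads): a 5-nt
#' sample multiplexing index at the very start of the raw read, a conserved
#' upstream context ending in the upstream anchor, the 15-nt random barcode
#' slot, the exact downstream anchor, and conserved downstream context.
#'
#' The anchors and their tolerances default to the published amplicon design:
#' a 12-nt upstream anchor `AGCCCCCAGGGA` searched with progressive
#' stringency (exact, then Hamming distance <= 2, then Levenshtein distance
#' <= 2) and a 5-nt downstream anchor `CACGC` that must match exactly.
#'
#' @param upstream_anchor Upstream anchor sequence (12 nt).
#' @param downstream_anchor Downstream anchor sequence (5 nt), exact match.
#' @param barcode_length Length of the random barcode slot (15).
#' @param anchor_max_mismatch Cap for both the Hamming and Levenshtein search
#'   stages on the upstream anchor.
#' @param expected_anchor_offset 1-based position of the upstream anchor in an
#'   error-free, template-oriented read.
#' @param position_tolerance Half-width of the accepted anchor-position
#'   window; the Levenshtein stage widens it by `anchor_max_mismatch` to
#'   leave room for indels.
#' @param upstream_context,downstream_context Conserved sequence before the
#'   anchor and after the downstream anchor. The defaults are synthetic
#'   stand-ins for the amplicon flanks (the real flank sequences are not part
#'   of this package); they only shape simulated reads and the
#'   template-artifact filter, and are fully user-configurable.
#' @param sample_barcode_length Length of the multiplexing index at the raw
#'   read start (5).
#' @return An object of class `read_template`.
#' @export
read_template <- function(upstream_anchor = "AGCCCCCAGGGA",
                          downstream_anchor = "CACGC",
                          barcode_length = 15L,
                          anchor_max_mismatch = 2L,
                          expected_anchor_offset = NULL,
                          position_tolerance = 5L,
                          upstream_context = "TGGTCGAGGTGAGCCCCACG",
                          downstream_context = "GGGTCATTAGTTCATAGCCC",
                          sample_barcode_length = 5L) {
  stopifnot(nchar(upstream_anchor) > 0, nchar(downstream_anchor) > 0,
            barcode_length >= 1, anchor_max_mismatch >= 0,
            position_tolerance >= 0, sample_barcode_length >= 1)
  if (is.null(expected_anchor_offset)) {
    expected_anchor_offset <- nchar(upstream_context) + 1L
  }
  stopifnot(expected_anchor_offset >= 1)
  t <- list(
    upstream_anchor = toupper(upstream_anchor),
    downstream_anchor = toupper(downstream_anchor),
    barcode_length = as.integer(barcode_length),
    anchor_max_mismatch = as.integer(anchor_max_mismatch),
    expected_anchor_offset = as.integer(expected_anchor_offset),
    position_tolerance = as.integer(position_tolerance),
    upstream_context = toupper(upstream_context),
    downstream_context = toupper(downstream_context),
    sample_barcode_length = as.integer(sample_barcode_length)
  )
  class(t) <- "read_template"
  t
}

#' @export
print.read_template <- function(x, ...) {
  cat("Amplicon read template\n")
  cat(sprintf("  upstream anchor   : %s (Hamming/Levenshtein <= %d)\n",
              x$upstream_anchor, x$anchor_max_mismatch))
  cat(sprintf("  barcode slot      : %d nt\n", x$barcode_length))
  cat(sprintf("  downstream anchor : %s (exact)\n", x$downstream_anchor))
  cat(sprintf("  anchor offset     : %d +/- %d\n",
              x$expected_anchor_offset, x$position_tolerance))
  cat(sprintf("  sample index      : %d nt at raw read start\n",
              x$sample_barcode_length))
  invisible(x)
}

# Conserved (non-barcode) parts of the template, used both to build simulated
# reads and to screen extracted barcodes for extraction artifacts.
template_conserved_regions <- function(template) {
  c(upstream = paste0(template$upstream_context, template$upstream_anchor),
    downstream = paste0(template$downstream_anchor,
                        template$downstream_context))
}

# Template-oriented insert for a given barcode (no sample index).
template_insert <- function(template, barcode) {
  paste0(template$upstream_context, template$upstream_anchor, barcode,
         template$downstream_anchor, template$downstream_context)
}

#' Sample sheet for demultiplexing
#'
#' @param entries Named character vector mapping `sample_id` to its
#'   multiplexing barcode (all the same length, typically 5 nt).
#' @param max_mismatch Hamming mismatches tolerated when assigning a read to
#'   a sample (published value: 1).
#' @return An object of class `sample_sheet`.
#' @export
sample_sheet <- function(entries, max_mismatch = 1L) {
  entries <- toupper(unlist(entries))
  if (is.null(names(entries)) || anyNA(names(entries)) ||
      any(names(entries) == "")) {
    stop("'entries' must be a named vector: sample_id -> barcode")
  }
  if (anyDuplicated(entries)) {
    stop("duplicate multiplexing barcodes in sample sheet: ",
         paste(entries[duplicated(entries)], collapse = ", "))
  }
  if (anyDuplicated(names(entries))) stop("duplicate sample ids")
  if (length(unique(nchar(entries))) != 1L) {
    stop("all multiplexing barcodes must have the same length")
  }
  max_mismatch <- as.integer(max_mismatch)
  if (length(entries) > 1L) {
    d <- vapply(entries, function(e) hamming_distance(entries, e),
                numeric(length(entries)))
    dmin <- min(d[upper.tri(d)])
    if (dmin <= 2L * max_mismatch) {
      warning(sprintf(paste0("minimum pairwise barcode distance (%d) is <= ",
                             "2 * max_mismatch (%d); some reads may be ",
                             "ambiguous"), dmin, 2L * max_mismatch))
    }
  }
  structure(list(entries = entries, max_mismatch = max_mismatch),
            class = "sample_sheet")
}

#' Read a sample sheet from a two-column TSV (sample_id, barcode)
#' @param path Path to the TSV file.
#' @param max_mismatch Mismatch tolerance, see [sample_sheet()].
#' @return A `sample_sheet`.
#' @export
read_sample_sheet <- function(path, max_mismatch = 1L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "barcode") %in% names(df))) {
    stop("sample sheet TSV needs columns 'sample_id' and 'barcode'")
  }
  sample_sheet(stats::setNames(df$barcode, df$sample_id), max_mismatch)
}
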