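#' Reverse-complement reads
#'
#' Strict Watson-Crick reverse complement over the alphabet `{A,C,G,T,N}`
#' (`N` maps to `N`). Applying it twice returns the input.
#'
#' @param reads Character vector of read sequences (names are read ids).
#' @return Character vector of reverse-complemented reads, names preserved.
#' @export
reverse_complement <- function(reads) {
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    offender <- if (!is.null(names(reads))) names(reads)[bad][1L] else
      paste0("#", which(bad)[1L])
    stop("non-nucleotide character in read ", offender)
  }
  revcomp_chr(reads)
}

#' Demultiplex pooled reads by their sample barcode
#'
#' The multiplexing barcode occupies a fixed slot at the start of each raw
#' read (length per the sample sheet). A read is assigned to a sample if and
#' only if exactly one sheet entry lies within Hamming distance
#' `max_mismatch` of that slot; reads matching zero or several entries are
#' unassigned. Assigned plus unassigned always equals the input.
#'
#' @param reads Named character vector of raw read sequences.
#' @param sheet A [sample_sheet()].
#' @return A list with `assignment` (per-read sample id, `NA` if
#'   unassigned), `samples` (named list of per-sample read vectors) and
#'   `unassigned` (read vector).
#' @export
demultiplex <- function(reads, sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  bclen <- nchar(sheet$entries[[1L]])
  region <- substr(reads, 1L, bclen)
  n_hit <- integer(length(reads))
  hit_sample <- rep(NA_character_, length(reads))
  for (s in names(sheet$entries)) {
    d <- hamming_distance(region, sheet$entries[[s]])
    ok <- d <= sheet$max_mismatch
    n_hit <- n_hit + ok
    hit_sample[ok] <- s
  }
  hit_sample[n_hit != 1L] <- NA_character_
  samples <- lapply(setNames(nm = names(sheet$entries)),
                    function(s) reads[!is.na(hit_sample) & hit_sample == s])
  structure(list(assignment = hit_sample, samples = samples,
                 unassigned = reads[is.na(hit_sample)]),
            class = "demux_result")
}

# Levenshtein-stage anchor search for a single read: scan every candidate
# start within the widened position window and every window width within
# +/- max_mismatch of the anchor length; accept edit distance <= max_mismatch,
# preferring smaller distance, then leftmost start, then narrowest window.
lev_anchor_search <- function(seq, anchor, max_mm, offsets, widths) {
  best_d <- Inf
  best_end <- NA_integer_
  best_pos <- NA_integer_
  L <- nchar(seq)
  for (p in offsets) {
    for (w in widths) {
      if (p + w - 1L > L) next
      d <- utils::adist(anchor, substr(seq, p, p + w - 1L))[1L]
      if (d < best_d) {
        best_d <- d
        best_pos <- p
        best_end <- p + w - 1L
      }
    }
  }
  if (best_d <= max_mm) c(pos = best_pos, end = best_end) else NULL
}

#' Extract the random barcode from oriented reads
#'
#' Locates the upstream anchor by progressive search stringency — exact
#' substring match, then Hamming distance up to the anchor mismatch cap, then
#' Levenshtein distance up to the same cap — with position validation at
#' every stage: the anchor start must fall within
#' `expected_anchor_offset +/- position_tolerance` (the Levenshtein stage
#' widens the window by the mismatch cap to leave room for indels). Among
#' candidate positions the leftmost minimal-distance match wins. The
#' `barcode_length` bases following the matched anchor are the candidate
#' barcode; the bases immediately after it must equal the downstream anchor
#' exactly, and a candidate containing `N` is dropped. Unextractable reads
#' are counted per failure mode, never fatal.
#'
#' @param reads Named character vector of reads already in template
#'   orientation (see [reverse_complement()]).
#' @param template A [read_template()].
#' @param stages Stage ladder to run, in order; truncating it (e.g.
#'   `c("exact", "hamming")`) disables the later stages without changing
#'   earlier-stage results.
#' @return A `data.frame` of successful observations with columns `read_id`,
#'   `barcode`, `match_stage` (`"exact"`, `"hamming"` or `"levenshtein"`) and
#'   `anchor_position`, with attribute `log`: a named integer vector of
#'   per-stage and per-failure-mode read counts.
#' @export
extract_barcodes <- function(reads, template,
                             stages = c("exact", "hamming", "levenshtein")) {
  stopifnot(inherits(template, "read_template"),
            all(stages %in% c("exact", "hamming", "levenshtein")))
  n <- length(reads)
  ids <- if (!is.null(names(reads))) names(reads) else as.character(seq_len(n))
  seqs <- unname(reads)
  anchor <- template$upstream_anchor
  alen <- nchar(anchor)
  mm <- template$anchor_max_mismatch
  exp_off <- template$expected_anchor_offset
  tol <- template$position_tolerance

  offsets <- seq.int(max(1L, exp_off - tol), exp_off + tol)
  first_zero <- rep(NA_integer_, n)
  best_d <- rep(Inf, n)
  best_pos <- rep(NA_integer_, n)
  for (o in offsets) {
    d <- hamming_distance(substr(seqs, o, o + alen - 1L), anchor)
    fz <- is.na(first_zero) & d == 0
    first_zero[fz] <- o
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_pos[upd] <- o
  }
  stage <- rep(NA_character_, n)
  anchor_end <- rep(NA_integer_, n)
  anchor_pos <- rep(NA_integer_, n)
  ex <- if ("exact" %in% stages) !is.na(first_zero) else rep(FALSE, n)
  stage[ex] <- "exact"
  anchor_pos[ex] <- first_zero[ex]
  anchor_end[ex] <- first_zero[ex] + alen - 1L
  hm <- if ("hamming" %in% stages) !ex & best_d <= mm else rep(FALSE, n)
  stage[hm] <- "hamming"
  anchor_pos[hm] <- best_pos[hm]
  anchor_end[hm] <- best_pos[hm] + alen - 1L

  if ("levenshtein" %in% stages) {
    lev_offsets <- seq.int(max(1L, exp_off - tol - mm), exp_off + tol + mm)
    lev_widths <- seq.int(max(1L, alen - mm), alen + mm)
    for (i in which(is.na(stage))) {
      hitv <- lev_anchor_search(seqs[i], anchor, mm, lev_offsets, lev_widths)
      if (!is.null(hitv)) {
        stage[i] <- "levenshtein"
        anchor_pos[i] <- hitv[["pos"]]
        anchor_end[i] <- hitv[["end"]]
      }
    }
  }

  outcome <- rep("no_anchor", n)
  found <- !is.na(stage)
  bstart <- anchor_end + 1L
  blen <- template$barcode_length
  barcode <- rep(NA_character_, n)
  barcode[found] <- substr(seqs[found], bstart[found],
                           bstart[found] + blen - 1L)
  dlen <- nchar(template$downstream_anchor)
  down <- rep(NA_character_, n)
  down[found] <- substr(seqs[found], bstart[found] + blen,
                        bstart[found] + blen + dlen - 1L)
  outcome[found] <- "extracted"
  outcome[found & nchar(barcode) < blen] <- "truncated"
  outcome[outcome == "extracted" & down != template$downstream_anchor] <-
    "bad_downstream"
  outcome[outcome == "extracted" & grepl("N", barcode, fixed = TRUE)] <-
    "barcode_N"

  keep <- outcome == "extracted"
  obs <- data.frame(read_id = ids[keep], barcode = barcode[keep],
                    match_stage = stage[keep],
                    anchor_position = anchor_pos[keep])
  log_counts <- c(
    input = n,
    extracted = sum(keep),
    stage_exact = sum(keep & stage == "exact"),
    stage_hamming = sum(keep & stage == "hamming"),
    stage_levenshtein = sum(keep & stage == "levenshtein"),
    no_anchor = sum(outcome == "no_anchor"),
    bad_downstream = sum(outcome == "bad_downstream"),
    barcode_N = sum(outcome == "barcode_N"),
    truncated = sum(outcome == "truncated")
  )
  attr(obs, "log") <- log_counts
  obs
}

#' Extract the barcode from a single read
#' @param read One read sequence (template orientation).
#' @param template A [read_template()].
#' @return A one-row data.frame as in [extract_barcodes()], or `NULL` if the
#'   read is unextractable.
#' @export
extract_barcode <- function(read, template) {
  obs <- extract_barcodes(setNames(read, "read"), template)
  if (nrow(obs) == 0L) NULL else obs
}

#' Tally barcode observations into a count table
#'
#' @param observations A `data.frame` with columns `barcode` and `sample_id`
#'   (one row per extracted read).
#' @param samples Optional character vector fixing the column set/order
#'   (samples with zero reads get all-zero columns).
#' @return Integer matrix of read counts, barcodes in rows, samples in
#'   columns. The grand total equals `nrow(observations)`.
#' @export
tally_observations <- function(observations, samples = NULL) {
  if (nrow(observations) == 0L) {
    return(matrix(integer(), nrow = 0L, ncol = length(samples),
                  dimnames = list(character(), samples)))
  }
  stopifnot(all(c("barcode", "sample_id") %in% names(observations)))
  if (is.null(samples)) samples <- sort(unique(observations$sample_id))
  tab <- table(factor(observations$barcode),
               factor(observations$sample_id, levels = samples))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}
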