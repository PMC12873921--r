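# Independent reference implementations used to cross-check the package:
# scalar brute-force code paths that share no vectorised machinery with the
# implementation under test.

# hand-rolled dynamic-programming edit distance (unit costs)
dp_levenshtein <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  na <- length(av)
  nb <- length(bv)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- c(i, integer(nb))
    for (j in seq_len(nb)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (av[i] != bv[j]))
    }
    prev <- cur
  }
  prev[nb + 1L]
}

dp_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  if (length(av) != length(bv)) return(Inf)
  sum(av != bv)
}

# Brute-force anchored extraction over all offsets and window widths,
# mirroring the documented stage semantics: per-stage position windows,
# leftmost minimal-distance match, then narrowest window; exact downstream
# anchor; no N in the barcode slot.
oracle_extract <- function(seq, tpl,
                           stages = c("exact", "hamming", "levenshtein")) {
  anchor <- tpl$upstream_anchor
  alen <- nchar(anchor)
  mm <- tpl$anchor_max_mismatch
  win <- seq.int(max(1L, tpl$expected_anchor_offset - tpl$position_tolerance),
                 tpl$expected_anchor_offset + tpl$position_tolerance)
  hit <- NULL
  if ("exact" %in% stages) {
    for (p in win) {
      if (substr(seq, p, p + alen - 1L) == anchor) {
        hit <- list(stage = "exact", pos = p, end = p + alen - 1L)
        break
      }
    }
  }
  if (is.null(hit) && "hamming" %in% stages) {
    best_d <- Inf
    for (p in win) {
      d <- dp_hamming(anchor, substr(seq, p, p + alen - 1L))
      if (d < best_d) {
        best_d <- d
        if (d <= mm) hit <- list(stage = "hamming", pos = p,
                                 end = p + alen - 1L)
      }
    }
  }
  if (is.null(hit) && "levenshtein" %in% stages) {
    wwin <- seq.int(max(1L, tpl$expected_anchor_offset -
                          tpl$position_tolerance - mm),
                    tpl$expected_anchor_offset + tpl$position_tolerance + mm)
    best_d <- Inf
    for (p in wwin) {
      for (w in seq.int(max(1L, alen - mm), alen + mm)) {
        if (p + w - 1L > nchar(seq)) next
        d <- dp_levenshtein(anchor, substr(seq, p, p + w - 1L))
        if (d < best_d) {
          best_d <- d
          if (d <= mm) hit <- list(stage = "levenshtein", pos = p,
                                   end = p + w - 1L)
        }
      }
    }
    if (best_d > mm) hit <- NULL
  }
  if (is.null(hit)) return(NULL)
  bstart <- hit$end + 1L
  barcode <- substr(seq, bstart, bstart + tpl$barcode_length - 1L)
  if (nchar(barcode) < tpl$barcode_length) return(NULL)
  if (grepl("N", barcode, fixed = TRUE)) return(NULL)
  down <- substr(seq, bstart + tpl$barcode_length,
                 bstart + tpl$barcode_length +
                   nchar(tpl$downstream_anchor) - 1L)
  if (down != tpl$downstream_anchor) return(NULL)
  list(barcode = barcode, stage = hit$stage, pos = hit$pos)
}

# Exhaustive trace of the stated collapse rule: visit barcodes by decreasing
# total count (ties lexicographic); merge into the most abundant finalized
# parent within edit distance 1 of the candidate, else finalize as parent.
oracle_collapse <- function(table) {
  bcs <- rownames(table)
  tot <- rowSums(table)
  ord <- order(-tot, bcs)
  parent <- integer(nrow(table))
  for (i in ord) {
    cand <- integer(0)
    for (j in ord) {
      if (j == i) break  # only barcodes ranked strictly above i
      if (parent[j] == j && dp_levenshtein(bcs[i], bcs[j]) <= 1L) {
        cand <- c(cand, j)
      }
    }
    parent[i] <- if (length(cand)) cand[1L] else i
  }
  out <- rowsum(table, group = parent, reorder = FALSE)
  rownames(out) <- bcs[as.integer(rownames(out))]
  out <- out[order(-rowSums(out), rownames(out)), , drop = FALSE]
  storage.mode(out) <- "integer"
  list(table = out, parent = setNames(bcs[parent], bcs))
}

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# small template used across tests (short flanks keep reads <= 60 nt)
small_template <- function(...) {
  read_template(upstream_context = "TGGTCGAG",
                downstream_context = "GGGTCATT", ...)
}
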