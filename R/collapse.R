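#' Collapse error-variant barcodes into their parent barcodes
#'
#' Sequencing and PCR errors scatter reads of one true barcode across
#' near-identical variants. Barcodes are visited in decreasing total
#' (cross-sample) read count, ties broken lexicographically. A barcode
#' becomes a parent if no already-finalised parent lies within Levenshtein
#' distance 1 (one substitution, insertion or deletion); otherwise it merges
#' into the most abundant such parent, and its per-sample counts are added to
#' the parent's. Children never absorb other children, and the grand total is
#' conserved exactly, per sample.
#'
#' @param table Integer count matrix (barcodes x samples), e.g. from
#'   [tally_observations()].
#' @return A list with `table` (collapsed count matrix, rows ordered by
#'   decreasing total) and `map` (a `data.frame` with columns `child`,
#'   `parent`, `child_total`, one row per input barcode; parents map to
#'   themselves).
#' @export
collapse_barcodes <- function(table) {
  if (is.null(dim(table)) || is.null(rownames(table))) {
    stop("'table' must be a matrix with barcode rownames")
  }
  n <- nrow(table)
  if (n == 0L) {
    return(list(table = table,
                map = data.frame(child = character(), parent = character(),
                                 child_total = integer())))
  }
  bcs <- rownames(table)
  tot <- rowSums(table)
  ord <- order(-tot, bcs)

  # candidate neighbours: pairs sharing a deletion key are the only possible
  # Levenshtein<=1 pairs; verified with a true distance before use
  keys <- deletion_keys(bcs)
  kdt <- data.table::data.table(
    id = rep.int(seq_len(n), lengths(keys)),
    delkey = unlist(keys, use.names = FALSE)
  )
  pairs <- kdt[, {
    u <- unique(id)
    if (length(u) > 1L) {
      cmb <- utils::combn(u, 2L)
      list(a = cmb[1L, ], b = cmb[2L, ])
    }
  }, by = delkey]
  adj <- vector("list", n)
  if (nrow(pairs) > 0L) {
    pr <- unique(pairs[, list(a = pmin(a, b), b = pmax(a, b))])
    same_len <- nchar(bcs[pr$a]) == nchar(bcs[pr$b])
    keepp <- logical(nrow(pr))
    if (any(same_len)) {
      keepp[same_len] <- hamming_distance_pairs(bcs[pr$a[same_len]],
                                                bcs[pr$b[same_len]]) <= 1L
    }
    if (any(!same_len)) {
      keepp[!same_len] <- levenshtein_distance(bcs[pr$a[!same_len]],
                                               bcs[pr$b[!same_len]]) <= 1L
    }
    pr <- pr[keepp & pr$a != pr$b, ]
    if (nrow(pr) > 0L) {
      adj_dt <- data.table::data.table(from = c(pr$a, pr$b),
                                       to = c(pr$b, pr$a))
      adj_split <- split(adj_dt$to, adj_dt$from)
      adj[as.integer(names(adj_split))] <- adj_split
    }
  }

  rank_of <- integer(n)
  rank_of[ord] <- seq_len(n)
  parent <- integer(n)  # 0 = not yet visited; parent id once visited
  for (i in ord) {
    nb <- adj[[i]]
    cand <- nb[parent[nb] == nb & nb != 0L]
    if (length(cand) == 0L) {
      parent[i] <- i
    } else {
      parent[i] <- cand[which.min(rank_of[cand])]
    }
  }

  out <- rowsum(table, group = parent, reorder = FALSE)
  rownames(out) <- bcs[as.integer(rownames(out))]
  out <- out[order(-rowSums(out), rownames(out)), , drop = FALSE]
  storage.mode(out) <- "integer"
  map <- data.frame(child = bcs, parent = bcs[parent],
                    child_total = as.integer(tot))
  map <- map[ord, ]
  rownames(map) <- NULL
  list(table = out, map = map)
}

# elementwise Hamming distance for equal-length string pairs
hamming_distance_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer())
  d <- integer(length(a))
  for (L in unique(nchar(a))) {
    i <- which(nchar(a) == L)
    acc <- integer(length(i))
    for (j in seq_len(L)) {
      acc <- acc + (substr(a[i], j, j) != substr(b[i], j, j))
    }
    d[i] <- acc
  }
  d
}

#' Filtering thresholds for collapsed barcode counts
#'
#' @param min_reads_per_fish A barcode is retained in a given fish only with
#'   at least this many reads in that fish (published value 3); lower counts
#'   are zeroed per fish, independently.
#' @param min_reads_library In the injected source library, barcodes below
#'   this count are removed entirely (published value 2).
#' @param template_artifact_max_dist Barcodes within this Levenshtein
#'   distance of any conserved template region are removed (published
#'   value 2).
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_reads_per_fish = 3L, min_reads_library = 2L,
                          template_artifact_max_dist = 2L) {
  stopifnot(min_reads_per_fish >= 0, min_reads_library >= 0,
            template_artifact_max_dist >= 0)
  structure(list(min_reads_per_fish = as.integer(min_reads_per_fish),
                 min_reads_library = as.integer(min_reads_library),
                 template_artifact_max_dist =
                   as.integer(template_artifact_max_dist)),
            class = "filter_policy")
}

#' Apply read-count thresholds to a collapsed count table
#'
#' Fish samples: every cell with fewer than `min_reads_per_fish` reads is set
#' to zero, independently per fish. The source library: barcodes with fewer
#' than `min_reads_library` reads are removed. Rows that become all-zero are
#' dropped.
#'
#' @param table Integer count matrix (barcodes x samples).
#' @param policy A [filter_policy()].
#' @param sample_class `"fish"` or `"source_library"`.
#' @return Filtered integer count matrix.
#' @export
filter_counts <- function(table, policy = filter_policy(),
                          sample_class = c("fish", "source_library")) {
  sample_class <- match.arg(sample_class)
  stopifnot(inherits(policy, "filter_policy"))
  if (nrow(table) == 0L) return(table)
  if (sample_class == "fish") {
    table[table < policy$min_reads_per_fish] <- 0L
  } else {
    table[table < policy$min_reads_library] <- 0L
  }
  table[rowSums(table) > 0L, , drop = FALSE]
}

#' Remove barcodes resembling conserved template sequence
#'
#' Faulty anchor matches can extract a slice of the conserved template
#' instead of the random barcode. A barcode is removed iff its minimal
#' Levenshtein distance to any window of any conserved region — window
#' lengths within +/- `max_dist` of the barcode length — is at most
#' `max_dist`.
#'
#' @param table Integer count matrix (barcodes x samples).
#' @param template A [read_template()] supplying the conserved regions, or a
#'   character vector of conserved sequences.
#' @param max_dist Maximum Levenshtein distance treated as an artifact
#'   (published value 2).
#' @return Filtered count matrix with attribute `removed`: a `data.frame`
#'   (`barcode`, `region`, `distance`) of dropped rows.
#' @export
remove_template_artifacts <- function(table, template, max_dist = 2L) {
  regions <- if (inherits(template, "read_template")) {
    template_conserved_regions(template)
  } else {
    stats::setNames(as.character(template), names(template))
  }
  if (length(regions) == 0L || all(nchar(regions) == 0L)) {
    warning("no conserved regions supplied; table unchanged")
    attr(table, "removed") <- data.frame(barcode = character(),
                                         region = character(),
                                         distance = integer())
    return(table)
  }
  if (is.null(names(regions))) names(regions) <- paste0("region", seq_along(regions))
  bcs <- rownames(table)
  if (length(bcs) == 0L) {
    attr(table, "removed") <- data.frame(barcode = character(),
                                         region = character(),
                                         distance = integer())
    return(table)
  }
  blen <- max(nchar(bcs))
  win_seq <- character()
  win_region <- character()
  for (r in names(regions)) {
    reg <- regions[[r]]
    for (w in seq.int(max(1L, blen - max_dist), blen + max_dist)) {
      if (nchar(reg) < w) next
      starts <- seq_len(nchar(reg) - w + 1L)
      win_seq <- c(win_seq, substring(reg, starts, starts + w - 1L))
      win_region <- c(win_region, rep(r, length(starts)))
    }
  }
  d <- utils::adist(bcs, win_seq)
  mind <- apply(d, 1L, min)
  drop <- mind <= max_dist
  removed <- data.frame(
    barcode = bcs[drop],
    region = win_region[apply(d[drop, , drop = FALSE], 1L, which.min)],
    distance = as.integer(mind[drop])
  )
  out <- table[!drop, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}
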