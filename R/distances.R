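#' Hamming distance between equal-length nucleotide strings
#'
#' Vectorised over `x`; `y` is a single string recycled against `x`. Strings
#' shorter than `y` (e.g. windows running off a read end) get distance `Inf`.
#'
#' @param x Character vector.
#' @param y Single string of the reference sequence.
#' @return Numeric vector of mismatch counts (`Inf` where lengths differ).
#' @export
hamming_distance <- function(x, y) {
  stopifnot(length(y) == 1L)
  ly <- nchar(y)
  d <- numeric(length(x))
  ok <- !is.na(x) & nchar(x) == ly
  d[!ok] <- Inf
  if (any(ok)) {
    xs <- x[ok]
    acc <- integer(length(xs))
    for (j in seq_len(ly)) {
      acc <- acc + (substr(xs, j, j) != substr(y, j, j))
    }
    d[ok] <- acc
  }
  d
}

#' Levenshtein distance between two nucleotide strings
#'
#' Thin wrapper over [utils::adist()] (unit-cost substitutions, insertions
#' and deletions), kept as a named primitive because edit distance 1 defines
#' the barcode-collapse neighbourhood.
#'
#' @param a,b Character vectors; distances are computed elementwise after
#'   recycling the shorter one.
#' @return Integer vector of edit distances.
#' @export
levenshtein_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  # adist() returns a full cross matrix; elementwise is cheaper done by
  # grouping on the (few) distinct values of b.
  for (bb in unique(b)) {
    i <- which(b == bb)
    out[i] <- as.integer(utils::adist(a[i], bb))
  }
  out
}

# Candidate-generation keys for Levenshtein<=1 lookup: the string itself plus
# every single-character deletion. Two strings within edit distance 1 always
# share at least one key; sharing a key is necessary, not sufficient, so
# candidates are verified with a real distance computation.
deletion_keys <- function(x) {
  lens <- nchar(x)
  keys <- vector("list", length(x))
  for (L in unique(lens)) {
    i <- which(lens == L)
    xi <- x[i]
    m <- matrix("", nrow = length(xi), ncol = L + 1L)
    m[, 1L] <- xi
    for (p in seq_len(L)) {
      m[, p + 1L] <- paste0(substr(xi, 1L, p - 1L), substr(xi, p + 1L, L))
    }
    keys[i] <- split(m, row(m))
  }
  keys
}
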