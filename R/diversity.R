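#' Round half away from zero
#'
#' Base R rounds half to even; abundance reports here use the conventional
#' round-half-up (e.g. 11.25 prints as 11.3 at one decimal).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalize a count table to reads per million (RPM)
#'
#' @param table Count matrix (barcodes x samples).
#' @return Numeric matrix where every non-empty column sums to 1e6; all-zero
#'   columns are left at zero and listed in attribute `zero_columns`.
#' @export
rpm_normalize <- function(table) {
  totals <- colSums(table)
  zero <- totals == 0
  scale <- ifelse(zero, 1, totals)
  out <- sweep(table, 2L, scale, "/") * 1e6
  out[, zero] <- 0
  attr(out, "zero_columns") <- colnames(table)[zero]
  out
}

#' Per-sample abundance and diversity metrics
#'
#' For each sample the nonzero abundances define: the number of unique
#' barcodes; the coefficient of variation (population SD over mean); the
#' Shannon diversity in bits, \eqn{-\sum p_i \log_2 p_i} over relative
#' abundances; and the quartile ratio Q3/Q1 (linear-interpolation quartiles).
#' A uniform sample of N barcodes attains the Shannon maximum
#' \eqn{\log_2 N}, CV 0 and Q3/Q1 of 1; clonally expanded, long-tailed
#' samples have larger CV and Q3/Q1 and smaller Shannon at equal richness.
#'
#' @param abundance Abundance or count matrix (barcodes x samples); metrics
#'   are scale-invariant per sample.
#' @return A `data.frame` with one row per sample: `sample_id`,
#'   `unique_barcodes`, `cv`, `shannon_bits`, `quartile_ratio`. Samples with
#'   no nonzero barcode get `NA` metrics.
#' @export
diversity_metrics <- function(abundance) {
  samples <- colnames(abundance)
  res <- lapply(seq_along(samples), function(j) {
    x <- abundance[, j]
    x <- x[x > 0]
    n <- length(x)
    if (n == 0L) {
      return(data.frame(sample_id = samples[j], unique_barcodes = 0L,
                        cv = NA_real_, shannon_bits = NA_real_,
                        quartile_ratio = NA_real_))
    }
    p <- x / sum(x)
    shannon <- -sum(p * log2(p))
    cv <- sqrt(mean((x - mean(x))^2)) / mean(x)
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    data.frame(sample_id = samples[j], unique_barcodes = n, cv = cv,
               shannon_bits = shannon, quartile_ratio = q[2] / q[1])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Positional nucleotide composition of a barcode set
#'
#' @param barcodes Character vector of equal-length sequences.
#' @return A 4 x L matrix (rows `A`, `C`, `G`, `T`) of per-position base
#'   frequencies; every column sums to 1.
#' @export
positional_composition <- function(barcodes) {
  if (length(barcodes) == 0L) stop("no barcodes supplied")
  lens <- nchar(barcodes)
  if (length(unique(lens)) != 1L) {
    stop("barcodes have mixed lengths: ",
         paste(utils::head(barcodes[lens != lens[1L]], 5L), collapse = ", "))
  }
  L <- lens[1L]
  m <- matrix(0, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
  for (j in seq_len(L)) {
    tb <- table(factor(substr(barcodes, j, j), levels = BASES))
    m[, j] <- as.numeric(tb) / length(barcodes)
  }
  m
}

#' Expected pairwise Hamming distance of uniform-random sequences
#'
#' Two independent uniform-random sequences of length L disagree at each
#' position with probability 3/4, so the expectation is `L * 3/4` (11.25 for
#' 15-nt barcodes).
#'
#' @param length Sequence length L.
#' @return The expectation `L * 3/4`.
#' @export
expected_pairwise_hamming <- function(length = 15L) {
  as.numeric(length) * 3 / 4
}

#' Mean pairwise Hamming distance over sampled barcode pairs
#'
#' Pairs of distinct indices are sampled uniformly without replacement
#' (rejection sampling over the unordered-pair space); when fewer than
#' `n_pairs` distinct pairs exist, sampling is with replacement instead.
#'
#' @param barcodes Character vector of equal-length sequences (>= 2).
#' @param n_pairs Number of pairs to sample (published value 20000).
#' @param seed Optional integer seed.
#' @return Mean Hamming distance, with attributes `se` (standard error of
#'   the sampled mean) and `n_pairs`.
#' @export
mean_pairwise_hamming <- function(barcodes, n_pairs = 20000L, seed = NULL) {
  n <- length(barcodes)
  if (n < 2L) return(NA_real_)
  if (length(unique(nchar(barcodes))) != 1L) {
    stop("barcodes must have equal lengths")
  }
  if (!is.null(seed)) set.seed(seed)
  space <- n * (n - 1) / 2
  if (space < n_pairs) {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1L, n_pairs, replace = TRUE)
    j <- j + (j >= i)  # uniform over ordered distinct pairs
  } else {
    i <- integer(0)
    j <- integer(0)
    seen <- character(0)
    while (length(i) < n_pairs) {
      need <- n_pairs - length(i)
      ii <- sample.int(n, need, replace = TRUE)
      jj <- sample.int(n - 1L, need, replace = TRUE)
      jj <- jj + (jj >= ii)
      a <- pmin(ii, jj)
      b <- pmax(ii, jj)
      key <- paste(a, b)
      new <- !duplicated(key) & !(key %in% seen)
      i <- c(i, a[new])
      j <- c(j, b[new])
      seen <- c(seen, key[new])
    }
  }
  d <- hamming_distance_pairs(barcodes[i], barcodes[j])
  out <- mean(d)
  attr(out, "se") <- stats::sd(d) / sqrt(length(d))
  attr(out, "n_pairs") <- length(d)
  out
}

#' Mutual-exclusivity statistics from a two-color cell tally
#'
#' Reports the percentage of double-positive cells among all fluorescent
#' cells, its complement (exclusively single-colored cells), and the
#' multi-transgene upper bound: with a 50:50 color mix, a cell carrying two
#' transgenes shows both colors only half the time, so the multi-transgene
#' fraction is at most twice the double-positive fraction.
#'
#' @param tally A [two_color_tally()] or a list with `green_only`,
#'   `red_only`, `double_positive`.
#' @return A list with `pct_double`, `pct_exclusive`,
#'   `pct_multi_upper_bound` (full precision) and `total` fluorescent cells.
#'   `format()`/`print()` round to report precision (2 decimals for the
#'   percentages, 1 for the bound).
#' @export
mutual_exclusivity_stats <- function(tally) {
  total <- tally$green_only + tally$red_only + tally$double_positive
  if (total <= 0) {
    out <- list(pct_double = NA_real_, pct_exclusive = NA_real_,
                pct_multi_upper_bound = NA_real_, total = 0)
    class(out) <- "mutual_exclusivity_stats"
    return(out)
  }
  pct_double <- 100 * tally$double_positive / total
  out <- list(pct_double = pct_double,
              pct_exclusive = 100 - pct_double,
              pct_multi_upper_bound = 2 * pct_double,
              total = total)
  class(out) <- "mutual_exclusivity_stats"
  out
}

#' @export
format.mutual_exclusivity_stats <- function(x, ...) {
  c(pct_double = sprintf("%.2f%%", round_half_up(x$pct_double, 2L)),
    pct_exclusive = sprintf("%.2f%%", round_half_up(x$pct_exclusive, 2L)),
    pct_multi_upper_bound = sprintf("%.1f%%",
                                    round_half_up(x$pct_multi_upper_bound,
                                                  1L)))
}

#' @export
print.mutual_exclusivity_stats <- function(x, ...) {
  f <- format(x)
  cat(sprintf("Double-positive cells      : %s (%d / %d)\n", f[["pct_double"]],
              as.integer(round(x$total * x$pct_double / 100)),
              as.integer(x$total)))
  cat(sprintf("Exclusive single-color     : %s\n", f[["pct_exclusive"]]))
  cat(sprintf("Multi-transgene upper bound: %s\n",
              f[["pct_multi_upper_bound"]]))
  invisible(x)
}

#' Brain-coverage estimate from per-fish fluorescent-neuron counts
#'
#' @param counts Integer vector of fluorescent-neuron counts, one per fish.
#' @param hindbrain_total Estimated total neurons in the structure
#'   (published estimate 25000 for the 5 dpf hindbrain).
#' @return A list: `mean_count` (full precision), `mean_count_printed`
#'   (truncated toward zero, the reporting convention), `pct_of_total`
#'   (rounded to the nearest integer percent) and `pct_of_total_raw`.
#' @export
brain_coverage <- function(counts, hindbrain_total = 25000L) {
  stopifnot(length(counts) >= 1L, all(counts >= 0), hindbrain_total > 0)
  m <- mean(counts)
  pct <- 100 * m / hindbrain_total
  list(mean_count = m,
       mean_count_printed = trunc(m),
       pct_of_total = round_half_up(pct, 0L),
       pct_of_total_raw = pct)
}

#' Per-fish unique-barcode counts and their summary
#'
#' @param table Filtered, collapsed count matrix (barcodes x fish).
#' @return A list with `per_fish` (named integer vector of barcodes with
#'   nonzero count per fish) and `summary` (`mean`, `median`, `sd` — sample
#'   SD, n-1 — and `range`; `sd` is `NA` for a single fish).
#' @export
unique_barcode_summary <- function(table) {
  per_fish <- colSums(table > 0)
  s <- list(mean = mean(per_fish),
            median = stats::median(per_fish),
            sd = if (length(per_fish) > 1L) stats::sd(per_fish) else NA_real_,
            range = range(per_fish))
  list(per_fish = per_fish, summary = s)
}
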