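#' @importFrom stats rbinom rlnorm rgeom runif setNames
#' @import data.table
NULL

BASES <- c("A", "C", "G", "T")

random_barcodes <- function(n, len) {
  m <- sample(BASES, n * len, replace = TRUE)
  dim(m) <- c(n, len)
  do.call(paste0, lapply(seq_len(len), function(j) m[, j]))
}

revcomp_chr <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Generate a random barcoded plasmid library
#'
#' Barcodes are drawn i.i.d. uniform over the four bases, so duplicate
#' sequences can occur with birthday-problem probability (negligible for a
#' 15-nt barcode at realistic library sizes). Relative abundances are either
#' uniform or lognormal-weighted.
#'
#' @param n_members Number of distinct plasmid clones to draw.
#' @param barcode_length Barcode length in nucleotides (default 15).
#' @param abundance_model `"uniform"` or `"lognormal"`.
#' @param lognormal_sigma sdlog of the lognormal abundance weights.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `barcode` and `abundance`
#'   (abundances sum to 1).
#' @export
generate_library <- function(n_members, barcode_length = 15L,
                             abundance_model = c("uniform", "lognormal"),
                             lognormal_sigma = 1, seed = NULL) {
  abundance_model <- match.arg(abundance_model)
  n_members <- as.integer(n_members)
  barcode_length <- as.integer(barcode_length)
  if (is.na(n_members) || n_members < 1L) stop("n_members must be >= 1")
  if (is.na(barcode_length) || barcode_length < 1L) {
    stop("barcode_length must be >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  bc <- random_barcodes(n_members, barcode_length)
  ab <- if (abundance_model == "uniform") {
    rep(1 / n_members, n_members)
  } else {
    w <- rlnorm(n_members, 0, lognormal_sigma)
    w / sum(w)
  }
  data.frame(barcode = bc, abundance = ab)
}

clone_sizes <- function(n, model, k = 1L, p = 0.5, meanlog = 0, sdlog = 1) {
  switch(model,
    fixed = rep(as.integer(k), n),
    geometric = rgeom(n, p) + 1L,
    lognormal = pmax(1L, as.integer(round(rlnorm(n, meanlog, sdlog)))),
    stop("unknown clone_size_model: ", model)
  )
}

#' Simulate mosaic fish: delayed integration plus clonal expansion
#'
#' Each fish undergoes `n_integrations` independent integration events; every
#' event draws exactly one library member (the single landing site admits one
#' barcode per founder cell) and founds a clone whose final size in cells is
#' drawn from the clone-size model. The lognormal default captures the
#' long-tailed clone-size distribution expected from variable integration
#' timing and proliferative capacity.
#'
#' @param library A library from [generate_library()] (columns `barcode`,
#'   `abundance`).
#' @param n_fish Number of fish to simulate.
#' @param n_integrations Integration events per fish (default 1600, the
#'   order observed per animal).
#' @param clone_size_model `"lognormal"`, `"fixed"` or `"geometric"`.
#' @param fixed_k,geom_p,lognormal_meanlog,lognormal_sdlog Model parameters.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `fish_id`, `barcode`, `clone_size`
#'   (one row per distinct barcode per fish; clone sizes of coincident draws
#'   of the same barcode are summed), with attribute `founder_counts`, a
#'   named integer vector of integration events per fish.
#' @export
simulate_mosaic_fish <- function(library, n_fish = 12L, n_integrations = 1600L,
                                 clone_size_model = c("lognormal", "fixed",
                                                      "geometric"),
                                 fixed_k = 1L, geom_p = 0.5,
                                 lognormal_meanlog = 0, lognormal_sdlog = 1,
                                 seed = NULL) {
  clone_size_model <- match.arg(clone_size_model)
  n_fish <- as.integer(n_fish)
  n_integrations <- as.integer(n_integrations)
  if (is.na(n_fish) || n_fish < 0L) stop("n_fish must be >= 0")
  if (is.na(n_integrations) || n_integrations < 1L) {
    stop("n_integrations must be >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  uniform <- length(unique(library$abundance)) == 1L
  per_fish <- vector("list", n_fish)
  fish_ids <- sprintf("fish%02d", seq_len(n_fish))
  for (f in seq_len(n_fish)) {
    idx <- if (uniform) {
      sample.int(nrow(library), n_integrations, replace = TRUE)
    } else {
      sample.int(nrow(library), n_integrations, replace = TRUE,
                 prob = library$abundance)
    }
    sz <- clone_sizes(n_integrations, clone_size_model, k = fixed_k,
                      p = geom_p, meanlog = lognormal_meanlog,
                      sdlog = lognormal_sdlog)
    agg <- rowsum(sz, idx)
    per_fish[[f]] <- data.frame(
      fish_id = fish_ids[f],
      barcode = library$barcode[as.integer(rownames(agg))],
      clone_size = as.integer(agg[, 1L])
    )
  }
  truth <- do.call(rbind, per_fish)
  if (is.null(truth)) {
    truth <- data.frame(fish_id = character(), barcode = character(),
                        clone_size = integer())
  }
  rownames(truth) <- NULL
  attr(truth, "founder_counts") <- setNames(rep(n_integrations, n_fish),
                                            fish_ids)
  truth
}

#' Founder (integration-event) counts of a simulated truth table
#' @param truth Output of [simulate_mosaic_fish()].
#' @return Named integer vector of integration events per fish.
#' @export
founder_counts <- function(truth) attr(truth, "founder_counts")

random_other_base <- function(cur) {
  idx <- match(cur, BASES)
  step <- sample.int(3L, length(cur), replace = TRUE)
  out <- BASES[((idx - 1L + step) %% 4L) + 1L]
  out[is.na(idx)] <- sample(BASES, sum(is.na(idx)), replace = TRUE)
  out
}

#' Inject independent per-base sequencing errors into reads
#'
#' Substitutions, insertions and deletions occur independently per base at
#' uniform rates (no quality model). Substituted bases are replaced by a
#' uniformly chosen different base.
#'
#' @param x Character vector of read sequences.
#' @param substitution_rate,insertion_rate,deletion_rate Per-base error
#'   probabilities in `[0, 1]`.
#' @return Character vector of mutated reads (names preserved).
#' @export
inject_errors <- function(x, substitution_rate = 0, insertion_rate = 0,
                          deletion_rate = 0) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0 | rates > 1)) stop("error rates must be in [0, 1]")
  lens <- nchar(x)
  if (substitution_rate > 0) {
    nerr <- rbinom(length(x), lens, substitution_rate)
    hit <- which(nerr > 0L)
    if (length(hit)) {
      ev_read <- rep(hit, nerr[hit])
      ev_pos <- ceiling(runif(length(ev_read)) * lens[ev_read])
      occ <- stats::ave(seq_along(ev_read), ev_read, FUN = seq_along)
      for (k in seq_len(max(occ))) {
        sel <- occ == k
        i <- ev_read[sel]
        p <- ev_pos[sel]
        s <- x[i]
        substr(s, p, p) <- random_other_base(substr(s, p, p))
        x[i] <- s
      }
    }
  }
  for (kind in c("insertion", "deletion")) {
    rate <- if (kind == "insertion") insertion_rate else deletion_rate
    if (rate <= 0) next
    lens <- nchar(x)
    nerr <- rbinom(length(x), lens, rate)
    for (i in which(nerr > 0L)) {
      for (e in seq_len(nerr[i])) {
        L <- nchar(x[i])
        p <- sample.int(L, 1L)
        x[i] <- if (kind == "insertion") {
          paste0(substr(x[i], 1L, p - 1L), sample(BASES, 1L),
                 substr(x[i], p, L))
        } else {
          paste0(substr(x[i], 1L, p - 1L), substr(x[i], p + 1L, L))
        }
      }
    }
  }
  x
}

#' Simulate amplicon reads for one fish
#'
#' Reads sample the fish's barcodes proportionally to clone size
#' (multinomial), are laid out on the conserved template, reverse-complemented
#' into sequencing orientation, prefixed with the fish's 5-nt multiplexing
#' barcode, and then subjected to per-base errors. With all error rates zero,
#' every read carries its source barcode between exact anchors.
#'
#' @param truth One fish's rows of a [simulate_mosaic_fish()] table
#'   (columns `barcode`, `clone_size`).
#' @param template A [read_template()].
#' @param sample_barcode The fish's multiplexing barcode (length per
#'   template).
#' @param depth Number of reads to emit.
#' @param substitution_rate,insertion_rate,deletion_rate Per-base error
#'   probabilities.
#' @param read_prefix Prefix for read identifiers.
#' @param seed Optional integer seed.
#' @return Named character vector of read sequences in sequencing
#'   orientation (names are read identifiers).
#' @export
simulate_reads <- function(truth, template, sample_barcode, depth,
                           substitution_rate = 0.002, insertion_rate = 1e-5,
                           deletion_rate = 1e-5, read_prefix = "read",
                           seed = NULL) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("depth must be a positive integer")
  if (nchar(sample_barcode) != template$sample_barcode_length) {
    stop("sample_barcode length does not match the template")
  }
  if (!is.null(seed)) set.seed(seed)
  pick <- sample.int(nrow(truth), depth, replace = TRUE,
                     prob = truth$clone_size)
  insert <- template_insert(template, truth$barcode[pick])
  reads <- paste0(toupper(sample_barcode), revcomp_chr(insert))
  reads <- inject_errors(reads, substitution_rate, insertion_rate,
                         deletion_rate)
  names(reads) <- sprintf("%s_%06d", read_prefix, seq_len(depth))
  attr(reads, "source_barcode") <- truth$barcode[pick]
  reads
}

#' Simulate the two-color mutual-exclusivity experiment
#'
#' Every cell independently acquires at most one landing-site integrant
#' (probability `p_landing_integration`; the recombined site cannot accept a
#' second) and, independently, at most one spontaneous enzyme-free integrant
#' (probability `p_spontaneous`). Construct colors are i.i.d. green with
#' probability `color_mix`. Double-positive cells therefore arise only when a
#' spontaneous integrant of the opposite color joins a landing-site
#' integrant.
#'
#' @param n_cells Number of cells (e.g. 25000 for a larval hindbrain).
#' @param p_landing_integration Probability a cell integrates at the landing
#'   site.
#' @param color_mix Fraction of green constructs in the library (0.5 for the
#'   50:50 two-member mix).
#' @param p_spontaneous Probability of an additional spontaneous integration.
#' @param seed Optional integer seed.
#' @return An object of class `two_color_tally`: counts `green_only`,
#'   `red_only`, `double_positive`, plus a `truth` list with the simulated
#'   number of multi-transgene and transduced cells.
#' @export
simulate_two_color <- function(n_cells, p_landing_integration,
                               color_mix = 0.5, p_spontaneous = 0,
                               seed = NULL) {
  stopifnot(n_cells >= 0,
            p_landing_integration >= 0, p_landing_integration <= 1,
            color_mix >= 0, color_mix <= 1,
            p_spontaneous >= 0, p_spontaneous <= 1)
  if (!is.null(seed)) set.seed(seed)
  land <- runif(n_cells) < p_landing_integration
  spont <- runif(n_cells) < p_spontaneous
  # colors belong to integrants, not cells: draw one per potential integrant
  col_land <- runif(n_cells) < color_mix
  col_spont <- runif(n_cells) < color_mix
  green <- (land & col_land) | (spont & col_spont)
  red <- (land & !col_land) | (spont & !col_spont)
  tally <- two_color_tally(
    green_only = sum(green & !red),
    red_only = sum(red & !green),
    double_positive = sum(green & red)
  )
  tally$truth <- list(multi_transgene = sum(land & spont),
                      transduced = sum(land | spont))
  tally
}

#' Construct a two-color cell tally
#' @param green_only,red_only,double_positive Non-negative cell counts.
#' @return An object of class `two_color_tally`.
#' @export
two_color_tally <- function(green_only, red_only, double_positive) {
  stopifnot(green_only >= 0, red_only >= 0, double_positive >= 0)
  structure(list(green_only = as.numeric(green_only),
                 red_only = as.numeric(red_only),
                 double_positive = as.numeric(double_positive)),
            class = "two_color_tally")
}
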