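test_that("generate_library returns the requested members with unit mass", {
  one <- generate_library(1, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$abundance, 1.0)

  lib <- generate_library(2000, barcode_length = 15, seed = 2)
  expect_equal(nrow(lib), 2000L)
  expect_equal(sum(lib$abundance), 1.0)
  expect_true(all(nchar(lib$barcode) == 15))
  expect_identical(lib, generate_library(2000, barcode_length = 15, seed = 2))
  expect_error(generate_library(0), "n_members")
  expect_error(generate_library(10, barcode_length = 0), "barcode_length")
})

test_that("uniform libraries have near-uniform positional base frequencies", {
  n <- 1e5
  lib <- generate_library(n, seed = 3)
  comp <- positional_composition(lib$barcode)
  # binomial 99% CI around 0.25, Bonferroni-widened across the 60 cells
  z <- stats::qnorm(1 - 0.01 / (2 * 60))
  half <- z * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(comp - 0.25) < half))
  # collision expectation n^2 / (2 * 4^15) < 0.1 at n = 1e4
  lib2 <- generate_library(1e4, seed = 4)
  expect_gte(length(unique(lib2$barcode)), 1e4 - 2)
})

test_that("mosaic fish have one barcode per founder and occupancy collisions", {
  lib <- generate_library(1e6, seed = 5)
  truth <- simulate_mosaic_fish(lib, n_fish = 8, n_integrations = 500,
                                clone_size_model = "fixed", fixed_k = 1,
                                seed = 6)
  expect_equal(unname(founder_counts(truth)), rep(500L, 8))
  # fixed(1) clones: total cells = founders; a rare library collision shows
  # up as one barcode with the summed clone size, never as extra cells
  expect_equal(as.vector(tapply(truth$clone_size, truth$fish_id, sum)),
               rep(500L, 8))
  distinct <- tapply(truth$barcode, truth$fish_id, length)
  # collision expectation 500^2 / (2e6) ~ 0.125 per fish
  expect_true(all(distinct >= 498 & distinct <= 500))
  expect_true(mean(distinct == 500) > 0.5)
})

test_that("lognormal clone sizes reproduce the model CV", {
  lib <- generate_library(1e5, seed = 7)
  sdlog <- 1
  truth <- simulate_mosaic_fish(lib, n_fish = 20, n_integrations = 2000,
                                clone_size_model = "lognormal",
                                lognormal_meanlog = 2, lognormal_sdlog = sdlog,
                                seed = 8)
  # at meanlog 2 the integer rounding barely distorts the continuous model
  cv_model <- sqrt(exp(sdlog^2) - 1)
  cvs <- tapply(truth$clone_size, truth$fish_id,
                function(x) stats::sd(x) / mean(x))
  se <- stats::sd(cvs) / sqrt(length(cvs))
  expect_lt(abs(mean(cvs) - cv_model), 3 * se + 0.02)
})

test_that("error-free reads carry their source barcode between exact anchors", {
  tpl <- small_template()
  truth <- data.frame(fish_id = "f", barcode = random_seqs(1, 15),
                      clone_size = 5L)
  reads <- simulate_reads(truth, tpl, "TTGAC", depth = 100,
                          substitution_rate = 0, insertion_rate = 0,
                          deletion_rate = 0, seed = 9)
  expect_length(reads, 100L)
  expect_true(all(substr(reads, 1, 5) == "TTGAC"))
  obs <- extract_barcodes(reverse_complement(reads), tpl)
  expect_equal(nrow(obs), 100L)
  expect_true(all(obs$match_stage == "exact"))
  expect_true(all(obs$barcode == truth$barcode))
  expect_error(simulate_reads(truth, tpl, "TTGAC", depth = 0), "depth")
})

test_that("substitutions hit the upstream anchor at the binomial rate", {
  tpl <- small_template()
  rate <- 0.002
  truth <- data.frame(fish_id = "f", barcode = random_seqs(1, 15),
                      clone_size = 1L)
  n <- 2e4
  reads <- simulate_reads(truth, tpl, "TTGAC", depth = n,
                          substitution_rate = rate, insertion_rate = 0,
                          deletion_rate = 0, seed = 10)
  oriented <- reverse_complement(reads)
  o <- tpl$expected_anchor_offset
  anchor_seen <- substr(oriented, o, o + 11)
  p_hit <- mean(anchor_seen != tpl$upstream_anchor)
  p_expect <- 1 - (1 - rate)^12
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(p_hit - p_expect), 4 * se)
})

test_that("read counts per barcode follow clone-size proportions", {
  tpl <- small_template()
  set.seed(14)
  truth <- data.frame(fish_id = "f", barcode = random_seqs(20, 15),
                      clone_size = sample(1:40, 20, replace = TRUE))
  reads <- simulate_reads(truth, tpl, "TTGAC", depth = 1e5,
                          substitution_rate = 0, insertion_rate = 0,
                          deletion_rate = 0, seed = 15)
  obs <- extract_barcodes(reverse_complement(reads), tpl)
  counts <- table(factor(obs$barcode, levels = truth$barcode))
  gof <- stats::chisq.test(as.integer(counts),
                           p = truth$clone_size / sum(truth$clone_size))
  expect_gt(gof$p.value, 0.001)
})

test_that("two-color double positives require spontaneous co-integration", {
  off <- simulate_two_color(20000, 0.1, 0.5, p_spontaneous = 0, seed = 16)
  expect_equal(off$double_positive, 0)
  expect_equal(off$truth$multi_transgene, 0L)

  sim <- simulate_two_color(4e5, 0.1, 0.5, p_spontaneous = 0.02, seed = 17)
  stats <- mutual_exclusivity_stats(sim)
  # doubling the double-positive fraction estimates the multi-transgene rate
  multi_pct <- 100 * sim$truth$multi_transgene / stats$total
  p <- stats$pct_double / 100
  se_pct <- 2 * 100 * sqrt(p * (1 - p) / stats$total)
  expect_lt(abs(stats$pct_multi_upper_bound - multi_pct), 3 * se_pct)
})

test_that("transduced-cell counts match the binomial expectation", {
  sim <- simulate_two_color(25000, 0.05, 0.5, p_spontaneous = 0, seed = 18)
  n_fluor <- sim$green_only + sim$red_only + sim$double_positive
  se <- sqrt(25000 * 0.05 * 0.95)
  expect_lt(abs(n_fluor - 1250), 4 * se)
})

test_that("simulation outputs are bit-identical under a fixed seed", {
  cfg <- default_config(seed = 42)
  cfg$library$n_members <- 500
  cfg$fish$n_fish <- 2
  cfg$fish$n_integrations <- 50
  cfg$reads$coverage_per_clone <- 5
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_simulation(cfg, d1)
  run_simulation(cfg, d2)
  r1 <- read_fastq(file.path(d1, "reads.fastq.gz"))
  r2 <- read_fastq(file.path(d2, "reads.fastq.gz"))
  expect_identical(r1, r2)
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
})
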