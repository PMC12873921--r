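test_that("reverse_complement is a strict involution with N handling", {
  expect_equal(unname(reverse_complement("ACGT")), "ACGT")
  expect_equal(unname(reverse_complement("AAAC")), "GTTT")
  expect_equal(unname(reverse_complement("ANCG")), "CGNT")
  x <- setNames(random_seqs(20, 30), paste0("r", 1:20))
  expect_identical(reverse_complement(reverse_complement(x)), x)
  expect_error(reverse_complement(c(bad = "ACXT")), "bad")
})

test_that("demultiplex assigns on unique within-tolerance matches only", {
  sheet <- sample_sheet(c(A = "TTGAC", B = "GGCAT"))
  tail <- strrep("A", 20)
  reads <- setNames(paste0(c("TTGAC", "TTGAT", "GGCAT", "CCCCC"), tail),
                    c("exact_A", "onemm_A", "exact_B", "nomatch"))
  dm <- demultiplex(reads, sheet)
  expect_equal(unname(dm$assignment), c("A", "A", "B", NA))
  expect_equal(names(dm$unassigned), "nomatch")
  expect_equal(length(dm$samples$A) + length(dm$samples$B) +
                 length(dm$unassigned), length(reads))

  # ambiguity: distance 1 to two entries -> unassigned
  amb_sheet <- suppressWarnings(sample_sheet(c(A = "TTGAC", B = "TTGAA")))
  dm2 <- demultiplex(setNames(paste0("TTGAG", tail), "amb"), amb_sheet)
  expect_equal(unname(dm2$assignment), NA_character_)
  expect_error(sample_sheet(c(A = "TTGAC", B = "TTGAC")), "duplicate")
})

test_that("the progressive ladder recovers barcodes through anchor damage", {
  tpl <- small_template()
  bc <- "GATTACAGATTACAG"
  insert <- paste0("TGGTCGAG", tpl$upstream_anchor, bc, "CACGC", "GGGTCATT")
  o <- tpl$expected_anchor_offset

  hit <- extract_barcode(insert, tpl)
  expect_equal(hit$barcode, bc)
  expect_equal(hit$match_stage, "exact")
  expect_equal(hit$anchor_position, o)

  # two substitutions inside the anchor -> hamming stage
  dam <- insert
  substr(dam, o, o) <- "T"          # A -> T
  substr(dam, o + 3, o + 3) <- "A"  # C -> A
  hit <- extract_barcode(dam, tpl)
  expect_equal(hit$barcode, bc)
  expect_equal(hit$match_stage, "hamming")

  # 1-nt deletion inside the anchor -> levenshtein stage, shifted slot
  del <- paste0(substr(insert, 1, o + 4), substr(insert, o + 6, nchar(insert)))
  hit <- extract_barcode(del, tpl)
  expect_equal(hit$barcode, bc)
  expect_equal(hit$match_stage, "levenshtein")

  # corrupted downstream anchor -> none
  baddown <- insert
  substr(baddown, o + 12 + 15, o + 12 + 15) <- "T"
  expect_null(extract_barcode(baddown, tpl))

  # N inside the barcode slot -> none
  nread <- insert
  substr(nread, o + 14, o + 14) <- "N"
  expect_null(extract_barcode(nread, tpl))

  # anchor shifted beyond even the widened Levenshtein window -> none
  shifted <- paste0(strrep("C", tpl$position_tolerance + 6), insert)
  expect_null(extract_barcode(shifted, tpl))
})

test_that("the ladder matches brute-force offset/edit-script search", {
  tpl <- small_template()
  set.seed(21)
  reads <- character(0)
  # planted reads with graded damage
  for (i in 1:400) {
    bc <- random_seqs(1, 15)
    r <- paste0("TGGTCGAG", tpl$upstream_anchor, bc, "CACGC",
                random_seqs(1, sample(5:12, 1)))
    nsub <- sample(0:3, 1)
    r <- inject_errors(r, substitution_rate = nsub / nchar(r))
    if (runif(1) < 0.3) r <- inject_errors(r, deletion_rate = 1 / nchar(r))
    if (runif(1) < 0.2) r <- inject_errors(r, insertion_rate = 1 / nchar(r))
    reads <- c(reads, r)
  }
  # pure random reads (mostly unextractable)
  reads <- c(reads, random_seqs(600, 60), random_seqs(50, 25))
  names(reads) <- paste0("r", seq_along(reads))

  obs <- extract_barcodes(reads, tpl)
  got <- setNames(rep(NA_character_, length(reads)), names(reads))
  got[obs$read_id] <- paste(obs$barcode, obs$match_stage, obs$anchor_position)
  want <- vapply(reads, function(r) {
    h <- oracle_extract(r, tpl)
    if (is.null(h)) NA_character_ else paste(h$barcode, h$stage, h$pos)
  }, character(1))
  expect_identical(unname(got), unname(want))
})

test_that("truncating the stage ladder never changes earlier-stage results", {
  tpl <- small_template()
  set.seed(22)
  reads <- character(0)
  for (i in 1:150) {
    bc <- random_seqs(1, 15)
    r <- paste0("TGGTCGAG", tpl$upstream_anchor, bc, "CACGC", "GGGTCATT")
    r <- inject_errors(r, substitution_rate = sample(0:3, 1) / nchar(r),
                       deletion_rate = 0.01)
    reads <- c(reads, r)
  }
  names(reads) <- paste0("r", seq_along(reads))
  full <- extract_barcodes(reads, tpl)
  for (k in 1:2) {
    trunc_stages <- c("exact", "hamming", "levenshtein")[seq_len(k)]
    part <- extract_barcodes(reads, tpl, stages = trunc_stages)
    keep <- full[full$match_stage %in% trunc_stages, ]
    rownames(keep) <- rownames(part) <- NULL
    attr(keep, "log") <- attr(part, "log") <- NULL
    expect_identical(part, keep, label = paste("stages <=", k))
  }
})

test_that("extraction yield is total at zero error and monotone in noise", {
  tpl <- small_template()
  truth <- data.frame(fish_id = "f", barcode = random_seqs(5, 15),
                      clone_size = rep(2L, 5))
  rates <- c(0, 0.005, 0.02, 0.08)
  yield <- vapply(seq_along(rates), function(i) {
    reads <- simulate_reads(truth, tpl, "TTGAC", depth = 3000,
                            substitution_rate = rates[i], insertion_rate = 0,
                            deletion_rate = 0, seed = 30 + i)
    obs <- extract_barcodes(reverse_complement(reads), tpl)
    nrow(obs) / 3000
  }, numeric(1))
  expect_equal(yield[1], 1)
  expect_true(all(diff(yield) <= 0))
})

test_that("read accounting is conserved through demux and extraction", {
  cfg <- default_config(seed = 23)
  cfg$library$n_members <- 300
  cfg$fish$n_fish <- 2
  cfg$fish$n_integrations <- 40
  cfg$reads$coverage_per_clone <- 10
  dir <- withr::local_tempdir()
  sim <- run_simulation(cfg, dir)
  res <- run_pipeline(sim$paths$fastq, sim$paths$sheet, cfg)
  m <- res$manifest
  expect_equal(m$reads_assigned + m$reads_unassigned, m$reads_input)
  ex <- m$extraction
  expect_equal(ex$extracted + ex$no_anchor + ex$bad_downstream +
                 ex$barcode_N + ex$truncated, ex$input)
  expect_equal(ex$stage_exact + ex$stage_hamming + ex$stage_levenshtein,
               ex$extracted)
  expect_equal(ex$input, m$reads_assigned)
})

test_that("tally_observations counts per (barcode, sample) cell", {
  obs <- data.frame(barcode = c("X", "X", "X", "Y"),
                    sample_id = c("fish1", "fish1", "fish1", "fish2"))
  tab <- tally_observations(obs)
  expect_equal(tab["X", "fish1"], 3L)
  expect_equal(tab["Y", "fish2"], 1L)
  expect_equal(tab["X", "fish2"], 0L)
  expect_equal(sum(tab), nrow(obs))
  empty <- tally_observations(data.frame(barcode = character(),
                                         sample_id = character()))
  expect_equal(nrow(empty), 0L)
})
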