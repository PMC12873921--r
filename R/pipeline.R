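#' Default pipeline configuration
#'
#' One nested list drives both the simulator and the analysis pipeline; it
#' round-trips losslessly through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]). The defaults are the study conditions the
#' package emulates: 12 fish, 1600 integration events per fish drawn from a
#' 1e6-member uniform 15-nt library, lognormal clone sizes, 50 reads per
#' clone mean depth, substitution rate 0.002 with rare indels, demultiplexing
#' at 1 mismatch and anchored extraction at the published tolerances.
#'
#' @param seed Master seed for every stochastic stage.
#' @return A nested configuration list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    library = list(n_members = 1e6, barcode_length = 15L,
                   abundance_model = "uniform", lognormal_sigma = 1),
    fish = list(n_fish = 12L, n_integrations = 1600L,
                clone_size_model = "lognormal", lognormal_meanlog = 0,
                lognormal_sdlog = 1, fixed_k = 1L, geom_p = 0.5),
    reads = list(coverage_per_clone = 50, substitution_rate = 0.002,
                 insertion_rate = 1e-5, deletion_rate = 1e-5),
    demux = list(max_mismatch = 1L),
    template = list(),  # overrides for read_template() arguments
    filter = list(min_reads_per_fish = 3L, min_reads_library = 2L,
                  template_artifact_max_dist = 2L),
    stats = list(n_pairs = 20000L, hindbrain_total = 25000L)
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return For `read_pipeline_config()`, a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- utils::modifyList(unclass(default_config()),
                           yaml::read_yaml(path))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config` list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_template <- function(config) {
  do.call(read_template, config$template)
}

#' Generate well-separated multiplexing barcodes
#'
#' Greedy rejection sampling of random barcodes with pairwise Hamming
#' distance at least `min_dist`, so one sequencing error cannot move a read
#' between samples at the 1-mismatch demultiplexing tolerance.
#'
#' @param n Number of barcodes.
#' @param len Barcode length (5).
#' @param min_dist Minimum pairwise Hamming distance (3).
#' @param seed Optional integer seed.
#' @return Character vector of `n` barcodes.
#' @export
make_sample_barcodes <- function(n, len = 5L, min_dist = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kept <- character(0)
  tries <- 0L
  while (length(kept) < n) {
    cand <- random_barcodes(1L, len)
    if (length(kept) == 0L ||
        all(hamming_distance(kept, cand) >= min_dist)) {
      kept <- c(kept, cand)
    }
    tries <- tries + 1L
    if (tries > 100000L) stop("cannot place ", n, " barcodes of length ", len,
                              " at pairwise distance >= ", min_dist)
  }
  kept
}

#' Simulate a full barcoded-transgenesis experiment to disk
#'
#' Generates the plasmid library, the mosaic fish (integration plus clonal
#' expansion), pooled amplicon reads in sequencing orientation, and writes
#' FASTQ, ground-truth and sample-sheet files consumable by
#' [run_pipeline()] unchanged, plus the echoed configuration and a manifest.
#'
#' @param config A [default_config()]-style configuration.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the `truth` table, `sample_sheet`, file
#'   `paths` and the `manifest`.
#' @export
run_simulation <- function(config = default_config(), out_dir) {
  if (is.null(config$library) || is.null(config$fish) ||
      is.null(config$reads)) {
    stop("configuration lacks a simulation block (library/fish/reads)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  template <- config_template(config)

  lib <- generate_library(config$library$n_members,
                          config$library$barcode_length,
                          config$library$abundance_model,
                          config$library$lognormal_sigma)
  truth <- simulate_mosaic_fish(
    lib, n_fish = config$fish$n_fish,
    n_integrations = config$fish$n_integrations,
    clone_size_model = config$fish$clone_size_model,
    fixed_k = config$fish$fixed_k, geom_p = config$fish$geom_p,
    lognormal_meanlog = config$fish$lognormal_meanlog,
    lognormal_sdlog = config$fish$lognormal_sdlog
  )
  fish_ids <- names(founder_counts(truth))
  sbc <- make_sample_barcodes(length(fish_ids),
                              template$sample_barcode_length)
  sheet <- if (length(fish_ids)) {
    sample_sheet(setNames(sbc, fish_ids),
                 max_mismatch = config$demux$max_mismatch)
  } else NULL

  depth_cfg <- config$reads
  reads <- vector("list", length(fish_ids))
  if (length(fish_ids)) for (f in seq_along(fish_ids)) {
    tf <- truth[truth$fish_id == fish_ids[f], , drop = FALSE]
    depth <- if (!is.null(depth_cfg$depth)) depth_cfg$depth else
      round(depth_cfg$coverage_per_clone * config$fish$n_integrations)
    reads[[f]] <- simulate_reads(
      tf, template, sheet$entries[[fish_ids[f]]], depth,
      substitution_rate = depth_cfg$substitution_rate,
      insertion_rate = depth_cfg$insertion_rate,
      deletion_rate = depth_cfg$deletion_rate,
      read_prefix = fish_ids[f]
    )
    attr(reads[[f]], "source_barcode") <- NULL
  }
  pooled <- unlist(reads)

  paths <- list(
    fastq = file.path(out_dir, "reads.fastq.gz"),
    truth = file.path(out_dir, "truth.tsv"),
    sheet = file.path(out_dir, "sample_sheet.tsv"),
    config = file.path(out_dir, "config.yaml"),
    manifest = file.path(out_dir, "sim_manifest.json")
  )
  if (length(pooled)) write_fastq(pooled, paths$fastq) else
    file.create(paths$fastq)
  write_tsv(truth, paths$truth)
  write_tsv(data.frame(sample_id = fish_ids, barcode = sbc), paths$sheet)
  write_pipeline_config(config, paths$config)
  manifest <- list(
    stage = "simulation",
    seed = config$seed,
    n_fish = length(fish_ids),
    n_reads = length(pooled),
    n_truth_barcodes = nrow(truth),
    package_version = as.character(utils::packageVersion("mosaicbc"))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(truth = truth, sample_sheet = sheet, paths = paths,
                 manifest = manifest))
}

#' Run the analysis pipeline end to end
#'
#' Executes the published stage order — demultiplex, reverse-complement,
#' anchored barcode extraction, Levenshtein-1 collapse, per-fish read-count
#' filter, template-artifact removal, RPM normalisation and diversity
#' statistics — with full read accounting at every boundary.
#'
#' @param reads Named character vector of raw reads, or a FASTQ path.
#' @param sheet A [sample_sheet()] or a sample-sheet TSV path.
#' @param config A [default_config()]-style configuration (template, filter
#'   and stats options are taken from it).
#' @param sample_class `"fish"` (per-fish >= 3-read filter) or
#'   `"source_library"` (>= 2-read filter).
#' @param out_dir Optional output directory; when given, all intermediate
#'   tables, the diversity report and the manifest are written there.
#' @return A list with `counts_raw`, `collapse` (table + map),
#'   `counts_filtered`, `counts_final`, `rpm`, `diversity`,
#'   `unique_summary`, `mean_hamming`, and `manifest`.
#' @export
run_pipeline <- function(reads, sheet, config = default_config(),
                         sample_class = "fish", out_dir = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.character(sheet) && length(sheet) == 1L) {
    sheet <- read_sample_sheet(sheet, config$demux$max_mismatch)
  }
  template <- config_template(config)
  policy <- filter_policy(config$filter$min_reads_per_fish,
                          config$filter$min_reads_library,
                          config$filter$template_artifact_max_dist)

  dm <- demultiplex(reads, sheet)
  obs_list <- vector("list", length(dm$samples))
  ext_log <- NULL
  for (s in seq_along(dm$samples)) {
    sid <- names(dm$samples)[s]
    r <- dm$samples[[s]]
    if (length(r) == 0L) {
      obs_list[[s]] <- NULL
      next
    }
    oriented <- reverse_complement(r)
    obs <- extract_barcodes(oriented, template)
    lg <- attr(obs, "log")
    ext_log <- if (is.null(ext_log)) lg else ext_log + lg
    if (nrow(obs)) obs$sample_id <- sid
    obs_list[[s]] <- obs
  }
  obs <- do.call(rbind, obs_list)
  if (is.null(obs)) {
    obs <- data.frame(read_id = character(), barcode = character(),
                      match_stage = character(), anchor_position = integer(),
                      sample_id = character())
  }
  if (is.null(ext_log)) {
    ext_log <- c(input = 0L, extracted = 0L, stage_exact = 0L,
                 stage_hamming = 0L, stage_levenshtein = 0L, no_anchor = 0L,
                 bad_downstream = 0L, barcode_N = 0L, truncated = 0L)
  }
  counts_raw <- tally_observations(obs, samples = names(sheet$entries))

  collapsed <- collapse_barcodes(counts_raw)
  counts_filtered <- filter_counts(collapsed$table, policy, sample_class)
  counts_final <- remove_template_artifacts(
    counts_filtered, template, policy$template_artifact_max_dist)
  rpm <- rpm_normalize(counts_final)
  diversity <- diversity_metrics(rpm)
  uniq <- unique_barcode_summary(counts_final)
  mh <- if (nrow(counts_final) >= 2L) {
    mean_pairwise_hamming(rownames(counts_final),
                          n_pairs = config$stats$n_pairs,
                          seed = config$seed)
  } else NA_real_

  manifest <- list(
    stage = "pipeline",
    seed = config$seed,
    reads_input = length(reads),
    reads_assigned = sum(!is.na(dm$assignment)),
    reads_unassigned = length(dm$unassigned),
    extraction = as.list(ext_log),
    barcodes_pre_collapse = nrow(counts_raw),
    barcodes_post_collapse = nrow(collapsed$table),
    barcodes_post_filter = nrow(counts_filtered),
    barcodes_post_artifact_removal = nrow(counts_final),
    artifact_removed = nrow(attr(counts_final, "removed")),
    reads_pre_collapse = sum(counts_raw),
    reads_post_collapse = sum(collapsed$table),
    package_version = as.character(utils::packageVersion("mosaicbc"))
  )
  stopifnot(manifest$reads_assigned + manifest$reads_unassigned ==
              manifest$reads_input,
            manifest$reads_pre_collapse == manifest$reads_post_collapse)

  out <- list(counts_raw = counts_raw, collapse = collapsed,
              counts_filtered = counts_filtered, counts_final = counts_final,
              rpm = rpm, diversity = diversity, unique_summary = uniq,
              mean_hamming = mh, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(counts_raw, file.path(out_dir, "counts_raw.tsv"))
    write_tsv(collapsed$map, file.path(out_dir, "collapse_map.tsv"))
    write_count_table(collapsed$table,
                      file.path(out_dir, "counts_collapsed.tsv"))
    write_count_table(counts_final, file.path(out_dir, "counts_final.tsv"))
    write_count_table(rpm, file.path(out_dir, "rpm.tsv"))
    write_tsv(diversity, file.path(out_dir, "diversity.tsv"))
    rm_df <- attr(counts_final, "removed")
    write_tsv(rm_df, file.path(out_dir, "artifact_removed.tsv"))
    jsonlite::write_json(
      c(manifest,
        list(unique_barcodes = as.list(uniq$per_fish),
             unique_summary = uniq$summary,
             mean_pairwise_hamming = as.numeric(mh))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
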