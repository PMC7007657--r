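#' Evaluation options
#'
#' Collects the metric, projection and statistics settings used across the
#' pipeline; every default here is a documented methodological choice
#' (symmetric MSD, classical 100th-percentile Hausdorff, unsigned
#' deviations, 64 x 64 projection pixels, exact Wilcoxon).
#'
#' @param msd_mode `"symmetric"` or `"directed"` (see
#'   [mean_surface_distance()]).
#' @param hd_percentile Hausdorff percentile, default 100 (classical HD).
#' @param topology tag records with [check_topology()] results?
#' @param project build per-record projection grids for population maps?
#' @param pixel_shape projection pixels per plane axis.
#' @param percentiles population map percentiles.
#' @param min_scans minimum contributing scans per map pixel.
#' @param stats_mode Wilcoxon mode, `"exact"` or `"approximate"`.
#' @return list of options.
#' @export
evaluate_options <- function(msd_mode = "symmetric", hd_percentile = 100,
                             topology = TRUE, project = TRUE,
                             pixel_shape = c(64, 64),
                             percentiles = c(50, 90), min_scans = 1,
                             stats_mode = "exact") {
  list(msd_mode = msd_mode, hd_percentile = hd_percentile,
       topology = topology, project = project,
       pixel_shape = as.integer(pixel_shape),
       percentiles = percentiles, min_scans = min_scans,
       stats_mode = stats_mode)
}

# Accumulator for evaluation results across patients.
new_eval_accum <- function() {
  list(records = list(), volumes = list(), grids = list(), boxes = list())
}

accum_record <- function(acc, out, structure, arm, opts) {
  acc$records[[length(acc$records) + 1]] <- out$record
  if (opts$project && !is.null(out$sds) && length(out$sds$distances)) {
    box <- out$box
    pg <- project_deviations(out$sds, box, opts$pixel_shape)
    key <- paste(structure, arm, sep = "\r")
    if (is.null(acc$grids[[key]])) acc$grids[[key]] <- list()
    acc$grids[[key]][[length(acc$grids[[key]]) + 1]] <- pg
    if (is.null(acc$boxes[[structure]])) acc$boxes[[structure]] <- list()
    acc$boxes[[structure]][[length(acc$boxes[[structure]]) + 1]] <- box
  }
  acc
}

# Evaluate one mask pair inside the pipeline.
eval_pair <- function(test, ref, labels, opts) {
  rec <- metric_record_shell(labels, test, ref)
  out <- compare_impl(test, ref, rec, opts$msd_mode,
                      opts$hd_percentile, opts$topology)
  if (!is.null(out$sds)) out$box <- bounding_box(test)
  out
}

# Evaluate every propagated / re-delineated mask of one simulated patient
# against the ground truth of its scan.
evaluate_patient_sim <- function(pat, opts) {
  acc <- new_eval_accum()
  for (scan in names(pat$gt))
    for (st in names(pat$gt[[scan]]))
      acc$volumes[[length(acc$volumes) + 1]] <- data.frame(
        patient_id = pat$patient_id, scan_id = scan, structure = st,
        volume_cm3 = volume(pat$gt[[scan]][[st]]),
        stringsAsFactors = FALSE)
  for (scan in c("pMR", "MR10", "MR20", "MR30")) {
    for (st in names(pat$gt[[scan]])) {
      ref <- pat$gt[[scan]][[st]]
      tests <- list()
      if (!is.null(pat$prop$CT_MR[[scan]][[st]]))
        tests$CT_MR <- pat$prop$CT_MR[[scan]][[st]]
      if (!is.null(pat$prop$MR_MR[[scan]][[st]]))
        tests$MR_MR <- pat$prop$MR_MR[[scan]][[st]]
      if (scan == "pMR" && !is.null(pat$iov[[st]]))
        tests$IOV <- pat$iov[[st]]
      for (arm in names(tests)) {
        out <- eval_pair(tests[[arm]], ref,
                         list(patient_id = pat$patient_id, scan_id = scan,
                              structure = st, arm = arm), opts)
        acc <- accum_record(acc, out, st, arm, opts)
      }
    }
  }
  acc
}

merge_accums <- function(accums) {
  merged <- new_eval_accum()
  merged$records <- do.call(rbind, unlist(lapply(accums, `[[`, "records"),
                                          recursive = FALSE))
  merged$volumes <- do.call(rbind, unlist(lapply(accums, `[[`, "volumes"),
                                          recursive = FALSE))
  for (acc in accums) {
    for (key in names(acc$grids))
      merged$grids[[key]] <- c(merged$grids[[key]], acc$grids[[key]])
    for (st in names(acc$boxes))
      merged$boxes[[st]] <- c(merged$boxes[[st]], acc$boxes[[st]])
  }
  rownames(merged$records) <- NULL
  merged
}

role_to_arm <- function(role) {
  c(propagated_CT_MR = "CT_MR", propagated_MR_MR = "MR_MR",
    redelineation_IOV = "IOV")[role]
}

#' Evaluate a cohort: metric records, volumes, projection grids
#'
#' Computes one metric record per propagated / re-delineated structure
#' against the ground truth of its scan, the ground-truth volume table,
#' and (optionally) the per-scan surface-deviation projection grids that
#' feed the population maps. Accepts either an in-memory `dirqa_cohort`
#' from [simulate_cohort()] or a manifest data frame whose `path` column
#' points at mask files; in the latter case masks on differing grids are
#' resampled onto the finer grid before comparison.
#'
#' @param x a `dirqa_cohort` or a validated manifest data frame.
#' @param opts an [evaluate_options()] list.
#' @return list with `records` (metric table), `gt_volumes`, `grids`
#'   (per structure/arm lists of projection grids), `boxes` (per-structure
#'   bounding boxes of evaluated masks).
#' @export
evaluate_cohort <- function(x, opts = evaluate_options()) {
  UseMethod("evaluate_cohort")
}

#' @export
evaluate_cohort.dirqa_cohort <- function(x, opts = evaluate_options()) {
  accums <- lapply(x$patients, evaluate_patient_sim, opts = opts)
  finish_eval(merge_accums(accums))
}

#' @export
evaluate_cohort.data.frame <- function(x, opts = evaluate_options()) {
  validate_manifest(x)
  if (any(is.na(x$path)))
    stop("manifest has records without file paths")
  acc <- new_eval_accum()
  gt_rows <- x[x$role == "ground_truth", ]
  for (r in seq_len(nrow(gt_rows))) {
    gtr <- gt_rows[r, ]
    ref <- read_mask(gtr$path, label = gtr$structure)
    acc$volumes[[length(acc$volumes) + 1]] <- data.frame(
      patient_id = gtr$patient_id, scan_id = gtr$scan_id,
      structure = gtr$structure, volume_cm3 = volume(ref),
      stringsAsFactors = FALSE)
    tests <- x[x$role != "ground_truth" &
                 x$patient_id == gtr$patient_id &
                 x$scan_id == gtr$scan_id &
                 x$structure == gtr$structure, ]
    if (!nrow(tests)) next
    for (tr in seq_len(nrow(tests))) {
      test <- read_mask(tests$path[tr], label = tests$structure[tr])
      h <- harmonize_grids(test, ref)
      arm <- unname(role_to_arm(tests$role[tr]))
      out <- eval_pair(h$test, h$ref,
                       list(patient_id = gtr$patient_id,
                            scan_id = gtr$scan_id,
                            structure = gtr$structure, arm = arm), opts)
      acc <- accum_record(acc, out, gtr$structure, arm, opts)
    }
  }
  finish_eval(acc)
}

finish_eval <- function(acc) {
  records <- do.call(rbind, if (is.data.frame(acc$records)) list(acc$records)
                            else acc$records)
  volumes <- do.call(rbind, if (is.data.frame(acc$volumes)) list(acc$volumes)
                            else acc$volumes)
  rownames(records) <- rownames(volumes) <- NULL
  list(records = records, gt_volumes = volumes,
       grids = acc$grids, boxes = acc$boxes)
}

#' Build the population projection maps from evaluation output
#'
#' For each (structure, arm): per plane and percentile, the pixelwise
#' population percentile over all scan-level projection grids of all
#' patients, with the display aspect from the mean structure.
#'
#' @param ev output of [evaluate_cohort()].
#' @param percentiles population percentiles.
#' @param min_scans minimum contributing scans per pixel.
#' @return Nested list: `maps[[structure]][[arm]][[plane]][[paste0("p", q)]]`.
#' @export
population_maps <- function(ev, percentiles = c(50, 90), min_scans = 1) {
  maps <- list()
  for (key in names(ev$grids)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    st <- parts[1]; arm <- parts[2]
    aspects <- mean_structure_aspect(ev$boxes[[st]])
    for (plane in dirqa_planes()) {
      plane_grids <- lapply(ev$grids[[key]], `[[`, plane)
      for (q in percentiles) {
        maps[[st]][[arm]][[plane]][[paste0("p", q)]] <-
          aggregate_population_map(plane_grids, q, min_scans = min_scans,
                                   aspect = aspects[[plane]])
      }
    }
  }
  maps
}

table1_block <- function(summaries, metric, mode = "exact") {
  med <- population_median_table(summaries)
  med <- med[med$metric == metric, ]
  wide <- stats::reshape(med[, c("structure", "arm", "median")],
                         direction = "wide", idvar = "structure",
                         timevar = "arm")
  names(wide) <- sub("^median\\.", "", names(wide))
  comparisons <- list(c("CT_MR", "MR_MR"), c("CT_MR", "IOV"),
                      c("MR_MR", "IOV"))
  for (cp in comparisons) {
    if (!all(cp %in% unique(summaries$arm))) next
    pc <- paired_comparison(summaries, cp[1], cp[2], mode = mode)
    pc <- pc[pc$metric == metric, ]
    tag <- paste(cp, collapse = "_vs_")
    wide[[paste0("delta_", tag)]] <-
      pc$delta[match(wide$structure, pc$structure)]
    wide[[paste0("p_", tag)]] <-
      pc$p_value[match(wide$structure, pc$structure)]
  }
  rownames(wide) <- NULL
  wide
}

#' Run the full evaluation pipeline
#'
#' Simulates (or ingests) a cohort, evaluates every record, and writes the
#' complete set of outputs to `out_dir`: `metrics.csv` (one row per
#' propagated / re-delineated structure, failures flagged, never dropped),
#' `table1_dsc.csv` / `table1_msd.csv` / `table1_hd.csv` (population
#' medians per arm with pairwise deltas and Wilcoxon p-values),
#' `table2_volumes.csv` (planning CT vs planning MR volumes),
#' `volume_ratio.csv`, `gt_volumes.csv`, percentile projection maps under
#' `maps/` (PNG + exact CSV sidecar), and `run.json` (configuration and
#' option echo with record counts). Outputs are deterministic for a fixed
#' configuration and seed.
#'
#' @param cohort a [cohort_config()] (simulated streaming, one patient in
#'   memory at a time), a `dirqa_cohort`, or a manifest data frame /
#'   manifest CSV path for ingesting masks from disk.
#' @param out_dir output directory, created if needed.
#' @param opts an [evaluate_options()] list.
#' @param render also render PNG maps (CSV sidecars are always written)?
#' @return `out_dir`, invisibly; the in-memory results as attribute
#'   `"results"`.
#' @export
run_pipeline <- function(cohort, out_dir, opts = evaluate_options(),
                         render = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- NULL
  if (inherits(cohort, "cohort_config")) {
    config <- cohort
    accums <- vector("list", config$n_patients)
    for (p in seq_len(config$n_patients)) {
      pat <- simulate_patient(config, p)
      accums[[p]] <- evaluate_patient_sim(pat, opts)
    }
    ev <- finish_eval(merge_accums(accums))
  } else if (inherits(cohort, "dirqa_cohort")) {
    config <- cohort$config
    ev <- evaluate_cohort(cohort, opts)
  } else {
    man <- if (is.character(cohort)) load_manifest(cohort) else cohort
    ev <- evaluate_cohort(man, opts)
  }

  write_metric_table(ev$records, file.path(out_dir, "metrics.csv"))
  readr::write_csv(ev$gt_volumes, file.path(out_dir, "gt_volumes.csv"))

  summaries <- patient_scan_average(ev$records)
  readr::write_csv(summaries, file.path(out_dir, "patient_summaries.csv"))
  for (m in c("dsc", "msd", "hd"))
    readr::write_csv(table1_block(summaries, m, opts$stats_mode),
                     file.path(out_dir, sprintf("table1_%s.csv", m)))

  t2 <- planning_volume_comparison(ev$gt_volumes, mode = opts$stats_mode)
  readr::write_csv(t2, file.path(out_dir, "table2_volumes.csv"))

  vr <- volume_ratio_table(ev$records, ev$gt_volumes)
  readr::write_csv(vr, file.path(out_dir, "volume_ratio.csv"))

  if (opts$project && length(ev$grids)) {
    maps <- population_maps(ev, opts$percentiles, opts$min_scans)
    map_dir <- file.path(out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    for (st in names(maps))
      for (arm in names(maps[[st]]))
        for (plane in names(maps[[st]][[arm]]))
          for (pq in names(maps[[st]][[arm]][[plane]])) {
            mp <- maps[[st]][[arm]][[plane]][[pq]]
            base <- file.path(map_dir,
                              sprintf("%s_%s_%s_%s", st, arm, plane, pq))
            export_map_csv(mp, paste0(base, ".csv"))
            if (render) render_map(mp, paste0(base, ".png"))
          }
  }

  meta <- list(
    package_version = as.character(utils::packageVersion("dirqa")),
    options = opts,
    config = if (!is.null(config))
      c(config[c("n_patients", "resolution", "seed", "amplitudes",
                 "corr_length", "ct_dilation_mm", "pinhole_patients")],
        list(grid = unclass(config$grid))) else NULL,
    counts = list(
      n_records = nrow(ev$records),
      n_propagated = sum(ev$records$arm %in% c("CT_MR", "MR_MR")),
      n_iov = sum(ev$records$arm == "IOV"),
      n_failed = sum(ev$records$status != "ok"),
      n_ratio_skipped = attr(vr, "n_skipped")))
  jsonlite::write_json(meta, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res <- structure(out_dir, results = ev)
  invisible(res)
}
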