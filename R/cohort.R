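scan_index <- function(scan) match(scan, dirqa_scans())

# Patient-level phantom specification: global size factor and center shift
# drawn once per patient, applied on top of the base spec.
patient_spec <- function(config, patient) {
  set.seed(sub_seed(config$seed, patient, 0L, 0L))
  pf <- clamp(exp(stats::rnorm(1, 0, config$patient_cv)), 0.88, 1.12)
  shift <- clamp(stats::rnorm(3, 0, config$patient_jitter_sd), -4, 4)
  spec <- config$phantom
  for (nm in names(spec)) {
    spec[[nm]]$size <- spec[[nm]]$size * pf
    spec[[nm]]$center <- spec[[nm]]$center + shift
    if (!is.null(spec[[nm]]$cc_range))
      spec[[nm]]$cc_range <- spec[[nm]]$cc_range + shift[3]
  }
  spec
}

ct_grid_for <- function(config) {
  if (is.null(config$ct_slice_mm)) return(config$grid)
  g <- config$grid
  extent_cc <- (g$shape[3] - 1) * g$spacing[3]
  voxel_grid(c(g$shape[1:2], floor(extent_cc / config$ct_slice_mm) + 1),
             c(g$spacing[1:2], config$ct_slice_mm), g$origin, g$axis_roles)
}

#' Simulate one synthetic patient
#'
#' Draws the patient's anatomy and produces: ground-truth masks on all
#' five imaging sessions (each with its own anatomical draw; the
#' planning-CT session additionally carries the per-structure CT
#' delineation bias as an exact-Euclidean dilation, optionally on a
#' coarser CT grid); propagated masks for both arms, i.e. the planning
#' masks carried over by the emulated registration — incomplete
#' compensation of the session-to-day anatomy change plus a smooth random
#' residual field with the arm's amplitude, one registration per (planning
#' scan, target scan) shared by all structures; and re-delineated masks on
#' the planning MR displaced by an intra-observer-amplitude field.
#'
#' @param config a [cohort_config()].
#' @param patient patient index in `1:n_patients`.
#' @return List with `patient_id`, `gt` (scan -> structure -> mask),
#'   `prop` (arm -> scan -> structure -> mask), `iov`
#'   (structure -> mask).
#' @export
simulate_patient <- function(config, patient) {
  grid <- config$grid
  spec <- patient_spec(config, patient)
  pinhole <- patient %in% config$pinhole_patients
  # every imaging session gets its own anatomy draw: bladder/rectum filling
  # differs between the CT and MR planning sessions just as it does between
  # treatment fractions
  params <- list()
  gt <- list()
  for (scan in c("pCT", "pMR", "MR10", "MR20", "MR30")) {
    params[[scan]] <- draw_phantom_params(
      spec, seed = sub_seed(config$seed, patient, scan_index(scan), 0L))
    gt[[scan]] <- rasterize_phantom(params[[scan]], grid, pinhole)
  }
  ctg <- ct_grid_for(config)
  gt[["pCT"]] <- lapply(gt[["pCT"]], function(m) {
    d <- config$ct_dilation_mm[m$label]
    m2 <- dilate_mask(m, if (is.na(d)) 0 else d)
    if (!grids_identical(ctg, grid)) m2 <- resample_mask(m2, ctg)
    m2
  })

  # planning masks in the MR frame (CT resampled back onto the MR grid if
  # it lives on a coarser one)
  ct_src <- lapply(gt[["pCT"]], function(m)
    if (grids_identical(m$grid, grid)) m else resample_mask(m, grid))
  mr_src <- gt[["pMR"]]

  prop <- list(CT_MR = list(), MR_MR = list())
  for (scan in c("pMR", "MR10", "MR20", "MR30")) {
    f <- random_displacement_field(
      grid, config$amplitudes[["CT_MR"]], config$corr_length[["CT_MR"]],
      seed = sub_seed(config$seed, patient, scan_index(scan), 1L))
    prop$CT_MR[[scan]] <- propagate_masks(ct_src, params[["pCT"]],
                                          params[[scan]], f,
                                          config$uncompensated[["CT_MR"]])
  }
  for (scan in c("MR10", "MR20", "MR30")) {
    f <- random_displacement_field(
      grid, config$amplitudes[["MR_MR"]], config$corr_length[["MR_MR"]],
      seed = sub_seed(config$seed, patient, scan_index(scan), 2L))
    prop$MR_MR[[scan]] <- propagate_masks(mr_src, params[["pMR"]],
                                          params[[scan]], f,
                                          config$uncompensated[["MR_MR"]])
  }

  fiov <- random_displacement_field(
    grid, config$amplitudes[["IOV"]], config$corr_length[["IOV"]],
    seed = sub_seed(config$seed, patient, scan_index("pMR"), 3L))
  idx <- warp_index(fiov)
  iov <- lapply(mr_src, function(m)
    structure_mask(warp_occ(m$occupancy, idx, grid$shape), grid, m$label))

  list(patient_id = sprintf("P%02d", patient), gt = gt, prop = prop,
       iov = iov)
}

# Carry the planning masks of one registration onto the scan of the day.
# The emulated registration aligns each structure's session anatomy with
# the anatomy of the day via the (known) similarity map between the two
# phantom draws — but incompletely: a residual fraction min(1, nu * |log
# volume ratio|) of that compensation is left out, so small anatomical
# differences are absorbed almost fully while large ones are not. On top
# rides the registration's smooth random residual field (arm amplitude).
# The modality delineation bias of the source is never compensated: it is
# invisible to an image-based registration.
propagate_masks <- function(src_masks, src_params, day_params, field, nu) {
  grid <- field$grid
  coords <- lapply(1:3, function(a) axis_coords(grid, a))
  fx <- as.numeric(field$ux)
  fy <- as.numeric(field$uy)
  fz <- as.numeric(field$uz)
  out <- list()
  for (nm in names(src_masks)) {
    src <- src_masks[[nm]]
    ps <- src_params[[nm]]
    pd <- day_params[[nm]]
    s <- pd$size_factor / ps$size_factor
    # volume scales with the cube of the size factor (square for the tube,
    # whose length is anatomy-fixed)
    m <- (if (ps$family == "tube") 2 else 3) * abs(log(s))
    resid <- min(1, if (nu > 0) nu * m else 0)
    comp <- 1 - resid
    # backward-map displacement of the full compensation: the warped mask
    # equals the source evaluated at x - u(x), so u(x) = x - A^{-1}(x)
    # with A the similarity map source -> day (scale s about the source
    # center, then translate to the day center). The tube's length is not
    # scale-coupled, so its CC axis gets translation only.
    scale_axes <- if (ps$family == "tube") c(TRUE, TRUE, FALSE)
    else c(TRUE, TRUE, TRUE)
    cs <- structure_center(ps)
    cd <- structure_center(pd)
    u1d <- lapply(1:3, function(a) {
      x <- coords[[a]]
      sa <- if (scale_axes[a]) s else 1
      comp * (x - (cs[a] + (x - cd[a]) / sa))
    })
    idx <- warp_source_index_sep_cpp(grid$shape, grid$spacing, fx, fy, fz,
                                     u1d[[1]], u1d[[2]], u1d[[3]])
    out[[nm]] <- structure_mask(warp_occ(src$occupancy, idx, grid$shape),
                                grid, src$label)
  }
  out
}

structure_center <- function(p) {
  ctr <- p$center
  if (p$family == "tube") ctr[3] <- mean(p$cc_range)
  ctr
}

patient_manifest <- function(pat, with_paths = FALSE) {
  rows <- list()
  add <- function(scan, structure, role) {
    path <- if (with_paths)
      sprintf("%s_%s_%s_%s.nii.gz", pat$patient_id, scan, structure, role)
    else NA_character_
    rows[[length(rows) + 1]] <<- data.frame(
      patient_id = pat$patient_id, scan_id = scan, structure = structure,
      role = role, path = path, stringsAsFactors = FALSE)
  }
  for (scan in names(pat$gt))
    for (st in names(pat$gt[[scan]])) add(scan, st, "ground_truth")
  for (arm in names(pat$prop))
    for (scan in names(pat$prop[[arm]]))
      for (st in names(pat$prop[[arm]][[scan]]))
        add(scan, st, paste0("propagated_", arm))
  for (st in names(pat$iov)) add("pMR", st, "redelineation_IOV")
  do.call(rbind, rows)
}

#' Simulate a synthetic cohort
#'
#' Runs [simulate_patient()] for every patient. With `out_dir` the masks
#' are written as NIfTI files (one patient at a time, so memory stays
#' bounded) together with `manifest.csv` and a JSON echo of the
#' configuration; without it the whole cohort is returned in memory
#' (intended for the reduced-resolution grid).
#'
#' The default configuration reproduces the study design counts: 12
#' patients x 8 structures x (4 CT-MR + 3 MR-MR) = 672 propagated
#' structures, plus 96 re-delineations and 480 ground truths.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional output directory (created if needed).
#' @return With `out_dir`: the manifest data frame (paths resolved),
#'   invisibly. Otherwise a `dirqa_cohort`: list with `config`,
#'   `patients`, `manifest`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(out_dir)) {
    patients <- lapply(seq_len(config$n_patients),
                       function(p) simulate_patient(config, p))
    manifest <- do.call(rbind, lapply(patients, patient_manifest))
    validate_manifest(manifest)
    return(structure(list(config = config, patients = patients,
                          manifest = manifest), class = "dirqa_cohort"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifests <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    pat <- simulate_patient(config, p)
    man <- patient_manifest(pat, with_paths = TRUE)
    for (r in seq_len(nrow(man))) {
      m <- cohort_mask(pat, man$scan_id[r], man$structure[r], man$role[r])
      write_mask(m, file.path(out_dir, man$path[r]))
    }
    manifests[[p]] <- man
  }
  manifest <- do.call(rbind, manifests)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  cfg <- config
  cfg$grid <- unclass(cfg$grid)
  jsonlite::write_json(cfg[setdiff(names(cfg), "phantom")],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$path <- file.path(out_dir, manifest$path)
  invisible(manifest)
}

# Fetch one mask out of a simulated patient by manifest coordinates.
cohort_mask <- function(pat, scan, structure, role) {
  switch(role,
         ground_truth = pat$gt[[scan]][[structure]],
         propagated_CT_MR = pat$prop$CT_MR[[scan]][[structure]],
         propagated_MR_MR = pat$prop$MR_MR[[scan]][[structure]],
         redelineation_IOV = pat$iov[[structure]],
         stop("unknown role: ", role))
}
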