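#' Default pelvic phantom specification
#'
#' Parametric stand-ins for the eight delineated pelvic structures on a
#' 128 x 128 x 160 mm field of view (RL x AP x CC): ellipsoids for the
#' prostate and penile bulb, paired small ellipsoids for the seminal
#' vesicles, paired lateral bands for the elective nodal volume CTV56, a
#' curved tube for the rectum, spheres for the bladder and femoral heads.
#' Sizes are mm; `scan_cv` is the log-normal coefficient of variation of
#' the structure size between scans (large for bladder and rectum, whose
#' filling varies, small for rigid structures); `jitter_sd` the mm SD of
#' scan-to-scan center motion.
#'
#' @return Named list of per-structure specifications.
#' @export
default_phantom_spec <- function() {
  list(
    prostate = list(family = "ellipsoid", center = c(64, 74, 70),
                    size = c(21, 20, 22), scan_cv = 0.03, jitter_sd = 1),
    SV = list(family = "paired_ellipsoid", center = c(64, 86, 94),
              size = c(8, 6, 10), offset_rl = 14, scan_cv = 0.05,
              jitter_sd = 1),
    CTV56 = list(family = "paired_ellipsoid", center = c(64, 74, 88),
                 size = c(10, 22, 42), offset_rl = 34, scan_cv = 0.02,
                 jitter_sd = 1),
    rectum = list(family = "tube", center = c(64, 96, 87),
                  size = c(13, 0, 0), cc_range = c(36, 138), curve_amp = 5,
                  scan_cv = 0.08, jitter_sd = 1.5),
    bladder = list(family = "sphere", center = c(64, 62, 106),
                   size = c(28, 28, 28), scan_cv = 0.10, jitter_sd = 2),
    femhead_L = list(family = "sphere", center = c(104, 70, 78),
                     size = c(12, 12, 12), scan_cv = 0.02, jitter_sd = 0.5),
    femhead_R = list(family = "sphere", center = c(24, 70, 78),
                     size = c(12, 12, 12), scan_cv = 0.02, jitter_sd = 0.5),
    penile_bulb = list(family = "ellipsoid", center = c(64, 88, 34),
                       size = c(10, 8, 9), scan_cv = 0.06, jitter_sd = 1))
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study design: 12 patients; scans pCT, pMR and
#' three follow-up MRs; 8 structures; residual propagation error larger
#' for the CT-MR arm than the MR-MR arm and comparable between MR-MR and
#' intra-observer variation; the prostate systematically delineated larger
#' on CT.
#'
#' @param n_patients number of patients.
#' @param resolution `"full"` (1 mm isotropic, 128 x 128 x 160 voxels) or
#'   `"reduced"` (64^3 voxels at 2 x 2 x 2.5 mm, same field of view).
#' @param seed master seed; every patient/scan/arm substream derives from
#'   it deterministically.
#' @param amplitudes mm SD of the residual deformation per arm.
#' @param corr_length mm correlation length of the deformation fields per
#'   arm.
#' @param ct_dilation_mm named per-structure mm dilation applied to the
#'   planning-CT ground truth (modality delineation bias: soft-tissue
#'   boundaries are drawn wider on CT); structures not named get 0.
#' @param uncompensated dimensionless per-arm rate at which the deformable
#'   registration fails to absorb anatomical change: the deterministic
#'   source-to-day compensation of each structure is applied incompletely,
#'   leaving a residual fraction `min(1, uncompensated * |log(V_src /
#'   V_day)|)` of the anatomical difference in place. 0 means anatomy is
#'   always fully compensated (only the random residual field remains); at
#'   1 a volume ratio of 1.2 leaves ~18% of the (small) difference while a
#'   ratio of 2 leaves ~70% of a large one — propagation absorbs small
#'   differences but not large ones. The inter-modality default is higher
#'   (1.5) than the intra-modality one (1.0): a mutual-information CT-MR
#'   registration has little CT soft-tissue contrast to drive deformable
#'   organ boundaries, whereas MR-MR cross-correlation locks onto them.
#' @param pinhole_patients integer patient indices whose bladder is
#'   delineated with a pinhole (genus-1) channel.
#' @param ct_slice_mm if not `NULL`, the planning CT ground truths live on
#'   a coarser grid with this CC slice thickness, exercising the
#'   resampling path of the pipeline.
#' @param phantom phantom specification, see [default_phantom_spec()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 12,
                          resolution = c("full", "reduced"),
                          seed = 1,
                          amplitudes = c(CT_MR = 2.0, MR_MR = 1.0,
                                         IOV = 0.8),
                          corr_length = c(CT_MR = 20, MR_MR = 20, IOV = 12),
                          ct_dilation_mm = c(prostate = 2),
                          uncompensated = c(CT_MR = 1.5, MR_MR = 1.0),
                          pinhole_patients = integer(0),
                          ct_slice_mm = NULL,
                          phantom = default_phantom_spec()) {
  resolution <- match.arg(resolution)
  grid <- if (resolution == "full") {
    voxel_grid(c(128, 128, 160), c(1, 1, 1))
  } else {
    voxel_grid(c(64, 64, 64), c(2, 2, 2.5))
  }
  stopifnot(n_patients >= 1,
            all(c("CT_MR", "MR_MR", "IOV") %in% names(amplitudes)),
            all(amplitudes >= 0), all(corr_length > 0),
            seed == round(seed), abs(seed) < 2^31)
  if (length(uncompensated) == 1L)
    uncompensated <- c(CT_MR = unname(uncompensated),
                       MR_MR = unname(uncompensated))
  stopifnot(all(c("CT_MR", "MR_MR") %in% names(uncompensated)),
            all(uncompensated >= 0))
  if (!is.null(ct_slice_mm)) stopifnot(ct_slice_mm > 0)
  cfg <- list(n_patients = as.integer(n_patients), resolution = resolution,
              grid = grid, seed = as.integer(seed),
              amplitudes = amplitudes, corr_length = corr_length,
              ct_dilation_mm = ct_dilation_mm,
              uncompensated = uncompensated,
              pinhole_patients = as.integer(pinhole_patients),
              ct_slice_mm = ct_slice_mm, phantom = phantom,
              patient_cv = 0.06, patient_jitter_sd = 1.5,
              scans = dirqa_scans(),
              structures = setdiff(dirqa_structures(), "other"))
  class(cfg) <- "cohort_config"
  cfg
}

# Deterministic hierarchical substreams below the master seed: patient in
# 1..n, scan index in 0..5, stream in 0..7; all results stay below 2^31.
sub_seed <- function(master, patient, scan = 0L, stream = 0L) {
  (abs(master) %% 1000000L) * 1000L + patient * 48L + scan * 8L + stream
}

#' Generate one scan's organ phantom set
#'
#' Draws the scan-specific size factors and center shifts for every
#' structure and rasterizes the analytic shapes onto the grid. With zero
#' variability (`scan_cv` and `jitter_sd` all 0) the masks are identical
#' across scans.
#'
#' @param grid a [voxel_grid()].
#' @param spec phantom specification, see [default_phantom_spec()].
#' @param seed scan seed (deterministic masks for a fixed seed).
#' @param pinhole carve a genus-1 channel through the bladder?
#' @return Named list of [structure_mask()] objects.
#' @export
make_organ_phantom <- function(grid, spec = default_phantom_spec(), seed = 1,
                               pinhole = FALSE) {
  rasterize_phantom(draw_phantom_params(spec, seed), grid, pinhole)
}

# Scan-specific realisation of the phantom spec: per structure the size
# factor and center shift of this imaging session.
draw_phantom_params <- function(spec, seed) {
  set.seed(seed)
  for (nm in names(spec)) {
    s <- spec[[nm]]
    f <- clamp(exp(stats::rnorm(1, 0, s$scan_cv)), 0.75, 1.3)
    shift <- clamp(stats::rnorm(3, 0, s$jitter_sd),
                   -3 * s$jitter_sd, 3 * s$jitter_sd)
    spec[[nm]]$center <- s$center + shift
    spec[[nm]]$size <- s$size * f
    spec[[nm]]$size_factor <- f
  }
  spec
}

rasterize_phantom <- function(params, grid, pinhole = FALSE) {
  masks <- list()
  for (nm in names(params)) {
    s <- params[[nm]]
    occ <- switch(s$family,
      ellipsoid = ellipsoid_occ(grid, s$center, s$size),
      sphere = ellipsoid_occ(grid, s$center, s$size),
      paired_ellipsoid = ellipsoid_occ(grid,
                                       s$center + c(s$offset_rl, 0, 0),
                                       s$size) |
                         ellipsoid_occ(grid,
                                       s$center - c(s$offset_rl, 0, 0),
                                       s$size),
      tube = tube_occ(grid, s$center, s$size[1], s$cc_range, s$curve_amp),
      stop("unknown shape family: ", s$family))
    if (pinhole && nm == "bladder")
      occ <- occ & !channel_occ(grid, s$center,
                                radius = min(6, s$size[1] / 3))
    if (!any(occ))
      stop("structure '", nm, "' rasterized to an empty mask")
    masks[[nm]] <- structure_mask(occ, grid, nm)
  }
  masks
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Axis-aligned ellipsoid occupancy over voxel centers; errors if the shape
# does not fit on the grid.
ellipsoid_occ <- function(grid, center, semi) {
  check_fits(grid, center - semi, center + semi)
  a1 <- ((axis_coords(grid, 1) - center[1]) / semi[1])^2
  a2 <- ((axis_coords(grid, 2) - center[2]) / semi[2])^2
  a3 <- ((axis_coords(grid, 3) - center[3]) / semi[3])^2
  outer(outer(a1, a2, "+"), a3, "+") <= 1
}

# Curved tube along CC: per slice a circle of radius r whose AP center
# follows a half-sine bow of amplitude curve_amp.
tube_occ <- function(grid, center, r, cc_range, curve_amp) {
  check_fits(grid, c(center[1] - r, center[2] - r - curve_amp, cc_range[1]),
             c(center[1] + r, center[2] + r + curve_amp, cc_range[2]))
  xs <- axis_coords(grid, 1)
  ys <- axis_coords(grid, 2)
  zs <- axis_coords(grid, 3)
  occ <- array(FALSE, grid$shape)
  in_z <- which(zs >= cc_range[1] & zs <= cc_range[2])
  for (k in in_z) {
    frac <- (zs[k] - cc_range[1]) / (cc_range[2] - cc_range[1])
    cy <- center[2] + curve_amp * sin(pi * frac)
    occ[, , k] <- outer((xs - center[1])^2, (ys - cy)^2, "+") <= r^2
  }
  occ
}

# Cylindrical channel along AP through the bladder center (the pinhole).
channel_occ <- function(grid, center, radius) {
  xs <- axis_coords(grid, 1)
  zs <- axis_coords(grid, 3)
  disk <- outer((xs - center[1])^2, (zs - center[3])^2, "+") <= radius^2
  ny <- grid$shape[2]
  aperm(array(disk, dim = c(grid$shape[1], grid$shape[3], ny)),
        c(1, 3, 2))
}

check_fits <- function(grid, lo, hi) {
  gmin <- grid$origin
  gmax <- grid$origin + (grid$shape - 1) * grid$spacing
  if (any(lo < gmin - grid$spacing) || any(hi > gmax + grid$spacing))
    stop("structure exceeds the grid extent")
  invisible(TRUE)
}

#' Smooth random displacement field
#'
#' A stand-in for the residual error of a deformable registration: three
#' independent smooth scalar components, built from white noise on a
#' coarse lattice (half the correlation length), Gaussian-smoothed at the
#' correlation length, trilinearly upsampled to the target grid, and
#' rescaled so the empirical per-component SD equals `amplitude` exactly.
#' Deterministic for a fixed seed; `amplitude = 0` yields the zero field.
#'
#' @param grid a [voxel_grid()].
#' @param amplitude mm displacement SD per component.
#' @param corr_length mm correlation (smoothing) length, > 0.
#' @param seed integer seed.
#' @return A `displacement_field`: list of mm component arrays `ux`, `uy`,
#'   `uz` on `grid`.
#' @export
random_displacement_field <- function(grid, amplitude, corr_length, seed) {
  stopifnot(amplitude >= 0, corr_length > 0)
  shape <- grid$shape
  if (amplitude == 0) {
    z <- array(0, shape)
    return(structure(list(ux = z, uy = z, uz = z, grid = grid,
                          amplitude = amplitude,
                          corr_length = corr_length),
                     class = "displacement_field"))
  }
  extent <- (shape - 1) * grid$spacing
  h <- corr_length / 2
  cdim <- pmax(4L, as.integer(ceiling(extent / h)) + 1L)
  sigma_vox <- rep(2, 3)  # 2 coarse voxels = corr_length in mm
  set.seed(seed)
  comp <- vector("list", 3)
  for (c_i in 1:3) {
    noise <- stats::rnorm(prod(cdim))
    sm <- smooth_gaussian_cpp(noise, cdim, sigma_vox)
    up <- upsample_trilinear_cpp(sm, cdim, shape)
    up <- up - mean(up)
    up <- up * (amplitude / stats::sd(up))
    comp[[c_i]] <- array(up, shape)
  }
  structure(list(ux = comp[[1]], uy = comp[[2]], uz = comp[[3]],
                 grid = grid, amplitude = amplitude,
                 corr_length = corr_length),
            class = "displacement_field")
}

#' Uniform translation field
#'
#' Convenience constructor for a constant displacement (mm per axis).
#' @param grid a [voxel_grid()].
#' @param t mm translation vector (RL, AP, CC array axes).
#' @return A `displacement_field`.
#' @export
translation_field <- function(grid, t) {
  structure(list(ux = array(t[1], grid$shape),
                 uy = array(t[2], grid$shape),
                 uz = array(t[3], grid$shape),
                 grid = grid, amplitude = NA_real_,
                 corr_length = NA_real_),
            class = "displacement_field")
}

# 1-based linear source indices of a backward NN warp (NA outside grid).
warp_index <- function(field) {
  g <- field$grid
  warp_source_index_cpp(g$shape, g$spacing,
                        as.numeric(field$ux), as.numeric(field$uy),
                        as.numeric(field$uz))
}

warp_occ <- function(occ, idx, shape) {
  out <- occ[idx]
  out[is.na(out)] <- FALSE
  array(out, shape)
}

#' Warp a binary mask by a displacement field
#'
#' Backward mapping with nearest-neighbour sampling: the warped mask at
#' voxel x takes the value of the source mask at x - u(x). The zero field
#' is the identity and a constant whole-voxel translation shifts the mask
#' exactly.
#'
#' @param mask a [structure_mask()].
#' @param field a `displacement_field` on the same grid.
#' @return Warped [structure_mask()].
#' @export
warp_mask <- function(mask, field) {
  if (!grids_identical(mask$grid, field$grid))
    stop("field grid does not match mask grid")
  occ <- warp_occ(mask$occupancy, warp_index(field), mask$grid$shape)
  structure_mask(occ, mask$grid, mask$label)
}

#' Perturb a contour with low-amplitude smooth noise
#'
#' Emulates intra-observer re-delineation: the boundary is displaced by a
#' smooth random field of SD `sigma` mm. The expected MSD against the
#' original increases monotonically with `sigma`; `sigma = 0` returns the
#' mask unchanged.
#'
#' @param mask a [structure_mask()].
#' @param sigma mm displacement SD, >= 0.
#' @param seed integer seed.
#' @param corr_length mm correlation length of the perturbation.
#' @return Perturbed [structure_mask()].
#' @export
perturb_contour <- function(mask, sigma, seed, corr_length = 12) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(mask)
  f <- random_displacement_field(mask$grid, sigma, corr_length, seed)
  warp_mask(mask, f)
}

#' Dilate a mask by a mm margin
#'
#' Adds every voxel whose center lies within `mm` of an occupied voxel
#' center (exact Euclidean distance, anisotropic spacing respected). Used
#' for the systematic CT-over-MR delineation bias.
#'
#' @param mask a [structure_mask()].
#' @param mm dilation margin in mm; 0 returns the mask unchanged.
#' @return Dilated [structure_mask()].
#' @export
dilate_mask <- function(mask, mm) {
  if (mm <= 0) return(mask)
  d2 <- edt_sq_cpp(as.logical(mask$occupancy), mask$grid$shape,
                   mask$grid$spacing)
  occ <- array(d2 <= mm^2 + 1e-9, mask$grid$shape)
  structure_mask(occ, mask$grid, mask$label)
}
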