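#' Structure volume in cm^3
#'
#' Occupied-voxel count times the voxel volume implied by the grid spacing.
#'
#' @param mask a [structure_mask()].
#' @return volume in cm^3 (0 for an empty mask).
#' @export
volume <- function(mask) {
  sum(mask$occupancy) * prod(mask$grid$spacing) / 1000
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` on voxel occupancy; symmetric in its
#' arguments, 1 for identical non-empty masks, 0 for disjoint masks. Both
#' masks must live on the identical grid (see [harmonize_grids()]); the
#' metric is undefined when both masks are empty and this raises an error
#' rather than silently returning 0 or 1.
#'
#' @param test,ref [structure_mask()] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(test, ref) {
  check_same_grid(test, ref)
  a <- sum(test$occupancy)
  b <- sum(ref$occupancy)
  if (a == 0 && b == 0)
    stop("Dice coefficient is undefined for two empty masks")
  2 * sum(test$occupancy & ref$occupancy) / (a + b)
}

#' Surface voxels of a mask
#'
#' A surface voxel is an occupied voxel with at least one face-adjacent
#' (6-connectivity) neighbour that is unoccupied or outside the image;
#' the image boundary counts as background.
#'
#' @param mask a non-empty [structure_mask()].
#' @return Integer matrix (n x 3) of 1-based voxel array indices.
#' @export
extract_surface <- function(mask) {
  which(surface_logical(mask$occupancy), arr.ind = TRUE)
}

# Logical array marking surface voxels (6-connectivity, boundary = background).
surface_logical <- function(occ) {
  if (!any(occ)) stop("mask is empty")
  array(surface_mask_cpp(as.logical(occ), dim(occ)), dim(occ))
}

#' Surface-to-surface distances
#'
#' For every surface voxel of `test`, the Euclidean mm distance (anisotropic
#' spacing respected) to the nearest surface voxel center of `ref`,
#' computed with an exact distance transform. This realises the
#' surface-distance measurement underlying MSD and HD: distances are taken
#' between voxel-center point sets of the two structure surfaces.
#'
#' @param test,ref non-empty [structure_mask()] objects on the same grid.
#' @return A `surface_distance_set`: list with `positions` (n x 3 mm matrix,
#'   columns RL/AP/CC), `distances` (nonnegative mm), and `labels`.
#' @param labels optional list of identifying labels (patient, scan,
#'   structure, role) carried through to projection maps.
#' @export
surface_distances <- function(test, ref, labels = list()) {
  check_same_grid(test, ref)
  if (is_empty_mask(test) || is_empty_mask(ref))
    stop("surface distances require two non-empty masks")
  surface_distances_impl(test, ref_surface_edt(ref), labels)
}

# Precompute the distance transform of a reference surface so that several
# evaluated masks can be measured against the same reference cheaply.
ref_surface_edt <- function(ref) {
  surf <- surface_logical(ref$occupancy)
  edt_sq_cpp(as.logical(surf), ref$grid$shape, ref$grid$spacing)
}

surface_distances_impl <- function(test, ref_edt_sq, labels = list()) {
  surf <- surface_logical(test$occupancy)
  lin <- which(surf)
  idx <- which(surf, arr.ind = TRUE)
  structure(list(
    positions = index_to_mm(test$grid, idx),
    distances = sqrt(ref_edt_sq[lin]),
    labels = labels), class = "surface_distance_set")
}

#' Mean surface distance (MSD)
#'
#' Average distance between the surfaces of two structures in mm.
#' `"symmetric"` (the default) pools the directed distances of both
#' directions before averaging; `"directed"` averages only the distances
#' from `test` surface voxels to the `ref` surface.
#'
#' @inheritParams surface_distances
#' @param mode `"symmetric"` or `"directed"`.
#' @return MSD in mm.
#' @export
mean_surface_distance <- function(test, ref,
                                  mode = c("symmetric", "directed")) {
  mode <- match.arg(mode)
  d1 <- surface_distances(test, ref)$distances
  if (mode == "directed") return(mean(d1))
  d2 <- surface_distances(ref, test)$distances
  mean(c(d1, d2))
}

#' Hausdorff distance (HD)
#'
#' Greatest surface-to-surface distance between two structures: the
#' maximum over both directed maxima (symmetric HD), the worst-case
#' disagreement. A percentile parameter is exposed (applied per direction
#' before taking the maximum) but defaults to 100, i.e. the classical
#' Hausdorff distance.
#'
#' @inheritParams surface_distances
#' @param percentile percentile of the directed distance distributions,
#'   in (0, 100]; 100 gives the classical maximum.
#' @return HD in mm.
#' @export
hausdorff_distance <- function(test, ref, percentile = 100) {
  stopifnot(percentile > 0, percentile <= 100)
  d1 <- surface_distances(test, ref)$distances
  d2 <- surface_distances(ref, test)$distances
  if (percentile >= 100) return(max(max(d1), max(d2)))
  max(stats::quantile(d1, percentile / 100, names = FALSE, type = 7),
      stats::quantile(d2, percentile / 100, names = FALSE, type = 7))
}

#' Compare an evaluated structure against its ground truth
#'
#' Computes DSC, MSD, HD, both volumes and topology tags for one
#' (evaluated, reference) mask pair and returns a one-row metric record.
#' Pairs with an empty mask yield a flagged failure record instead of an
#' error: failed propagations are findings, not data to discard.
#'
#' @param test evaluated (propagated / re-delineated) [structure_mask()].
#' @param ref ground-truth [structure_mask()] on the same grid.
#' @param labels list with `patient_id`, `scan_id`, `structure`, `arm`.
#' @param msd_mode passed to [mean_surface_distance()].
#' @param hd_percentile passed to [hausdorff_distance()].
#' @param topology compute [check_topology()] tags of `test` (components,
#'   handle flag)?
#' @return One-row data frame with the columns of [write_metric_table()].
#' @export
compare_structures <- function(test, ref, labels,
                               msd_mode = c("symmetric", "directed"),
                               hd_percentile = 100, topology = TRUE) {
  msd_mode <- match.arg(msd_mode)
  check_same_grid(test, ref)
  rec <- metric_record_shell(labels, test, ref)
  compare_impl(test, ref, rec, msd_mode, hd_percentile, topology)$record
}

metric_record_shell <- function(labels, test, ref) {
  data.frame(
    patient_id = as.character(labels$patient_id),
    scan_id = as.character(labels$scan_id),
    structure = as.character(labels$structure),
    arm = as.character(labels$arm),
    status = "ok",
    dsc = NA_real_, msd = NA_real_, hd = NA_real_,
    volume_test_cm3 = volume(test), volume_ref_cm3 = volume(ref),
    n_components = NA_integer_, has_handle = NA,
    stringsAsFactors = FALSE)
}

# Crop a mask pair to the tight union bounding box of their occupied
# voxels. Exact for all metrics: the box is tight, so no voxel gains or
# loses a background neighbour, and every surface voxel of either mask
# lies inside the box. The cropped grid origin keeps mm coordinates
# identical to the full grid.
crop_pair <- function(test, ref) {
  d <- test$grid$shape
  m <- test$occupancy | ref$occupancy
  p1 <- rowSums(matrix(m, d[1]))
  p23 <- matrix(colSums(matrix(m, d[1])), d[2], d[3])
  p2 <- rowSums(p23)
  p3 <- colSums(p23)
  r1 <- range(which(p1 > 0)); r2 <- range(which(p2 > 0))
  r3 <- range(which(p3 > 0))
  sub <- function(msk) {
    g <- msk$grid
    occ <- msk$occupancy[r1[1]:r1[2], r2[1]:r2[2], r3[1]:r3[2], drop = FALSE]
    g2 <- voxel_grid(dim(occ), g$spacing,
                     g$origin + (c(r1[1], r2[1], r3[1]) - 1) * g$spacing,
                     g$axis_roles)
    structure_mask(occ, g2, msk$label)
  }
  list(test = sub(test), ref = sub(ref))
}

# Workhorse shared by compare_structures() and the pipeline: computes all
# metrics on the union-cropped pair and returns the test->ref surface
# distance set alongside the record (consumed by the projection maps).
compare_impl <- function(test, ref, rec, msd_mode, hd_percentile,
                         topology) {
  te <- is_empty_mask(test)
  re <- is_empty_mask(ref)
  if (te || re) {
    rec$status <- if (te && re) "failed_empty_both"
                  else if (te) "failed_empty_test" else "failed_empty_ref"
    return(list(record = rec, sds = NULL))
  }
  cp <- crop_pair(test, ref)
  test <- cp$test
  ref <- cp$ref
  redt <- ref_surface_edt(ref)
  sds <- surface_distances_impl(test, redt,
                                labels = rec[c("patient_id", "scan_id",
                                               "structure", "arm")])
  d_tr <- sds$distances
  tedt <- edt_sq_cpp(as.logical(surface_logical(test$occupancy)),
                     test$grid$shape, test$grid$spacing)
  d_rt <- surface_distances_impl(ref, tedt)$distances
  rec$dsc <- dice(test, ref)
  rec$msd <- if (msd_mode == "symmetric") mean(c(d_tr, d_rt)) else mean(d_tr)
  if (hd_percentile >= 100) {
    rec$hd <- max(max(d_tr), max(d_rt))
  } else {
    rec$hd <- max(stats::quantile(d_tr, hd_percentile / 100,
                                  names = FALSE, type = 7),
                  stats::quantile(d_rt, hd_percentile / 100,
                                  names = FALSE, type = 7))
  }
  if (topology) {
    top <- check_topology(test)
    rec$n_components <- top$n_components
    rec$has_handle <- top$has_handle
  }
  list(record = rec, sds = sds)
}

check_same_grid <- function(test, ref) {
  if (!grids_identical(test$grid, ref$grid))
    stop("masks live on different grids; resample first ",
         "(see harmonize_grids)")
  invisible(TRUE)
}
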