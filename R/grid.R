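#' Voxel grid geometry
#'
#' A `voxel_grid` describes a regular, possibly anisotropic 3D sampling
#' lattice: the number of voxels per array axis, the spacing in mm, the mm
#' position of the first voxel center, and the mapping of array axes onto
#' the main patient directions (Right-Left, Anterior-Posterior,
#' Cranio-Caudal). Voxel centers lie at `origin + (index - 1) * spacing`
#' for 1-based array indices; all distances are in mm.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3, mm per voxel along each axis
#'   (all > 0).
#' @param origin numeric vector of length 3, mm coordinate of the center of
#'   voxel (1,1,1).
#' @param axis_roles character vector of length 3 assigning each array axis
#'   a patient direction; must be a permutation of `c("RL","AP","CC")`. The
#'   default maps axis 1 to RL, axis 2 to AP and axis 3 to CC.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0),
                       axis_roles = c("RL", "AP", "CC")) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive mm values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite mm values")
  if (length(axis_roles) != 3L ||
      !setequal(axis_roles, c("RL", "AP", "CC")))
    stop("'axis_roles' must be a permutation of RL, AP, CC")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 axis_roles = as.character(axis_roles)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, spacing %s mm (%s)\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(x$axis_roles, collapse = "/")))
  invisible(x)
}

grids_identical <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol) &&
    identical(a$axis_roles, b$axis_roles)
}

#' Binary structure mask on a voxel grid
#'
#' Binds a strictly binary occupancy array to a [voxel_grid()] and a
#' structure label. Any nonzero/`TRUE` value counts as occupied.
#'
#' @param occupancy logical or numeric 3D array matching `grid$shape`;
#'   nonzero values are treated as occupied.
#' @param grid a [voxel_grid()].
#' @param label structure name; one of the controlled vocabulary
#'   `r paste(dirqa_structures(), collapse = ", ")` or any other non-empty
#'   string (stored with label class "other" semantics).
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(occupancy, grid, label = "other") {
  if (!inherits(grid, "voxel_grid")) stop("'grid' must be a voxel_grid")
  if (length(dim(occupancy)) != 3L)
    stop("'occupancy' must be a 3D array")
  if (!identical(as.integer(dim(occupancy)), grid$shape))
    stop("occupancy dimensions do not match grid shape")
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("'label' must be a non-empty string")
  occ <- array(as.logical(occupancy != 0), dim = grid$shape)
  structure(list(occupancy = occ, grid = grid, label = label),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d occupied of %d voxels (%.2f cm3)\n",
              x$label, sum(x$occupancy), length(x$occupancy), volume(x)))
  print(x$grid)
  invisible(x)
}

#' Controlled structure vocabulary
#'
#' The eight pelvic structures of the study design plus "other".
#' @return character vector of labels.
#' @export
dirqa_structures <- function() {
  c("prostate", "SV", "CTV56", "rectum", "bladder",
    "femhead_L", "femhead_R", "penile_bulb", "other")
}

is_empty_mask <- function(mask) !any(mask$occupancy)

#' Per-axis voxel center coordinates in mm
#' @noRd
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' mm coordinates (columns RL, AP, CC) of given voxel array indices
#' @noRd
index_to_mm <- function(grid, idx) {
  mm <- sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
  colnames(mm) <- grid$axis_roles
  mm[, c("RL", "AP", "CC"), drop = FALSE]
}

#' Resample a mask onto another grid (nearest neighbour)
#'
#' Maps every voxel center of the target grid to the nearest voxel of the
#' source grid (in mm along matching patient axes) and copies its occupancy;
#' target centers falling outside the source grid become background. Used to
#' bring masks delineated on a coarse grid (e.g. 3 mm CT slices) onto the
#' finer grid of the comparison partner before metrics are computed.
#'
#' @param mask a [structure_mask()].
#' @param target a [voxel_grid()] with the same axis roles.
#' @return A [structure_mask()] on `target`.
#' @export
resample_mask <- function(mask, target) {
  src <- mask$grid
  if (!identical(src$axis_roles, target$axis_roles))
    stop("resampling across differing axis role orders is not supported")
  if (grids_identical(src, target)) return(mask)
  idx <- vector("list", 3L)
  for (a in 1:3) {
    mm <- axis_coords(target, a)
    i <- as.integer(round((mm - src$origin[a]) / src$spacing[a])) + 1L
    i[i < 1L | i > src$shape[a]] <- NA_integer_
    idx[[a]] <- i
  }
  occ <- array(FALSE, dim = target$shape)
  ok1 <- !is.na(idx[[1]]); ok2 <- !is.na(idx[[2]]); ok3 <- !is.na(idx[[3]])
  if (any(ok1) && any(ok2) && any(ok3)) {
    occ[ok1, ok2, ok3] <-
      mask$occupancy[idx[[1]][ok1], idx[[2]][ok2], idx[[3]][ok3], drop = FALSE]
  }
  structure_mask(occ, target, mask$label)
}

#' Pick the finer of two grids
#'
#' Comparisons require both masks on one grid; the pipeline resamples the
#' coarser mask onto the finer grid (smaller voxel volume) by nearest
#' neighbour. Ties resolve to the first grid.
#' @noRd
finer_grid <- function(a, b) {
  if (prod(b$spacing) < prod(a$spacing)) b else a
}

#' Bring two masks onto a common grid for comparison
#'
#' If the grids already match, returns the masks unchanged; otherwise
#' resamples the coarser-grid mask onto the finer grid.
#'
#' @param test,ref [structure_mask()] objects.
#' @return list with elements `test`, `ref`, and `resampled` (logical).
#' @export
harmonize_grids <- function(test, ref) {
  if (grids_identical(test$grid, ref$grid))
    return(list(test = test, ref = ref, resampled = FALSE))
  g <- finer_grid(test$grid, ref$grid)
  list(test = resample_mask(test, g), ref = resample_mask(ref, g),
       resampled = TRUE)
}
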