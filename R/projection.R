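#' Bounding box along the main patient directions
#'
#' The smallest axis-aligned box (axes ordered RL, AP, CC) containing every
#' occupied voxel center of the structure.
#'
#' @param mask a non-empty [structure_mask()].
#' @return A `bounding_box`: 2 x 3 matrix, rows `min`/`max`, columns
#'   `RL`/`AP`/`CC`, in mm.
#' @export
bounding_box <- function(mask) {
  if (is_empty_mask(mask)) stop("mask is empty")
  idx <- which(mask$occupancy, arr.ind = TRUE)
  mm <- index_to_mm(mask$grid, idx)
  box <- rbind(min = apply(mm, 2, min), max = apply(mm, 2, max))
  structure(box, class = "bounding_box")
}

box_extent <- function(box) box["max", ] - box["min", ]

# In-plane patient axes per projection plane: c(horizontal, vertical).
# The plane-normal axis is the one dropped by the projection.
plane_axes <- function(plane) {
  switch(plane,
         transversal = c("RL", "AP"),
         sagittal    = c("AP", "CC"),
         coronal     = c("RL", "CC"),
         stop("unknown plane: ", plane))
}

#' Projection plane vocabulary
#'
#' The three principal planes a surface deviation is projected into.
#' @return character vector: transversal, sagittal, coronal.
#' @export
dirqa_planes <- function() c("transversal", "sagittal", "coronal")

#' Project surface deviations onto the three principal planes
#'
#' Each surface voxel drops its plane-normal coordinate; the remaining two
#' mm coordinates are mapped affinely from the bounding-box extent onto a
#' fixed pixel grid (half-open pixels, the max coordinate clamped into the
#' last pixel), and the deviations landing in each pixel are averaged.
#' Because the pixel count is fixed per structure type, grids from scans
#' and patients of differing size can be aggregated pixelwise.
#'
#' @param sds a `surface_distance_set` from [surface_distances()].
#' @param box the structure's [bounding_box()] (by default that of the
#'   evaluated structure the surface voxels come from).
#' @param pixel_shape integer pair, pixels per plane axis (horizontal,
#'   vertical); applied to all three planes.
#' @param planes which planes to produce.
#' @return Named list of `projection_grid` objects, one per plane, each
#'   with `mean` (matrix, mm, `NA` where no voxel projects), `count`,
#'   `plane`, `pixel_shape` and the `labels` of `sds`.
#' @export
project_deviations <- function(sds, box, pixel_shape = c(64, 64),
                               planes = dirqa_planes()) {
  if (!length(sds$distances)) stop("empty surface distance set")
  pixel_shape <- as.integer(pixel_shape)
  stopifnot(length(pixel_shape) == 2L, all(pixel_shape >= 1L))
  out <- list()
  for (plane in planes) {
    ax <- plane_axes(plane)
    i <- pixel_index(sds$positions[, ax[1]], box[, ax[1]], pixel_shape[1])
    j <- pixel_index(sds$positions[, ax[2]], box[, ax[2]], pixel_shape[2])
    pix <- i + (j - 1L) * pixel_shape[1]
    cnt <- tabulate(pix, nbins = prod(pixel_shape))
    sums <- numeric(prod(pixel_shape))
    agg <- rowsum(sds$distances, pix)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    mean_dev <- ifelse(cnt > 0, sums / cnt, NA_real_)
    out[[plane]] <- structure(list(
      plane = plane,
      pixel_shape = pixel_shape,
      mean = matrix(mean_dev, pixel_shape[1], pixel_shape[2]),
      count = matrix(cnt, pixel_shape[1], pixel_shape[2]),
      labels = sds$labels), class = "projection_grid")
  }
  out
}

# Affine map of an mm coordinate to a 1-based pixel index on [1, n]:
# half-open pixels over the box extent, the upper edge clamped into the
# last pixel; a zero-extent axis maps everything to pixel 1.
pixel_index <- function(x, range, n) {
  ext <- range[2] - range[1]
  if (ext <= 0) return(rep(1L, length(x)))
  i <- floor((x - range[1]) / ext * n) + 1L
  pmin(pmax(as.integer(i), 1L), n)
}

#' Pixelwise population percentile over scan-level projection grids
#'
#' For one structure and comparison arm, stacks the per-scan mean-deviation
#' grids of one plane and takes the stated percentile in each pixel over
#' the scans in which that pixel is defined (linear interpolation between
#' order statistics; the median of an even count is the midpoint). Pixels
#' defined in fewer than `min_scans` scans are reported missing.
#'
#' @param grids list of `projection_grid` objects sharing plane and
#'   pixel_shape.
#' @param percentile percentile in (0, 100]; the study design uses 50 and 90.
#' @param min_scans minimum number of contributing scans per pixel.
#' @param aspect display aspect ratio (width/height) from
#'   [mean_structure_aspect()]; optional.
#' @return A `population_projection_map`: list with `values` (matrix, mm),
#'   `n_contributing`, `plane`, `percentile`, `aspect`.
#' @export
aggregate_population_map <- function(grids, percentile, min_scans = 1,
                                     aspect = NA_real_) {
  if (!length(grids)) stop("no projection grids supplied")
  plane <- grids[[1]]$plane
  shp <- grids[[1]]$pixel_shape
  for (g in grids) {
    if (!identical(g$plane, plane)) stop("mixed planes in grid list")
    if (!identical(g$pixel_shape, shp)) stop("mixed pixel shapes in grid list")
  }
  stack <- vapply(grids, function(g) g$mean, matrix(0, shp[1], shp[2]))
  stack <- array(stack, dim = c(shp[1], shp[2], length(grids)))
  n_contrib <- apply(!is.na(stack), c(1, 2), sum)
  values <- apply(stack, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < min_scans || !length(v)) return(NA_real_)
    stats::quantile(v, percentile / 100, names = FALSE, type = 7)
  })
  structure(list(plane = plane, percentile = percentile,
                 values = values, n_contributing = n_contrib,
                 aspect = aspect),
            class = "population_projection_map")
}

#' Mean-structure aspect ratio per plane
#'
#' Averages the bounding-box extent per patient axis over all scans of all
#' patients and returns, per plane, the ratio of the two in-plane mean
#' extents (horizontal / vertical). Projection images are rendered with
#' equal width and the height implied by this ratio, so that the displayed
#' shape corresponds to the mean structure.
#'
#' @param boxes list of [bounding_box()] objects.
#' @return Named numeric vector of aspect ratios per plane.
#' @export
mean_structure_aspect <- function(boxes) {
  if (!length(boxes)) stop("no bounding boxes supplied")
  ext <- vapply(boxes, box_extent, numeric(3))
  mean_ext <- rowMeans(ext)
  vapply(dirqa_planes(), function(p) {
    ax <- plane_axes(p)
    mean_ext[ax[1]] / mean_ext[ax[2]]
  }, numeric(1))
}

#' Render a population projection map to PNG
#'
#' Fixed raster width; the height follows from the map's aspect ratio.
#' The colour scale is linear in mm from 0 to `zmax` (defaulting to the
#' map maximum); missing pixels are drawn grey. The exact numbers are
#' available via [export_map_csv()].
#'
#' @param map a `population_projection_map`.
#' @param path PNG destination.
#' @param width_px raster width in pixels.
#' @param zmax top of the colour scale in mm; `NULL` uses the map maximum.
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, width_px = 480, zmax = NULL) {
  aspect <- if (is.finite(map$aspect) && map$aspect > 0) map$aspect else 1
  height_px <- max(64L, as.integer(round(width_px / aspect)))
  vals <- map$values
  if (is.null(zmax))
    zmax <- if (all(is.na(vals))) 1 else max(vals, na.rm = TRUE)
  if (zmax <= 0) zmax <- 1
  grDevices::png(path, width = width_px, height = height_px + 80L)
  op <- graphics::par(mar = c(3.5, 1, 2.2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  pal <- grDevices::hcl.colors(64, "viridis")
  graphics::image(seq_len(nrow(vals)), seq_len(ncol(vals)),
                  matrix(0, nrow(vals), ncol(vals)),
                  col = "grey85", axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("%s, p%d (max %.1f mm)",
                                 map$plane, map$percentile, zmax))
  if (!all(is.na(vals)))
    graphics::image(seq_len(nrow(vals)), seq_len(ncol(vals)),
                    pmin(vals, zmax), zlim = c(0, zmax), col = pal,
                    add = TRUE, useRaster = FALSE)
  graphics::mtext(sprintf("0 mm – %.1f mm (grey = no data)", zmax),
                  side = 1, line = 1.5, cex = 0.9)
  invisible(path)
}

#' Numeric sidecar for a projection map
#'
#' Writes the pixel matrix as CSV (full double precision) so map values can
#' be inspected and round-tripped exactly; `read_map_csv()` reads it back.
#'
#' @param map a `population_projection_map`.
#' @param path CSV destination / source.
#' @return `export_map_csv()` returns `path` invisibly; `read_map_csv()`
#'   the numeric matrix.
#' @export
export_map_csv <- function(map, path) {
  # 17 significant digits guarantee a bit-exact double round trip
  chr <- matrix(sprintf("%.17g", map$values), nrow(map$values))
  chr[is.na(map$values)] <- "NA"
  df <- as.data.frame(chr, stringsAsFactors = FALSE)
  names(df) <- sprintf("px%03d", seq_len(ncol(df)))
  readr::write_csv(df, path, na = "NA")
  invisible(path)
}

#' @rdname export_map_csv
#' @export
read_map_csv <- function(path) {
  # parse via R's strtod (correctly rounded) for a bit-exact round trip
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  m <- as.matrix(as.data.frame(df))
  matrix(as.numeric(m), nrow(m), ncol(m))
}
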