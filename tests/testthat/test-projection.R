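test_that("bounding box is tight, ordered RL/AP/CC and shift-equivariant", {
  g <- voxel_grid(c(12, 12, 12), c(1, 2, 3))
  occ <- array(FALSE, c(12, 12, 12)); occ[4, 5, 6] <- TRUE
  b <- bounding_box(structure_mask(occ, g))
  expect_equal(unname(b["min", ]), unname(b["max", ]))
  expect_equal(unname(b["min", c("RL", "AP", "CC")]), c(3, 8, 15))

  # axis-aligned ellipsoid semi-axes (10, 20, 30) mm -> extents ~ (20,40,60)
  ge <- voxel_grid(c(30, 50, 70), c(1, 1, 1))
  ctr <- c(14, 24, 34)
  cs <- lapply(1:3, function(a) seq_len(ge$shape[a]) - 1)
  occ2 <- outer(outer((cs[[1]] - ctr[1])^2 / 100,
                      (cs[[2]] - ctr[2])^2 / 400, "+"),
                (cs[[3]] - ctr[3])^2 / 900, "+") <= 1
  be <- bounding_box(structure_mask(occ2, ge))
  ext <- be["max", ] - be["min", ]
  expect_true(all(abs(ext - c(20, 40, 60)) <= 1))

  # translation by whole voxels moves the box rigidly
  occ3 <- array(FALSE, c(12, 12, 12)); occ3[2:4, 3:5, 4:6] <- TRUE
  occ4 <- array(FALSE, c(12, 12, 12)); occ4[5:7, 4:6, 5:7] <- TRUE
  b3 <- bounding_box(structure_mask(occ3, g))
  b4 <- bounding_box(structure_mask(occ4, g))
  expect_equal(b4 - b3, matrix(rep(c(3, 1, 1) * g$spacing, each = 2), 2, 3,
                               dimnames = dimnames(b3)))
})

test_that("projection grids bin deviations like the independent oracle", {
  set.seed(21)
  n <- 200
  pos <- cbind(RL = runif(n, 10, 40), AP = runif(n, -5, 25),
               CC = runif(n, 0, 60))
  d <- runif(n, 0, 8)
  sds <- structure(list(positions = pos, distances = d, labels = list()),
                   class = "surface_distance_set")
  box <- rbind(min = apply(pos, 2, min), max = apply(pos, 2, max))
  colnames(box) <- c("RL", "AP", "CC")
  grids <- project_deviations(sds, box, pixel_shape = c(7, 5))
  planes <- list(transversal = c("RL", "AP"), sagittal = c("AP", "CC"),
                 coronal = c("RL", "CC"))
  for (pl in names(planes)) {
    oracle <- bf_project(pos, d, box, planes[[pl]], c(7, 5))
    expect_equal(grids[[pl]]$mean, oracle$mean, tolerance = 1e-12)
    expect_equal(grids[[pl]]$count, oracle$count)
    # conservation: sum(mean * count) equals the sum of all deviations
    g <- grids[[pl]]
    expect_equal(sum(g$mean * g$count, na.rm = TRUE), sum(d))
    # every pixel mean lies within the range of its contributors
    expect_true(all(is.na(g$mean) | (g$mean >= min(d) - 1e-12 &
                                       g$mean <= max(d) + 1e-12)))
    expect_identical(is.na(g$mean), g$count == 0)
  }
  # a single voxel lands in exactly one pixel per plane
  one <- structure(list(positions = pos[1, , drop = FALSE],
                        distances = 3.3, labels = list()),
                   class = "surface_distance_set")
  g1 <- project_deviations(one, box, c(7, 5))
  for (pl in names(planes)) {
    expect_equal(sum(g1[[pl]]$count), 1)
    expect_equal(sum(g1[[pl]]$mean, na.rm = TRUE), 3.3)
  }
})

test_that("refining the pixel grid preserves count-weighted total deviation", {
  set.seed(31)
  n <- 300
  pos <- cbind(RL = runif(n, 0, 30), AP = runif(n, 0, 30),
               CC = runif(n, 0, 30))
  d <- runif(n, 0, 5)
  sds <- structure(list(positions = pos, distances = d, labels = list()),
                   class = "surface_distance_set")
  box <- rbind(min = apply(pos, 2, min), max = apply(pos, 2, max))
  colnames(box) <- c("RL", "AP", "CC")
  for (np in list(c(4, 4), c(8, 8), c(16, 16))) {
    g <- project_deviations(sds, box, np)$transversal
    expect_equal(sum(g$mean * g$count, na.rm = TRUE), sum(d))
    expect_equal(sum(g$count), n)
  }
})

test_that("uniform 5 mm expansion projects to constant maps", {
  inner <- sphere_mask(12, pad = 8)
  outer_m <- dilate_mask(inner, 5)
  sds <- surface_distances(outer_m, inner)
  grids <- project_deviations(sds, bounding_box(outer_m), c(16, 16))
  for (pl in dirqa_planes()) {
    vals <- grids[[pl]]$mean
    expect_true(all(abs(vals[!is.na(vals)] - 5) <= sqrt(3)))
  }
})

test_that("population percentiles follow the interpolated order statistics", {
  base <- matrix(NA_real_, 3, 3)
  grids <- lapply(1:10, function(v) {
    g <- base; g[2, 2] <- v; g[1, 1] <- 11 - v
    structure(list(plane = "transversal", pixel_shape = c(3L, 3L),
                   mean = g, count = matrix(as.integer(!is.na(g)), 3, 3),
                   labels = list()), class = "projection_grid")
  })
  p50 <- aggregate_population_map(grids, 50)
  p90 <- aggregate_population_map(grids, 90)
  expect_equal(p50$values[2, 2], 5.5)   # midpoint of {1..10}
  expect_equal(p90$values[2, 2], 9.1)   # type-7 interpolation
  expect_equal(p50$n_contributing[2, 2], 10)
  expect_true(is.na(p50$values[3, 3]))
  # identical grids reproduce themselves at any percentile
  same <- aggregate_population_map(grids[c(1, 1, 1)], 90)
  expect_equal(same$values, grids[[1]]$mean)
  # monotone percentiles wherever both are defined
  both <- !is.na(p50$values) & !is.na(p90$values)
  expect_true(all(p90$values[both] >= p50$values[both]))
  expect_error(aggregate_population_map(list(), 50), "no projection grids")
  bad <- grids[[1]]; bad$pixel_shape <- c(4L, 4L)
  expect_error(aggregate_population_map(list(grids[[1]], bad), 50),
               "mixed pixel shapes")
})

test_that("mean-structure aspect averages extents and ignores uniform scale", {
  mk_box <- function(ext) {
    b <- rbind(min = c(0, 0, 0), max = ext)
    colnames(b) <- c("RL", "AP", "CC")
    structure(b, class = "bounding_box")
  }
  boxes <- list(mk_box(c(20, 40, 60)), mk_box(c(40, 20, 60)))
  asp <- mean_structure_aspect(boxes)
  expect_equal(unname(asp["transversal"]), 1)   # mean extents (30, 30, 60)
  expect_equal(unname(asp["sagittal"]), 0.5)
  expect_equal(unname(asp["coronal"]), 0.5)
  cube <- list(mk_box(c(10, 10, 10)), mk_box(c(10, 10, 10)))
  expect_true(all(mean_structure_aspect(cube) == 1))
  scaled <- lapply(boxes, function(b) structure(b * 3, class = class(b)))
  expect_equal(mean_structure_aspect(scaled), asp)
  expect_error(mean_structure_aspect(list()), "no bounding boxes")
})

test_that("map rendering writes PNGs and CSV sidecars round-trip exactly", {
  dir <- withr::local_tempdir()
  vals <- matrix(runif(64, 0, 7), 8, 8)
  vals[1, ] <- NA
  mp <- structure(list(plane = "transversal", percentile = 50,
                       values = vals, n_contributing = matrix(3L, 8, 8),
                       aspect = 1.5),
                  class = "population_projection_map")
  png_path <- file.path(dir, "m.png")
  render_map(mp, png_path)
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
  # fully-missing map renders without error
  mp2 <- mp; mp2$values[] <- NA
  render_map(mp2, file.path(dir, "m2.png"))
  expect_true(file.exists(file.path(dir, "m2.png")))
  csv_path <- file.path(dir, "m.csv")
  export_map_csv(mp, csv_path)
  expect_identical(unname(read_map_csv(csv_path)), unname(vals))
})
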