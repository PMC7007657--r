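test_that("volume matches analytic values", {
  g <- voxel_grid(c(10, 10, 10), c(1, 1, 1))
  solid <- structure_mask(array(TRUE, c(10, 10, 10)), g)
  expect_equal(volume(solid), 1.0)
  expect_equal(volume(structure_mask(array(FALSE, c(10, 10, 10)), g)), 0)
  sph <- sphere_mask(20, spacing = c(0.5, 0.5, 0.5))
  expect_lt(abs(volume(sph) - 4 / 3 * pi * 20^3 / 1000) /
              (4 / 3 * pi * 20^3 / 1000), 0.01)
})

test_that("dice matches analytic nested-sphere overlap and handles edge cases", {
  a <- sphere_mask(6)
  expect_equal(dice(a, a), 1.0)
  g <- a$grid
  left <- array(FALSE, g$shape); left[1:3, , ] <- TRUE
  right <- array(FALSE, g$shape); right[8:10, , ] <- TRUE
  expect_equal(dice(structure_mask(left, g), structure_mask(right, g)), 0)
  empty <- structure_mask(array(FALSE, g$shape), g)
  expect_error(dice(empty, empty), "undefined")
  # concentric spheres r = 20 / 25 mm: DSC = 2*20^3 / (20^3 + 25^3)
  big <- sphere_mask(25)
  small <- sphere_mask(20, pad = 8)  # same 57^3 grid, concentric
  expect_identical(big$grid$shape, small$grid$shape)
  expect_lt(abs(dice(small, big) - 2 * 20^3 / (20^3 + 25^3)), 0.01)
  expect_equal(dice(small, big), dice(big, small))
})

test_that("surface extraction matches the neighbour-scan oracle", {
  g <- voxel_grid(c(7, 7, 7), c(1, 1, 1))
  occ <- array(FALSE, c(7, 7, 7)); occ[2:6, 2:6, 2:6] <- TRUE
  expect_equal(nrow(extract_surface(structure_mask(occ, g))), 98)
  occ3 <- array(FALSE, c(7, 7, 7)); occ3[3:5, 3:5, 3:5] <- TRUE
  expect_equal(nrow(extract_surface(structure_mask(occ3, g))), 26)
  single <- array(FALSE, c(7, 7, 7)); single[4, 4, 4] <- TRUE
  expect_equal(nrow(extract_surface(structure_mask(single, g))), 1)
  expect_error(extract_surface(structure_mask(array(FALSE, c(7, 7, 7)), g)),
               "empty")
  for (seed in 1:5) {
    m <- random_mask(c(8, 8, 8), 0.3, seed)
    expect_identical(dirqa:::surface_logical(m$occupancy),
                     bf_surface(m$occupancy))
  }
  # a mask filling the whole grid is all surface at the image boundary shell
  full <- structure_mask(array(TRUE, c(3, 3, 3)), voxel_grid(c(3, 3, 3),
                                                             c(1, 1, 1)))
  expect_equal(nrow(extract_surface(full)), 26)
})

test_that("surface distances equal the all-pairs oracle on random pairs", {
  for (seed in 1:8) {
    sp <- list(c(1, 1, 1), c(0.7, 1.1, 2.0))[[(seed %% 2) + 1]]
    a <- random_mask(c(8, 8, 8), 0.25, seed, spacing = sp)
    b <- random_mask(c(8, 8, 8), 0.25, seed + 100, spacing = sp)
    if (!any(a$occupancy) || !any(b$occupancy)) next
    d <- surface_distances(a, b)$distances
    expect_equal(sort(d), sort(bf_surface_distances(a, b)), tolerance = 1e-12)
    expect_equal(mean_surface_distance(a, b, "symmetric"), bf_msd(a, b),
                 tolerance = 1e-12)
    expect_equal(mean_surface_distance(a, b, "directed"),
                 bf_msd(a, b, "directed"), tolerance = 1e-12)
    expect_equal(hausdorff_distance(a, b), bf_hd(a, b), tolerance = 1e-12)
  }
})

test_that("concentric spheres recover the 5 mm analytic shell distance", {
  big <- sphere_mask(25)
  small <- sphere_mask(20, pad = 8)
  voxdiag <- sqrt(3)
  d <- surface_distances(small, big)$distances
  expect_true(all(abs(d - 5) <= voxdiag))
  expect_lt(abs(mean_surface_distance(small, big) - 5), voxdiag)
  expect_lt(abs(mean_surface_distance(small, big, "directed") - 5), voxdiag)
  expect_lt(abs(hausdorff_distance(small, big) - 5), voxdiag)
  m <- sphere_mask(10)
  expect_equal(mean_surface_distance(m, m), 0)
  expect_equal(hausdorff_distance(m, m), 0)
})

test_that("metrics are translation invariant and scale with spacing", {
  a <- random_mask(c(10, 10, 10), 0.2, 3)
  b <- random_mask(c(10, 10, 10), 0.2, 4)
  shift <- function(m, by) {
    d <- m$grid$shape
    occ <- array(FALSE, d)
    occ[(1 + by):d[1], , ] <- m$occupancy[1:(d[1] - by), , ]
    structure_mask(occ, m$grid, m$label)
  }
  g2 <- voxel_grid(c(14, 10, 10), c(1, 1, 1))
  embed <- function(m) {
    occ <- array(FALSE, c(14, 10, 10)); occ[1:10, , ] <- m$occupancy
    structure_mask(occ, g2, m$label)
  }
  a2 <- embed(a); b2 <- embed(b)
  expect_equal(dice(shift(a2, 3), shift(b2, 3)), dice(a2, b2))
  expect_equal(mean_surface_distance(shift(a2, 3), shift(b2, 3)),
               mean_surface_distance(a2, b2))
  expect_equal(hausdorff_distance(shift(a2, 3), shift(b2, 3)),
               hausdorff_distance(a2, b2))
  # spacing scaling: k * spacing multiplies distances by k, dice unchanged
  k <- 2.5
  rescale <- function(m) structure_mask(m$occupancy,
                                        voxel_grid(m$grid$shape,
                                                   m$grid$spacing * k),
                                        m$label)
  expect_equal(dice(rescale(a), rescale(b)), dice(a, b))
  expect_equal(mean_surface_distance(rescale(a), rescale(b)),
               k * mean_surface_distance(a, b))
  expect_equal(hausdorff_distance(rescale(a), rescale(b)),
               k * hausdorff_distance(a, b))
})

test_that("compare_structures aggregates metrics and flags empty pairs", {
  labels <- list(patient_id = "P01", scan_id = "MR10",
                 structure = "prostate", arm = "CT_MR")
  m <- sphere_mask(8)
  rec <- compare_structures(m, m, labels)
  expect_equal(rec$dsc, 1)
  expect_equal(rec$msd, 0)
  expect_equal(rec$hd, 0)
  expect_equal(rec$status, "ok")
  expect_equal(rec$n_components, 1L)
  expect_false(rec$has_handle)

  big <- sphere_mask(25); small <- sphere_mask(20, pad = 8)
  rec2 <- compare_structures(small, big, labels)
  expect_lt(abs(rec2$dsc - 0.677), 0.01)
  expect_lt(abs(rec2$msd - 5), sqrt(3))
  expect_lt(abs(rec2$hd - 5), sqrt(3))
  expect_lte(rec2$msd, rec2$hd)

  empty <- structure_mask(array(FALSE, m$grid$shape), m$grid)
  expect_equal(compare_structures(empty, m, labels)$status,
               "failed_empty_test")
  expect_equal(compare_structures(m, empty, labels)$status,
               "failed_empty_ref")
  both <- compare_structures(empty, empty, labels)
  expect_equal(both$status, "failed_empty_both")
  expect_true(is.na(both$dsc))

  for (seed in 10:14) {
    a <- random_mask(c(9, 9, 9), 0.25, seed)
    b <- random_mask(c(9, 9, 9), 0.25, seed + 50)
    if (!any(a$occupancy) || !any(b$occupancy)) next
    r <- compare_structures(a, b, labels)
    expect_lte(r$msd, r$hd)
    expect_gte(r$dsc, 0); expect_lte(r$dsc, 1)
    expect_lte(r$hd, sqrt(sum((a$grid$shape * a$grid$spacing)^2)))
  }
})

test_that("metrics complete on genus-1 and multi-component masks", {
  cfg <- tiny_cohort_config(pinhole_patients = 1)
  ph <- make_organ_phantom(cfg$grid, cfg$phantom, seed = 3, pinhole = TRUE)
  labels <- list(patient_id = "P01", scan_id = "pMR",
                 structure = "bladder", arm = "IOV")
  rec <- compare_structures(ph$bladder, ph$bladder, labels)
  expect_equal(rec$status, "ok")
  expect_true(rec$has_handle)
  rec2 <- compare_structures(ph$SV, ph$SV, labels)  # two lobes
  expect_equal(rec2$n_components, 2L)
  expect_equal(rec2$dsc, 1)
})
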