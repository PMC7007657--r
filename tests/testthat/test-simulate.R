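test_that("organ phantoms hit analytic volumes and are deterministic", {
  g <- voxel_grid(c(64, 64, 64), c(2, 2, 2.5))
  spec <- list(prostate = list(family = "ellipsoid", center = c(64, 64, 80),
                               size = c(20, 22, 25), scan_cv = 0,
                               jitter_sd = 0))
  m <- make_organ_phantom(g, spec, seed = 1)$prostate
  v_true <- 4 / 3 * pi * 20 * 22 * 25 / 1000
  expect_lt(abs(volume(m) - v_true) / v_true, 0.02)
  # zero variability: identical masks for different scan seeds
  m2 <- make_organ_phantom(g, spec, seed = 999)$prostate
  expect_identical(m$occupancy, m2$occupancy)
  # fixed seed, nonzero variability: bit-identical on regeneration
  cfg <- tiny_cohort_config()
  a <- make_organ_phantom(cfg$grid, cfg$phantom, seed = 42)
  b <- make_organ_phantom(cfg$grid, cfg$phantom, seed = 42)
  expect_identical(lapply(a, `[[`, "occupancy"),
                   lapply(b, `[[`, "occupancy"))
  # a structure that cannot fit errors out before producing masks
  bad <- list(bladder = list(family = "sphere", center = c(64, 64, 80),
                             size = c(200, 200, 200), scan_cv = 0,
                             jitter_sd = 0))
  expect_error(make_organ_phantom(g, bad, seed = 1), "exceeds the grid")
})

test_that("pinhole bladders are genus-1", {
  cfg <- tiny_cohort_config()
  ph <- make_organ_phantom(cfg$grid, cfg$phantom, seed = 7, pinhole = TRUE)
  expect_true(check_topology(ph$bladder)$has_handle)
  ph0 <- make_organ_phantom(cfg$grid, cfg$phantom, seed = 7, pinhole = FALSE)
  expect_false(check_topology(ph0$bladder)$has_handle)
})

test_that("displacement fields have the stated SD, scale and determinism", {
  g <- voxel_grid(c(48, 48, 48), c(2, 2, 2))
  f <- random_displacement_field(g, amplitude = 3, corr_length = 20,
                                 seed = 5)
  for (comp in list(f$ux, f$uy, f$uz))
    expect_lt(abs(sd(comp) - 3) / 3, 0.1)
  f2 <- random_displacement_field(g, 3, 20, seed = 5)
  expect_identical(f$ux, f2$ux)
  f3 <- random_displacement_field(g, 3, 20, seed = 6)
  expect_false(identical(f$ux, f3$ux))
  z <- random_displacement_field(g, 0, 20, seed = 5)
  expect_true(all(z$ux == 0) && all(z$uy == 0) && all(z$uz == 0))
})

test_that("warping is identity at zero field and exact for translations", {
  m <- sphere_mask(10, spacing = c(1, 1, 2))
  g <- m$grid
  expect_identical(warp_mask(m, translation_field(g, c(0, 0, 0)))$occupancy,
                   m$occupancy)
  w <- warp_mask(m, translation_field(g, c(2, -1, 4)))  # whole voxels
  expect_equal(sum(w$occupancy), sum(m$occupancy))
  iw <- which(w$occupancy, arr.ind = TRUE)
  im <- which(m$occupancy, arr.ind = TRUE)
  expect_equal(iw[order(iw[, 3], iw[, 2], iw[, 1]), ] -
                 im[order(im[, 3], im[, 2], im[, 1]), ],
               matrix(rep(c(2, -1, 2), each = nrow(im)), ncol = 3,
                      dimnames = dimnames(im)))
  # displacement bound: HD(warped, original) <= max |u| + voxel diagonal
  for (seed in 1:5) {
    f <- random_displacement_field(m$grid, amplitude = 2, corr_length = 15,
                                   seed = seed)
    wm <- warp_mask(m, f)
    umax <- max(sqrt(f$ux^2 + f$uy^2 + f$uz^2))
    expect_lte(hausdorff_distance(wm, m),
               umax + sqrt(sum(m$grid$spacing^2)))
  }
})

test_that("contour perturbation is identity at sigma 0 and reproducible", {
  m <- sphere_mask(12, spacing = c(1.5, 1.5, 1.5))
  expect_identical(perturb_contour(m, 0, seed = 1)$occupancy, m$occupancy)
  a <- perturb_contour(m, 1.5, seed = 4)
  b <- perturb_contour(m, 1.5, seed = 4)
  expect_identical(a$occupancy, b$occupancy)
})

test_that("dilation adds a metric margin", {
  m <- sphere_mask(10, pad = 8)
  d <- dilate_mask(m, 5)
  sd5 <- surface_distances(d, m)$distances
  expect_true(all(sd5 <= 5 + sqrt(3) + 1e-9))
  expect_gt(volume(d), volume(m))
  expect_identical(dilate_mask(m, 0)$occupancy, m$occupancy)
})

test_that("the simulated cohort reproduces the study design counts", {
  cfg <- tiny_cohort_config(n_patients = 2)
  co <- simulate_cohort(cfg)
  man <- co$manifest
  # per patient: 5 scans x 8 ground truths, 8 x (4 + 3) propagated, 8 IOV
  expect_equal(sum(man$role == "ground_truth"), 2 * 5 * 8)
  expect_equal(sum(man$role %in% c("propagated_CT_MR",
                                   "propagated_MR_MR")), 2 * 8 * 7)
  expect_equal(sum(man$role == "propagated_CT_MR"), 2 * 8 * 4)
  expect_equal(sum(man$role == "propagated_MR_MR"), 2 * 8 * 3)
  expect_equal(sum(man$role == "redelineation_IOV"), 2 * 8)
  # full determinism under the master seed
  co2 <- simulate_cohort(tiny_cohort_config(n_patients = 2))
  expect_identical(
    co$patients[[1]]$prop$CT_MR$MR10$bladder$occupancy,
    co2$patients[[1]]$prop$CT_MR$MR10$bladder$occupancy)
  expect_identical(co$manifest, co2$manifest)
})

test_that("CT delineation bias makes planning-CT prostates larger", {
  # direction of the cohort median: individual patients can flip because
  # the CT session draws its own anatomy, but the 2 mm dilation dominates
  # across patients
  cfg <- tiny_cohort_config(n_patients = 6, ct_dilation_mm = c(prostate = 2))
  co <- simulate_cohort(cfg)
  v_ct <- sapply(co$patients, function(p) volume(p$gt$pCT$prostate))
  v_mr <- sapply(co$patients, function(p) volume(p$gt$pMR$prostate))
  expect_gt(median(v_ct), median(v_mr))
  # no bias configured for the bladder
  b_ct <- sapply(co$patients, function(p) volume(p$gt$pCT$bladder))
  b_mr <- sapply(co$patients, function(p) volume(p$gt$pMR$bladder))
  expect_lt(abs(log(median(b_ct) / median(b_mr))), 0.5)
})

test_that("cohorts written to disk round trip through the manifest", {
  dir <- withr::local_tempdir()
  cfg <- tiny_cohort_config(n_patients = 1)
  man <- simulate_cohort(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  expect_true(all(file.exists(man$path)))
  loaded <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(loaded), nrow(man))
  # a mask read back equals its in-memory twin
  co <- simulate_cohort(cfg)
  row <- man[man$role == "propagated_MR_MR" & man$structure == "prostate" &
               man$scan_id == "MR20", ]
  disk <- read_mask(row$path, label = "prostate")
  mem <- co$patients[[1]]$prop$MR_MR$MR20$prostate
  expect_identical(disk$occupancy, mem$occupancy)
  expect_equal(disk$grid$spacing, mem$grid$spacing)
})

test_that("the coarse-CT mode exercises the resampling path", {
  cfg <- tiny_cohort_config(n_patients = 1, ct_slice_mm = 7.5)
  pat <- simulate_patient(cfg, 1)
  expect_equal(pat$gt$pCT$prostate$grid$spacing[3], 7.5)
  expect_equal(pat$gt$pMR$prostate$grid$spacing[3], 2.5)
  # propagated CT masks live on the MR grid
  expect_equal(pat$prop$CT_MR$MR10$prostate$grid$spacing[3], 2.5)
  ev <- dirqa:::evaluate_patient_sim(pat, evaluate_options(project = FALSE,
                                                           topology = FALSE))
  recs <- do.call(rbind, ev$records)
  expect_true(all(recs$status == "ok"))
})
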