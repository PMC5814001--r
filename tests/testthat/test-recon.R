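make_noiseless_scan <- function(map, geom, N0 = 1e8) {
  plan <- plan_currents(view_attenuation(map, geom), N0)
  simulate_projections(map, geom, plan, "reference", noise = "off")
}

test_that("vacuum projections reconstruct to zero", {
  vac <- attenuation_map(matrix(0, 64, 64), spacing = 0.5)
  g <- fan_geometry(n_cols = 96, pitch = 0.8, angles = 0:359)
  rec <- reconstruct(make_noiseless_scan(vac, g), vac)
  expect_lt(max(abs(rec$values)), 1e-12)
})

test_that("full-fan disk reconstruction recovers mu_water in the central ROI", {
  disk <- water_disk(n = 256, spacing = 0.125, radius = 8)
  g <- fan_geometry(n_cols = 288, pitch = 0.1875, angles = 0:359)
  rec <- reconstruct(make_noiseless_scan(disk, g), disk)
  msk <- central_mask(256) # 50%-radius central ROI (disk radius 64 px)
  expect_lt(abs(mean(rec$values[, , 1][msk]) - 0.206) / 0.206, 0.02)
})

test_that("displaced-detector reconstruction is accurate and untruncated", {
  disk <- water_disk(n = 256, spacing = 0.125, radius = 8)
  # XVI-like 11.5 cm shift scaled into this detector's coverage
  g <- fan_geometry(n_cols = 150, pitch = 0.375, offset = 11.25,
                    angles = 0:359)
  rec <- reconstruct(make_noiseless_scan(disk, g), disk,
                     weighting = "displaced-detector")
  img <- rec$values[, , 1]
  msk <- central_mask(256)
  expect_lt(abs(mean(img[msk]) - 0.206) / 0.206, 0.03)
  left <- msk; left[129:256, ] <- FALSE
  right <- msk; right[1:128, ] <- FALSE
  expect_lt(abs(mean(img[left]) - mean(img[right])) / mean(img[msk]), 0.02)
})

test_that("reconstruction is linear in the sinogram", {
  disk <- water_disk(n = 64, spacing = 0.5, radius = 8)
  g <- fan_geometry(n_cols = 96, pitch = 0.75, angles = seq(0, 357, 3))
  proj <- make_noiseless_scan(disk, g)
  rec1 <- reconstruct(proj, disk)
  proj3 <- proj
  proj3$log_integrals <- 3 * proj$log_integrals
  rec3 <- reconstruct(proj3, disk)
  expect_equal(rec3$values, 3 * rec1$values, tolerance = 1e-9)
})

test_that("an off-center disk reconstructs at its true world position", {
  shifted <- water_disk(n = 128, spacing = 0.25, radius = 4, offset = c(3, -2))
  g <- fan_geometry(n_cols = 220, pitch = 0.375, angles = 0:359)
  rec <- reconstruct(make_noiseless_scan(shifted, g), shifted)
  img <- rec$values[, , 1]
  w <- pmax(img, 0); w[w < 0.1] <- 0
  xs <- cbctcm:::.axis_coords(shifted, 1)
  ys <- cbctcm:::.axis_coords(shifted, 2)
  cx <- sum(w * xs) / sum(w)
  cy <- sum(sweep(w, 2, ys, `*`)) / sum(w)
  expect_lt(abs(cx - 3), 0.25)
  expect_lt(abs(cy - -2), 0.25)
})

test_that("more quanta give monotonically less reconstructed noise", {
  ph <- water_disk(n = 128, spacing = 0.25, radius = 8)
  g <- fan_geometry(n_cols = 220, pitch = 0.375, angles = 0:359)
  prof <- view_attenuation(ph, g)
  noise_at <- function(N0, seed) {
    plan <- plan_currents(prof, N0)
    pr <- simulate_projections(ph, g, plan, "reference", noise = "on",
                               seed = seed)
    rec <- reconstruct(pr, ph)
    msk <- central_mask(128)
    sd(rec$values[, , 1][msk]) / mean(rec$values[, , 1][msk])
  }
  lv <- vapply(c(1e8, 1e9, 1e10), noise_at, numeric(1), seed = 77)
  expect_true(all(diff(lv) < 0))
})

test_that("reconstruction guards its preconditions", {
  disk <- water_disk(n = 32, spacing = 0.5, radius = 4)
  g_partial <- fan_geometry(n_cols = 48, pitch = 1, angles = seq(0, 180, 2))
  proj <- make_noiseless_scan(disk, g_partial)
  expect_error(reconstruct(proj, disk), "full rotation")

  g_full <- fan_geometry(n_cols = 48, pitch = 1, angles = seq(0, 350, 10))
  proj2 <- make_noiseless_scan(disk, g_full)
  expect_warning(reconstruct(proj2, disk, weighting = "displaced-detector"),
                 "zero offset")
})

test_that("3D FDK reconstructs a slab phantom's central slice", {
  ph <- make_elliptical_phantom(64, 0.5, body_axes = c(10, 10),
                                body_material = "water", n_slices = 8,
                                slice_thickness = 0.5)
  g <- scan_geometry(100, 150, n_cols = 96, n_rows = 24, pitch = 0.75,
                     angles = seq(0, 357, 3))
  rec <- reconstruct(make_noiseless_scan(ph, g), ph)
  mid <- rec$values[, , 4]
  msk <- central_mask(64)
  expect_lt(abs(mean(mid[msk]) - 0.206) / 0.206, 0.05)
})
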