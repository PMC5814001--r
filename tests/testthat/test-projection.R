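test_that("vacuum scan transmits everything and log-normalizes to zero", {
  vac <- attenuation_map(matrix(0, 16, 16), spacing = 0.5)
  g <- fan_geometry(n_cols = 24, pitch = 0.8, angles = seq(0, 300, 60))
  plan <- plan_currents(rep(1, 6), 6e4)
  pr <- simulate_projections(vac, g, plan, "reference", noise = "off")
  expect_equal(as.numeric(pr$counts),
               rep(1e4 / 24, length(pr$counts)))
  expect_equal(max(abs(pr$log_integrals)), 0)
})

test_that("noiseless log integrals equal the Siddon integrals", {
  ph <- make_elliptical_phantom(32, 0.4, body_axes = c(5, 3))
  g <- fan_geometry(n_cols = 40, pitch = 0.6, angles = seq(0, 315, 45))
  plan <- plan_currents(view_attenuation(ph, g), 1e8)
  pr <- simulate_projections(ph, g, plan, "tcm", noise = "off")
  for (i in c(1, 4, 8)) {
    det <- cbctcm:::detector_positions(g, i)
    src <- matrix(cbctcm:::source_position(g, i), nrow(det), 3, byrow = TRUE)
    I <- cbctcm:::siddon_batch(ph, src, det)
    expect_equal(as.numeric(pr$log_integrals[i, 1, ]), as.numeric(I),
                 tolerance = 1e-9)
  }
})

test_that("Poisson sampling matches the Beer-Lambert expectation (mean and variance)", {
  disk <- water_disk(n = 32, spacing = 0.5, radius = 6)
  g <- fan_geometry(n_cols = 16, pitch = 1.5, angles = c(0, 90))
  plan <- plan_currents(view_attenuation(disk, g), 4e5)
  noiseless <- simulate_projections(disk, g, plan, "reference", noise = "off")
  elem <- c(1, 1, 8) # central-ish column of view 1
  lambda <- noiseless$counts[elem[1], elem[2], elem[3]]
  draws <- vapply(1:200, function(r)
    simulate_projections(disk, g, plan, "reference", noise = "on",
                         seed = 5000 + r)$counts[elem[1], elem[2], elem[3]],
    numeric(1))
  expect_lt(abs(mean(draws) - lambda) / lambda, 0.05)
  expect_lt(abs(var(draws) - lambda) / lambda, 0.25) # var of var is larger
})

test_that("projection simulation is reproducible, linear, and bowtie-consistent", {
  ph <- make_elliptical_phantom(24, 0.5, body_axes = c(4, 2.5))
  g <- fan_geometry(n_cols = 30, pitch = 0.8, angles = seq(0, 324, 36))
  prof <- view_attenuation(ph, g)
  plan1 <- plan_currents(prof, 1e6)
  plan2 <- plan_currents(prof, 2e6)

  a <- simulate_projections(ph, g, plan1, "tcm", noise = "on", seed = 9)
  b <- simulate_projections(ph, g, plan1, "tcm", noise = "on", seed = 9)
  expect_identical(a$counts, b$counts)
  c_ <- simulate_projections(ph, g, plan1, "tcm", noise = "on", seed = 10)
  expect_false(identical(a$counts, c_$counts))

  # doubling quanta doubles expected counts (noise off)
  na <- simulate_projections(ph, g, plan1, "reference", noise = "off")
  nb <- simulate_projections(ph, g, plan2, "reference", noise = "off")
  expect_equal(nb$counts, 2 * na$counts, tolerance = 1e-12)

  # flat bowtie is bitwise identical to no bowtie
  f1 <- simulate_projections(ph, g, plan1, "reference", noise = "on", seed = 3)
  f2 <- simulate_projections(ph, g, plan1, "reference", noise = "on", seed = 3,
                             bowtie_profile = rep(2, g$n_cols))
  expect_identical(f1$counts, f2$counts)

  # a real bowtie reshapes incident fluence at unchanged view totals
  bw <- bowtie_profile(g$n_cols, depth = 0.5)
  fb <- simulate_projections(ph, g, plan1, "reference", noise = "off",
                             bowtie_profile = bw)
  expect_equal(sum(fb$incident[1, ]), sum(na$incident[1, ]))
  expect_gt(fb$incident[1, 15], fb$incident[1, 1])

  expect_error(simulate_projections(ph, g, plan1, "reference", noise = "on"),
               "seed")
  expect_error(simulate_projections(ph, g, plan1, "reference",
                                    bowtie_profile = rep(-1, g$n_cols),
                                    noise = "off"),
               "positive")
})

test_that("zero-count clamping warns and keeps log integrals finite", {
  # heavily attenuating object with starving fluence
  ph <- make_elliptical_phantom(32, 0.5, body_axes = c(7, 7),
                                body_material = "bone")
  g <- fan_geometry(n_cols = 20, pitch = 1.2, angles = c(0, 120, 240))
  plan <- plan_currents(view_attenuation(ph, g), 3000)
  expect_warning(
    pr <- simulate_projections(ph, g, plan, "reference", noise = "on",
                               seed = 2),
    "clamped")
  expect_gt(pr$n_clamped, 0)
  expect_true(all(is.finite(pr$log_integrals)))
})

test_that("projection sets serialize with their sidecar", {
  ph <- make_elliptical_phantom(16, 0.5, body_axes = c(3, 2))
  g <- fan_geometry(n_cols = 12, pitch = 1, angles = c(0, 180))
  plan <- plan_currents(view_attenuation(ph, g), 1e5)
  pr <- simulate_projections(ph, g, plan, "reference", noise = "off")
  path <- tempfile(fileext = ".nii")
  on.exit(unlink(c(path, paste0(sub("\\.nii$", "", path), ".json"))))
  write_projections(pr, path)
  back <- read_volume(path)
  expect_equal(back$values, pr$counts, ignore_attr = TRUE)
  side <- jsonlite::read_json(paste0(sub("\\.nii$", "", path), ".json"))
  expect_equal(side$geometry$n_cols, 12)
})
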