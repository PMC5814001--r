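test_that("reference variance follows the uniform-current noise model", {
  expect_equal(reference_variance(rep(1, 7), 49), 1) # P^2 / N0
  expect_equal(reference_variance(c(1, 4), 100), 0.1) # 1/50 + 4/50
  A <- c(1.2, 3.5, 8, 2)
  expect_equal(reference_variance(A, 2000), reference_variance(A, 1000) / 2)
  expect_error(reference_variance(c(1, 2), 0), "positive")
  expect_error(reference_variance(c(0.5, 2), 10), ">= 1")
})

test_that("the hand-derived two-view plan is exact", {
  p <- plan_currents(c(1, 4), 100)
  expect_equal(p$N0_prime, 90)
  expect_equal(p$N0i_prime, c(30, 60))
  expect_equal(p$sigma2_ref, 0.1)
  expect_equal(p$sigma2_tcm, 0.1)
  expect_equal(p$reduction_fraction, 0.1)
})

test_that("equal attenuation gives no modulation (Cauchy-Schwarz equality case)", {
  p <- plan_currents(rep(2.5, 12), 600)
  expect_equal(p$N0_prime, 600)
  expect_equal(p$N0i_prime, rep(50, 12))
  expect_equal(p$reduction_fraction, 0)
})

test_that("plan invariants hold over random profiles", {
  set.seed(31)
  for (i in 1:200) {
    P <- sample(2:40, 1)
    A <- 1 + rexp(P, rate = 1 / 20)
    N0 <- runif(1, 10, 1e8)
    p <- plan_currents(A, N0)
    expect_true(all(p$N0i_prime > 0))
    expect_lt(abs(sum(p$N0i_prime) - p$N0_prime), 1e-9 * p$N0_prime)
    expect_lt(abs(p$sigma2_tcm - p$sigma2_ref), 1e-9 * p$sigma2_ref)
    expect_true(p$reduction_fraction >= 0 && p$reduction_fraction < 1)
    # dose-reduction guarantee and monotone allocation
    expect_lte(p$N0_prime, N0 * (1 + 1e-12))
    ord <- order(A)
    expect_true(all(diff(p$N0i_prime[ord]) >= -1e-9 * max(p$N0i_prime)))
  }
})

test_that("scaling N0 scales the plan without changing the reduction", {
  A <- c(2, 9, 5, 1.3, 7)
  p1 <- plan_currents(A, 100)
  p2 <- plan_currents(A, 700)
  expect_equal(p2$N0_prime, 7 * p1$N0_prime)
  expect_equal(p2$N0i_prime, 7 * p1$N0i_prime)
  expect_equal(p2$reduction_fraction, p1$reduction_fraction)
})

test_that("sqrt allocation matches a brute-force constrained minimizer", {
  set.seed(17)
  for (i in 1:12) {
    P <- sample(2:5, 1)
    A <- 1 + rexp(P, rate = 1 / 10)
    p <- plan_currents(A, 50)
    brute <- oracle_min_total(A, p$sigma2_ref)
    expect_lt(abs(brute - p$N0_prime) / p$N0_prime, 1e-4)
  }
})

test_that("proportional mode is variance-matched but saves nothing", {
  A <- c(1.5, 6, 3, 9)
  p <- plan_currents(A, 400, allocation_mode = "proportional")
  expect_equal(p$sigma2_tcm, p$sigma2_ref)
  expect_equal(p$N0_prime, 400) # the literal proportional rule cannot reduce
  expect_equal(p$reduction_fraction, 0)
  expect_equal(p$N0i_prime / A, rep(p$N0i_prime[1] / A[1], 4))
})

test_that("planner rejects invalid profiles", {
  expect_error(plan_currents(c(0.9, 2), 10), ">= 1")
  expect_error(plan_currents(numeric(0), 10), "non-empty")
})

test_that("plan serialization writes the per-view table and summary", {
  p <- plan_currents(c(1, 4, 2), 300)
  tp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".json")
  on.exit(unlink(c(tp, sp)))
  tab <- write_plan(p, tp, sp)
  expect_equal(nrow(read.csv(tp)), 3)
  s <- jsonlite::read_json(sp)
  expect_equal(s$N0, 300)
  expect_equal(s$N0_prime, p$N0_prime)
})

test_that("dose proxy: vacuum is zero, symmetry at the center, modulation lowers the mean", {
  vac <- attenuation_map(matrix(0, 24, 24), spacing = 0.5)
  g <- fan_geometry(n_cols = 32, pitch = 0.8, angles = seq(0, 350, 10))
  pv <- plan_currents(view_attenuation(vac, g), 1e6)
  expect_true(all(dose_proxy_map(vac, g, pv, "reference")$values == 0))

  # centered disk, uniform plan: per-view contributions at the exact center
  # voxel are equal within every orbit of the grid's symmetry group (the
  # continuum equality over all views only holds up to chord voxelization)
  disk <- water_disk(n = 49, spacing = 0.25, radius = 4)
  gd <- fan_geometry(n_cols = 64, pitch = 0.5, angles = seq(0, 350, 10))
  ctrv <- vapply(seq_len(36), function(i) {
    src <- cbctcm:::source_position(gd, i)
    2 * exp(-siddon_line_integral(disk, src, c(0, 0, 0))) * disk$values[25, 25, 1]
  }, numeric(1))
  ang <- gd$angles
  orbit <- pmin(ang %% 90, 90 - ang %% 90) # dihedral orbit label
  for (o in split(ctrv, orbit))
    expect_lt(diff(range(o)) / mean(o), 1e-9)
  expect_lt(diff(range(ctrv)) / mean(ctrv), 0.06) # voxel-layer bound

  # eccentric phantom: modulated mean proxy below reference
  ecc <- make_elliptical_phantom(48, 0.5, body_axes = c(10, 5))
  ge <- fan_geometry(n_cols = 64, pitch = 0.75, angles = seq(0, 355, 5))
  pe <- plan_currents(view_attenuation(ecc, ge), 1e6)
  dr <- dose_proxy_map(ecc, ge, pe, "reference")
  dt <- dose_proxy_map(ecc, ge, pe, "tcm")
  expect_lt(dose_proxy_mean(dt) / dose_proxy_mean(dr), 1)

  bad <- fan_geometry(n_cols = 64, pitch = 0.75, angles = seq(0, 355, 10))
  expect_error(dose_proxy_map(ecc, bad, pe, "tcm"), "views")
})
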