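test_that("IE fit recovers exact model members at the interval bounds", {
  g <- sample_geometry(200, 200)
  planar <- simulate_curve("planar", modulus = 1000, geometry = g)
  fp <- fit_ie(planar)
  expect_equal(fp$alpha, 1, tolerance = 1e-6)
  expect_equal(fp$E, 1000, tolerance = 1e-6)
  expect_equal(fp$r_squared, 1, tolerance = 1e-9)
  expect_true(fp$at_bound)

  hertz <- simulate_curve("hertz", modulus = 1000,
                          geometry = sphere_geometry(100))
  fh <- fit_ie(hertz)
  expect_equal(fh$alpha, 1.5, tolerance = 1e-6)
  expect_equal(fh$E, 1000, tolerance = 1e-6)
  expect_equal(fh$r_squared, 1, tolerance = 1e-9)
})

test_that("IE fit recovers interior generating exponents on noiseless curves", {
  g <- sample_geometry(160, 140)
  for (a in seq(1.0, 1.5, by = 0.1)) {
    cu <- simulate_curve("ie", modulus = 700, alpha = a, geometry = g)
    fit <- fit_ie(cu)
    expect_equal(fit$alpha, a, tolerance = 1e-6)
    expect_equal(fit$E, 700, tolerance = 1e-5)
  }
})

test_that("full-range linear fit is exact on planar curves and biased low on Hertz", {
  g <- sample_geometry(200, 200)
  planar <- simulate_curve("planar", modulus = 1000, geometry = g)
  fl <- fit_linear_full(planar)
  expect_equal(fl$E, 1000, tolerance = 1e-9)
  expect_equal(fl$r_squared, 1, tolerance = 1e-12)

  # Hertz curve over delta in (0, 0.2 R]: through-origin projection of
  # delta^1.5 on delta. Continuum oracle: the fitted E approaches
  # C(1.5) * [int d^2.5 / int d^2] / C(1) = (4/3)sqrt(R) * (3/3.5) *
  # dmax^0.5 / (pi R / 2) of the generating E.
  R <- 100
  gs <- sphere_geometry(R)
  dmax <- 0.2 * R
  hertz <- simulate_curve("hertz", modulus = 1000, geometry = gs,
                          strain_fraction = 0.1, n_points = 2000)
  stopifnot(abs(max(hertz$displacement) - dmax) < 1e-9)
  fl2 <- fit_linear_full(hertz)
  oracle <- 1000 * (4 / 3) * sqrt(R) * (3 / 3.5) * sqrt(dmax) / (pi * R / 2)
  expect_lt(fl2$E, 1000)
  expect_equal(fl2$E, oracle, tolerance = 2e-3)  # discrete vs continuum
})

test_that("two-point fit matches the full fit on linear data but is pair-dependent on Hertz data", {
  g <- sample_geometry(200, 200)
  planar <- simulate_curve("planar", modulus = 1000, geometry = g)
  tp <- fit_two_point(planar)
  expect_equal(tp$E, fit_linear_full(planar)$E, tolerance = 1e-9)

  hertz <- simulate_curve("hertz", modulus = 1000,
                          geometry = sphere_geometry(100))
  e1 <- fit_two_point(hertz, indices = c(1, 2))$E
  e2 <- fit_two_point(hertz, indices = c(30, 40))$E
  expect_gt(abs(e2 - e1) / e1, 0.5)  # strongly pair-dependent

  expect_error(fit_two_point(planar, indices = c(3, 3)), "degenerate")
  flatf <- force_curve(1:10, rep(0, 10))
  expect_error(fit_two_point(flatf, geometry = g, noise_floor = 0.5),
               "fewer than 2")
})

test_that("Hertz fit recovers E exactly and scales as 1/sqrt(R)", {
  gs <- sphere_geometry(100)
  hertz <- simulate_curve("hertz", modulus = 1000, geometry = gs)
  expect_equal(fit_hertz(hertz)$E, 1000, tolerance = 1e-9)
  # halving the assumed radius scales the fitted E by sqrt(2)
  expect_equal(fit_hertz(hertz, radius = 50)$E, 1000 * sqrt(2),
               tolerance = 1e-9)
  # nesting: IE with the interval collapsed to 1.5 equals the Hertz fit
  ie15 <- fit_ie(hertz, alpha_bounds = c(1.5, 1.5))
  expect_equal(ie15$E, 1000, tolerance = 1e-9)
  expect_equal(ie15$alpha, 1.5)
})

test_that("r_squared follows its definition", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # SSres 1, SStot 2
  expect_error(r_squared(c(2, 2), c(1, 2)), "identical")
})

test_that("IE never fits worse than the linear model on any curve", {
  g <- sample_geometry(180, 150)
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, 1, 1.5)
    cu <- simulate_curve("ie", modulus = 10^runif(1, 2, 3.5), alpha = a,
                         geometry = g, noise_rel = runif(1, 0, 0.1),
                         seed = 1000 + i)
    expect_gte(fit_ie(cu)$r_squared, fit_linear_full(cu)$r_squared - 1e-12)
  }
})

test_that("linear fits underestimate E whenever the generating exponent exceeds 1", {
  g <- sample_geometry(220, 200)
  for (a in c(1.1, 1.25, 1.47)) {
    cu <- simulate_curve("ie", modulus = 1000, alpha = a, geometry = g)
    expect_lt(fit_linear_full(cu)$E, fit_ie(cu)$E)
  }
})

test_that("fitted moduli and exponents are invariant under geometric unit scaling", {
  g <- sample_geometry(150, 120)
  cu <- simulate_curve("ie", modulus = 900, alpha = 1.3, geometry = g,
                       noise_rel = 0.03, seed = 77)
  for (s in c(0.25, 4)) {
    scaled <- force_curve(cu$displacement * s, cu$force * s^2,
                          geometry = sample_geometry(150 * s, 120 * s))
    f0 <- fit_ie(cu)
    fs <- fit_ie(scaled)
    expect_equal(fs$alpha, f0$alpha, tolerance = 1e-9)
    expect_equal(fs$E, f0$E, tolerance = 1e-9)
    expect_equal(fit_linear_full(scaled)$E, fit_linear_full(cu)$E,
                 tolerance = 1e-9)
  }
})

test_that("fitted exponent does not depend on sample size", {
  # geometrically scaled copies of the same curve family get identical alpha
  base <- sample_geometry(100, 100)
  cu <- simulate_curve("ie", modulus = 1000, alpha = 1.35, geometry = base,
                       noise_rel = 0.04, seed = 5)
  a0 <- fit_ie(cu)$alpha
  for (s in c(0.5, 2, 5)) {
    scaled <- force_curve(cu$displacement * s, cu$force * s^2,
                          geometry = sample_geometry(100 * s, 100 * s))
    expect_equal(fit_ie(scaled)$alpha, a0, tolerance = 1e-9)
  }
})

test_that("IE fit under 5% noise recovers parameters with small median error", {
  g <- sample_geometry(200, 200)
  n_rep <- 200
  errs_E <- errs_a <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    cu <- simulate_curve("ie", modulus = 1000, alpha = 1.25, geometry = g,
                         noise_rel = 0.05, seed = 20000 + i)
    fit <- fit_ie(cu)
    errs_E[i] <- abs(fit$E - 1000) / 1000
    errs_a[i] <- abs(fit$alpha - 1.25)
  }
  expect_lt(median(errs_E), 0.10)
  expect_lt(median(errs_a), 0.05)
})

test_that("degenerate fit inputs raise informative errors", {
  g <- sample_geometry(100, 100)
  neg <- force_curve(1:5, rep(-1, 5), geometry = g)
  expect_error(fit_ie(neg), "non-positive")
  expect_error(fit_ie(force_curve(c(0, 0, 0, 1), c(0, 0, 0, 1))), "geometry",
               ignore.case = TRUE)
  # log-force objective demands positive forces
  mix <- force_curve(1:5, c(-0.1, 1, 2, 3, 4), geometry = g)
  expect_error(fit_ie(mix, objective = "log_force"), "positive")
})

test_that("optional intercept and log-force objective behave sensibly", {
  g <- sample_geometry(200, 200)
  cu <- simulate_curve("planar", modulus = 1000, geometry = g)
  # add a constant force offset: the intercept variant absorbs it
  shifted <- force_curve(cu$displacement, cu$force + 0.05, geometry = g)
  expect_equal(fit_linear_full(shifted, intercept = TRUE)$E, 1000,
               tolerance = 1e-6)
  expect_false(abs(fit_linear_full(shifted)$E - 1000) < 1)
  # noiseless member: both objectives agree
  ie <- simulate_curve("ie", modulus = 800, alpha = 1.2, geometry = g)
  expect_equal(fit_ie(ie, objective = "log_force")$alpha, 1.2,
               tolerance = 1e-5)
})
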