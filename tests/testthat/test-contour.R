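test_that("extract_contour traces a disk boundary at the right scale", {
  R <- 40
  m <- disk_mask(R)
  ct <- extract_contour(m)
  expect_s3_class(ct, "contour_profile")
  span_y <- max(ct$y) - min(ct$y)
  span_x <- max(ct$x) - min(ct$x)
  expect_lt(abs(span_y - 2 * R), 1.5)
  expect_lt(abs(span_x - 2 * R), 1.5)
  # pixel_size scales coordinates
  ct2 <- extract_contour(m, pixel_size = 0.5)
  expect_equal(max(ct2$y) - min(ct2$y), span_y * 0.5)
})

test_that("extract_contour rejects tiny, empty and multi-component masks", {
  expect_error(extract_contour(matrix(0, 20, 20)), ">= 9 pixels")
  single <- matrix(0, 20, 20)
  single[10, 10] <- 1
  expect_error(extract_contour(single), ">= 9 pixels")
  two <- matrix(0, 40, 40)
  two[5:12, 5:12] <- 1
  two[25:32, 25:32] <- 1
  expect_error(extract_contour(two), "multiple components")
})

test_that("a boundary bump of known height survives extraction", {
  m <- disk_mask(30, size = 81)
  # add a 4-px bump on top of the disk (columns at the apex)
  apex_row <- which(m[, 41] == 1)[1]
  m[(apex_row - 4):(apex_row - 1), 40:42] <- 1L
  ct <- extract_contour(m)
  plain <- extract_contour(disk_mask(30, size = 81))
  expect_gt(max(ct$y), max(plain$y) + 3)
})

test_that("upper_fraction selects the connected top segment", {
  # full circle, center origin: the upper 10% window is y >= R(1 - 2f)
  circ <- circle_outline(radius = 100, n = 2000)
  ct <- contour_profile(circ$x, circ$y)
  up <- upper_fraction(ct, 0.1)
  expect_true(all(up$y >= 100 * (1 - 2 * 0.1) - 1e-9))
  expect_equal(min(up$y), 80, tolerance = 0.01)  # within sampling resolution
  # fraction 1 returns the whole contour
  expect_equal(length(upper_fraction(ct, 1)$x), length(ct$x))
  # the selected indices form one connected run across the arc apex
  expect_equal(length(up$x), sum(ct$y >= 100 * (1 - 2 * 0.1)))
})

test_that("non_planarity matches hand-computed values and scales as 1/length", {
  # perfectly flat upper contour: zero variance
  flat <- contour_profile(1:50, rep(80, 50), height = 100)
  expect_equal(non_planarity(flat, height = 100), 0)

  # two-level contour: half the points at 0.9 h, half at h, h = 1
  h <- 1
  two <- contour_profile(1:40, rep(c(0.9, 1), each = 20), height = h)
  expect_equal(non_planarity(two, height = h), 0.05 / 0.95,
               tolerance = 1e-12)

  # chi carries 1/length: scaling contour and frame by 2 halves it
  up <- circle_arc_points(radius = 100, fraction = 0.1, n = 300)
  c1 <- contour_profile(up$x, up$y, height = 200)
  c2 <- contour_profile(2 * up$x, 2 * up$y, height = 400)
  expect_equal(non_planarity(c2, 400), non_planarity(c1, 200) / 2,
               tolerance = 1e-12)

  expect_error(non_planarity(contour_profile(1:5, rep(0, 5), height = 1),
                             height = 1), "mean y")
})

test_that("circle reference chi agrees with the analytic continuum limit", {
  # closed-form oracle: for f = 0.1, chi_circle * h converges to
  # 2 * sqrt(<sin^2> - <sin>^2) / (1 + <sin>) over theta in [th0, pi - th0]
  f <- 0.1
  th0 <- asin(1 - 2 * f)
  m1 <- integrate(function(t) sin(t), th0, pi - th0)$value / (pi - 2 * th0)
  m2 <- integrate(function(t) sin(t)^2, th0, pi - th0)$value / (pi - 2 * th0)
  chi_cont <- sqrt(m2 - m1^2) / (2 * (1 + m1))  # times 1/R with h = 2R
  h <- 2
  expect_lt(abs(chi_circle_reference(h, f, n_points = 4000) - chi_cont) /
              chi_cont, 0.02)
  # determinism: identical inputs give identical values
  expect_identical(chi_circle_reference(200, 0.1, 333),
                   chi_circle_reference(200, 0.1, 333))
  expect_gt(chi_circle_reference(200, 0.05, 100), 0)
})

test_that("normalized non-planarity is ~1 for circles, 0 for flat tops, higher for castellated tops", {
  circ <- circle_outline(radius = 100, n = 3000)
  expect_equal(normalized_non_planarity(contour_profile(circ$x, circ$y)), 1,
               tolerance = 0.02)

  # rasterized circle: within the <= 2% rasterization band at 200 px diameter
  m <- simulate_mask(radius_px = 100)
  expect_equal(normalized_non_planarity(extract_contour(m$mask)), 1,
               tolerance = 0.02)

  # flat-topped outline: zero numerator
  xx <- c(seq(-50, 50, by = 1), seq(49, -49, by = -1))
  yy <- c(rep(100, 101), rep(0, 99))
  flat <- contour_profile(xx, yy)
  expect_equal(normalized_non_planarity(flat, fraction = 0.05), 0)

  # a castellated (two-level) top concentrates y at the window extremes and
  # exceeds the circle reference
  xc <- seq(-100, 100, by = 1)
  yc <- ifelse(floor((xc + 100) / 50) %% 2 == 0, 200, 182)
  n <- length(xc)
  cast <- contour_profile(c(xc, rev(xc[-c(1, n)])),
                          c(yc, rep(0, n - 2)))
  expect_gt(normalized_non_planarity(cast), 1)
})

test_that("vertical stretching is self-similar for the normalized ratio", {
  # a taller-than-wide ellipse has the same y-distribution over its relative
  # upper window as the height-matched reference circle, so the ratio stays
  # near 1 (deviations only from arc-length sampling density)
  th <- seq(0, 2 * pi, length.out = 3000)[-1]
  ell <- contour_profile(100 * cos(th), 150 * sin(th))
  expect_equal(normalized_non_planarity(ell), 1, tolerance = 0.02)
})

test_that("smoothness is 1 for straight segments and 0.9324 for the circle cap", {
  straight <- contour_profile(seq(0, 100, by = 1), rep(5, 101))
  expect_equal(contour_smoothness(straight), 1, tolerance = 1e-12)

  # closed-form circle-arc oracle: chord 1.2 R vs arc 1.28700 R
  arc <- circle_arc_points(radius = 100, fraction = 0.1, n = 2000)
  up <- contour_profile(arc$x, arc$y, height = 200)
  expect_equal(contour_smoothness(up), 1.2 / (pi - 2 * asin(0.8)),
               tolerance = 1e-4)
  expect_equal(contour_smoothness(up), 0.9324, tolerance = 1e-3)
})

test_that("smoothness is scale- and translation-invariant and drops with bumps", {
  arc <- circle_arc_points(radius = 80, fraction = 0.1, n = 500)
  base <- contour_profile(arc$x, arc$y, height = 160)
  s0 <- contour_smoothness(base)
  moved <- contour_profile(3 * arc$x + 500, 3 * arc$y, height = 480)
  expect_equal(contour_smoothness(moved), s0, tolerance = 1e-12)

  # high-frequency bumps increase arc length at fixed chord
  bumpy <- contour_profile(arc$x,
                           arc$y + 2 * sin(seq(0, 40 * pi,
                                               length.out = 500)),
                           height = 160)
  expect_lt(contour_smoothness(bumpy), s0)

  expect_error(contour_smoothness(contour_profile(c(1, 1), c(2, 2))),
               "degenerate")
})
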