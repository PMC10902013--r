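# Fixtures built in code; no binary files.

# Ordered points on the upper arc of a circle (y >= R * (1 - 2 * fraction)),
# uniform in polar angle, optionally in a base-origin frame.
circle_arc_points <- function(radius = 100, fraction = 0.1, n = 400,
                              base_origin = TRUE) {
  theta0 <- asin(1 - 2 * fraction)
  theta <- seq(pi - theta0, theta0, length.out = n)  # left to right
  y <- radius * sin(theta)
  if (base_origin) y <- y + radius
  list(x = radius * cos(theta), y = y)
}

# Full circle outline as a closed polyline, uniform in angle.
circle_outline <- function(radius = 100, n = 2000) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-1]
  list(x = radius * cos(theta), y = radius * sin(theta))
}

# A filled-disk mask (image orientation) without going through simulate_mask.
disk_mask <- function(radius_px, size = 2 * radius_px + 9) {
  cx <- (size + 1) / 2
  xm <- matrix(seq_len(size) - cx, size, size, byrow = TRUE)
  ym <- matrix(seq_len(size) - cx, size, size)
  matrix(as.integer(xm^2 + ym^2 <= radius_px^2), size, size)
}

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(max(abs(object - expected) / abs(expected)), rel_tol)
}
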