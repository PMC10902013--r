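#' Simulate a force-displacement curve
#'
#' Seeded forward simulation of the contact-model force laws with additive
#' Gaussian noise, for testing and calibration. Displacements are evenly
#' spaced on `(0, strain_fraction * h]`; the noise standard deviation is
#' `noise_rel` times the maximum noise-free force (multiplicative noise,
#' sd proportional to each point's force, is available as an option).
#'
#' @param model `"planar"`, `"hertz"` or `"ie"`.
#' @param modulus Generating effective modulus E (Pa).
#' @param alpha Generating exponent (IE model only).
#' @param geometry A [sample_geometry()]. The Hertz model uses
#'   `R = height/2` and expects `width == height`.
#' @param strain_fraction Maximum strain delta/h simulated (default 0.10).
#' @param n_points Number of points (default 50, >= 3).
#' @param noise_rel Gaussian noise sd as a fraction of max force (default 0).
#' @param noise_type `"additive"` (default) or `"multiplicative"`.
#' @param seed RNG seed; identical seeds give identical curves and the
#'   caller's RNG stream is left untouched.
#' @param sample_id Identifier stored on the curve.
#' @return A [force_curve()] with the geometry attached and the generating
#'   ground truth in `attr(curve, "truth")` (fields `model`, `E`, `alpha`,
#'   `width`, `height`).
#' @examples
#' g <- sphere_geometry(100)
#' cu <- simulate_curve("hertz", modulus = 1000, geometry = g,
#'                      noise_rel = 0.05, seed = 42)
#' attr(cu, "truth")$E
#' @export
simulate_curve <- function(model = c("ie", "planar", "hertz"), modulus,
                           alpha = NULL, geometry, strain_fraction = 0.10,
                           n_points = 50L, noise_rel = 0,
                           noise_type = c("additive", "multiplicative"),
                           seed = NULL, sample_id = NA_character_) {
  model <- match.arg(model)
  noise_type <- match.arg(noise_type)
  g <- .as_geometry(geometry)
  .check_scalar(modulus, "modulus", positive = TRUE)
  .check_scalar(strain_fraction, "strain_fraction", positive = TRUE)
  .check_scalar(n_points, "n_points", positive = TRUE)
  if (n_points < 3) .stop_invalid("`n_points` must be >= 3")
  .check_scalar(noise_rel, "noise_rel", nonneg = TRUE)
  n <- as.integer(n_points)
  delta <- strain_fraction * g$height * seq_len(n) / n
  f_exact <- switch(model,
    planar = force_planar(modulus, g, delta),
    hertz = {
      if (abs(g$width - g$height) > 1e-9 * g$height) {
        .stop_invalid("the Hertz model needs a spherical geometry (width == height)")
      }
      force_hertz(modulus, g$height / 2, delta)
    },
    ie = {
      if (is.null(alpha)) .stop_invalid("`alpha` is required for the IE model")
      force_ie(modulus, alpha, g, delta)
    })
  f <- if (noise_rel > 0) {
    .with_seed(seed, {
      sd <- if (noise_type == "additive") noise_rel * max(f_exact)
            else noise_rel * f_exact
      f_exact + stats::rnorm(n, 0, sd)
    })
  } else f_exact
  cu <- force_curve(delta, f, sample_id = sample_id, geometry = g,
                    strain_limit = strain_fraction)
  attr(cu, "truth") <- list(model = model, E = modulus,
                            alpha = switch(model, planar = 1, hertz = 1.5,
                                           ie = alpha),
                            width = g$width, height = g$height,
                            noise_rel = noise_rel, seed = seed)
  cu
}

# Seeded harmonic roughness: three harmonics at k, 2k, 3k with weights
# 1, 1/2, 1/4 (normalized), random phases. |perturbation| <= amp by
# construction, so outlines stay simple for amp < 1.
.roughness_fun <- function(amp, freq, seed) {
  if (amp == 0) return(function(theta) rep(0, length(theta)))
  phases <- .with_seed(seed, stats::runif(3L, 0, 2 * pi))
  w <- c(1, 0.5, 0.25) / 1.75
  function(theta) {
    amp * (w[1L] * sin(freq * theta + phases[1L]) +
           w[2L] * sin(2 * freq * theta + phases[2L]) +
           w[3L] * sin(3 * freq * theta + phases[3L]))
  }
}

#' Simulate a spheroid silhouette mask
#'
#' Generates a binary mask (plus ground-truth outline) of a quasi-circular
#' silhouette: a radial outline \eqn{r(\theta) = R[1 + roughness(\theta)]}
#' built from a seeded low-order harmonic series, with its upper half
#' optionally squashed toward the equatorial plane. `cap_flattening = 0`
#' leaves a (rough) circle; `cap_flattening = 1` collapses the upper half to
#' a flat top (a half-disk for zero roughness), covering the spherical-cap to
#' planar-top geometric regimes.
#'
#' @param radius_px Base outline radius in pixels (>= 20).
#' @param cap_flattening In `[0, 1]`: 0 = spherical cap, 1 = flat top.
#' @param roughness_amp Bump amplitude as a fraction of the radius
#'   (< 0.3 guarantees a simple outline).
#' @param roughness_freq Number of bumps per circumference (>= 1).
#' @param image_size Square image side in pixels; default fits the shape
#'   with an 8-px margin.
#' @param seed RNG seed for the bump phases.
#' @return A list with `mask` (0/1 matrix in image orientation, row 1 = top),
#'   `contour` (ground-truth [contour_profile()] polyline in y-up pixel
#'   coordinates) and `spec` (the generating parameters).
#' @examples
#' s <- simulate_mask(radius_px = 60, roughness_amp = 0.05, seed = 7)
#' normalized_non_planarity(extract_contour(s$mask))
#' @export
simulate_mask <- function(radius_px = 100, cap_flattening = 0,
                          roughness_amp = 0, roughness_freq = 8L,
                          image_size = NULL, seed = NULL) {
  .check_scalar(radius_px, "radius_px", positive = TRUE)
  if (radius_px < 20) .stop_invalid("`radius_px` must be >= 20")
  .check_scalar(cap_flattening, "cap_flattening", nonneg = TRUE)
  if (cap_flattening > 1) .stop_invalid("`cap_flattening` must be in [0, 1]")
  .check_scalar(roughness_amp, "roughness_amp", nonneg = TRUE)
  if (roughness_amp >= 0.3) {
    .stop_invalid("`roughness_amp` >= 0.3 risks a self-intersecting outline")
  }
  .check_scalar(roughness_freq, "roughness_freq", positive = TRUE)
  R <- radius_px
  rough <- .roughness_fun(roughness_amp, as.integer(roughness_freq), seed)
  if (is.null(image_size)) {
    image_size <- ceiling(2 * R * (1 + roughness_amp)) + 16L
  }
  .check_scalar(image_size, "image_size", positive = TRUE)
  size <- as.integer(image_size)
  if (size < 2 * R * (1 + roughness_amp) + 4) {
    .stop_invalid("`image_size` too small for the shape")
  }
  cx <- (size + 1) / 2
  cy <- (size + 1) / 2
  squash <- 1 - cap_flattening  # vertical scale of the upper half

  # ground-truth outline: polar points, upper half squashed
  theta <- seq(0, 2 * pi, length.out = 2048L + 1L)[-1L]
  rr <- R * (1 + rough(theta))
  gx <- rr * cos(theta)
  gy <- rr * sin(theta)
  gy[gy > 0] <- gy[gy > 0] * squash
  truth <- contour_profile(gx + cx, gy + cy, pixel_size = 1)

  # rasterize via the inverse squash map: pixel (x, y) is inside iff the
  # un-squashed point (x, y/squash for y > 0) lies inside the base outline
  col_x <- (seq_len(size)) - cx
  row_y <- (cy - seq_len(size))  # row 1 = top of image = largest y
  xm <- matrix(col_x, nrow = size, ncol = size, byrow = TRUE)
  ym <- matrix(row_y, nrow = size, ncol = size)
  y0 <- ym
  up <- ym > 0
  if (squash == 0) {
    y0[up] <- Inf  # nothing above the equator survives full flattening
  } else {
    y0[up] <- ym[up] / squash
  }
  rho <- sqrt(xm^2 + y0^2)
  ang <- atan2(y0, xm)
  inside <- is.finite(y0) & rho <= R * (1 + rough(ang))
  # keep the flat top itself at full flattening (pixels on the equator row)
  mask <- matrix(as.integer(inside), size, size)
  list(mask = mask, contour = truth,
       spec = list(radius_px = R, cap_flattening = cap_flattening,
                   roughness_amp = roughness_amp,
                   roughness_freq = as.integer(roughness_freq),
                   image_size = size, seed = seed))
}

.draw_dist <- function(spec, n, name) {
  if (is.numeric(spec) && length(spec) == 1L) return(rep(spec, n))
  if (!is.list(spec) || is.null(spec$dist)) {
    .stop_invalid("`", name, "` must be a single number or ",
                  "list(dist = ..., ...)")
  }
  switch(spec$dist,
    constant = rep(spec$value, n),
    uniform = stats::runif(n, spec$min, spec$max),
    normal = stats::rnorm(n, spec$mean, spec$sd),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    .stop_invalid("unknown distribution '", spec$dist, "' in `", name, "`"))
}

#' Simulate a cohort of force curves with known ground truth
#'
#' Draws per-sample modulus, exponent and size from the given distribution
#' specs (a single number, or `list(dist = "uniform", min =, max =)`,
#' `list(dist = "normal", mean =, sd =)`,
#' `list(dist = "lognormal", meanlog =, sdlog =)`), then simulates one IE
#' curve per sample with `x = h = size`. Fully reproducible from the seed.
#'
#' @param n Number of samples (>= 1).
#' @param modulus,alpha,size Distribution specs for E (Pa), the exponent,
#'   and the sample width/height (um).
#' @param strain_fraction,n_points,noise_rel As in [simulate_curve()].
#' @param seed Master seed; per-curve seeds are derived from it.
#' @return A list with `curves` (list of [force_curve()]s) and `truth`
#'   (data.frame: `sample_id`, `E`, `alpha`, `width`, `height`).
#' @examples
#' co <- simulate_cohort(3, modulus = 1000,
#'                       alpha = list(dist = "uniform", min = 1, max = 1.5),
#'                       size = 200, noise_rel = 0.05, seed = 1)
#' co$truth
#' @export
simulate_cohort <- function(n, modulus, alpha = 1.25, size = 200,
                            strain_fraction = 0.10, n_points = 50L,
                            noise_rel = 0.05, seed = NULL) {
  .check_scalar(n, "n", positive = TRUE)
  n <- as.integer(n)
  draws <- .with_seed(seed, {
    list(E = .draw_dist(modulus, n, "modulus"),
         alpha = .draw_dist(alpha, n, "alpha"),
         size = .draw_dist(size, n, "size"),
         sub_seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  if (any(draws$E <= 0) || any(draws$size <= 0)) {
    .stop_invalid("modulus and size draws must be positive; ",
                  "check the distribution specs")
  }
  ids <- sprintf("sim%03d", seq_len(n))
  curves <- lapply(seq_len(n), function(i) {
    simulate_curve("ie", modulus = draws$E[i], alpha = draws$alpha[i],
                   geometry = sample_geometry(draws$size[i], draws$size[i]),
                   strain_fraction = strain_fraction, n_points = n_points,
                   noise_rel = noise_rel, seed = draws$sub_seeds[i],
                   sample_id = ids[i])
  })
  list(curves = curves,
       truth = data.frame(sample_id = ids, E = draws$E, alpha = draws$alpha,
                          width = draws$size, height = draws$size))
}
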