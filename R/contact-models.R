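#' Rest geometry of a compressed sample
#'
#' Bundles the width `x` and height `h` of a sample at rest, both in
#' micrometres. The width is taken to represent both the width and the length
#' of the sample; `width` here is the single lateral extent entering the
#' interpolating prefactor. For a sphere of radius `R`, `x = h = 2R`.
#'
#' @param width Lateral extent x of the sample at rest (um), > 0.
#' @param height Rest height h of the sample along the force axis (um), > 0.
#' @param reduce_width How to reduce a two-valued lateral extent
#'   (`width` of length 2, e.g. width and length measured separately) to the
#'   single x: `"none"` (default; a length-2 width is an error) or
#'   `"geometric_mean"`.
#' @return An object of class `sample_geometry` with fields `width`, `height`.
#' @examples
#' sample_geometry(200, 180)
#' sphere_geometry(100)   # x = h = 2R = 200 um
#' @export
sample_geometry <- function(width, height,
                            reduce_width = c("none", "geometric_mean")) {
  reduce_width <- match.arg(reduce_width)
  if (length(width) == 2L && reduce_width == "geometric_mean") {
    .check_numeric(width, "width")
    if (any(width <= 0)) .stop_invalid("`width` must be > 0")
    width <- sqrt(prod(width))
  }
  .check_scalar(width, "width", positive = TRUE)
  .check_scalar(height, "height", positive = TRUE)
  structure(list(width = width, height = height), class = "sample_geometry")
}

#' @rdname sample_geometry
#' @param radius Sphere radius R (um), > 0.
#' @export
sphere_geometry <- function(radius) {
  .check_scalar(radius, "radius", positive = TRUE)
  sample_geometry(2 * radius, 2 * radius)
}

#' @export
print.sample_geometry <- function(x, ...) {
  cat(sprintf("<sample_geometry> width x = %g um, height h = %g um\n",
              x$width, x$height))
  invisible(x)
}

.as_geometry <- function(geometry) {
  if (inherits(geometry, "sample_geometry")) return(geometry)
  if (is.numeric(geometry) && length(geometry) == 2L) {
    return(sample_geometry(geometry[[1L]], geometry[[2L]]))
  }
  .stop_invalid("`geometry` must be a sample_geometry object or a numeric ",
                "vector c(width, height)")
}

#' Interpolating contact prefactor C(alpha, x, h)
#'
#' The geometric prefactor of the integrated-elasticity force law
#' \eqn{F = E\,C(\alpha,x,h)\,\delta^\alpha}:
#' \deqn{C(\alpha,x,h) = 2\left[(1.5-\alpha)\left(\frac{\pi}{4}\right)^{3-2\alpha}
#'   + (\alpha-1)\left(\frac{4}{3\sqrt 2}\right)^{2\alpha-2}\right]
#'   \left(\frac{x^2}{h}\right)^{2-\alpha}}
#' It reduces exactly to the planar-contact prefactor \eqn{\pi x^2/4h} at
#' \eqn{\alpha = 1} and to the Hertz prefactor \eqn{\frac{4}{3}\sqrt{R}} at
#' \eqn{\alpha = 1.5} with \eqn{x = h = 2R}. The expression is evaluable for
#' any finite `alpha`, but only \eqn{[1, 1.5]} is the physically motivated
#' interpolation regime; fitting functions flag estimates at those bounds.
#'
#' @param alpha Power-law exponent (dimensionless); may be a vector.
#' @param width,height Sample rest width x and height h (um), > 0.
#' @return Prefactor in units of um^(2 - alpha).
#' @examples
#' ie_prefactor(1, 100, 100)          # pi * 100^2 / 400 = 78.5398
#' ie_prefactor(1.5, 200, 200)        # (4/3) * sqrt(100) = 13.3333
#' @export
ie_prefactor <- function(alpha, width, height) {
  .check_numeric(alpha, "alpha")
  .check_scalar(width, "width", positive = TRUE)
  .check_scalar(height, "height", positive = TRUE)
  shape <- (1.5 - alpha) * (pi / 4)^(3 - 2 * alpha) +
    (alpha - 1) * (4 / (3 * sqrt(2)))^(2 * alpha - 2)
  2 * shape * (width^2 / height)^(2 - alpha)
}

#' Contact-model force laws
#'
#' Forward evaluation of the three force-displacement laws used throughout
#' the package. `force_planar()` is the ideal planar parallel contact for a
#' cylindrical sample of diameter x, \eqn{F = (\pi x^2/4h) E \delta};
#' `force_hertz()` is the Hertz sphere-on-plane solution
#' \eqn{F = \frac{4}{3} E \sqrt{R}\, \delta^{1.5}}; `force_ie()` is the
#' integrated-elasticity law \eqn{F = E\,C(\alpha,x,h)\,\delta^\alpha}, which
#' reproduces the other two at its boundary exponents.
#'
#' @param E Effective elastic modulus (Pa), > 0.
#' @param geometry A [sample_geometry()] (or `c(width, height)` in um).
#' @param radius Sphere radius R (um), > 0 (Hertz only).
#' @param delta Displacement(s) of the plate into the sample (um), >= 0.
#' @param alpha Power-law exponent (IE only).
#' @return Force(s) in uN.
#' @examples
#' g <- sample_geometry(100, 100)
#' force_planar(1000, g, 10)                 # 0.7854 uN
#' force_hertz(1000, 100, 10)                # = force_ie at alpha = 1.5
#' force_ie(1000, 1.5, sphere_geometry(100), 10)
#' @export
force_planar <- function(E, geometry, delta) {
  g <- .as_geometry(geometry)
  .check_scalar(E, "E", positive = TRUE)
  .check_numeric(delta, "delta", nonneg = TRUE)
  .UN_PER_PA_UM2 * (pi * g$width^2 / (4 * g$height)) * E * delta
}

#' @rdname force_planar
#' @export
force_hertz <- function(E, radius, delta) {
  .check_scalar(E, "E", positive = TRUE)
  .check_scalar(radius, "radius", positive = TRUE)
  .check_numeric(delta, "delta", nonneg = TRUE)
  .UN_PER_PA_UM2 * (4 / 3) * E * sqrt(radius) * delta^1.5
}

#' @rdname force_planar
#' @export
force_ie <- function(E, alpha, geometry, delta) {
  g <- .as_geometry(geometry)
  .check_scalar(E, "E", positive = TRUE)
  .check_scalar(alpha, "alpha")
  .check_numeric(delta, "delta", nonneg = TRUE)
  .UN_PER_PA_UM2 * E * ie_prefactor(alpha, g$width, g$height) * delta^alpha
}

#' Convert between effective and Young's moduli
#'
#' The effective elastic constant E of the power-law fits relates to the
#' Young's modulus \eqn{\tilde E} through \eqn{1/E = (1 - \nu^2)/\tilde E},
#' i.e. \eqn{\tilde E = E (1 - \nu^2)}, with \eqn{\nu} the Poisson's ratio of
#' the sample (the indenting plate is taken as rigid). Fitted moduli are
#' reported as effective E; convert only when a Poisson's ratio is actually
#' known for the sample.
#'
#' @param E Effective modulus (Pa).
#' @param E_young Young's modulus (Pa).
#' @param poisson_ratio Poisson's ratio, in `[0, 1)` (physically `[0, 0.5]`).
#' @return A modulus in Pa.
#' @examples
#' young_modulus(1000, 0.5)        # 750
#' effective_modulus(750, 0.5)     # 1000
#' @export
young_modulus <- function(E, poisson_ratio) {
  .check_scalar(E, "E", positive = TRUE)
  .check_scalar(poisson_ratio, "poisson_ratio", nonneg = TRUE)
  if (poisson_ratio >= 1) .stop_invalid("`poisson_ratio` must be < 1")
  E * (1 - poisson_ratio^2)
}

#' @rdname young_modulus
#' @export
effective_modulus <- function(E_young, poisson_ratio) {
  .check_scalar(E_young, "E_young", positive = TRUE)
  .check_scalar(poisson_ratio, "poisson_ratio", nonneg = TRUE)
  if (poisson_ratio >= 1) .stop_invalid("`poisson_ratio` must be < 1")
  E_young / (1 - poisson_ratio^2)
}
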