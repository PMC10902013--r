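#' @rdname fit_ie
#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result:%s> E = %.6g Pa, alpha = %.4f, R^2 = %.6f, n = %d%s%s\n",
              x$model, x$E, x$alpha, x$r_squared, x$n,
              if (isTRUE(x$at_bound)) " [alpha at bound]" else "",
              if (!isTRUE(x$converged)) " [NOT CONVERGED]" else ""))
  if (nzchar(x$notes)) cat("  notes: ", x$notes, "\n", sep = "")
  invisible(x)
}

.fit_result <- function(model, E, alpha, observed, predicted, at_bound = FALSE,
                        converged = TRUE, notes = "") {
  rss <- sum((observed - predicted)^2)
  r2 <- if (stats::var(observed) > 0) {
    1 - rss / sum((observed - mean(observed))^2)
  } else NA_real_
  structure(
    list(model = model, E = E, alpha = alpha, r_squared = r2,
         residual_ss = rss, n = length(observed), at_bound = at_bound,
         converged = converged, notes = notes),
    class = "fit_result"
  )
}

# Shared preprocessing: duplicate-delta averaging, optional zero-delta drop.
.fit_data <- function(curve, drop_zero = TRUE, min_points = 3L) {
  stopifnot(inherits(curve, "force_curve"))
  cu <- .collapse_duplicates(curve)
  d <- cu$displacement
  f <- cu$force
  if (drop_zero) {
    keep <- d > 0
    d <- d[keep]
    f <- f[keep]
  }
  if (length(d) < min_points) {
    .stop_invalid("need at least ", min_points,
                  " points with positive displacement to fit")
  }
  list(delta = d, force = f)
}

# Given the regressor g(alpha) with F-hat = E * g, the least-squares E is
# linear-in-E: E = sum(F g) / sum(g g).
.profile_E <- function(force, g) sum(force * g) / sum(g * g)

#' Coefficient of determination on force
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean of the observed forces. Used uniformly for all models so
#' their precisions are comparable.
#'
#' @param observed,predicted Equal-length force vectors (length >= 2).
#' @return A single number, <= 1 (negative when the model does worse than
#'   the observed mean).
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))   # 0.5
#' @export
r_squared <- function(observed, predicted) {
  .check_numeric(observed, "observed")
  .check_numeric(predicted, "predicted")
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    .stop_invalid("`observed` and `predicted` must have equal length >= 2")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    .stop_invalid("R^2 is undefined: observed values are all identical")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Integrated-elasticity (IE) regression
#'
#' Fits \eqn{F = E\,C(\alpha, x, h)\,\delta^\alpha} to a force-displacement
#' curve with the exponent free within `alpha_bounds`. Because E enters
#' linearly once \eqn{\alpha} is fixed, E is profiled in closed form and the
#' search is a bounded scalar minimization of the residual sum of squares
#' over \eqn{\alpha} alone; the interval endpoints are always evaluated as
#' candidates so exact boundary solutions are returned exactly. A log-log
#' least-squares slope is recorded in the notes as a diagnostic starting
#' exponent.
#'
#' @param curve A [force_curve()] (already truncated/zeroed as desired).
#' @param geometry A [sample_geometry()]; defaults to the curve's own.
#' @param alpha_bounds Search interval for the exponent. The default
#'   `c(1, 1.5)` spans planar to spherical contact, the regime where the
#'   interpolating prefactor is physically motivated; widen deliberately.
#' @param objective `"force"` (default) minimizes squared force residuals;
#'   `"log_force"` minimizes squared log-force residuals (requires strictly
#'   positive forces).
#' @param alpha_tol Absolute tolerance on the fitted exponent.
#' @return A `fit_result` with fields `model`, `E` (Pa), `alpha`,
#'   `r_squared`, `residual_ss`, `n`, `at_bound`, `converged`, `notes`.
#'   Non-convergence is reported via `converged = FALSE`, not an error.
#' @examples
#' g <- sphere_geometry(100)
#' cu <- simulate_curve("hertz", modulus = 1000, geometry = g)
#' fit_ie(cu)   # recovers E = 1000 Pa, alpha = 1.5
#' @export
fit_ie <- function(curve, geometry = curve$geometry,
                   alpha_bounds = c(1, 1.5),
                   objective = c("force", "log_force"),
                   alpha_tol = 1e-8) {
  objective <- match.arg(objective)
  g <- .as_geometry(geometry)
  .check_numeric(alpha_bounds, "alpha_bounds")
  if (length(alpha_bounds) != 2L || diff(alpha_bounds) < 0) {
    .stop_invalid("`alpha_bounds` must be c(lower, upper)")
  }
  dat <- .fit_data(curve)
  d <- dat$delta
  f <- dat$force
  if (all(f <= 0)) .stop_invalid("all forces are non-positive; nothing to fit")
  if (objective == "log_force" && any(f <= 0)) {
    .stop_invalid("log-force objective requires strictly positive forces")
  }

  regressor <- function(a) {
    .UN_PER_PA_UM2 * ie_prefactor(a, g$width, g$height) * d^a
  }
  rss_at <- if (objective == "force") {
    function(a) {
      gg <- regressor(a)
      sum((f - .profile_E(f, gg) * gg)^2)
    }
  } else {
    function(a) {
      lg <- log(regressor(a))
      sum((log(f) - (mean(log(f) - lg) + lg))^2)
    }
  }
  E_at <- if (objective == "force") {
    function(a) .profile_E(f, regressor(a))
  } else {
    function(a) exp(mean(log(f) - log(regressor(a))))
  }

  # diagnostic log-log slope (clipped to bounds)
  pos <- f > 0
  alpha0 <- tryCatch(
    unname(stats::coef(stats::lm(log(f[pos]) ~ log(d[pos])))[2L]),
    error = function(e) NA_real_)
  alpha0_clipped <- min(max(alpha0, alpha_bounds[1L]), alpha_bounds[2L])

  converged <- TRUE
  notes <- sprintf("alpha0(loglog)=%.4f", alpha0)
  cand <- alpha_bounds
  if (diff(alpha_bounds) > 0) {
    opt <- tryCatch(
      stats::optimize(rss_at, interval = alpha_bounds, tol = alpha_tol),
      error = function(e) NULL)
    if (is.null(opt)) {
      converged <- FALSE
      notes <- paste0(notes, "; optimizer failed, reporting log-log start")
      cand <- c(cand, alpha0_clipped)
    } else {
      cand <- c(cand, opt$minimum)
    }
  }
  rss_cand <- vapply(cand, rss_at, numeric(1))
  alpha_hat <- cand[which.min(rss_cand)]
  E_hat <- E_at(alpha_hat)
  at_bound <- any(abs(alpha_hat - alpha_bounds) < 1e-6)

  pred <- E_hat * regressor(alpha_hat)
  .fit_result("ie", E_hat, alpha_hat, f, pred,
              at_bound = at_bound, converged = converged, notes = notes)
}

#' Baseline linear and Hertz fits
#'
#' `fit_linear_full()` fits the ideal planar-contact law
#' \eqn{F = (\pi x^2/4h) E \delta} to the whole curve by through-origin least
#' squares (an intercept can be allowed deliberately). `fit_two_point()` takes
#' the slope from just two points chosen at the onset of the force increase
#' (the first two consecutive points above `noise_floor`, or explicit
#' `indices`), converts it to E the same way, and reports \eqn{R^2} of that
#' line against the whole curve, exposing how strongly this common shortcut
#' depends on the chosen pair. `fit_hertz()` fits the spherical-contact law
#' \eqn{F = \frac{4}{3} E \sqrt{R}\,\delta^{1.5}} with the exponent held at 1.5.
#'
#' @inheritParams fit_ie
#' @param intercept Allow a free intercept in the full linear fit (default
#'   FALSE: the force law has none and the curve is zeroed at contact).
#' @param noise_floor Force level (uN) defining the onset of force increase
#'   for the two-point rule.
#' @param indices Optional explicit pair of point indices (after
#'   duplicate-displacement averaging) overriding the noise-floor rule.
#' @param radius Sphere radius R (um) for the Hertz fit.
#' @return A `fit_result`; `alpha` is fixed at 1 (linear) or 1.5 (Hertz).
#' @examples
#' g <- sample_geometry(200, 200)
#' cu <- simulate_curve("planar", modulus = 1000, geometry = g)
#' fit_linear_full(cu)    # E = 1000 Pa
#' @export
fit_linear_full <- function(curve, geometry = curve$geometry,
                            intercept = FALSE) {
  g <- .as_geometry(geometry)
  dat <- .fit_data(curve, drop_zero = FALSE)
  d <- dat$delta
  f <- dat$force
  if (all(d == 0)) .stop_invalid("all displacements are zero")
  if (intercept) {
    co <- stats::coef(stats::lm(f ~ d))
    slope <- unname(co[2L])
    pred <- co[1L] + slope * d
    notes <- sprintf("intercept=%.6g uN", co[1L])
  } else {
    slope <- sum(f * d) / sum(d * d)
    pred <- slope * d
    notes <- ""
  }
  E <- slope * 4 * g$height / (pi * g$width^2) / .UN_PER_PA_UM2
  .fit_result("linear_full", E, 1, f, pred, notes = notes)
}

#' @rdname fit_linear_full
#' @export
fit_two_point <- function(curve, geometry = curve$geometry, noise_floor = 0,
                          indices = NULL) {
  g <- .as_geometry(geometry)
  dat <- .fit_data(curve, drop_zero = FALSE, min_points = 2L)
  d <- dat$delta
  f <- dat$force
  if (is.null(indices)) {
    .check_scalar(noise_floor, "noise_floor", nonneg = TRUE)
    above <- f > noise_floor
    i <- which(above[-length(above)] & above[-1L])[1L]
    if (is.na(i)) {
      .stop_invalid("fewer than 2 consecutive points above the noise floor")
    }
    indices <- c(i, i + 1L)
  }
  if (length(indices) != 2L || any(indices < 1L) || any(indices > length(d))) {
    .stop_invalid("`indices` must be two valid point indices")
  }
  d2 <- d[indices]
  f2 <- f[indices]
  if (d2[1L] == d2[2L]) {
    .stop_invalid("degenerate pair: both points have the same displacement")
  }
  slope <- diff(f2) / diff(d2)
  E <- slope * 4 * g$height / (pi * g$width^2) / .UN_PER_PA_UM2
  pred <- slope * d  # through-origin line at the two-point slope
  .fit_result("linear_two_point", E, 1, f, pred,
              notes = sprintf("points=%d;%d", indices[1L], indices[2L]))
}

#' @rdname fit_linear_full
#' @export
fit_hertz <- function(curve, radius = NULL) {
  if (is.null(radius)) {
    if (is.null(curve$geometry)) .stop_invalid("`radius` is required")
    radius <- curve$geometry$height / 2
  }
  .check_scalar(radius, "radius", positive = TRUE)
  dat <- .fit_data(curve)
  gg <- .UN_PER_PA_UM2 * (4 / 3) * sqrt(radius) * dat$delta^1.5
  E <- .profile_E(dat$force, gg)
  .fit_result("hertz", E, 1.5, dat$force, E * gg)
}
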