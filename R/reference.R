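#' Reference-cube geometry and fit
#'
#' Reference measurements use a polyacrylamide gel cube of edge L. For the
#' IE regression the cube is assigned the effective diameter of the sphere
#' of equal volume, \eqn{d = L (6/\pi)^{1/3}}, used as both x and h; the
#' linear reference fit uses the cube-specific law \eqn{F = L E \delta}.
#'
#' @param edge_L Cube edge length L (um), > 0.
#' @return `cube_effective_diameter()`: the equal-volume sphere diameter (um).
#' @examples
#' cube_effective_diameter(100)   # 124.07
#' @export
cube_effective_diameter <- function(edge_L) {
  .check_scalar(edge_L, "edge_L", positive = TRUE)
  edge_L * (6 / pi)^(1 / 3)
}

#' @rdname cube_effective_diameter
#' @param curve A [force_curve()] measured on the cube.
#' @return `fit_cube_linear()`: a `fit_result` with `model = "cube_linear"`,
#'   E from the through-origin slope s as \eqn{E = s/L}.
#' @export
fit_cube_linear <- function(curve, edge_L) {
  .check_scalar(edge_L, "edge_L", positive = TRUE)
  dat <- .fit_data(curve, drop_zero = FALSE)
  d <- dat$delta
  f <- dat$force
  if (all(d == 0)) .stop_invalid("all displacements are zero")
  slope <- sum(f * d) / sum(d * d)
  E <- slope / edge_L / .UN_PER_PA_UM2
  .fit_result("cube_linear", E, 1, f, slope * d)
}

.model_family <- function(model) {
  switch(model,
         ie = "ie",
         hertz = "hertz",
         linear_full = "linear",
         linear_two_point = "linear",
         cube_linear = "linear",
         .stop_invalid("unknown model name: ", model))
}

#' Relative modulus against a reference sample
#'
#' The ratio \eqn{E/E^{ref}} between a sample's fitted modulus and that of a
#' reference sample, valid only when both were analyzed with the same model
#' family (IE with IE, linear with linear): relative moduli are comparable
#' across experiments in a way absolute ones are not.
#'
#' @param sample_fit,ref_fit `fit_result` objects from the same model family.
#' @return A one-row data.frame: `sample_id` slot free for the caller,
#'   `model`, `ref_model`, `e_sample`, `e_ref` (Pa) and `ratio`.
#' @export
relative_modulus <- function(sample_fit, ref_fit) {
  stopifnot(inherits(sample_fit, "fit_result"), inherits(ref_fit, "fit_result"))
  fam_s <- .model_family(sample_fit$model)
  fam_r <- .model_family(ref_fit$model)
  if (fam_s != fam_r) {
    .stop_invalid("cross-model ratio rejected: sample family '", fam_s,
                  "' vs reference family '", fam_r,
                  "'; both must be analyzed with the same model")
  }
  if (sample_fit$E <= 0 || ref_fit$E <= 0) {
    .stop_invalid("relative modulus requires positive fitted E on both sides")
  }
  data.frame(model = sample_fit$model, ref_model = ref_fit$model,
             family = fam_s, e_sample = sample_fit$E, e_ref = ref_fit$E,
             ratio = sample_fit$E / ref_fit$E)
}

#' Cohort modulus ratio with bootstrap interval
#'
#' Ratio of the mean fitted moduli of two sample groups (for example two
#' spheroid cell types analyzed with the same regression), with a seeded
#' nonparametric bootstrap percentile confidence interval.
#'
#' @param group_a,group_b Numeric vectors of fitted moduli, or lists of
#'   `fit_result` objects.
#' @param n_boot Number of bootstrap resamples (default 1999).
#' @param seed RNG seed for the bootstrap (the caller's RNG stream is left
#'   untouched).
#' @param conf Confidence level (default 0.95).
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"` (mean of
#'   all cross pairs a_i / b_j).
#' @return A list with `ratio`, `conf_low`, `conf_high`, `n_a`, `n_b`,
#'   `n_boot`, `method`.
#' @examples
#' cohort_ratio(c(1000, 1100, 900), c(100, 110, 90), n_boot = 199, seed = 1)
#' @export
cohort_ratio <- function(group_a, group_b, n_boot = 1999L, seed = NULL,
                         conf = 0.95, method = c("ratio_of_means",
                                                 "mean_of_ratios")) {
  method <- match.arg(method)
  extract <- function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    vapply(g, function(f) {
      stopifnot(inherits(f, "fit_result"))
      f$E
    }, numeric(1))
  }
  a <- extract(group_a)
  b <- extract(group_b)
  .check_numeric(a, "group_a")
  .check_numeric(b, "group_b")
  .check_scalar(n_boot, "n_boot", positive = TRUE)
  point_of <- function(a, b) {
    mb <- mean(b)
    if (mb == 0) .stop_invalid("undefined ratio: denominator group mean is 0")
    if (method == "ratio_of_means") mean(a) / mb
    else mean(outer(a, b, "/"))
  }
  point <- point_of(a, b)
  boot <- .with_seed(seed, {
    vapply(seq_len(as.integer(n_boot)), function(i) {
      point_of(a[sample.int(length(a), replace = TRUE)],
               b[sample.int(length(b), replace = TRUE)])
    }, numeric(1))
  })
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(ratio = point, conf_low = qs[1L], conf_high = qs[2L],
       n_a = length(a), n_b = length(b), n_boot = as.integer(n_boot),
       method = method)
}
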