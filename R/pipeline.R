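#' Analysis run configuration
#'
#' Bundles the options of the standard analysis pipeline. Defaults follow
#' the measurement protocol the models assume: curves truncated to 10\%
#' strain, the IE exponent searched on `[1, 1.5]`, through-origin linear
#' fits, no contact-offset detection (instrument exports are pre-zeroed).
#'
#' @param strain_fraction Strain truncation limit (default 0.10).
#' @param alpha_bounds IE exponent search interval (default `c(1, 1.5)`).
#' @param linear_intercept Allow an intercept in the full linear fit
#'   (default FALSE).
#' @param noise_floor Force noise floor in uN (two-point rule and optional
#'   contact detection; default 0).
#' @param detect_contact Run [detect_contact_offset()] before fitting
#'   (default FALSE).
#' @param geometry_fraction Upper contour fraction for geometry metrics
#'   (default 0.10).
#' @param seed Seed recorded with results and used for any resampling.
#' @return An object of class `run_config`; its FNV-1a hash is stamped on
#'   every results table for traceability.
#' @export
run_config <- function(strain_fraction = 0.10, alpha_bounds = c(1, 1.5),
                       linear_intercept = FALSE, noise_floor = 0,
                       detect_contact = FALSE, geometry_fraction = 0.10,
                       seed = NULL) {
  cfg <- list(strain_fraction = strain_fraction, alpha_bounds = alpha_bounds,
              linear_intercept = linear_intercept, noise_floor = noise_floor,
              detect_contact = detect_contact,
              geometry_fraction = geometry_fraction, seed = seed)
  cfg$hash <- .fnv1a_hash(cfg)
  structure(cfg, class = "run_config")
}

.fit_row <- function(fit, sample_id, hash) {
  data.frame(sample_id = sample_id, model = fit$model, E = fit$E,
             alpha = fit$alpha, r_squared = fit$r_squared,
             residual_ss = fit$residual_ss, n = fit$n,
             at_bound = fit$at_bound, converged = fit$converged,
             notes = fit$notes, config = hash)
}

#' Fit a set of curves with the standard model battery
#'
#' For each curve: strain truncation, optional contact-offset removal, then
#' the IE, full-range linear and two-point linear fits. One row per sample
#' per model. Per-sample failures are collected, not fatal.
#'
#' @param curves A [force_curve()] or list of them; each needs a geometry
#'   (attached or via `geometry`).
#' @param config A [run_config()].
#' @param geometry Optional single [sample_geometry()] applied to curves
#'   lacking one.
#' @return A data.frame with columns `sample_id`, `model`, `E` (Pa),
#'   `alpha`, `r_squared`, `residual_ss`, `n`, `at_bound`, `converged`,
#'   `notes`, `config`. Failed samples are reported in
#'   `attr(result, "failures")` (named character vector of messages).
#' @examples
#' co <- simulate_cohort(2, modulus = 1000, alpha = 1.3, seed = 1)
#' analyze_curves(co$curves)
#' @export
analyze_curves <- function(curves, config = run_config(), geometry = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(curves, "force_curve")) curves <- list(curves)
  if (length(curves) == 0L) .stop_invalid("no input curves")
  rows <- list()
  failures <- character()
  for (i in seq_along(curves)) {
    cu <- curves[[i]]
    id <- if (!is.na(cu$sample_id)) cu$sample_id else sprintf("curve%03d", i)
    res <- tryCatch({
      if (is.null(cu$geometry)) {
        if (is.null(geometry)) .stop_invalid("curve has no geometry")
        cu$geometry <- .as_geometry(geometry)
      }
      cu <- truncate_to_strain(cu, fraction = config$strain_fraction)
      if (config$detect_contact) {
        cu <- apply_contact_offset(
          cu, detect_contact_offset(cu, config$noise_floor))
      }
      fits <- list(
        fit_ie(cu, alpha_bounds = config$alpha_bounds),
        fit_linear_full(cu, intercept = config$linear_intercept),
        fit_two_point(cu, noise_floor = config$noise_floor))
      do.call(rbind, lapply(fits, .fit_row, sample_id = id,
                            hash = config$hash))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures[id] <- res else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    .stop_invalid("all samples failed: ",
                  paste(names(failures), failures, sep = ": ",
                        collapse = "; "))
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Geometry metrics for a set of silhouettes
#'
#' Per silhouette: raw upper-contour non-planarity \eqn{\chi} (1/px or
#' 1/length), the circle-normalized non-planarity, and the smoothness
#' \eqn{l/d} of the upper contour fraction.
#'
#' @param shapes A list of mask matrices and/or [contour_profile()]s (a
#'   single one is accepted too).
#' @param config A [run_config()] (uses `geometry_fraction`).
#' @param ids Optional names for the rows; defaults to list names or
#'   `shape001`, ...
#' @return A data.frame with `sample_id`, `chi`, `chi_normalized`,
#'   `smoothness`, `fraction`, `n_points`, `config`; failures in
#'   `attr(result, "failures")`.
#' @export
geometry_metrics <- function(shapes, config = run_config(), ids = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.matrix(shapes) || inherits(shapes, "contour_profile")) {
    shapes <- list(shapes)
  }
  if (length(shapes) == 0L) .stop_invalid("no input shapes")
  if (is.null(ids)) {
    ids <- if (!is.null(names(shapes)) && all(nzchar(names(shapes)))) {
      names(shapes)
    } else sprintf("shape%03d", seq_along(shapes))
  }
  frac <- config$geometry_fraction
  rows <- list()
  failures <- character()
  for (i in seq_along(shapes)) {
    res <- tryCatch({
      contour <- if (is.matrix(shapes[[i]])) extract_contour(shapes[[i]])
                 else shapes[[i]]
      stopifnot(inherits(contour, "contour_profile"))
      shifted <- contour_profile(contour$x, contour$y - min(contour$y),
                                 pixel_size = contour$pixel_size)
      upper <- upper_fraction(shifted, frac)
      data.frame(sample_id = ids[i],
                 chi = non_planarity(upper, height = shifted$height),
                 chi_normalized = normalized_non_planarity(contour, frac),
                 smoothness = contour_smoothness(upper),
                 fraction = frac, n_points = length(upper$x),
                 config = config$hash)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures[ids[i]] <- res
    else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) {
    .stop_invalid("all shapes failed: ",
                  paste(names(failures), failures, sep = ": ",
                        collapse = "; "))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Relative moduli of samples against a reference
#'
#' Joins a sample results table (from [analyze_curves()]) with a reference
#' results table by model family (IE with IE, linear with linear) and
#' reports \eqn{E/E^{ref}} per sample per family. When the reference table
#' holds several fits of one family their mean E is used.
#'
#' @param sample_results,reference_results Data.frames with at least
#'   `sample_id`, `model`, `E` columns (as produced by [analyze_curves()];
#'   for a cube reference, a row with `model = "cube_linear"` from
#'   [fit_cube_linear()] works).
#' @param config A [run_config()].
#' @return A data.frame `sample_id`, `family`, `model`, `E`, `E_ref`,
#'   `ratio`, `config`.
#' @export
compare_moduli <- function(sample_results, reference_results,
                           config = run_config()) {
  stopifnot(is.data.frame(sample_results), is.data.frame(reference_results))
  fam_s <- vapply(sample_results$model, .model_family, character(1))
  fam_r <- vapply(reference_results$model, .model_family, character(1))
  shared <- intersect(unique(fam_s), unique(fam_r))
  if (length(shared) == 0L) {
    .stop_invalid("no shared model family between samples and reference")
  }
  rows <- lapply(shared, function(fam) {
    e_ref <- mean(reference_results$E[fam_r == fam])
    if (e_ref <= 0) .stop_invalid("non-positive reference modulus for ",
                                  "family '", fam, "'")
    sub <- sample_results[fam_s == fam, , drop = FALSE]
    data.frame(sample_id = sub$sample_id, family = fam, model = sub$model,
               E = sub$E, E_ref = e_ref, ratio = sub$E / e_ref,
               config = config$hash)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
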