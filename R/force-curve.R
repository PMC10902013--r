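#' Force-displacement curve
#'
#' Container for one compression (approach) curve: paired displacement and
#' force arrays in instrument units (um, uN), optionally with the sample's
#' rest geometry attached. Points are stored sorted by displacement.
#'
#' @param displacement Plate displacement into the sample (um), >= 0.
#' @param force Measured force (uN), same length as `displacement`.
#' @param sample_id Optional sample identifier.
#' @param geometry Optional [sample_geometry()].
#' @param strain_limit Optional fraction of the rest height the curve has
#'   been truncated to (set by [truncate_to_strain()]).
#' @return An object of class `force_curve` with fields `displacement`,
#'   `force`, `sample_id`, `geometry`, `strain_limit`.
#' @seealso [truncate_to_strain()], [detect_contact_offset()], [fit_ie()]
#' @export
force_curve <- function(displacement, force, sample_id = NA_character_,
                        geometry = NULL, strain_limit = NULL) {
  .check_numeric(displacement, "displacement", nonneg = TRUE)
  .check_numeric(force, "force")
  if (length(displacement) != length(force)) {
    .stop_invalid("`displacement` and `force` must have equal length")
  }
  if (length(displacement) < 2L) {
    .stop_invalid("a force curve needs at least 2 points")
  }
  if (!is.null(geometry)) geometry <- .as_geometry(geometry)
  ord <- order(displacement)
  structure(
    list(displacement = displacement[ord], force = force[ord],
         sample_id = as.character(sample_id)[1L], geometry = geometry,
         strain_limit = strain_limit),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %s: %d points, delta in [%.4g, %.4g] um, F in [%.4g, %.4g] uN\n",
              if (is.na(x$sample_id)) "(unnamed)" else x$sample_id,
              length(x$displacement), min(x$displacement),
              max(x$displacement), min(x$force), max(x$force)))
  if (!is.null(x$geometry)) print(x$geometry)
  invisible(x)
}

#' @export
length.force_curve <- function(x) length(x$displacement)

#' @export
as.data.frame.force_curve <- function(x, ...) {
  data.frame(displacement = x$displacement, force = x$force)
}

# Instrument step-hold phases repeat displacements; average their forces so
# every delta is unique before least squares.
.collapse_duplicates <- function(curve) {
  d <- curve$displacement
  if (!anyDuplicated(d)) return(curve)
  du <- unique(d)  # d is sorted, so du is too
  f <- as.numeric(tapply(curve$force, match(d, du), mean))
  curve$displacement <- du
  curve$force <- f
  curve
}

#' Truncate a curve to a strain limit
#'
#' Keeps the points with \eqn{\delta \le} `fraction` times the rest height.
#' Analysing only the first ~10\% of squeezing keeps the sample in its
#' elastic regime (it recovers its shape on release) and justifies the
#' small-deformation contact models.
#'
#' @param curve A [force_curve()].
#' @param rest_height Rest height h (um); defaults to the height of the
#'   curve's attached geometry.
#' @param fraction Strain fraction limit in (0, 1]; default 0.10.
#' @return The truncated `force_curve` (metadata preserved, `strain_limit`
#'   set). Fewer than 3 surviving points is an error.
#' @examples
#' g <- sample_geometry(200, 200)
#' cu <- simulate_curve("planar", modulus = 1000, geometry = g,
#'                      strain_fraction = 0.3, n_points = 31)
#' length(truncate_to_strain(cu, fraction = 0.1))
#' @export
truncate_to_strain <- function(curve, rest_height = NULL, fraction = 0.10) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(rest_height)) {
    if (is.null(curve$geometry)) {
      .stop_invalid("`rest_height` is required when the curve has no geometry")
    }
    rest_height <- curve$geometry$height
  }
  .check_scalar(rest_height, "rest_height", positive = TRUE)
  .check_scalar(fraction, "fraction", positive = TRUE)
  if (fraction > 1) .stop_invalid("`fraction` must be in (0, 1]")
  keep <- curve$displacement <= fraction * rest_height
  if (sum(keep) < 3L) {
    .stop_invalid("fewer than 3 points survive truncation to ",
                  fraction * 100, "% strain")
  }
  curve$displacement <- curve$displacement[keep]
  curve$force <- curve$force[keep]
  curve$strain_limit <- fraction
  curve
}

#' Detect the contact point of a raw curve
#'
#' Locates the first sustained exceedance of a force noise floor and returns
#' the displacement/force offsets that re-zero the curve at contact. Exported
#' instrument data is usually pre-zeroed; this handles raw exports with a
#' pre-contact baseline.
#'
#' @param curve A [force_curve()].
#' @param noise_floor Force level (uN) below which readings are baseline
#'   noise, >= 0.
#' @param min_run Number of consecutive points that must exceed the floor for
#'   the exceedance to count as sustained (default 3; truncated at the end of
#'   the curve).
#' @return A list with `delta_offset` (um), `force_offset` (uN) and
#'   `contact_index`. Both offsets are 0 when the curve already starts above
#'   the floor. No point exceeding the floor is an error.
#' @seealso [apply_contact_offset()]
#' @export
detect_contact_offset <- function(curve, noise_floor, min_run = 3L) {
  stopifnot(inherits(curve, "force_curve"))
  .check_scalar(noise_floor, "noise_floor", nonneg = TRUE)
  f <- curve$force
  n <- length(f)
  above <- f > noise_floor
  idx <- NA_integer_
  for (i in which(above)) {
    run <- i:min(i + min_run - 1L, n)
    if (all(above[run])) { idx <- i; break }
  }
  if (is.na(idx)) .stop_invalid("no sustained exceedance of the noise floor: ",
                                "curve never makes contact")
  if (idx == 1L) {
    return(list(delta_offset = 0, force_offset = 0, contact_index = 1L))
  }
  list(delta_offset = curve$displacement[idx - 1L],
       force_offset = mean(f[seq_len(idx - 1L)]),
       contact_index = idx)
}

#' @rdname detect_contact_offset
#' @param offsets The list returned by `detect_contact_offset()`.
#' @return `apply_contact_offset()` returns the shifted curve: pre-contact
#'   points dropped, `delta_offset`/`force_offset` subtracted.
#' @export
apply_contact_offset <- function(curve, offsets) {
  stopifnot(inherits(curve, "force_curve"))
  keep <- seq(offsets$contact_index, length(curve$displacement))
  force_curve(curve$displacement[keep] - offsets$delta_offset,
              curve$force[keep] - offsets$force_offset,
              sample_id = curve$sample_id, geometry = curve$geometry,
              strain_limit = curve$strain_limit)
}
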