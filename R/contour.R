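#' Ordered sample silhouette contour
#'
#' Ordered boundary points of a sample silhouette, in physical orientation:
#' the y axis is parallel to the force direction and increases toward the
#' indenter. Coordinates may be pixels or physical lengths.
#'
#' @param x,y Coordinates of the ordered boundary points (equal length >= 2).
#' @param pixel_size Physical length per pixel, if the coordinates are pixels.
#' @param height Full sample height h along y; defaults to `max(y) - min(y)`.
#'   Upper-contour segments carry the height of their parent contour.
#' @return An object of class `contour_profile` with fields `x`, `y`,
#'   `pixel_size`, `height`.
#' @export
contour_profile <- function(x, y, pixel_size = NULL, height = NULL) {
  .check_numeric(x, "x")
  .check_numeric(y, "y")
  if (length(x) != length(y) || length(x) < 2L) {
    .stop_invalid("`x` and `y` must have equal length >= 2")
  }
  if (is.null(height)) height <- max(y) - min(y)
  if (!is.null(pixel_size)) .check_scalar(pixel_size, "pixel_size", positive = TRUE)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 pixel_size = pixel_size, height = height),
            class = "contour_profile")
}

#' @export
print.contour_profile <- function(x, ...) {
  cat(sprintf("<contour_profile> %d points, x in [%.4g, %.4g], y in [%.4g, %.4g], height = %.4g\n",
              length(x$x), min(x$x), max(x$x), min(x$y), max(x$y), x$height))
  invisible(x)
}

#' Extract the outer contour of a binary mask
#'
#' Traces the iso-level 0.5 boundary of a single-component binary mask
#' (marching squares, sub-pixel resolution) and converts it to the physical
#' y-up orientation: image row 1 is the top of the image and is flipped so
#' that y increases toward the indenter.
#'
#' @param mask A numeric or logical matrix in image orientation (rows from
#'   the top); nonzero/`TRUE` marks the sample. Must contain exactly one
#'   foreground component of at least 9 pixels and no holes.
#' @param pixel_size Physical length per pixel (default 1: coordinates stay
#'   in pixels).
#' @return A [contour_profile()] of the closed outer boundary.
#' @examples
#' m <- simulate_mask(radius_px = 40)$mask
#' extract_contour(m)
#' @export
extract_contour <- function(mask, pixel_size = 1) {
  if (is.logical(mask)) mask <- mask + 0
  if (!is.matrix(mask) || !is.numeric(mask)) {
    .stop_invalid("`mask` must be a numeric or logical matrix")
  }
  .check_scalar(pixel_size, "pixel_size", positive = TRUE)
  fg <- mask != 0
  if (sum(fg) < 9L) {
    .stop_invalid("mask must contain a foreground component of >= 9 pixels")
  }
  nr <- nrow(fg)
  nc <- ncol(fg)
  # pad with background so boundary components touching the frame still close
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2L:(nr + 1L), 2L:(nc + 1L)] <- fg
  # contourLines wants z[x, y]: x = image column (left-right), y flipped row (up)
  z <- t(padded)[, (nr + 2L):1L]
  cl <- grDevices::contourLines(x = seq_len(nc + 2L) - 2L,
                                y = seq_len(nr + 2L) - 2L,
                                z = z, levels = 0.5)
  if (length(cl) == 0L) .stop_invalid("no contour found in mask")
  if (length(cl) > 1L) {
    .stop_invalid("mask has ", length(cl),
                  " level-0.5 contours: multiple components or holes")
  }
  cx <- cl[[1L]]$x
  cy <- cl[[1L]]$y
  np <- length(cx)
  # drop a repeated closing point so no boundary point is counted twice
  if (np > 2L && cx[1L] == cx[np] && cy[1L] == cy[np]) {
    cx <- cx[-np]
    cy <- cy[-np]
  }
  contour_profile(cx * pixel_size, cy * pixel_size, pixel_size = pixel_size)
}

#' Upper fraction of a contour
#'
#' Returns the connected contour segment whose points satisfy
#' \eqn{y \ge y_{max} - f h}, where h is the full contour height — the part
#' of the silhouette that faces the indenting plate. For a closed contour
#' the maximal cyclic run containing the topmost point is taken.
#'
#' @param contour A [contour_profile()].
#' @param fraction Analyzed upper height fraction, in (0, 1]; default 0.10.
#' @return A `contour_profile` holding the segment, carrying the parent's
#'   `height`. Fewer than 3 segment points is an error.
#' @export
upper_fraction <- function(contour, fraction = 0.10) {
  stopifnot(inherits(contour, "contour_profile"))
  .check_scalar(fraction, "fraction", positive = TRUE)
  if (fraction > 1) .stop_invalid("`fraction` must be in (0, 1]")
  y <- contour$y
  n <- length(y)
  thr <- max(y) - fraction * contour$height
  above <- y >= thr
  if (all(above)) {
    sel <- seq_len(n)
  } else {
    # maximal cyclic run of `above` containing the topmost point
    top <- which.max(y)
    lo <- top
    steps <- 0L
    repeat {
      prev <- if (lo == 1L) n else lo - 1L
      if (!above[prev] || steps >= n - 1L) break
      lo <- prev
      steps <- steps + 1L
    }
    hi <- top
    steps <- 0L
    repeat {
      nxt <- if (hi == n) 1L else hi + 1L
      if (!above[nxt] || nxt == lo || steps >= n - 1L) break
      hi <- nxt
      steps <- steps + 1L
    }
    sel <- if (lo <= hi) lo:hi else c(lo:n, 1L:hi)
  }
  if (length(sel) < 3L) {
    .stop_invalid("fewer than 3 contour points in the upper ",
                  fraction * 100, "% segment")
  }
  contour_profile(contour$x[sel], contour$y[sel],
                  pixel_size = contour$pixel_size, height = contour$height)
}

#' Deviation from macroscopic planarity
#'
#' The non-planarity of an upper-contour segment,
#' \deqn{\chi = \sqrt{\tfrac{1}{N}\sum_i (y_i - \langle y\rangle)^2} \,/\, (h \langle y\rangle),}
#' the root-mean-square of the boundary-point y coordinates divided by the
#' sample height times the mean y. \eqn{\chi} carries units of 1/length and
#' is frame-dependent through \eqn{\langle y\rangle}; coordinates must be in
#' a frame with the origin at the sample's lowest point (y increasing toward
#' the indenter), so \eqn{\langle y\rangle \approx h} for the upper cap.
#' Compare samples through [normalized_non_planarity()], which handles the
#' frame and divides by the same quantity for an ideal circle.
#'
#' @param upper A [contour_profile()] segment (from [upper_fraction()]),
#'   with y measured from the sample base.
#' @param height Full sample height h; defaults to the segment's carried
#'   parent height.
#' @return \eqn{\chi}, in 1/length units of the coordinates. Exactly 0 for a
#'   perfectly flat segment.
#' @export
non_planarity <- function(upper, height = NULL) {
  stopifnot(inherits(upper, "contour_profile"))
  if (is.null(height)) height <- upper$height
  .check_scalar(height, "height", positive = TRUE)
  y <- upper$y
  my <- mean(y)
  if (my <= 0) {
    .stop_invalid("chi is undefined: mean y must be > 0 ",
                  "(use base-origin coordinates)")
  }
  sqrt(mean((y - my)^2)) / (height * my)
}

#' Circle reference for the non-planarity ratio
#'
#' \eqn{\chi} of the upper-fraction arc of an ideal circle whose diameter
#' equals the sample height, sampled uniformly in arc length at the same
#' point count as the measured segment and placed in the same base-origin
#' frame. This is the denominator of the normalized non-planarity.
#'
#' @param height Circle diameter = sample height h (any length unit).
#' @param fraction Upper height fraction (default 0.10).
#' @param n_points Number of sample points along the arc (>= 3).
#' @return \eqn{\chi_{circle}} in 1/length units of `height`.
#' @export
chi_circle_reference <- function(height, fraction = 0.10, n_points = 256L) {
  .check_scalar(height, "height", positive = TRUE)
  .check_scalar(fraction, "fraction", positive = TRUE)
  if (fraction > 1) .stop_invalid("`fraction` must be in (0, 1]")
  .check_scalar(n_points, "n_points", positive = TRUE)
  if (n_points < 3) .stop_invalid("`n_points` must be >= 3")
  r <- height / 2
  # polar angle of the cut y = r (1 - 2 fraction); fraction 1 -> full circle
  s <- 1 - 2 * fraction
  theta0 <- if (s <= -1) -pi / 2 else asin(s)
  theta <- seq(theta0, pi - theta0, length.out = as.integer(n_points))
  y <- r * sin(theta) + r  # base-origin frame
  my <- mean(y)
  sqrt(mean((y - my)^2)) / (height * my)
}

# Resample an open polyline to n points uniformly spaced in arc length.
# Removes the grid-direction density bias of marching-squares boundaries so
# point-array statistics weight the curve by length, not by pixel crossings.
.resample_arclength <- function(x, y, n) {
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  t <- c(0, cumsum(seg))
  total <- t[length(t)]
  if (total == 0) .stop_invalid("degenerate contour: zero arc length")
  keep <- c(TRUE, seg > 0)  # approx() needs strictly increasing abscissae
  ti <- seq(0, total, length.out = n)
  list(x = stats::approx(t[keep], x[keep], xout = ti)$y,
       y = stats::approx(t[keep], y[keep], xout = ti)$y)
}

#' Normalized non-planarity of a silhouette
#'
#' The ratio \eqn{\chi_{sample}/\chi_{circle}}: the sample's upper-contour
#' non-planarity relative to an ideal circle of the same height, sampled at
#' the same density. 1 for a circular cap, 0 for a perfectly flat top,
#' > 1 for caps more strongly curved than the matched circle.
#'
#' @param contour A full [contour_profile()] (any y frame; it is shifted to
#'   base-origin internally).
#' @param fraction Analyzed upper height fraction (default 0.10).
#' @param reference `"height"` (default) matches the reference-circle
#'   diameter to the sample height; `"width"` matches it to the sample width.
#' @details The measured upper segment is resampled to uniform arc-length
#' spacing (same point count) before \eqn{\chi} is taken, and the circle
#' reference is sampled uniformly along its arc at the same count, so both
#' sides of the ratio weight their curves by length rather than by how often
#' a boundary crosses the pixel grid.
#' @return Dimensionless ratio.
#' @examples
#' m <- simulate_mask(radius_px = 100)
#' normalized_non_planarity(extract_contour(m$mask))   # ~ 1 for a circle
#' @export
normalized_non_planarity <- function(contour, fraction = 0.10,
                                     reference = c("height", "width")) {
  stopifnot(inherits(contour, "contour_profile"))
  reference <- match.arg(reference)
  shifted <- contour_profile(contour$x, contour$y - min(contour$y),
                             pixel_size = contour$pixel_size)
  upper <- upper_fraction(shifted, fraction)
  n <- length(upper$x)
  rs <- .resample_arclength(upper$x, upper$y, n)
  chi_s <- non_planarity(contour_profile(rs$x, rs$y,
                                         height = shifted$height),
                         height = shifted$height)
  ref_diam <- switch(reference,
                     height = shifted$height,
                     width = max(shifted$x) - min(shifted$x))
  chi_c <- chi_circle_reference(ref_diam, fraction, n_points = n)
  chi_s / chi_c
}

#' Smoothness of an upper contour segment
#'
#' The chord-to-arc ratio \eqn{l/d}: \eqn{l} is the end-to-end extent of the
#' segment along x and \eqn{d} its polyline arc length. 1 for a straight
#' horizontal segment; smaller for curved or rough contours (the upper 10\%
#' arc of an ideal circle gives 0.9324). To suppress pixel-staircase bias in
#' the arc length, the polyline is lightly smoothed with a centered moving
#' average before measuring \eqn{d}; set `smooth_window = 1` for raw mode.
#'
#' @param upper A [contour_profile()] segment (>= 2 points).
#' @param smooth_window Odd moving-average window (default 3; 1 = raw).
#' @return Dimensionless \eqn{l/d} in (0, 1] for simple contours.
#' @export
contour_smoothness <- function(upper, smooth_window = 3L) {
  stopifnot(inherits(upper, "contour_profile"))
  .check_scalar(smooth_window, "smooth_window", positive = TRUE)
  x <- upper$x
  y <- upper$y
  if (smooth_window > 1 && length(x) > smooth_window) {
    w <- as.integer(smooth_window)
    if (w %% 2L == 0L) .stop_invalid("`smooth_window` must be odd")
    ker <- rep(1 / w, w)
    xs <- as.numeric(stats::filter(x, ker, sides = 2))
    ys <- as.numeric(stats::filter(y, ker, sides = 2))
    # keep the raw endpoints where the centered window is undefined
    na <- is.na(xs)
    xs[na] <- x[na]
    ys[na] <- y[na]
    x <- xs
    y <- ys
  }
  l <- abs(x[length(x)] - x[1L])
  d <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (d == 0) .stop_invalid("degenerate contour: zero arc length")
  l / d
}
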