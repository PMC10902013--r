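#' Column mapping for delimited force-table exports
#'
#' Describes how to pull a force curve out of an instrument export:
#' which columns hold displacement and force (by name or position) and what
#' units they are in. Everything is converted to the package's internal
#' um/uN system on read.
#'
#' @param displacement,force Column name or 1-based index.
#' @param time Optional time column (name or index); carried through but not
#'   used by the fits.
#' @param displacement_unit One of `"um"`, `"mm"`, `"m"`.
#' @param force_unit One of `"uN"`, `"mN"`, `"N"`.
#' @return An object of class `column_map`.
#' @export
column_map <- function(displacement = "displacement", force = "force",
                       time = NULL,
                       displacement_unit = c("um", "mm", "m"),
                       force_unit = c("uN", "mN", "N")) {
  displacement_unit <- match.arg(displacement_unit)
  force_unit <- match.arg(force_unit)
  if (identical(displacement, force)) {
    .stop_invalid("displacement and force columns must be distinct")
  }
  structure(list(displacement = displacement, force = force, time = time,
                 displacement_unit = displacement_unit,
                 force_unit = force_unit),
            class = "column_map")
}

.length_factor <- c(um = 1, mm = 1e3, m = 1e6)
.force_factor <- c(uN = 1, mN = 1e3, N = 1e6)

.pick_column <- function(df, key, what, path) {
  if (is.numeric(key)) {
    if (key < 1 || key > ncol(df)) {
      .stop_invalid("column index ", key, " (", what, ") out of range in ",
                    path)
    }
    return(df[[as.integer(key)]])
  }
  if (!key %in% names(df)) {
    .stop_invalid("missing column '", key, "' (", what, ") in ", path,
                  "; found: ", paste(names(df), collapse = ", "))
  }
  df[[key]]
}

.as_numeric_column <- function(x, what, path) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0L) {
    .stop_invalid("non-numeric ", what, " value '", x[bad[1L]],
                  "' at data row ", bad[1L], " of ", path)
  }
  out
}

#' Read a force-displacement table
#'
#' Reads a delimited text export (comma-separated, header row, UTF-8 by
#' default; MicroTester-style), maps and unit-converts the displacement and
#' force columns, and returns a [force_curve()] in um/uN.
#'
#' @param path Path to the delimited file.
#' @param map A [column_map()].
#' @param geometry Optional [sample_geometry()] to attach.
#' @param sample_id Defaults to the file name without extension.
#' @param sep Field separator (default `","`).
#' @param header Whether the file has a header row (default TRUE; with
#'   `header = FALSE` use positional column indices in the map).
#' @return A [force_curve()].
#' @seealso [write_force_table()]
#' @export
read_force_table <- function(path, map = column_map(), geometry = NULL,
                             sample_id = NULL, sep = ",", header = TRUE) {
  stopifnot(inherits(map, "column_map"))
  if (!file.exists(path)) .stop_invalid("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, comment.char = "",
                          encoding = "UTF-8")
  d <- .as_numeric_column(.pick_column(df, map$displacement, "displacement",
                                       path), "displacement", path)
  f <- .as_numeric_column(.pick_column(df, map$force, "force", path),
                          "force", path)
  d <- d * .length_factor[[map$displacement_unit]]
  f <- f * .force_factor[[map$force_unit]]
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  force_curve(d, f, sample_id = sample_id, geometry = geometry)
}

#' @rdname read_force_table
#' @param curve A [force_curve()] to write (um/uN, header
#'   `displacement,force`).
#' @export
write_force_table <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a silhouette mask or contour table
#'
#' `read_mask()` reads a single-channel PNG or TIFF image (any nonzero pixel
#' is sample) into a 0/1 matrix in image orientation. `read_contour_table()`
#' reads a delimited table of ordered boundary coordinates with columns
#' `x,y` (y up, toward the indenter).
#'
#' @param path Path to the file.
#' @return `read_mask()`: a 0/1 matrix. `read_contour_table()`: a
#'   [contour_profile()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) .stop_invalid("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    .stop_invalid("unsupported mask format '.", ext, "' (use PNG or TIFF)"))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel
  matrix(as.integer(img != 0), nrow(img), ncol(img))
}

#' @rdname read_mask
#' @param sep Field separator (default `","`).
#' @export
read_contour_table <- function(path, sep = ",") {
  if (!file.exists(path)) .stop_invalid("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  x <- .as_numeric_column(.pick_column(df, "x", "x", path), "x", path)
  y <- .as_numeric_column(.pick_column(df, "y", "y", path), "y", path)
  contour_profile(x, y)
}
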