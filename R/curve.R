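#' Construct a detector trace
#'
#' A curve is one detector trace of a chromatography run: a series of signal
#' values (typically UV absorbance in mAU) sampled along the elution volume.
#' Vendor exports name UV channels with a wavelength suffix (e.g.
#' \code{"UV 1_280"}); when no explicit wavelength is supplied it is parsed
#' from the name with [wavelength_from_name()].
#'
#' @param name Curve name, a non-empty string (e.g. \code{"UV 1_280"}).
#' @param x Elution volumes (ml, or the unit given in \code{x_unit}).
#'   Must be finite, nondecreasing and of length >= 2.
#' @param y Signal values aligned with \code{x}; finite, same length.
#' @param x_unit,y_unit Axis unit labels as printed in the source file.
#' @param wavelength_nm Optional detection wavelength in nm; default is
#'   parsed from \code{name} (\code{NA} when the name carries none).
#' @return An object of class \code{"fplc_curve"}: a list with fields
#'   \code{name}, \code{wavelength_nm}, \code{x}, \code{y}, \code{x_unit},
#'   \code{y_unit}.
#' @examples
#' cv <- fplc_curve("UV 1_280", x = c(0, 1, 2), y = c(0, 5, 1))
#' cv$wavelength_nm
#' @export
fplc_curve <- function(name, x, y, x_unit = "ml", y_unit = "mAU",
                       wavelength_nm = wavelength_from_name(name)) {
  if (!is_string(name) || !nzchar(name)) {
    fplc_stop("curve 'name' must be a non-empty string", "fplcplot_invalid_curve")
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    fplc_stop(sprintf("curve '%s': x and y lengths differ (%d vs %d)",
                      name, length(x), length(y)), "fplcplot_invalid_curve")
  }
  if (length(x) < 2L) {
    fplc_stop(sprintf("curve '%s': needs at least 2 points", name),
              "fplcplot_invalid_curve")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    fplc_stop(sprintf("curve '%s': x and y must be finite (no NA/NaN/Inf)", name),
              "fplcplot_invalid_curve")
  }
  if (is.unsorted(x)) {
    fplc_stop(sprintf("curve '%s': x (elution volume) must be nondecreasing", name),
              "fplcplot_invalid_curve")
  }
  if (anyDuplicated(x)) {
    warning(sprintf("curve '%s': duplicated x values kept as-is", name),
            call. = FALSE)
  }
  wl <- if (length(wavelength_nm) == 0L || is.null(wavelength_nm)) {
    NA_integer_
  } else {
    as.integer(wavelength_nm)
  }
  structure(
    list(name = name, wavelength_nm = wl, x = x, y = y,
         x_unit = as.character(x_unit), y_unit = as.character(y_unit)),
    class = "fplc_curve"
  )
}

#' Parse a detection wavelength out of a curve name
#'
#' Unicorn exports label UV channels like \code{"UV 1_280"} or
#' \code{"UV 2_260"}. The wavelength is taken from the trailing integer after
#' the last underscore; failing that, an embedded 260/280/230 token is
#' recognized. Total function: unmatched names give \code{NA}.
#'
#' @param name Character vector of curve names.
#' @return Integer vector of wavelengths in nm (\code{NA} where absent).
#' @examples
#' wavelength_from_name(c("UV 1_280", "UV 2_260", "Cond"))
#' @export
wavelength_from_name <- function(name) {
  vapply(as.character(name), function(nm) {
    if (is.na(nm)) return(NA_integer_)
    m <- regmatches(nm, regexpr("_([0-9]+)[[:space:]]*$", nm))
    if (length(m) == 1L && nzchar(m)) {
      return(as.integer(sub("^_", "", trimws(m))))
    }
    t <- regmatches(nm, regexpr("(?<![0-9])(260|280|230)(?![0-9])", nm, perl = TRUE))
    if (length(t) == 1L && nzchar(t)) return(as.integer(t))
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' @export
print.fplc_curve <- function(x, ...) {
  wl <- if (is.na(x$wavelength_nm)) "" else sprintf(" [%d nm]", x$wavelength_nm)
  cat(sprintf("<fplc_curve> %s%s: %d points, %.6g-%.6g %s, %s\n",
              x$name, wl, length(x$x), x$x[1], x$x[length(x$x)],
              x$x_unit, x$y_unit))
  invisible(x)
}
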