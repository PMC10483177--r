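#' Construct a chromatogram
#'
#' A chromatogram is one parsed purification run: one or more detector
#' [fplc_curve()] traces plus the collector/injection/logbook event marks the
#' instrument recorded, and metadata about the source file.
#'
#' @param curves A list of [fplc_curve()] objects with unique names.
#' @param fraction_events Data frame with columns \code{start_ml} (numeric,
#'   strictly increasing) and \code{label} (unique non-empty strings), one row
#'   per collected fraction start mark. May be \code{NULL}/empty.
#' @param injection_events Data frame with columns \code{volume_ml},
#'   \code{label}; may be \code{NULL}/empty.
#' @param logbook Data frame with columns \code{volume_ml}, \code{text};
#'   may be \code{NULL}/empty.
#' @param meta Named list of source metadata (e.g. \code{source},
#'   \code{dialect}, \code{id}).
#' @return An object of class \code{"chromatogram"}.
#' @examples
#' cv <- fplc_curve("UV 1_280", x = 0:10, y = c(0:5, 4:0))
#' ch <- chromatogram(list(cv),
#'   fraction_events = data.frame(start_ml = c(2, 4), label = c("A1", "A2")))
#' @export
chromatogram <- function(curves, fraction_events = NULL,
                         injection_events = NULL, logbook = NULL,
                         meta = list()) {
  if (inherits(curves, "fplc_curve")) curves <- list(curves)
  if (!is.list(curves) || length(curves) < 1L ||
      !all(vapply(curves, inherits, logical(1), "fplc_curve"))) {
    fplc_stop("'curves' must be a non-empty list of fplc_curve objects",
              "fplcplot_invalid_chromatogram")
  }
  nms <- vapply(curves, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    fplc_stop(sprintf("duplicate curve names: %s",
                      paste(unique(nms[duplicated(nms)]), collapse = ", ")),
              "fplcplot_invalid_chromatogram")
  }
  names(curves) <- nms

  fraction_events <- normalize_events(fraction_events, c("start_ml", "label"))
  if (nrow(fraction_events)) {
    if (anyNA(fraction_events$start_ml) || any(!is.finite(fraction_events$start_ml))) {
      fplc_stop("fraction start volumes must be finite", "fplcplot_invalid_chromatogram")
    }
    if (any(diff(fraction_events$start_ml) <= 0)) {
      fplc_stop("fraction start volumes must be strictly increasing",
                "fplcplot_invalid_chromatogram")
    }
    if (anyDuplicated(fraction_events$label) || any(!nzchar(fraction_events$label))) {
      fplc_stop("fraction labels must be unique and non-empty",
                "fplcplot_invalid_chromatogram")
    }
  }
  injection_events <- normalize_events(injection_events, c("volume_ml", "label"))
  logbook <- normalize_events(logbook, c("volume_ml", "text"))
  for (ev in list(injection_events, logbook)) {
    if (nrow(ev) && (anyNA(ev[[1L]]) || any(!is.finite(ev[[1L]])))) {
      fplc_stop("event volumes must be finite", "fplcplot_invalid_chromatogram")
    }
  }

  structure(
    list(curves = curves, fraction_events = fraction_events,
         injection_events = injection_events, logbook = logbook,
         meta = meta),
    class = "chromatogram"
  )
}

normalize_events <- function(ev, cols) {
  if (is.null(ev) || (is.data.frame(ev) && nrow(ev) == 0L)) {
    ev <- stats::setNames(data.frame(numeric(0), character(0),
                                     stringsAsFactors = FALSE), cols)
    return(ev)
  }
  if (!is.data.frame(ev) || !all(cols %in% names(ev))) {
    fplc_stop(sprintf("event table must have columns: %s",
                      paste(cols, collapse = ", ")),
              "fplcplot_invalid_chromatogram")
  }
  ev <- ev[, cols, drop = FALSE]
  ev[[1L]] <- as.numeric(ev[[1L]])
  ev[[2L]] <- as.character(ev[[2L]])
  rownames(ev) <- NULL
  ev
}

#' Fraction labels of a chromatogram
#' @param chrom A [chromatogram()].
#' @return Character vector of fraction labels in elution order.
#' @export
fraction_labels <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  chrom$fraction_events$label
}

#' The primary UV curve of a chromatogram
#'
#' The 280 nm channel if present (the protein-sensitive trace that fraction
#' and volume highlights are drawn under), otherwise the first curve.
#'
#' @param chrom A [chromatogram()].
#' @return An [fplc_curve()].
#' @export
primary_curve <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  wl <- vapply(chrom$curves, `[[`, integer(1), "wavelength_nm")
  i <- which(!is.na(wl) & wl == 280L)
  if (length(i)) chrom$curves[[i[1L]]] else chrom$curves[[1L]]
}

#' Build contiguous fraction intervals from collector start marks
#'
#' The fraction collector records only the volume at which each fraction
#' starts; the fraction ends where the next one begins. The last fraction is
#' closed at \code{x_end} (by convention the maximum elution volume of the
#' primary UV curve, i.e. as far as a filled area can visually extend). The
#' resulting intervals tile \code{[first start, x_end]} with no gaps or
#' overlaps.
#'
#' @param events Data frame of fraction start marks with columns
#'   \code{start_ml} (strictly increasing) and \code{label}, or a
#'   [chromatogram()] (its \code{fraction_events} are used and \code{x_end}
#'   defaults to the primary curve's maximum volume).
#' @param x_end Right edge of the last fraction; must exceed the last start.
#' @return Data frame with columns \code{label}, \code{start_ml},
#'   \code{end_ml}; zero rows when there are no fraction marks.
#' @examples
#' ev <- data.frame(start_ml = c(5, 6, 7), label = c("1", "2", "3"))
#' fraction_intervals(ev, x_end = 8.5)
#' @export
fraction_intervals <- function(events, x_end = NULL) {
  if (inherits(events, "chromatogram")) {
    if (is.null(x_end)) {
      pc <- primary_curve(events)
      x_end <- pc$x[length(pc$x)]
    }
    events <- events$fraction_events
  }
  events <- normalize_events(events, c("start_ml", "label"))
  if (nrow(events) == 0L) {
    return(data.frame(label = character(0), start_ml = numeric(0),
                      end_ml = numeric(0), stringsAsFactors = FALSE))
  }
  if (is.null(x_end) || !is_scalar_number(x_end)) {
    fplc_stop("'x_end' must be a finite number", "fplcplot_boundary_error")
  }
  starts <- events$start_ml
  if (any(diff(starts) <= 0)) {
    fplc_stop("fraction starts must be strictly increasing", "fplcplot_boundary_error")
  }
  last <- starts[length(starts)]
  if (x_end <= last) {
    fplc_stop(sprintf(
      "x_end (%g) must lie beyond the last fraction start (%g): the final fraction would have zero or negative width",
      x_end, last), "fplcplot_boundary_error")
  }
  data.frame(label = events$label,
             start_ml = starts,
             end_ml = c(starts[-1L], x_end),
             stringsAsFactors = FALSE)
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d curve(s), %d fraction(s)\n",
              length(x$curves), nrow(x$fraction_events)))
  for (cv in x$curves) print(cv)
  if (nrow(x$fraction_events)) {
    cat("Fractions:", paste(x$fraction_events$label, collapse = " "), "\n")
  }
  invisible(x)
}
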