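#' Normalize a curve's signal values
#'
#' Chromatogram channels often sit on an arbitrary detector offset;
#' \code{"shift_min_zero"} (the default used when plotting) anchors the
#' minimum at zero while keeping mAU units readable on the axis.
#' \code{"minmax_01"} rescales to \code{[0, 1]}, useful for overlaying
#' channels of very different magnitude. Each curve is normalized
#' independently; x is untouched. Both methods are idempotent.
#'
#' @param curve An [fplc_curve()].
#' @param method \code{"none"}, \code{"shift_min_zero"} or \code{"minmax_01"}.
#' @return A new [fplc_curve()] (for \code{"minmax_01"} the y unit becomes
#'   \code{"relative"}).
#' @export
normalize_curve <- function(curve, method = c("shift_min_zero", "minmax_01", "none")) {
  if (!inherits(curve, "fplc_curve")) {
    fplc_stop("'curve' must be an fplc_curve", "fplcplot_precondition_error")
  }
  method <- match.arg(method)
  if (method == "none") return(curve)
  y <- curve$y
  rng <- range(y)
  if (method == "shift_min_zero") {
    y2 <- y - rng[1L]
    yu <- curve$y_unit
  } else {
    if (rng[2L] == rng[1L]) {
      fplc_stop(sprintf("curve '%s' is constant: min-max normalization is degenerate",
                        curve$name), "fplcplot_degenerate_error")
    }
    y2 <- (y - rng[1L]) / (rng[2L] - rng[1L])
    yu <- "relative"
  }
  fplc_curve(curve$name, curve$x, y2, x_unit = curve$x_unit, y_unit = yu,
             wavelength_nm = curve$wavelength_nm)
}

#' Restrict a curve to an elution-volume window
#'
#' Keeps the samples with \code{vmin <= x <= vmax} and adds linearly
#' interpolated boundary points at exactly \code{vmin} and \code{vmax} when
#' those fall between samples, so that filled areas and integrals start and
#' stop exactly at the requested volumes. The window is clipped to the
#' curve's extent; a window with no overlap is an error.
#'
#' @param curve An [fplc_curve()].
#' @param vmin,vmax Window bounds, \code{vmin < vmax}.
#' @return A new [fplc_curve()] covering the overlap of the window with the
#'   curve's extent.
#' @examples
#' cv <- fplc_curve("UV 1_280", x = 0:3, y = c(0, 10, 10, 0))
#' restrict_to_range(cv, 0.5, 2.5)$y
#' @export
restrict_to_range <- function(curve, vmin, vmax) {
  if (!inherits(curve, "fplc_curve")) {
    fplc_stop("'curve' must be an fplc_curve", "fplcplot_precondition_error")
  }
  if (!is_scalar_number(vmin) || !is_scalar_number(vmax) || vmin >= vmax) {
    fplc_stop("need finite vmin < vmax", "fplcplot_precondition_error")
  }
  x <- curve$x; y <- curve$y; n <- length(x)
  lo <- max(vmin, x[1L]); hi <- min(vmax, x[n])
  if (lo >= hi) {
    fplc_stop(sprintf("range [%g, %g] does not overlap curve extent [%g, %g]",
                      vmin, vmax, x[1L], x[n]), "fplcplot_empty_selection")
  }
  keep <- which(x >= lo & x <= hi)
  xs <- x[keep]; ys <- y[keep]
  interp <- function(x0) stats::approx(x, y, xout = x0, ties = "ordered")$y
  if (length(xs) == 0L || xs[1L] > lo) {
    xs <- c(lo, xs); ys <- c(interp(lo), ys)
  }
  if (xs[length(xs)] < hi) {
    xs <- c(xs, hi); ys <- c(ys, interp(hi))
  }
  suppressWarnings(  # duplicated x at window edges is fine here
    fplc_curve(curve$name, xs, ys, x_unit = curve$x_unit, y_unit = curve$y_unit,
               wavelength_nm = curve$wavelength_nm)
  )
}

#' Trapezoidal area under a curve over an interval
#'
#' Integrates the piecewise-linear interpolant of the (unevenly sampled)
#' trace over the interval, after clipping via [restrict_to_range()]. When a
#' [fit_baseline_als()] model is given, its baseline is subtracted first, so
#' the area quantifies signal above baseline (and may be negative where the
#' trace dips below it). Areas are additive over adjacent intervals.
#'
#' @param curve An [fplc_curve()].
#' @param interval Numeric \code{c(start, end)} in ml, or a one-row slice of
#'   a [fraction_intervals()] data frame.
#' @param baseline Optional [fit_baseline_als()] model for this curve.
#' @return Area in ml x signal units (ml.mAU for a UV trace).
#' @export
integrate_auc <- function(curve, interval, baseline = NULL) {
  if (is.data.frame(interval)) {
    if (nrow(interval) != 1L || !all(c("start_ml", "end_ml") %in% names(interval))) {
      fplc_stop("'interval' data frame must be a single fraction-interval row",
                "fplcplot_precondition_error")
    }
    interval <- c(interval$start_ml, interval$end_ml)
  }
  if (!is.numeric(interval) || length(interval) != 2L) {
    fplc_stop("'interval' must be c(start, end)", "fplcplot_precondition_error")
  }
  if (!is.null(baseline)) curve <- subtract_baseline(curve, baseline)
  seg <- restrict_to_range(curve, interval[1L], interval[2L])
  n <- length(seg$x)
  sum(diff(seg$x) * (seg$y[-1L] + seg$y[-n]) / 2)
}

#' Clip a chromatogram and its annotations to a zoom window
#'
#' Applies a zoom window to every view that feeds rendering: curves and
#' baselines are restricted to the x window, fraction intervals partially
#' inside are truncated and those fully outside dropped, and the volume
#' highlight range is clipped. The area of any sub-interval inside the window
#' is unchanged by zooming. Zooming is therefore compatible with every other
#' plot feature.
#'
#' @param chrom A [chromatogram()].
#' @param selection A [chrom_selection()]; its \code{zoom} supplies the
#'   window (full extent when absent).
#' @param baselines Optional named list of [fit_baseline_als()] models,
#'   keyed by curve name.
#' @return A list of class \code{"chrom_view"} with elements \code{curves},
#'   \code{baselines} (curves of baseline values, clipped), \code{intervals}
#'   (all fraction intervals, clipped), \code{volume_range} (clipped, or
#'   \code{NULL}), \code{xlim}, \code{ylim} (\code{NULL} unless the zoom set
#'   one).
#' @export
apply_zoom <- function(chrom, selection = chrom_selection(), baselines = NULL) {
  if (!inherits(chrom, "chromatogram")) {
    fplc_stop("'chrom' must be a chromatogram", "fplcplot_precondition_error")
  }
  if (!inherits(selection, "chrom_selection")) {
    fplc_stop("'selection' must be a chrom_selection", "fplcplot_precondition_error")
  }
  xr <- range(unlist(lapply(chrom$curves, `[[`, "x")))
  zoom <- selection$zoom
  xlim <- if (is.null(zoom)) xr else zoom[1:2]
  ylim <- if (!is.null(zoom) && length(zoom) == 4L) zoom[3:4] else NULL
  if (xlim[2L] <= xr[1L] || xlim[1L] >= xr[2L]) {
    fplc_stop(sprintf("zoom window [%g, %g] excludes all data ([%g, %g])",
                      xlim[1L], xlim[2L], xr[1L], xr[2L]),
              "fplcplot_empty_selection")
  }

  clip_curve <- function(cv) {
    if (xlim[1L] <= cv$x[1L] && xlim[2L] >= cv$x[length(cv$x)]) return(cv)
    tryCatch(restrict_to_range(cv, xlim[1L], xlim[2L]),
             fplcplot_empty_selection = function(e) NULL)
  }
  curves <- Filter(Negate(is.null), lapply(chrom$curves, clip_curve))
  if (length(curves) == 0L) {
    fplc_stop("zoom window excludes all curves", "fplcplot_empty_selection")
  }

  bviews <- NULL
  if (!is.null(baselines)) {
    bviews <- list()
    for (nm in names(baselines)) {
      cv <- chrom$curves[[nm]]
      if (is.null(cv)) next
      bcv <- suppressWarnings(
        fplc_curve(nm, cv$x, baselines[[nm]]$z,
                   x_unit = cv$x_unit, y_unit = cv$y_unit,
                   wavelength_nm = cv$wavelength_nm))
      bc <- clip_curve(bcv)
      if (!is.null(bc)) bviews[[nm]] <- bc
    }
  }

  iv <- fraction_intervals(chrom)
  if (nrow(iv)) {
    iv$start_ml <- pmax(iv$start_ml, xlim[1L])
    iv$end_ml <- pmin(iv$end_ml, xlim[2L])
    iv <- iv[iv$start_ml < iv$end_ml, , drop = FALSE]
    rownames(iv) <- NULL
  }

  vr <- selection$volume_range
  if (!is.null(vr)) {
    vr <- c(max(vr[1L], xlim[1L]), min(vr[2L], xlim[2L]))
    if (vr[1L] >= vr[2L]) vr <- NULL
  }

  structure(list(curves = curves, baselines = bviews, intervals = iv,
                 volume_range = vr, xlim = xlim, ylim = ylim),
            class = "chrom_view")
}
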