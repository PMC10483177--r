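#' Fit an asymmetric-least-squares baseline to a curve
#'
#' Estimates the slowly varying non-peak component of a chromatogram trace
#' (buffer absorbance, detector drift) with the Whittaker smoother under
#' asymmetric weights (Eilers-style ALS, the standard chromatography choice).
#' The baseline \eqn{z} minimizes
#' \deqn{\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2}
#' where the weights are re-derived each iteration as \eqn{w_i = p} where
#' \eqn{y_i > z_i} (points above the baseline, i.e. peaks, count little) and
#' \eqn{w_i = 1 - p} otherwise. With small \eqn{p} the fit hugs the lower
#' envelope of the signal; \eqn{\lambda} sets its stiffness. Second
#' differences are taken on the sample index (slight x non-uniformity is
#' ignored), which keeps the system pentadiagonal and is solved sparsely.
#'
#' Iteration stops when the relative change of \eqn{z} falls below
#' \code{tol}, or after \code{max_iter} passes. The fit is deterministic.
#'
#' @param curve An [fplc_curve()] with at least 3 points.
#' @param lambda Smoothness penalty, > 0. Because second differences are
#'   taken per sample, the smoother's half-width is about \eqn{\lambda^{1/4}}
#'   samples; the default \code{1e11} makes that roughly 1 ml at the 0.002 ml
#'   sampling of typical vendor exports -- stiff on the scale of the
#'   narrowest SEC peaks, so the baseline tracks drift rather than peaks.
#'   For data sampled at a coarser spacing, scale \code{lambda} by
#'   \eqn{(\Delta x_{ref}/\Delta x)^4}.
#' @param p Asymmetry, in (0, 1). Default \code{0.01}.
#' @param max_iter Maximum reweighting iterations, >= 1. Default 20.
#' @param tol Relative-change convergence threshold. Default \code{1e-6}.
#' @return An object of class \code{"baseline_model"}: list with
#'   \code{curve_name}, \code{z} (baseline values aligned 1:1 with the
#'   curve), \code{params}, \code{converged}, \code{n_iter}.
#' @examples
#' cv <- fplc_curve("UV 1_280", x = seq(0, 10, by = 0.05),
#'                  y = 2 + 0.1 * seq(0, 10, by = 0.05) +
#'                      50 * dnorm(seq(0, 10, by = 0.05), 5, 0.3))
#' bm <- fit_baseline_als(cv)
#' bm$converged
#' @export
fit_baseline_als <- function(curve, lambda = 1e11, p = 0.01,
                             max_iter = 20L, tol = 1e-6) {
  if (!inherits(curve, "fplc_curve")) {
    fplc_stop("'curve' must be an fplc_curve", "fplcplot_precondition_error")
  }
  m <- length(curve$y)
  if (m < 3L) {
    fplc_stop("baseline fit needs at least 3 points (second differences undefined)",
              "fplcplot_precondition_error")
  }
  if (!is_scalar_number(lambda) || lambda <= 0) {
    fplc_stop("'lambda' must be a positive number", "fplcplot_precondition_error")
  }
  if (!is_scalar_number(p) || p <= 0 || p >= 1) {
    fplc_stop("'p' must lie strictly between 0 and 1", "fplcplot_precondition_error")
  }
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) {
    fplc_stop("'max_iter' must be >= 1", "fplcplot_precondition_error")
  }

  y <- curve$y
  D <- Matrix::diff(Matrix::Diagonal(m), differences = 2L)
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z_prev <- NULL
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    A <- Matrix::Diagonal(x = w) + P
    z <- as.numeric(Matrix::solve(A, w * y))
    if (!is.null(z_prev)) {
      rel <- sqrt(sum((z - z_prev)^2)) / max(sqrt(sum(z_prev^2)), .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; z_prev <- z; break }
    }
    z_prev <- z
    w <- ifelse(y > z, p, 1 - p)
  }
  structure(
    list(curve_name = curve$name, z = z_prev,
         params = list(lambda = lambda, p = p, max_iter = max_iter, tol = tol),
         converged = converged, n_iter = n_iter),
    class = "baseline_model"
  )
}

#' Subtract a fitted baseline from its curve
#'
#' @param curve The [fplc_curve()] the model was fitted to.
#' @param model A [fit_baseline_als()] result for that curve.
#' @return A new [fplc_curve()] with \code{y - z} and the name suffixed
#'   \code{" (baseline-corrected)"}.
#' @export
subtract_baseline <- function(curve, model) {
  if (!inherits(curve, "fplc_curve") || !inherits(model, "baseline_model")) {
    fplc_stop("need an fplc_curve and a baseline_model", "fplcplot_precondition_error")
  }
  if (!identical(model$curve_name, curve$name)) {
    fplc_stop(sprintf("model was fitted to curve '%s', not '%s'",
                      model$curve_name, curve$name), "fplcplot_precondition_error")
  }
  if (length(model$z) != length(curve$y)) {
    fplc_stop(sprintf("baseline length (%d) does not match curve length (%d)",
                      length(model$z), length(curve$y)),
              "fplcplot_precondition_error")
  }
  fplc_curve(paste0(curve$name, " (baseline-corrected)"),
             curve$x, curve$y - model$z,
             x_unit = curve$x_unit, y_unit = curve$y_unit,
             wavelength_nm = curve$wavelength_nm)
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> '%s': %d points, lambda=%g, p=%g, %s after %d iteration(s)\n",
              x$curve_name, length(x$z), x$params$lambda, x$params$p,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}
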