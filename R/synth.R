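#' Recipe for a synthetic chromatogram with known ground truth
#'
#' Describes a simulated run as Gaussian elution peaks on a linear drift
#' with additive Gaussian detector noise, plus a regular fraction-collection
#' scheme. The defaults emulate a size-exclusion run on a ~24 ml analytical
#' column (Superdex-200-class): one dominant monomer peak at 14 ml, a 280 nm
#' channel and a weaker 260 nm
#' channel (A260/A280 ~ 0.55, typical for pure protein), mild linear drift,
#' 0.5 mAU detector noise, 0.002 ml sampling, and 0.5 ml fractions collected
#' across the elution region.
#'
#' @param peaks List of named numeric vectors \code{c(center=, height=,
#'   sigma=)} (ml, mAU, ml); sigma > 0.
#' @param drift \code{c(intercept=, slope=)} in mAU and mAU/ml.
#' @param noise_sd Gaussian noise sd in mAU, >= 0.
#' @param x_start,x_end,step Sampling grid in ml; \code{x_start < x_end},
#'   \code{step > 0}.
#' @param channels Named list mapping curve name to per-peak height scale
#'   (scalar, or one value per peak).
#' @param fraction_start,fraction_width,n_fractions Fraction scheme; must fit
#'   inside \code{[x_start, x_end]}. \code{n_fractions = 0} disables it.
#' @param seed Integer RNG seed; the generator is fully reproducible.
#' @return An object of class \code{"synth_spec"}.
#' @export
synth_spec <- function(peaks = list(c(center = 14, height = 60, sigma = 0.35)),
                       drift = c(intercept = 2, slope = 0.15),
                       noise_sd = 0.5,
                       x_start = 0, x_end = 24, step = 0.002,
                       channels = list("UV 1_280" = 1, "UV 2_260" = 0.55),
                       fraction_start = 8, fraction_width = 0.5,
                       n_fractions = 24L,
                       seed = 1L) {
  if (!is.list(peaks) || length(peaks) < 1L) {
    fplc_stop("'peaks' must be a non-empty list", "fplcplot_invalid_spec")
  }
  for (pk in peaks) {
    if (!is.numeric(pk) || !all(c("center", "height", "sigma") %in% names(pk)) ||
        !is.finite(pk[["sigma"]]) || pk[["sigma"]] <= 0) {
      fplc_stop("each peak needs finite c(center=, height=, sigma=) with sigma > 0",
                "fplcplot_invalid_spec")
    }
  }
  if (!is_scalar_number(x_start) || !is_scalar_number(x_end) || x_start >= x_end) {
    fplc_stop("need x_start < x_end", "fplcplot_invalid_spec")
  }
  if (!is_scalar_number(step) || step <= 0) {
    fplc_stop("'step' must be > 0", "fplcplot_invalid_spec")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    fplc_stop("'noise_sd' must be >= 0", "fplcplot_invalid_spec")
  }
  if (!is.list(channels) || length(channels) < 1L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    fplc_stop("'channels' must be a named list of height scales",
              "fplcplot_invalid_spec")
  }
  n_fractions <- as.integer(n_fractions)
  if (n_fractions > 0L) {
    if (!is_scalar_number(fraction_start) || !is_scalar_number(fraction_width) ||
        fraction_width <= 0) {
      fplc_stop("invalid fraction scheme", "fplcplot_invalid_spec")
    }
    if (fraction_start < x_start ||
        fraction_start + n_fractions * fraction_width > x_end) {
      fplc_stop("fraction scheme does not fit inside [x_start, x_end]",
                "fplcplot_invalid_spec")
    }
  }
  seed <- as.integer(seed)
  if (is.na(seed)) fplc_stop("'seed' must be an integer", "fplcplot_invalid_spec")
  structure(list(peaks = peaks, drift = drift, noise_sd = noise_sd,
                 x_start = x_start, x_end = x_end, step = step,
                 channels = channels, fraction_start = fraction_start,
                 fraction_width = fraction_width, n_fractions = n_fractions,
                 seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic chromatogram with its ground truth
#'
#' Evaluates the [synth_spec()] recipe on its sampling grid: for each channel
#' \eqn{y(x) = drift(x) + \sum_k scale_k\, h_k e^{-(x-c_k)^2 / 2\sigma_k^2}
#' + N(0, noise\_sd^2)}. Fractions are labelled \code{"1"}, \code{"2"}, ...
#' at their start volumes. The RNG state is saved and restored, so calling
#' this does not disturb the caller's random stream; the same seed always
#' yields the identical chromatogram.
#'
#' @param spec A [synth_spec()].
#' @return A list with \code{chromatogram} (a [chromatogram()]) and
#'   \code{truth}: \code{x} (grid), \code{drift} (drift values on the grid),
#'   \code{clean} (named list of noiseless channel values) and
#'   \code{peak_auc} (channels x peaks matrix of exact Gaussian areas,
#'   \eqn{scale \cdot height \cdot \sigma \sqrt{2\pi}}, in ml.mAU).
#' @export
synth_chromatogram <- function(spec) {
  if (!inherits(spec, "synth_spec")) {
    fplc_stop("'spec' must be a synth_spec", "fplcplot_invalid_spec")
  }
  x <- seq(spec$x_start, spec$x_end, by = spec$step)
  drift_y <- spec$drift[["intercept"]] + spec$drift[["slope"]] * x

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  n_pk <- length(spec$peaks)
  curves <- list()
  clean <- list()
  peak_auc <- matrix(NA_real_, nrow = length(spec$channels), ncol = n_pk,
                     dimnames = list(names(spec$channels), NULL))
  for (ci in seq_along(spec$channels)) {
    nm <- names(spec$channels)[ci]
    scales <- rep_len(as.numeric(spec$channels[[ci]]), n_pk)
    y <- drift_y
    for (k in seq_len(n_pk)) {
      pk <- spec$peaks[[k]]
      y <- y + scales[k] * pk[["height"]] *
        exp(-0.5 * ((x - pk[["center"]]) / pk[["sigma"]])^2)
      peak_auc[ci, k] <- scales[k] * pk[["height"]] * pk[["sigma"]] * sqrt(2 * pi)
    }
    clean[[nm]] <- y
    if (spec$noise_sd > 0) y <- y + stats::rnorm(length(x), 0, spec$noise_sd)
    curves[[nm]] <- fplc_curve(nm, x, y)
  }

  fractions <- NULL
  if (spec$n_fractions > 0L) {
    starts <- spec$fraction_start + spec$fraction_width * (seq_len(spec$n_fractions) - 1L)
    fractions <- data.frame(start_ml = starts,
                            label = as.character(seq_len(spec$n_fractions)),
                            stringsAsFactors = FALSE)
  }

  chrom <- chromatogram(curves, fraction_events = fractions,
                        meta = list(source = NA_character_, dialect = NULL,
                                    id = NA_character_,
                                    skipped_columns = character(0)))
  list(chromatogram = chrom,
       truth = list(x = x, drift = drift_y, clean = clean, peak_auc = peak_auc,
                    spec = spec))
}
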