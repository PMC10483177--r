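# Shared fixtures and independent oracles for the test suite.

# A small randomized synth recipe: modest grids keep the suite fast while
# still exercising ragged lengths, multiple channels and fraction schemes.
random_spec <- function(seed) {
  set.seed(seed)
  n_pk <- sample(1:3, 1)
  x_end <- runif(1, 10, 30)
  peaks <- lapply(seq_len(n_pk), function(i) {
    c(center = runif(1, 0.2 * x_end, 0.85 * x_end),
      height = runif(1, 5, 120),
      sigma = runif(1, 0.15, 0.8))
  })
  n_fr <- sample(c(0L, 4L, 10L), 1)
  width <- if (n_fr > 0) runif(1, 0.3, (0.5 * x_end) / n_fr) else 0.5
  synth_spec(
    peaks = peaks,
    drift = c(intercept = runif(1, -3, 5), slope = runif(1, -0.2, 0.3)),
    noise_sd = runif(1, 0, 1),
    x_start = 0, x_end = x_end, step = runif(1, 0.01, 0.05),
    channels = list("UV 1_280" = 1, "UV 2_260" = runif(1, 0.3, 0.9)),
    fraction_start = 0.25 * x_end, fraction_width = width, n_fractions = n_fr,
    seed = seed
  )
}

all_dialects <- function() {
  combos <- list(
    list("utf-8", "\t", "."), list("utf-8", ";", "."), list("utf-8", ",", "."),
    list("utf-8", "\t", ","), list("utf-8", ";", ","),
    list("utf-16-le", "\t", "."), list("utf-16-le", ";", ","),
    list("utf-16-be", "\t", "."), list("utf-16-be", ",", "."),
    list("latin-1", "\t", "."), list("latin-1", ";", ",")
  )
  lapply(combos, function(cm) unicorn_dialect(cm[[1]], cm[[2]], cm[[3]]))
}

# Field-wise chromatogram comparison at print precision (meta excluded:
# source path and dialect legitimately differ across formats).
expect_chrom_equal <- function(a, b, tolerance = 1e-8) {
  expect_equal(names(a$curves), names(b$curves))
  for (nm in names(a$curves)) {
    ca <- a$curves[[nm]]; cb <- b$curves[[nm]]
    expect_equal(ca$x, cb$x, tolerance = tolerance)
    expect_equal(ca$y, cb$y, tolerance = tolerance)
    expect_identical(ca$x_unit, cb$x_unit)
    expect_identical(ca$y_unit, cb$y_unit)
    expect_identical(ca$wavelength_nm, cb$wavelength_nm)
  }
  expect_equal(a$fraction_events$start_ml, b$fraction_events$start_ml,
               tolerance = tolerance)
  expect_identical(a$fraction_events$label, b$fraction_events$label)
  expect_equal(a$injection_events, b$injection_events, tolerance = tolerance)
  expect_equal(a$logbook, b$logbook, tolerance = tolerance)
  invisible(TRUE)
}

# Independent dense-matrix oracle for the ALS baseline: same objective and
# iteration, solved with base-R dense linear algebra.
als_dense_oracle <- function(y, lambda, p, max_iter = 20L, tol = 1e-6) {
  m <- length(y)
  D <- diff(diag(m), differences = 2)
  P <- lambda * crossprod(D)
  w <- rep(1, m)
  z_prev <- NULL
  for (it in seq_len(max_iter)) {
    z <- solve(diag(w) + P, w * y)
    if (!is.null(z_prev)) {
      rel <- sqrt(sum((z - z_prev)^2)) / max(sqrt(sum(z_prev^2)), .Machine$double.eps)
      if (rel < tol) { z_prev <- z; break }
    }
    z_prev <- z
    w <- ifelse(y > z, p, 1 - p)
  }
  as.numeric(z_prev)
}

# Brute-force fine-grid integral of the piecewise-linear interpolant.
pl_integral_oracle <- function(x, y, lo, hi, n = 200001L) {
  g <- seq(lo, hi, length.out = n)
  v <- approx(x, y, xout = g, ties = "ordered")$y
  sum((v[-1] + v[-n]) / 2) * (hi - lo) / (n - 1)
}

# Drift + three well-separated Gaussian peaks with mAU-scale noise: the
# standard recovery scenario for baseline fitting.
three_peak_spec <- function(seed = 101) {
  synth_spec(
    peaks = list(c(center = 6, height = 50, sigma = 0.3),
                 c(center = 12, height = 90, sigma = 0.4),
                 c(center = 18, height = 30, sigma = 0.35)),
    drift = c(intercept = 3, slope = 0.2),
    noise_sd = 0.5,
    x_start = 0, x_end = 24, step = 0.002,
    channels = list("UV 1_280" = 1),
    n_fractions = 0L,
    seed = seed
  )
}
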