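# Normalization, range restriction, AUC integration, zoom.

test_that("normalization methods match their definitions and are idempotent", {
  cv <- fplc_curve("c", 0:2, c(2, 3, 4))
  expect_equal(normalize_curve(cv, "shift_min_zero")$y, c(0, 1, 2))
  expect_equal(normalize_curve(cv, "minmax_01")$y, c(0, 0.5, 1))
  expect_identical(normalize_curve(cv, "none"), cv)

  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    cv <- fplc_curve("c", sort(runif(n, 0, 20)), rnorm(n, 10, 4))
    for (m in c("shift_min_zero", "minmax_01")) {
      once <- normalize_curve(cv, m)
      twice <- normalize_curve(once, m)
      expect_equal(twice$y, once$y, tolerance = 1e-12)
      expect_identical(once$x, cv$x)                       # x untouched
      expect_identical(which.max(once$y), which.max(cv$y)) # argmax preserved
    }
  }
  flat <- fplc_curve("c", 0:2, c(1, 1, 1))
  expect_error(normalize_curve(flat, "minmax_01"), class = "fplcplot_degenerate_error")
})

test_that("range restriction interpolates exact boundary points", {
  cv <- fplc_curve("c", 0:3, c(0, 10, 10, 0))
  r <- restrict_to_range(cv, 0.5, 2.5)
  expect_equal(r$x, c(0.5, 1, 2, 2.5))
  expect_equal(r$y, c(5, 10, 10, 5))

  # full-extent range is the identity
  full <- restrict_to_range(cv, 0, 3)
  expect_equal(full$x, cv$x)
  expect_equal(full$y, cv$y)

  expect_error(restrict_to_range(cv, 5, 6), class = "fplcplot_empty_selection")
  expect_error(restrict_to_range(cv, 2, 1), class = "fplcplot_precondition_error")

  set.seed(51)
  for (i in 1:100) {
    n <- sample(5:100, 1)
    cv <- fplc_curve("c", sort(runif(n, 0, 20)), rnorm(n))
    ext <- range(cv$x)
    vmin <- runif(1, ext[1] - 1, ext[2] - 0.1)
    vmax <- vmin + runif(1, 0.1, 5)
    r <- tryCatch(restrict_to_range(cv, vmin, vmax),
                  fplcplot_empty_selection = function(e) NULL)
    if (is.null(r)) next
    expect_true(all(r$x >= vmin - 1e-12 & r$x <= vmax + 1e-12))
    expect_equal(r$x[1], max(vmin, ext[1]))
    expect_equal(r$x[length(r$x)], min(vmax, ext[2]))
  }
})

test_that("trapezoid AUC matches closed forms and a fine-grid oracle", {
  # unit rectangle
  rect <- fplc_curve("r", c(0, 1), c(1, 1))
  expect_equal(integrate_auc(rect, c(0, 1)), 1.0)

  # sampled Gaussian vs analytic area
  A <- 55; sigma <- 0.3; mu <- 10
  x <- seq(mu - 8 * sigma, mu + 8 * sigma, by = 0.002)
  g <- fplc_curve("g", x, A * exp(-0.5 * ((x - mu) / sigma)^2))
  auc <- integrate_auc(g, c(mu - 6 * sigma, mu + 6 * sigma))
  expect_equal(auc, A * sigma * sqrt(2 * pi), tolerance = 1e-3)

  # piecewise-linear interpolant oracle on an irregular curve
  set.seed(61)
  x <- sort(runif(40, 0, 10)); y <- rnorm(40, 5)
  cv <- fplc_curve("c", x, y)
  expect_equal(integrate_auc(cv, c(2.3, 7.7)),
               pl_integral_oracle(x, y, 2.3, 7.7), tolerance = 1e-6)
})

test_that("AUC is additive over adjacent fraction intervals", {
  out <- synth_chromatogram(synth_spec(seed = 8, noise_sd = 0.3, step = 0.01))
  ch <- out$chromatogram
  cv <- primary_curve(ch)
  iv <- fraction_intervals(ch)
  parts <- vapply(seq_len(nrow(iv)),
                  function(i) integrate_auc(cv, iv[i, ]), numeric(1))
  whole <- integrate_auc(cv, c(iv$start_ml[1], iv$end_ml[nrow(iv)]))
  expect_equal(sum(parts), whole, tolerance = 1e-9)
})

test_that("baseline-corrected AUC subtracts the baseline area", {
  out <- synth_chromatogram(three_peak_spec(seed = 3))
  cv <- out$chromatogram$curves[[1]]
  bm <- fit_baseline_als(cv)
  raw <- integrate_auc(cv, c(10, 14))
  corr <- integrate_auc(cv, c(10, 14), baseline = bm)
  zcv <- fplc_curve(cv$name, cv$x, bm$z)
  expect_equal(corr, raw - integrate_auc(zcv, c(10, 14)), tolerance = 1e-9)
})

test_that("zoom clips views without changing in-window areas", {
  out <- synth_chromatogram(synth_spec(seed = 12, step = 0.01))
  ch <- out$chromatogram
  cv <- primary_curve(ch)

  # full-extent window is the identity on all views
  v0 <- apply_zoom(ch, chrom_selection())
  expect_equal(v0$curves[[cv$name]]$x, cv$x)
  expect_equal(nrow(v0$intervals), nrow(fraction_intervals(ch)))

  # fractions every 0.5 ml from 8; window from 8.75 truncates the first visible one
  v <- apply_zoom(ch, chrom_selection(zoom = c(8.75, 14)))
  expect_equal(v$intervals$start_ml[1], 8.75)
  expect_true(all(v$intervals$end_ml <= 14))
  expect_true(all(v$curves[[cv$name]]$x >= 8.75 & v$curves[[cv$name]]$x <= 14))

  # AUC of any interval inside the window is invariant under zooming
  set.seed(71)
  for (i in 1:25) {
    w0 <- runif(1, 0, 20); w1 <- w0 + runif(1, 1, 4)
    vz <- tryCatch(apply_zoom(ch, chrom_selection(zoom = c(w0, w1))),
                   fplcplot_empty_selection = function(e) NULL)
    if (is.null(vz)) next
    zoomed <- vz$curves[[cv$name]]
    a <- runif(1, max(w0, min(cv$x)), max(w0, min(cv$x)) + (w1 - w0) / 2)
    b <- a + runif(1, 0.1, (w1 - a) * 0.9)
    if (b <= a || b > min(w1, max(cv$x))) next
    expect_equal(integrate_auc(zoomed, c(a, b)), integrate_auc(cv, c(a, b)),
                 tolerance = 1e-12)
  }

  expect_error(apply_zoom(ch, chrom_selection(zoom = c(100, 110))),
               class = "fplcplot_empty_selection")
})
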