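# Domain types: curve validation, wavelength parsing, fraction-interval
# geometry.

test_that("wavelength is parsed from curve-name suffixes and embedded tokens", {
  expect_identical(wavelength_from_name("UV 1_280"), 280L)
  expect_identical(wavelength_from_name("UV 2_260"), 260L)
  expect_identical(wavelength_from_name("UV1_230"), 230L)
  expect_identical(wavelength_from_name("Cond"), NA_integer_)
  expect_identical(wavelength_from_name("UV 280nm trace"), 280L)
  expect_identical(wavelength_from_name(c("UV 1_280", "pH")), c(280L, NA_integer_))
  cv <- fplc_curve("UV 1_280", x = c(0, 1), y = c(0, 1))
  expect_identical(cv$wavelength_nm, 280L)
})

test_that("curve construction rejects malformed inputs", {
  expect_error(fplc_curve("", c(0, 1), c(0, 1)), class = "fplcplot_invalid_curve")
  expect_error(fplc_curve("a", c(0, 1, 2), c(0, 1)), class = "fplcplot_invalid_curve")
  expect_error(fplc_curve("a", 1, 1), class = "fplcplot_invalid_curve")
  expect_error(fplc_curve("a", c(1, 0), c(0, 1)), class = "fplcplot_invalid_curve")
  expect_warning(fplc_curve("a", c(0, 1, 1, 2), c(0, 1, 2, 3)), "duplicated")

  # randomized malformed inputs: NaN/Inf/NA anywhere, or mismatched lengths
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:20, 1)
    x <- sort(runif(n)); y <- runif(n)
    mode <- sample(c("nan", "inf", "na", "len"), 1)
    if (mode == "len") {
      y <- y[-1]
    } else {
      bad <- switch(mode, nan = NaN, inf = sample(c(Inf, -Inf), 1), na = NA_real_)
      if (runif(1) < 0.5) x[sample(n, 1)] <- bad else y[sample(n, 1)] <- bad
      if (is.na(x[1]) || is.nan(x[1])) x <- x  # keep as-is; sortedness check may also fire
    }
    expect_error(fplc_curve("c", x, y), class = "fplcplot_invalid_curve")
  }
})

test_that("chromatogram enforces unique curve names and valid events", {
  cv <- fplc_curve("UV 1_280", 0:5, c(0, 1, 4, 2, 1, 0))
  expect_error(chromatogram(list(cv, cv)), class = "fplcplot_invalid_chromatogram")
  expect_error(
    chromatogram(list(cv), fraction_events = data.frame(start_ml = c(2, 1),
                                                        label = c("a", "b"))),
    class = "fplcplot_invalid_chromatogram")
  expect_error(
    chromatogram(list(cv), fraction_events = data.frame(start_ml = c(1, 2),
                                                        label = c("a", "a"))),
    class = "fplcplot_invalid_chromatogram")
  ch <- chromatogram(list(cv), fraction_events = data.frame(start_ml = c(1, 2),
                                                            label = c("a", "b")))
  expect_identical(fraction_labels(ch), c("a", "b"))
})

test_that("fraction intervals tile contiguously up to x_end", {
  ev <- data.frame(start_ml = c(5, 6, 7), label = c("1", "2", "3"))
  iv <- fraction_intervals(ev, x_end = 8.5)
  expect_identical(iv$label, c("1", "2", "3"))
  expect_equal(iv$start_ml, c(5, 6, 7))
  expect_equal(iv$end_ml, c(6, 7, 8.5))

  # degenerate zero-width final fraction
  expect_error(fraction_intervals(data.frame(start_ml = 2, label = "A"), x_end = 2),
               class = "fplcplot_boundary_error")
  expect_error(fraction_intervals(ev, x_end = 6.9),
               class = "fplcplot_boundary_error")
  # empty event list is not an error
  expect_identical(nrow(fraction_intervals(data.frame(start_ml = numeric(0),
                                                      label = character(0)),
                                           x_end = 5)), 0L)
})

test_that("fraction intervals tile exactly for random event lists", {
  # interval-arithmetic oracle: sorted intervals must chain end-to-start and
  # their widths must sum to the covered span
  set.seed(11)
  for (rep in 1:20) {
    n <- 50L
    starts <- sort(runif(n, 0, 100))
    while (any(diff(starts) <= 0)) starts <- sort(runif(n, 0, 100))
    x_end <- starts[n] + 1
    ev <- data.frame(start_ml = starts, label = as.character(seq_len(n)))
    iv <- fraction_intervals(ev, x_end)
    expect_identical(nrow(iv), n)
    expect_true(all(iv$start_ml < iv$end_ml))            # nonempty interiors
    expect_equal(iv$end_ml[-n], iv$start_ml[-1])          # contiguous, no gaps/overlaps
    expect_equal(sum(iv$end_ml - iv$start_ml), x_end - starts[1],
                 tolerance = 1e-12)                       # widths tile the span
    expect_equal(iv$start_ml[1], starts[1])
    expect_equal(iv$end_ml[n], x_end)
  }
})

test_that("the primary curve is the 280 nm channel when present", {
  c280 <- fplc_curve("UV 1_280", 0:3, c(0, 1, 2, 0))
  c260 <- fplc_curve("UV 2_260", 0:3, c(0, 1, 2, 0))
  cond <- fplc_curve("Cond", 0:3, c(5, 5, 5, 5))
  expect_identical(primary_curve(chromatogram(list(c260, c280)))$name, "UV 1_280")
  expect_identical(primary_curve(chromatogram(list(cond, c260)))$name, "Cond")
})
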