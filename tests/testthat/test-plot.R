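# Rendering decision tree and figure export.

fixture_chrom <- function(seed = 19) {
  synth_chromatogram(synth_spec(seed = seed, step = 0.02))$chromatogram
}

test_that("the default render draws only the curves", {
  ch <- fixture_chrom()
  fig <- render_chromatogram(ch)
  expect_identical(layer_inventory(fig), c("curve", "curve"))
  expect_identical(fig$labels$x, "Elution volume (ml)")
  expect_identical(fig$labels$y, "mAU")
})

test_that("each enabled feature adds exactly its documented layers", {
  ch <- fixture_chrom()
  fig <- render_chromatogram(
    ch,
    plot_style(show_baseline = TRUE, show_fraction_labels = TRUE),
    chrom_selection(fractions = c("3", "4", "5")))
  expect_identical(layer_inventory(fig),
                   c("curve", "curve", "baseline",
                     "fraction_highlight", "fraction_highlight", "fraction_highlight",
                     "fraction_ticks", "fraction_labels"))

  # all five flags exercised together
  fig2 <- render_chromatogram(
    ch,
    plot_style(fill_under_curve = TRUE, show_baseline = TRUE,
               show_fraction_labels = TRUE),
    chrom_selection(fractions = "2", volume_range = c(12, 15)))
  expect_identical(layer_inventory(fig2),
                   c("fill", "fill", "curve", "curve", "baseline",
                     "fraction_highlight", "range_highlight",
                     "fraction_ticks", "fraction_labels"))
})

test_that("the layer inventory follows the decision tree for all flag combinations", {
  ch <- fixture_chrom()
  n_curves <- length(ch$curves)
  for (fill in c(FALSE, TRUE)) for (bl in c(FALSE, TRUE)) {
    for (fr in c(FALSE, TRUE)) for (vr in c(FALSE, TRUE)) {
      for (strip in c(FALSE, TRUE)) {
        style <- plot_style(fill_under_curve = fill, show_baseline = bl,
                            show_fraction_labels = strip)
        sel <- chrom_selection(
          fractions = if (fr) c("1", "2") else character(0),
          volume_range = if (vr) c(10, 13) else NULL)
        fig <- render_chromatogram(ch, style, sel)
        expected <- c(
          rep("fill", if (fill) n_curves else 0),
          rep("curve", n_curves),
          rep("baseline", if (bl) 1 else 0),
          rep("fraction_highlight", if (fr) 2 else 0),
          rep("range_highlight", if (vr) 1 else 0),
          if (strip) c("fraction_ticks", "fraction_labels"))
        expect_identical(layer_inventory(fig), as.character(expected))
      }
    }
  }
})

test_that("unknown fraction labels are rejected with the available ones listed", {
  ch <- fixture_chrom()
  err <- tryCatch(
    render_chromatogram(ch, selection = chrom_selection(fractions = "T99")),
    error = function(e) e)
  expect_s3_class(err, "fplcplot_unknown_fraction")
  expect_match(conditionMessage(err), "T99")
  expect_match(conditionMessage(err), "Available")
})

test_that("zoom drops out-of-window highlight layers", {
  ch <- fixture_chrom()
  fig <- render_chromatogram(
    ch, plot_style(),
    chrom_selection(fractions = c("1", "24"), zoom = c(7.9, 9)))
  # fraction 24 starts at 19.5 ml, outside the window: only one highlight drawn
  expect_identical(sum(layer_inventory(fig) == "fraction_highlight"), 1L)
})

test_that("raster exports have the promised pixel dimensions", {
  fig <- render_chromatogram(fixture_chrom())
  ftif <- withr::local_tempfile(fileext = ".tiff")
  export_figure(fig, ftif, width = 6, height = 4, dpi = 300)
  img <- tiff::readTIFF(ftif)
  expect_identical(dim(img)[1:2], c(1200L, 1800L))
  fpng <- withr::local_tempfile(fileext = ".png")
  export_figure(fig, fpng, width = 3, height = 2, dpi = 150)
  expect_identical(dim(png::readPNG(fpng))[1:2], c(300L, 450L))
})

test_that("vector exports carry the right magic bytes", {
  fig <- render_chromatogram(fixture_chrom())
  fpdf <- withr::local_tempfile(fileext = ".pdf")
  feps <- withr::local_tempfile(fileext = ".eps")
  export_figure(fig, fpdf)
  export_figure(fig, feps)
  expect_identical(rawToChar(readBin(fpdf, "raw", 4)), "%PDF")
  expect_identical(rawToChar(readBin(feps, "raw", 2)), "%!")
  expect_gt(file.size(fpdf), 0)
  expect_gt(file.size(feps), 0)
})

test_that("repeated renders export byte-identically after timestamp stripping", {
  ch <- fixture_chrom()
  style <- plot_style(show_baseline = TRUE, show_fraction_labels = TRUE)
  sel <- chrom_selection(fractions = c("5", "6"), volume_range = c(13, 15))
  f1 <- withr::local_tempfile(fileext = ".pdf")
  f2 <- withr::local_tempfile(fileext = ".pdf")
  export_figure(render_chromatogram(ch, style, sel), f1)
  export_figure(render_chromatogram(ch, style, sel), f2)
  expect_identical(fplcplot:::figure_bytes(f1), fplcplot:::figure_bytes(f2))

  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  export_figure(render_chromatogram(ch, style, sel), p1)
  export_figure(render_chromatogram(ch, style, sel), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("unsupported formats and unwritable paths fail cleanly", {
  fig <- render_chromatogram(fixture_chrom())
  expect_error(export_figure(fig, "out.svg"), "pdf, eps, tiff, png",
               class = "fplcplot_format_error")

  # unwritable destination: a directory that does not exist
  base <- withr::local_tempdir()
  target <- file.path(base, "no-such-dir", "fig.pdf")
  expect_error(export_figure(fig, target))
  expect_false(file.exists(target))
  expect_length(list.files(base, recursive = TRUE, all.files = TRUE, no.. = TRUE), 0L)
})
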