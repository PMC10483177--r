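# Rendering: a chromatogram + plot_style + chrom_selection -> ggplot figure.
#
# The figure is assembled as a decision tree over the style/selection flags:
# each enabled feature contributes exactly its documented layer(s), in a
# fixed order, so that the layer inventory of a figure is predictable and
# introspectable (see layer_inventory()).

curve_color <- function(style, curve) {
  nm <- curve$name
  if (nm %in% names(style$curve_colors)) return(style$curve_colors[[nm]])
  wl <- curve$wavelength_nm
  if (!is.na(wl) && as.character(wl) %in% names(style$curve_colors)) {
    return(style$curve_colors[[as.character(wl)]])
  }
  style$default_color
}

curve_df <- function(cv) data.frame(x = cv$x, y = cv$y)

#' Render a chromatogram into an annotated figure
#'
#' Draws, in order: optional filled areas under each curve; the curves in
#' their style colors (260 nm red, 280 nm blue by default); optional fitted
#' baselines (same color as their curve, dashed); the selected fraction
#' areas (purple by default) and the volume-range highlight, both
#' alpha-composited so overlaps show through; and the optional fraction
#' tick-and-label strip under the plot. A zoom window clips every layer.
#' Rendering is deterministic for a fixed input.
#'
#' @param chrom A [chromatogram()].
#' @param style A [plot_style()].
#' @param selection A [chrom_selection()]; its fraction labels must exist in
#'   the file (unknown labels raise an error listing the available ones).
#' @param baselines Baselines to draw when \code{style$show_baseline}:
#'   \code{NULL} (fit [fit_baseline_als()] with defaults to the primary
#'   curve), a character vector of curve names to fit, or a named list of
#'   ready [fit_baseline_als()] models aligned to the *normalized* curves.
#' @return A ggplot object; its layer roles are readable with
#'   [layer_inventory()].
#' @export
render_chromatogram <- function(chrom, style = plot_style(),
                                selection = chrom_selection(),
                                baselines = NULL) {
  if (!inherits(chrom, "chromatogram")) {
    fplc_stop("'chrom' must be a chromatogram", "fplcplot_precondition_error")
  }
  if (!inherits(style, "plot_style")) {
    fplc_stop("'style' must be a plot_style", "fplcplot_precondition_error")
  }
  if (!inherits(selection, "chrom_selection")) {
    fplc_stop("'selection' must be a chrom_selection", "fplcplot_precondition_error")
  }
  avail <- fraction_labels(chrom)
  missing <- setdiff(selection$fractions, avail)
  if (length(missing)) {
    fplc_stop(sprintf("unknown fraction label(s): %s. Available: %s",
                      paste(missing, collapse = ", "),
                      if (length(avail)) paste(avail, collapse = ", ") else "(none)"),
              "fplcplot_unknown_fraction")
  }

  norm_curves <- lapply(chrom$curves, normalize_curve, method = style$normalization)
  nchrom <- chromatogram(norm_curves, fraction_events = chrom$fraction_events,
                         injection_events = chrom$injection_events,
                         logbook = chrom$logbook, meta = chrom$meta)

  bmodels <- NULL
  if (style$show_baseline) {
    if (is.null(baselines)) baselines <- primary_curve(nchrom)$name
    if (is.character(baselines)) {
      unknown <- setdiff(baselines, names(nchrom$curves))
      if (length(unknown)) {
        fplc_stop(sprintf("unknown curve(s) for baseline: %s. Available: %s",
                          paste(unknown, collapse = ", "),
                          paste(names(nchrom$curves), collapse = ", ")),
                  "fplcplot_unknown_curve")
      }
      bmodels <- stats::setNames(
        lapply(baselines, function(nm) fit_baseline_als(nchrom$curves[[nm]])),
        baselines)
    } else if (is.list(baselines)) {
      bmodels <- baselines
    }
  }

  view <- apply_zoom(nchrom, selection, baselines = bmodels)

  layers <- list()
  roles <- character(0)
  add <- function(layer, role) {
    layers[[length(layers) + 1L]] <<- layer
    roles <<- c(roles, role)
  }

  # (1) fill under each curve
  if (style$fill_under_curve) {
    for (cv in view$curves) {
      add(ggplot2::geom_area(data = curve_df(cv),
                             ggplot2::aes(x = x, y = y),
                             fill = style$fill_color, alpha = style$fill_alpha),
          "fill")
    }
  }
  # (2) the curves
  for (cv in view$curves) {
    add(ggplot2::geom_line(data = curve_df(cv),
                           ggplot2::aes(x = x, y = y),
                           colour = curve_color(style, cv), linewidth = 0.6),
        "curve")
  }
  # (3) baselines, same color as their curve, dashed
  if (style$show_baseline && length(view$baselines)) {
    for (nm in names(view$baselines)) {
      bcv <- view$baselines[[nm]]
      add(ggplot2::geom_line(data = curve_df(bcv),
                             ggplot2::aes(x = x, y = y),
                             colour = curve_color(style, bcv),
                             linewidth = 0.5, linetype = "dashed"),
          "baseline")
    }
  }
  # (4) selected fraction areas + volume-range area (alpha-composited)
  pc <- primary_curve(nchrom)
  if (length(selection$fractions) && nrow(view$intervals)) {
    sel_iv <- view$intervals[view$intervals$label %in% selection$fractions, ,
                             drop = FALSE]
    for (i in seq_len(nrow(sel_iv))) {
      seg <- restrict_to_range(pc, sel_iv$start_ml[i], sel_iv$end_ml[i])
      add(ggplot2::geom_area(data = curve_df(seg),
                             ggplot2::aes(x = x, y = y),
                             fill = style$fraction_highlight_color,
                             alpha = style$fraction_highlight_alpha),
          "fraction_highlight")
    }
  }
  if (!is.null(view$volume_range)) {
    seg <- restrict_to_range(pc, view$volume_range[1L], view$volume_range[2L])
    add(ggplot2::geom_area(data = curve_df(seg),
                           ggplot2::aes(x = x, y = y),
                           fill = style$volume_highlight_color,
                           alpha = style$volume_highlight_alpha),
        "range_highlight")
  }

  # y extent of the drawn data, for strip placement and zoom
  ys <- unlist(lapply(view$curves, `[[`, "y"))
  ylo <- if (is.null(view$ylim)) min(ys) else view$ylim[1L]
  yhi <- if (is.null(view$ylim)) max(ys) else view$ylim[2L]
  dy <- max(yhi - ylo, .Machine$double.eps)
  ylim <- c(ylo, yhi)

  # (5) fraction tick marks + labels under the plot
  if (style$show_fraction_labels && nrow(view$intervals)) {
    strip_iv <- view$intervals
    if (length(selection$fractions)) {
      strip_iv <- strip_iv[strip_iv$label %in% selection$fractions, , drop = FALSE]
    }
    if (nrow(strip_iv)) {
      dx <- view$xlim[2L] - view$xlim[1L]
      rows <- strip_rows(strip_iv$start_ml, strip_iv$label, dx)
      tick_df <- data.frame(x = strip_iv$start_ml,
                            y0 = ylo - 0.02 * dy, y1 = ylo - 0.06 * dy)
      lab_df <- data.frame(x = strip_iv$start_ml,
                           y = ylo - (0.11 + 0.06 * (rows - 1L)) * dy,
                           label = strip_iv$label)
      add(ggplot2::geom_segment(data = tick_df,
                                ggplot2::aes(x = x, xend = x,
                                             y = y0, yend = y1),
                                colour = "grey30", linewidth = 0.4),
          "fraction_ticks")
      add(ggplot2::geom_text(data = lab_df,
                             ggplot2::aes(x = x, y = y,
                                          label = label),
                             size = 2.6, colour = "grey20"),
          "fraction_labels")
      ylim[1L] <- ylo - 0.20 * dy
    }
  }

  fig <- Reduce(`+`, layers,
                ggplot2::ggplot() +
                  ggplot2::labs(x = style$x_lab, y = style$y_lab) +
                  ggplot2::theme_classic())
  fig <- fig + ggplot2::coord_cartesian(xlim = view$xlim, ylim = ylim)
  attr(fig, "layer_inventory") <- roles
  fig
}

# Assign strip labels to row 1 or 2 so adjacent labels do not collide;
# deterministic width heuristic in x units.
strip_rows <- function(starts, labels, dx) {
  n <- length(starts)
  rows <- integer(n)
  last_end <- c(-Inf, -Inf)
  for (i in seq_len(n)) {
    w <- 0.012 * dx * max(nchar(labels[i]), 1L)
    r <- if (starts[i] - w / 2 >= last_end[1L]) 1L else 2L
    rows[i] <- r
    last_end[r] <- starts[i] + w / 2
  }
  rows
}

#' Layer roles of a rendered figure
#'
#' @param fig A figure from [render_chromatogram()].
#' @return Character vector naming the role of each layer, in drawing order
#'   (\code{"fill"}, \code{"curve"}, \code{"baseline"},
#'   \code{"fraction_highlight"}, \code{"range_highlight"},
#'   \code{"fraction_ticks"}, \code{"fraction_labels"}).
#' @export
layer_inventory <- function(fig) {
  inv <- attr(fig, "layer_inventory")
  if (is.null(inv)) {
    fplc_stop("not a figure produced by render_chromatogram()",
              "fplcplot_precondition_error")
  }
  inv
}

#' Export a figure to a publication-quality file
#'
#' Vector output as PDF or EPS (for lossless downstream editing), raster as
#' TIFF or PNG at the requested resolution (a 6 x 4 inch figure at 300 dpi
#' gives an 1800 x 1200 pixel raster). Files are written atomically: on
#' failure no partial file is left behind.
#'
#' @param fig A ggplot figure (e.g. from [render_chromatogram()]).
#' @param path Output path; the extension determines the format when
#'   \code{format} is \code{NULL}.
#' @param format \code{"pdf"}, \code{"eps"}, \code{"tiff"} or \code{"png"}.
#' @param width,height Figure size in inches.
#' @param dpi Raster resolution in dots per inch (tiff/png only).
#' @return The path, invisibly.
#' @export
export_figure <- function(fig, path, format = NULL, width = 6, height = 4,
                          dpi = 300) {
  supported <- c("pdf", "eps", "tiff", "png")
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% supported) {
    fplc_stop(sprintf("unsupported format '%s': supported formats are %s",
                      format, paste(supported, collapse = ", ")),
              "fplcplot_format_error")
  }
  if (!is_scalar_number(dpi) || dpi <= 0) {
    fplc_stop("'dpi' must be a positive number", "fplcplot_precondition_error")
  }
  atomic_write(path, function(tmp) {
    switch(format,
      pdf = grDevices::pdf(tmp, width = width, height = height,
                           onefile = FALSE, useDingbats = FALSE),
      eps = grDevices::postscript(tmp, width = width, height = height,
                                  horizontal = FALSE, onefile = FALSE,
                                  paper = "special"),
      tiff = grDevices::tiff(tmp, width = width, height = height,
                             units = "in", res = dpi, type = "cairo",
                             compression = "lzw"),
      png = grDevices::png(tmp, width = width, height = height,
                           units = "in", res = dpi, type = "cairo")
    )
    dev <- grDevices::dev.cur()
    on.exit(if (grDevices::dev.cur() == dev) grDevices::dev.off(dev), add = TRUE)
    print(fig)
  })
}

# File bytes with volatile device metadata (creation/modification timestamps
# in PDF and EPS headers) blanked, for byte-level reproducibility checks.
# Works at the byte level: PDF content streams may contain arbitrary binary.
figure_bytes <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdf", "eps", "ps")) {
    for (pat in c("/CreationDate (", "/ModDate (")) {
      raw <- blank_after_marker(raw, pat, terminator = as.raw(0x29)) # ')'
    }
    raw <- blank_after_marker(raw, "%%CreationDate:", terminator = as.raw(0x0A))
  }
  raw
}

blank_after_marker <- function(raw, marker, terminator) {
  pr <- charToRaw(marker)
  m <- length(pr); n <- length(raw)
  if (n < m) return(raw)
  starts <- which(raw == pr[1L])
  for (i in starts) {
    if (i + m - 1L > n || !identical(raw[i:(i + m - 1L)], pr)) next
    j <- i + m
    while (j <= n && raw[j] != terminator) {
      raw[j] <- as.raw(0x20)
      j <- j + 1L
    }
  }
  raw
}
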