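#' Plot style for chromatogram figures
#'
#' Everything about how a figure looks, kept separate from *what* is
#' selected in one particular file (see [chrom_selection()]). Styles persist
#' across files — [save_style()] / [load_style()] round-trip them exactly —
#' which supports plotting many similar figures with a uniform look, while
#' fraction selections are always restated per file.
#'
#' @param curve_colors Named color map applied per curve. Names are either
#'   wavelengths (\code{"260"}, \code{"280"}, \code{"230"}) or full curve
#'   names; defaults follow chromatography convention: 260 nm red, 280 nm
#'   blue.
#' @param default_color Color for curves the map does not cover.
#' @param fill_under_curve Fill the area under each curve? Off (transparent)
#'   by default.
#' @param fill_color,fill_alpha Fill color/alpha when \code{fill_under_curve}.
#' @param fraction_highlight_color,fraction_highlight_alpha Color (default
#'   purple) and alpha for the area under the curve of selected fractions.
#' @param volume_highlight_color,volume_highlight_alpha Color/alpha for the
#'   highlighted elution-volume range. Highlights are alpha-composited, so
#'   overlap of fraction and volume highlights shows through.
#' @param show_baseline Draw the fitted baseline (same color as its curve,
#'   dashed)?
#' @param show_fraction_labels Draw the fraction tick-and-label strip under
#'   the plot?
#' @param x_lab,y_lab Axis labels.
#' @param normalization Normalization applied to each curve before drawing;
#'   see [normalize_curve()].
#' @return An object of class \code{"plot_style"}.
#' @export
plot_style <- function(curve_colors = c("260" = "red", "280" = "blue"),
                       default_color = "grey30",
                       fill_under_curve = FALSE,
                       fill_color = "grey70", fill_alpha = 0.5,
                       fraction_highlight_color = "purple",
                       fraction_highlight_alpha = 0.45,
                       volume_highlight_color = "goldenrod",
                       volume_highlight_alpha = 0.35,
                       show_baseline = FALSE,
                       show_fraction_labels = FALSE,
                       x_lab = "Elution volume (ml)", y_lab = "mAU",
                       normalization = "shift_min_zero") {
  curve_colors <- unlist(curve_colors)
  all_colors <- c(curve_colors, default_color, fill_color,
                  fraction_highlight_color, volume_highlight_color)
  bad <- all_colors[!is_valid_color(all_colors)]
  if (length(bad)) {
    fplc_stop(sprintf("invalid color(s): %s (use a name from colours() or #RRGGBB)",
                      paste(unique(bad), collapse = ", ")),
              "fplcplot_invalid_style")
  }
  for (a in c(fill_alpha, fraction_highlight_alpha, volume_highlight_alpha)) {
    if (!is_scalar_number(a) || a <= 0 || a > 1) {
      fplc_stop("alpha values must lie in (0, 1]", "fplcplot_invalid_style")
    }
  }
  normalization <- match.arg(normalization, c("shift_min_zero", "minmax_01", "none"))
  structure(
    list(curve_colors = curve_colors, default_color = default_color,
         fill_under_curve = isTRUE(fill_under_curve),
         fill_color = fill_color, fill_alpha = fill_alpha,
         fraction_highlight_color = fraction_highlight_color,
         fraction_highlight_alpha = fraction_highlight_alpha,
         volume_highlight_color = volume_highlight_color,
         volume_highlight_alpha = volume_highlight_alpha,
         show_baseline = isTRUE(show_baseline),
         show_fraction_labels = isTRUE(show_fraction_labels),
         x_lab = as.character(x_lab), y_lab = as.character(y_lab),
         normalization = normalization),
    class = "plot_style"
  )
}

#' Per-file plot selections
#'
#' What to highlight in *this* chromatogram: selected fraction labels, an
#' elution-volume range, and a zoom window. Selections are deliberately not
#' persisted by [save_style()] — fractions are defined anew for every file —
#' so a config file containing selection keys is rejected.
#'
#' @param fractions Character vector of fraction labels to highlight (must
#'   exist in the file; checked at render time).
#' @param volume_range Optional \code{c(vmin, vmax)} elution-volume highlight.
#' @param zoom Optional zoom window \code{c(xmin, xmax)} or
#'   \code{c(xmin, xmax, ymin, ymax)}.
#' @return An object of class \code{"chrom_selection"}.
#' @export
chrom_selection <- function(fractions = character(0), volume_range = NULL,
                            zoom = NULL) {
  fractions <- as.character(fractions)
  if (!is.null(volume_range)) {
    volume_range <- as.numeric(volume_range)
    if (length(volume_range) != 2L || anyNA(volume_range) ||
        volume_range[1L] >= volume_range[2L]) {
      fplc_stop("volume_range must be c(vmin, vmax) with vmin < vmax",
                "fplcplot_invalid_selection")
    }
  }
  if (!is.null(zoom)) {
    zoom <- as.numeric(zoom)
    if (!length(zoom) %in% c(2L, 4L) || anyNA(zoom) || zoom[1L] >= zoom[2L] ||
        (length(zoom) == 4L && zoom[3L] >= zoom[4L])) {
      fplc_stop("zoom must be c(xmin, xmax) or c(xmin, xmax, ymin, ymax) with min < max",
                "fplcplot_invalid_selection")
    }
  }
  structure(list(fractions = fractions, volume_range = volume_range, zoom = zoom),
            class = "chrom_selection")
}

style_fields <- function() names(formals(plot_style))

selection_like_keys <- function() {
  c("fractions", "selected_fractions", "volume_range", "range", "zoom")
}

#' Save or load a plot style config
#'
#' The config is a flat, diff-friendly JSON file holding exactly the fields
#' of [plot_style()], at full numeric precision (round-trips exactly).
#' Selection keys (\code{fractions}, \code{volume_range}, \code{zoom}, ...)
#' are rejected on load: selections are per-file and never persisted.
#' Unknown keys are an error listing them, never silently ignored.
#'
#' @param style A [plot_style()].
#' @param path Config file path.
#' @return \code{save_style}: the path, invisibly. \code{load_style}: a
#'   [plot_style()].
#' @export
save_style <- function(style, path) {
  if (!inherits(style, "plot_style")) {
    fplc_stop("'style' must be a plot_style", "fplcplot_precondition_error")
  }
  fields <- unclass(style)
  fields$curve_colors <- as.list(fields$curve_colors)  # keep names in JSON
  atomic_write(path, function(tmp) {
    # digits = I(17): serialize doubles at full precision so alphas
    # round-trip exactly
    jsonlite::write_json(fields, tmp, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  })
}

#' @rdname save_style
#' @export
load_style <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(cfg)) {
    fplc_stop("style config must be a JSON object", "fplcplot_format_error")
  }
  keys <- names(cfg)
  sel <- intersect(keys, selection_like_keys())
  if (length(sel)) {
    fplc_stop(sprintf(
      "style config must not contain selection keys (%s): fractions, volume ranges and zoom are defined per file, not persisted with the style",
      paste(sel, collapse = ", ")), "fplcplot_config_error")
  }
  unknown <- setdiff(keys, style_fields())
  if (length(unknown)) {
    fplc_stop(sprintf("unknown style config key(s): %s (valid keys: %s)",
                      paste(unknown, collapse = ", "),
                      paste(style_fields(), collapse = ", ")),
              "fplcplot_config_error")
  }
  if (!is.null(cfg$curve_colors)) cfg$curve_colors <- unlist(cfg$curve_colors)
  do.call(plot_style, cfg)
}
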