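# Readers for Unicorn curve exports and the generic instrument template.
#
# Unicorn layout ("column pairing"): every curve or event owns an adjacent
# (x, y) column pair. Header row 1 carries one name per pair, header row 2 the
# units. Curves may have different lengths; short columns are padded with
# trailing empty cells. Event pairs are recognized by unit-row tokens:
# "(Fractions)", "Injection", "Logbook" (case-insensitive substring match).

split_cells <- function(line, delimiter) {
  # strsplit drops trailing empty fields; appending the delimiter keeps them
  cells <- strsplit(paste0(line, delimiter), delimiter, fixed = TRUE)[[1L]]
  cells
}

parse_cell_num <- function(cells, decimal_mark) {
  if (decimal_mark != ".") cells <- gsub(decimal_mark, ".", cells, fixed = TRUE)
  suppressWarnings(as.numeric(cells))
}

# Split lines into a padded character matrix (rows x columns).
as_cell_matrix <- function(lines, delimiter) {
  rows <- lapply(lines, split_cells, delimiter = delimiter)
  ncol <- max(lengths(rows))
  mat <- matrix("", nrow = length(rows), ncol = ncol)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    mat[i, seq_along(r)] <- r
  }
  trimws(mat)
}

# Trailing empty cells terminate a column's series; internal empties are
# ambiguous and rejected.
column_series <- function(col, what, col_idx) {
  nz <- which(nzchar(col))
  if (length(nz) == 0L) return(character(0))
  k <- nz[length(nz)]
  if (any(!nzchar(col[seq_len(k)]))) {
    bad <- which(!nzchar(col[seq_len(k)]))
    fplc_stop(sprintf("%s column %d has internal empty cells at data row(s) %s",
                      what, col_idx, paste(utils::head(bad, 5L), collapse = ", ")),
              "fplcplot_format_error")
  }
  col[seq_len(k)]
}

event_kind <- function(unit_label) {
  u <- tolower(unit_label)
  if (grepl("fraction", u, fixed = TRUE)) return("fraction")
  if (grepl("injection", u, fixed = TRUE)) return("injection")
  if (grepl("logbook", u, fixed = TRUE)) return("logbook")
  NA_character_
}

#' Read a Unicorn tab-separated curve export
#'
#' Parses the paired-column ASCII export written by Unicorn software: one
#' (volume, value) column pair per curve, plus fraction/injection/logbook
#' event pairs. Handles UTF-16 encoded files and comma-decimal locales via
#' [detect_dialect()].
#'
#' When the export contains several chromatograms (curve names prefixed
#' \code{"Chrom.1_"}, \code{"Chrom.2_"}, ...), only the first is kept, with a
#' warning.
#'
#' @param input Path to the export file, or a raw vector of its bytes.
#' @param dialect A [unicorn_dialect()]; auto-detected when \code{NULL}.
#' @return A [chromatogram()]. The \code{meta} field records the source path,
#'   the dialect used, the chromatogram id (when prefixed) and a
#'   \code{skipped_columns} character vector of header names that could not
#'   be mapped (also raised as warnings).
#' @examples
#' # a small synthetic export shipped with the package
#' f <- system.file("extdata", "synthetic_unicorn_export.txt", package = "fplcplot")
#' read_unicorn_txt(f)
#' @export
read_unicorn_txt <- function(input, dialect = NULL) {
  if (is.null(dialect)) dialect <- detect_dialect(input)
  dec <- decode_text(input)
  parse_paired_columns(dec$lines, dialect,
                       source = if (is.character(input)) input else NA_character_)
}

#' Read a Unicorn CSV curve export
#'
#' Same layout as the tab-separated export with the delimiter fixed to comma
#' or semicolon (semicolon goes with comma-decimal locales).
#'
#' @inheritParams read_unicorn_txt
#' @return A [chromatogram()], field-wise equal to what the .txt rendering of
#'   the same run parses to.
#' @export
read_unicorn_csv <- function(input, dialect = NULL) {
  if (is.null(dialect)) dialect <- detect_dialect(input)
  if (!dialect$delimiter %in% c(",", ";")) {
    fplc_stop("not a CSV export: delimiter is not ',' or ';'",
              "fplcplot_format_error")
  }
  read_unicorn_txt(input, dialect)
}

parse_paired_columns <- function(lines, dialect, source = NA_character_) {
  if (length(lines) < dialect$n_header_rows + 1L) {
    fplc_stop("file too short: need header rows plus at least one data row",
              "fplcplot_format_error")
  }
  mat <- as_cell_matrix(lines, dialect$delimiter)
  hdr1 <- mat[1L, ]
  hdr2 <- mat[2L, ]
  data <- mat[-(1:2), , drop = FALSE]
  ncol <- ncol(mat)
  if (ncol %% 2L == 1L) {
    mat <- cbind(mat, "")
    hdr1 <- c(hdr1, ""); hdr2 <- c(hdr2, "")
    data <- cbind(data, "")
    ncol <- ncol + 1L
  }

  pair_starts <- seq(1L, ncol, by = 2L)
  pair_name <- vapply(pair_starts, function(j) {
    if (nzchar(hdr1[j])) hdr1[j] else hdr1[j + 1L]
  }, character(1))

  # multi-chromatogram exports: keep the first id only
  chrom_id <- NA_character_
  prefixes <- regmatches(pair_name, regexpr("^Chrom\\.[0-9]+", pair_name))
  has_prefix <- grepl("^Chrom\\.[0-9]+[ _]", pair_name)
  keep_pair <- rep(TRUE, length(pair_starts))
  if (any(has_prefix)) {
    ids <- sub("^(Chrom\\.[0-9]+)[ _].*$", "\\1", pair_name[has_prefix])
    chrom_id <- ids[1L]
    other <- has_prefix & sub("^(Chrom\\.[0-9]+)[ _].*$", "\\1", pair_name) != chrom_id
    if (any(other)) {
      warning(sprintf("export contains multiple chromatograms; keeping '%s', skipping: %s",
                      chrom_id,
                      paste(unique(sub("^(Chrom\\.[0-9]+)[ _].*$", "\\1",
                                       pair_name[other])), collapse = ", ")),
              call. = FALSE)
      keep_pair[other] <- FALSE
    }
    pair_name[has_prefix] <- sub("^Chrom\\.[0-9]+[ _]+", "", pair_name[has_prefix])
  }

  curves <- list()
  fractions <- NULL
  injections <- NULL
  logbook <- NULL
  skipped <- character(0)

  for (k in seq_along(pair_starts)) {
    j <- pair_starts[k]
    name <- pair_name[k]
    xcol0 <- data[, j]
    ycol0 <- data[, j + 1L]
    if (!nzchar(name) && !any(nzchar(xcol0)) && !any(nzchar(ycol0))) next
    if (!keep_pair[k]) next
    if (!nzchar(name)) {
      warning(sprintf("unnamed column pair at columns %d-%d skipped", j, j + 1L),
              call. = FALSE)
      skipped <- c(skipped, sprintf("<unnamed pair at column %d>", j))
      next
    }
    xs <- column_series(xcol0, name, j)
    ys <- column_series(ycol0, name, j + 1L)
    if (length(xs) == 0L) {
      skipped <- c(skipped, name)
      warning(sprintf("column pair '%s' has no data; skipped", name), call. = FALSE)
      next
    }
    if (length(xs) != length(ys)) {
      fplc_stop(sprintf("column pair '%s': x and y series have different lengths (%d vs %d)",
                        name, length(xs), length(ys)), "fplcplot_format_error")
    }
    xv <- parse_cell_num(xs, dialect$decimal_mark)
    if (anyNA(xv)) {
      fplc_stop(sprintf("column pair '%s': non-numeric volume cells at data row(s) %s",
                        name, paste(utils::head(which(is.na(xv)), 5L), collapse = ", ")),
                "fplcplot_format_error")
    }
    kind <- event_kind(hdr2[j + 1L])
    yv <- parse_cell_num(ys, dialect$decimal_mark)
    if (is.na(kind) && anyNA(yv)) {
      # numeric x with text y but no recognized event token: keep as
      # logbook-like events rather than dropping the column silently
      kind <- "logbook"
      warning(sprintf("column pair '%s' has text values but no recognized event token; kept as logbook events",
                      name), call. = FALSE)
    }
    if (is.na(kind)) {
      curves[[length(curves) + 1L]] <-
        fplc_curve(name, xv, yv, x_unit = hdr2[j], y_unit = hdr2[j + 1L])
    } else if (kind == "fraction") {
      fr <- data.frame(start_ml = xv, label = ys, stringsAsFactors = FALSE)
      if (any(diff(fr$start_ml) <= 0)) {
        bad <- which(diff(fr$start_ml) <= 0) + 1L
        fplc_stop(sprintf("fraction volumes are not strictly increasing at row(s) %s",
                          paste(bad, collapse = ", ")), "fplcplot_format_error")
      }
      fractions <- rbind(fractions, fr)
    } else if (kind == "injection") {
      injections <- rbind(injections,
                          data.frame(volume_ml = xv, label = ys,
                                     stringsAsFactors = FALSE))
    } else {
      logbook <- rbind(logbook,
                       data.frame(volume_ml = xv, text = ys,
                                  stringsAsFactors = FALSE))
    }
  }

  if (length(curves) == 0L) {
    fplc_stop("no numeric curve column pairs found in file", "fplcplot_format_error")
  }
  chromatogram(curves, fraction_events = fractions,
               injection_events = injections, logbook = logbook,
               meta = list(source = source, dialect = dialect, id = chrom_id,
                           skipped_columns = skipped))
}

#' Read the generic instrument template
#'
#' For data from non-Unicorn instruments: a tab-separated file whose first
#' column is a shared elution-volume axis, followed by one column per curve
#' (row 1 names, row 2 units). An optional trailing column pair holds fraction
#' start volumes and labels, marked by \code{"(Fractions)"} in the unit row.
#' A blank copy is written by [write_template()] or the \code{template} CLI
#' command.
#'
#' @inheritParams read_unicorn_txt
#' @return A [chromatogram()] whose curves share the x column.
#' @examples
#' f <- system.file("extdata", "template_example.txt", package = "fplcplot")
#' read_template(f)
#' @export
read_template <- function(input) {
  dec <- decode_text(input)
  lines <- dec$lines
  if (length(lines) < 3L) {
    fplc_stop("template too short: need 2 header rows plus data",
              "fplcplot_format_error")
  }
  mat <- as_cell_matrix(lines, "\t")
  hdr1 <- mat[1L, ]
  hdr2 <- mat[2L, ]
  data <- mat[-(1:2), , drop = FALSE]

  xs <- column_series(data[, 1L], hdr1[1L], 1L)
  xv <- parse_cell_num(xs, ".")
  if (anyNA(xv)) {
    fplc_stop("template x column contains non-numeric cells", "fplcplot_format_error")
  }
  x_unit <- hdr2[1L]

  curves <- list()
  fractions <- NULL
  j <- 2L
  while (j <= ncol(mat)) {
    name <- hdr1[j]
    unit <- hdr2[j]
    col <- data[, j]
    if (!nzchar(name) && !any(nzchar(col))) { j <- j + 1L; next }
    if (j + 1L <= ncol(mat) && !is.na(event_kind(hdr2[j + 1L])) &&
        event_kind(hdr2[j + 1L]) == "fraction") {
      fs <- column_series(col, name, j)
      fl <- column_series(data[, j + 1L], name, j + 1L)
      if (length(fs) != length(fl)) {
        fplc_stop("template fraction columns have different lengths",
                  "fplcplot_format_error")
      }
      fractions <- data.frame(start_ml = parse_cell_num(fs, "."), label = fl,
                              stringsAsFactors = FALSE)
      j <- j + 2L
      next
    }
    ys <- column_series(col, name, j)
    yv <- parse_cell_num(ys, ".")
    if (anyNA(yv)) {
      fplc_stop(sprintf("template column '%s' contains non-numeric cells", name),
                "fplcplot_format_error")
    }
    if (length(yv) > length(xv)) {
      fplc_stop(sprintf("template column '%s' is longer than the x column", name),
                "fplcplot_format_error")
    }
    curves[[length(curves) + 1L]] <-
      fplc_curve(name, xv[seq_along(yv)], yv, x_unit = x_unit, y_unit = unit)
    j <- j + 1L
  }
  if (length(curves) == 0L) {
    fplc_stop("template contains no curve columns", "fplcplot_format_error")
  }
  chromatogram(curves, fraction_events = fractions,
               meta = list(source = if (is.character(input)) input else NA_character_,
                           dialect = unicorn_dialect(column_pairing = FALSE),
                           id = NA_character_, skipped_columns = character(0)))
}
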