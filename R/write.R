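# Writers emitting syntactically valid Unicorn-dialect files and the generic
# template. Numbers are printed with 10 significant digits so that a
# write -> parse round trip reproduces every field at print precision.

encode_and_write <- function(lines, path, encoding) {
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  atomic_write(path, function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con), add = TRUE)
    if (encoding == "utf-8") {
      writeBin(charToRaw(enc2utf8(txt)), con)
    } else if (encoding == "latin-1") {
      lat <- iconv(txt, from = "UTF-8", to = "latin1")
      if (is.na(lat)) {
        fplc_stop("content contains characters outside latin-1", "fplcplot_io_error")
      }
      writeBin(charToRaw(lat), con)
    } else {
      to <- if (encoding == "utf-16-le") "UTF-16LE" else "UTF-16BE"
      bom <- if (encoding == "utf-16-le") as.raw(c(0xFF, 0xFE)) else as.raw(c(0xFE, 0xFF))
      body <- iconv(enc2utf8(txt), from = "UTF-8", to = to, toRaw = TRUE)[[1L]]
      writeBin(c(bom, body), con)
    }
  })
}

pad_columns <- function(cols) {
  n <- max(lengths(cols))
  lapply(cols, function(cl) c(cl, rep("", n - length(cl))))
}

#' Write a chromatogram as a Unicorn-dialect curve export
#'
#' Emits the paired-column layout (see [read_unicorn_txt()]) in the requested
#' dialect; the written file re-parses to a field-wise equal chromatogram at
#' print precision (10 significant digits). Used to generate test fixtures
#' and to convert between dialects.
#'
#' @param chrom A [chromatogram()] with at least one curve.
#' @param path Output file path (written atomically).
#' @param dialect A [unicorn_dialect()] controlling encoding, delimiter and
#'   decimal mark.
#' @return The path, invisibly.
#' @export
write_unicorn_txt <- function(chrom, path, dialect = unicorn_dialect()) {
  if (!inherits(chrom, "chromatogram")) {
    fplc_stop("'chrom' must be a chromatogram", "fplcplot_precondition_error")
  }
  if (!inherits(dialect, "unicorn_dialect")) {
    fplc_stop("'dialect' must be a unicorn_dialect", "fplcplot_precondition_error")
  }
  if (length(chrom$curves) == 0L) {
    fplc_stop("chromatogram has no curves; nothing to write",
              "fplcplot_precondition_error")
  }
  hdr1 <- character(0); hdr2 <- character(0)
  cols <- list()
  add_pair <- function(name, xu, yu, xs, ys) {
    hdr1 <<- c(hdr1, name, "")
    hdr2 <<- c(hdr2, xu, yu)
    cols[[length(cols) + 1L]] <<- xs
    cols[[length(cols) + 1L]] <<- ys
  }
  for (cv in chrom$curves) {
    add_pair(cv$name, cv$x_unit, cv$y_unit,
             fmt_num(cv$x, dialect$decimal_mark),
             fmt_num(cv$y, dialect$decimal_mark))
  }
  if (nrow(chrom$fraction_events)) {
    add_pair("Fraction", "ml", "(Fractions)",
             fmt_num(chrom$fraction_events$start_ml, dialect$decimal_mark),
             chrom$fraction_events$label)
  }
  if (nrow(chrom$injection_events)) {
    add_pair("Injection", "ml", "Injection",
             fmt_num(chrom$injection_events$volume_ml, dialect$decimal_mark),
             chrom$injection_events$label)
  }
  if (nrow(chrom$logbook)) {
    add_pair("Run Log", "ml", "Logbook",
             fmt_num(chrom$logbook$volume_ml, dialect$decimal_mark),
             chrom$logbook$text)
  }
  cols <- pad_columns(cols)
  n <- length(cols[[1L]])
  rows <- vapply(seq_len(n), function(i) {
    paste(vapply(cols, `[[`, character(1), i), collapse = dialect$delimiter)
  }, character(1))
  lines <- c(paste(hdr1, collapse = dialect$delimiter),
             paste(hdr2, collapse = dialect$delimiter),
             rows)
  encode_and_write(lines, path, dialect$encoding)
}

#' Write a chromatogram in the generic template layout
#'
#' Requires all curves to share an identical x axis (the template has a
#' single shared volume column). Fraction marks, when present, are written as
#' a trailing (start, label) column pair.
#'
#' @inheritParams write_unicorn_txt
#' @return The path, invisibly.
#' @export
write_template <- function(chrom, path) {
  if (!inherits(chrom, "chromatogram") || length(chrom$curves) == 0L) {
    fplc_stop("'chrom' must be a chromatogram with at least one curve",
              "fplcplot_precondition_error")
  }
  x0 <- chrom$curves[[1L]]$x
  for (cv in chrom$curves) {
    if (length(cv$x) != length(x0) || any(cv$x != x0)) {
      fplc_stop("template layout requires all curves to share the same x axis",
                "fplcplot_precondition_error")
    }
  }
  hdr1 <- c("Volume", vapply(chrom$curves, `[[`, character(1), "name"))
  hdr2 <- c(chrom$curves[[1L]]$x_unit,
            vapply(chrom$curves, `[[`, character(1), "y_unit"))
  cols <- c(list(fmt_num(x0)),
            lapply(chrom$curves, function(cv) fmt_num(cv$y)))
  if (nrow(chrom$fraction_events)) {
    hdr1 <- c(hdr1, "Fraction", "")
    hdr2 <- c(hdr2, "ml", "(Fractions)")
    cols <- c(cols, list(fmt_num(chrom$fraction_events$start_ml),
                         chrom$fraction_events$label))
  }
  cols <- pad_columns(cols)
  n <- length(cols[[1L]])
  rows <- vapply(seq_len(n), function(i) {
    paste(vapply(cols, `[[`, character(1), i), collapse = "\t")
  }, character(1))
  lines <- c(paste(hdr1, collapse = "\t"), paste(hdr2, collapse = "\t"), rows)
  encode_and_write(lines, path, "utf-8")
}

#' Write a blank template for manual data entry
#'
#' Emits the generic template with example header rows and a handful of
#' placeholder data rows, ready to be filled in with data from any
#' instrument and read back with [read_template()].
#'
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_blank_template <- function(path) {
  lines <- c(
    "Volume\tUV 280\tUV 260\tFraction\t",
    "ml\tmAU\tmAU\tml\t(Fractions)",
    "0\t0\t0\t0.5\tA1",
    "0.5\t1\t0.6\t1\tA2",
    "1\t2\t1.2\t\t",
    "1.5\t1\t0.6\t\t",
    "2\t0\t0\t\t")
  encode_and_write(lines, path, "utf-8")
}
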