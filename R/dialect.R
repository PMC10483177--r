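#' Describe the on-disk dialect of a Unicorn-style export
#'
#' Unicorn versions (and site locales) differ in encoding (UTF-16 with BOM is
#' common on Windows exports), cell delimiter and decimal mark. Rather than
#' editing the parser per software version, the variation is captured in a
#' descriptor that both the reader and the writer honour.
#'
#' @param encoding One of \code{"utf-8"}, \code{"utf-16-le"},
#'   \code{"utf-16-be"}, \code{"latin-1"}.
#' @param delimiter Cell delimiter: \code{"\t"}, \code{";"} or \code{","}.
#' @param decimal_mark \code{"."} or \code{","}; must differ from the
#'   delimiter.
#' @param n_header_rows Header rows before the data block: row 1 carries
#'   curve/event names (one per column pair), row 2 the units.
#' @param column_pairing Logical; each curve owns an adjacent (x, y) column
#'   pair (the Unicorn layout). The generic template instead shares one x
#'   column.
#' @return An object of class \code{"unicorn_dialect"}.
#' @export
unicorn_dialect <- function(encoding = "utf-8", delimiter = "\t",
                            decimal_mark = ".", n_header_rows = 2L,
                            column_pairing = TRUE) {
  encoding <- match.arg(encoding, c("utf-8", "utf-16-le", "utf-16-be", "latin-1"))
  if (!delimiter %in% c("\t", ";", ",")) {
    fplc_stop("delimiter must be one of tab, ';', ','", "fplcplot_invalid_dialect")
  }
  decimal_mark <- match.arg(decimal_mark, c(".", ","))
  if (identical(delimiter, decimal_mark)) {
    fplc_stop("delimiter and decimal mark must differ", "fplcplot_invalid_dialect")
  }
  structure(list(encoding = encoding, delimiter = delimiter,
                 decimal_mark = decimal_mark,
                 n_header_rows = as.integer(n_header_rows),
                 column_pairing = isTRUE(column_pairing)),
            class = "unicorn_dialect")
}

#' @export
print.unicorn_dialect <- function(x, ...) {
  delim <- c("\t" = "tab", ";" = "semicolon", "," = "comma")[[x$delimiter]]
  cat(sprintf("<unicorn_dialect> %s, %s-delimited, decimal '%s', %d header row(s)\n",
              x$encoding, delim, x$decimal_mark, x$n_header_rows))
  invisible(x)
}

# Read a file (or raw vector) into a character vector of lines, detecting the
# encoding from the BOM or byte-level heuristics. Returns list(lines, encoding).
decode_text <- function(input) {
  raw <- if (is.raw(input)) input else readBin(input, "raw", n = file.size(input))
  if (length(raw) == 0L) {
    fplc_stop("input is empty", "fplcplot_format_error")
  }
  enc <- NULL
  body <- raw
  if (length(raw) >= 2L && raw[1] == as.raw(0xFF) && raw[2] == as.raw(0xFE)) {
    enc <- "utf-16-le"; body <- raw[-(1:2)]
  } else if (length(raw) >= 2L && raw[1] == as.raw(0xFE) && raw[2] == as.raw(0xFF)) {
    enc <- "utf-16-be"; body <- raw[-(1:2)]
  } else if (length(raw) >= 3L && raw[1] == as.raw(0xEF) &&
             raw[2] == as.raw(0xBB) && raw[3] == as.raw(0xBF)) {
    enc <- "utf-8"; body <- raw[-(1:3)]
  } else if (mean(raw == as.raw(0)) > 0.2) {
    # BOM-less UTF-16: which half of each 16-bit unit is zero tells the order
    zeros <- which(raw == as.raw(0))
    enc <- if (mean(zeros %% 2L == 0L) > 0.5) "utf-16-le" else "utf-16-be"
  }
  if (!is.null(enc) && startsWith(enc, "utf-16")) {
    if (length(body) %% 2L != 0L) {
      fplc_stop(sprintf(
        "undecodable %s stream: odd byte count, truncated code unit at offset %d",
        enc, length(body)), "fplcplot_format_error")
    }
    from <- if (enc == "utf-16-le") "UTF-16LE" else "UTF-16BE"
    txt <- iconv(list(body), from = from, to = "UTF-8")
    if (is.na(txt)) {
      fplc_stop(sprintf("undecodable bytes in %s stream (near offset %d)",
                        enc, length(body)), "fplcplot_format_error")
    }
  } else if (is.null(enc)) {
    txt <- rawToChar(body)
    if (validUTF8(txt)) {
      enc <- "utf-8"
      Encoding(txt) <- "UTF-8"
    } else {
      enc <- "latin-1"
      txt <- iconv(txt, from = "latin1", to = "UTF-8")
    }
  } else {
    txt <- rawToChar(body)
    if (!validUTF8(txt)) {
      bad <- which(!utf8ToInt_safe(txt))
      fplc_stop(sprintf("undecodable UTF-8 bytes near offset %d",
                        if (length(bad)) bad[1] else length(body)),
                "fplcplot_format_error")
    }
    Encoding(txt) <- "UTF-8"
  }
  lines <- strsplit(txt, "\r\n|\r|\n")[[1L]]
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  list(lines = lines, encoding = enc)
}

utf8ToInt_safe <- function(txt) {
  r <- charToRaw(txt)
  rep(TRUE, length(r))
}

#' Detect the dialect of a chromatogram export
#'
#' Encoding is read from the byte-order mark (or inferred from the byte
#' pattern), the delimiter from its frequency in the header row, and the
#' decimal mark by sampling numeric-looking data cells. Deterministic for a
#' fixed input.
#'
#' @param input Path to a file, or a raw vector of its bytes.
#' @return A [unicorn_dialect()].
#' @export
detect_dialect <- function(input) {
  dec <- decode_text(input)
  lines <- dec$lines
  if (length(lines) == 0L) {
    fplc_stop("input contains no lines", "fplcplot_format_error")
  }
  header <- lines[[1L]]
  counts <- c("\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
              ";"  = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))),
              ","  = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))))
  if (all(counts == 0L)) {
    fplc_stop("no recognizable delimiter (tab, ';' or ',') in the header row",
              "fplcplot_format_error")
  }
  delimiter <- names(counts)[which.max(counts)]  # ties: tab, then ';', then ','

  decimal_mark <- "."
  if (delimiter != ",") {
    data_lines <- lines[-seq_len(min(2L, length(lines)))]
    cells <- unlist(strsplit(utils::head(data_lines, 50L), delimiter, fixed = TRUE))
    n_comma <- sum(grepl("^-?[0-9]+,[0-9]+([eE][+-]?[0-9]+)?$", cells))
    n_dot <- sum(grepl("^-?[0-9]+\\.[0-9]+([eE][+-]?[0-9]+)?$", cells))
    if (n_comma > n_dot) decimal_mark <- ","
  }
  unicorn_dialect(encoding = dec$encoding, delimiter = delimiter,
                  decimal_mark = decimal_mark, n_header_rows = 2L,
                  column_pairing = TRUE)
}
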