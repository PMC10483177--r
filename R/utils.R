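# Internal helpers shared across the package.

fplc_stop <- function(msg, class = "fplcplot_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "fplcplot_error", "error", "condition")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

#' @noRd
is_valid_color <- function(x) {
  if (!is.character(x)) return(rep(FALSE, length(x)))
  vapply(x, function(col) {
    if (is.na(col) || !nzchar(col)) return(FALSE)
    if (grepl("^#([0-9A-Fa-f]{6}|[0-9A-Fa-f]{8})$", col)) return(TRUE)
    col %in% grDevices::colours()
  }, logical(1), USE.NAMES = FALSE)
}

# Format a number for file output: round-trippable, locale-independent.
fmt_num <- function(x, decimal_mark = ".") {
  s <- sprintf("%.10g", x)
  if (decimal_mark != ".") s <- gsub(".", decimal_mark, s, fixed = TRUE)
  s
}

# Write lines atomically: a partially written file is never left at `path`.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  tmp <- tempfile(pattern = ".fplc", tmpdir = dir)
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    fplc_stop(sprintf("could not move temporary file into place at '%s'", path),
              "fplcplot_io_error")
  }
  ok <- TRUE
  invisible(path)
}
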