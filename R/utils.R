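# Case-fold + trim + collapse internal whitespace; the canonical key form for
# every table lookup in the package (terms, taxon labels, environment strings).
fold_key <- function(x) {
  stringr::str_squish(stringr::str_to_lower(as.character(x)))
}

ts_abort <- function(message, class, ...) {
  abort(message, class = c(class, "traitsynth_error"), ...)
}

ts_stopifnot_cols <- function(df, cols, what, class = "traitsynth_validation_error") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    ts_abort(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = class
    )
  }
  invisible(df)
}

# readr wrapper with quiet, reproducible defaults used for every CSV the
# package reads; all key columns are read as character and typed explicitly.
ts_read_csv <- function(path, col_types = readr::cols(.default = readr::col_character())) {
  if (!file.exists(path)) {
    ts_abort(sprintf("file not found: %s", path), class = "traitsynth_io_error")
  }
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  locale = readr::locale(encoding = "UTF-8"))
}

ts_write_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}
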