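#' Hierarchical environment labels
#'
#' Isolation-source information is harmonized into a hierarchical scheme of
#' up to four underscore-joined levels of increasing specificity: `"host"`,
#' `"host_animal"`, `"host_animal_endotherm"`,
#' `"host_animal_endotherm_intestinal"`.  These helpers parse, render and
#' validate such labels.
#'
#' @param label Character vector of rendered labels.
#' @return `env_label_parse()` returns a list of character vectors (one per
#'   label, `NA` labels give `character(0)`); `env_label_depth()` an integer
#'   vector; `env_label_render()` a character vector.
#' @export
#' @examples
#' env_label_depth("host_animal_endotherm_intestinal")
env_label_parse <- function(label) {
  lapply(as.character(label), function(x) {
    if (is.na(x) || x == "") return(character(0))
    stringr::str_split_1(x, stringr::fixed("_"))
  })
}

#' @rdname env_label_parse
#' @param levels Character vector of level terms (1 to 4, all non-empty).
#' @export
env_label_render <- function(levels) {
  if (length(levels) == 0) return(NA_character_)
  paste(levels, collapse = "_")
}

#' @rdname env_label_parse
#' @export
env_label_depth <- function(label) {
  lengths(env_label_parse(label))
}

validate_env_labels <- function(labels) {
  parsed <- env_label_parse(labels)
  ok <- vapply(parsed, function(p) {
    length(p) >= 1 && length(p) <= 4 && all(nzchar(p))
  }, logical(1))
  blank <- is.na(labels) | labels == ""
  bad <- !ok & !blank
  if (any(bad)) {
    ts_abort(sprintf("invalid environment label(s): %s",
                     paste(unique(labels[bad]), collapse = ", ")),
             class = "traitsynth_table_error")
  }
  invisible(labels)
}

#' Concatenate per-source environment fields into one raw string
#'
#' All columns of a source that carry environment information are joined into
#' a single comma-separated string (separator `", "`, source column order,
#' blank fields dropped) — the key the environment translation table is
#' indexed by.
#'
#' @param ... Character vectors (the environment columns, recycled to equal
#'   length), or a single data frame of them.
#' @return Character vector of concatenated strings (`NA` where all fields
#'   are blank).
#' @export
concat_environment <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.data.frame(dots[[1]])) dots <- as.list(dots[[1]])
  if (length(dots) == 0) return(character(0))
  m <- do.call(cbind, lapply(dots, as.character))
  apply(m, 1, function(row) {
    row <- stringr::str_trim(row[!is.na(row) & stringr::str_trim(row) != ""])
    if (length(row) == 0) NA_character_ else paste(row, collapse = ", ")
  })
}

#' Translate raw environment strings into hierarchical labels
#'
#' The translation table maps exact concatenated strings (compared after
#' trimming and case folding) to their curated label.  Untranslated strings
#' yield a blank label and are returned in the `untranslated` report for
#' later curation; they are never passed through.
#'
#' @param raw Character vector of concatenated environment strings, or a list
#'   of character vectors of per-column fields (concatenated internally with
#'   [concat_environment()]).
#' @param env_map Data frame with columns `string`, `label`.
#' @return A list with `label` (character vector; `NA` where blank or
#'   untranslated) and `untranslated` (tibble `string`, `n`).
#' @export
#' @examples
#' m <- data.frame(string = "soil, rice paddy", label = "soil_agricultural")
#' translate_environment(list(c("soil", "rice paddy")), m)$label
translate_environment <- function(raw, env_map) {
  if (is.list(raw) && !is.data.frame(raw)) {
    raw <- vapply(raw, function(fields) {
      fields <- stringr::str_trim(as.character(fields))
      fields <- fields[!is.na(fields) & fields != ""]
      if (length(fields) == 0) NA_character_ else paste(fields, collapse = ", ")
    }, character(1))
  }
  env_map <- as_tibble(env_map)
  ts_stopifnot_cols(env_map, c("string", "label"), "environment translation table",
                    class = "traitsynth_table_error")
  validate_env_labels(env_map$label)
  label <- env_map$label[match(fold_key(raw), fold_key(env_map$string))]
  blank <- is.na(raw) | fold_key(raw) == ""
  label[blank] <- NA_character_
  missed <- raw[is.na(label) & !blank]
  untranslated <- tibble(string = missed) |>
    dplyr::count(.data$string, name = "n") |>
    arrange(dplyr::desc(.data$n), .data$string)
  list(label = label, untranslated = untranslated)
}
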