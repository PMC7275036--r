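#' Apply the scripted corrections table
#'
#' Datum-specific fixes (wrong units, misspellings, superseded values) are
#' scripted as a corrections table so every change is transparent and
#' reproducible.  A correction matches exactly the cells whose dataset,
#' taxon, trait and current value equal its key; each matching cell is
#' replaced (or blanked, when the corrected value is empty) exactly once.
#' The log records every application, and corrections that matched nothing
#' are logged with a warning — they usually indicate the table needs
#' maintenance after an upstream source changed.
#'
#' Values of numeric traits are compared with a small relative tolerance
#' (1e-6) so that unit-converted floating-point values match the value a
#' curator read off the emitted table.
#'
#' @param table A combined record-level tibble (see [combine()]).
#' @param corrections Data frame with columns
#'   `dataset,taxon,trait,original,corrected,comment,reference`.
#' @return A list: `table` (corrected tibble) and `log` (one row per
#'   correction: key columns plus `n_matched`).
#' @export
apply_corrections <- function(table, corrections) {
  if (is.null(corrections) || nrow(corrections) == 0) {
    return(list(table = table,
                log = tibble(dataset = character(), taxon = character(),
                             trait = character(), original = character(),
                             corrected = character(), n_matched = integer())))
  }
  corrections <- as_tibble(corrections)
  ts_stopifnot_cols(corrections, c("dataset", "taxon", "trait", "original",
                                   "corrected"), "corrections table",
                    class = "traitsynth_table_error")
  log <- corrections[, c("dataset", "taxon", "trait", "original", "corrected")]
  log$n_matched <- 0L

  for (i in seq_len(nrow(corrections))) {
    cr <- corrections[i, ]
    if (!cr$trait %in% names(table)) next
    col <- table[[cr$trait]]
    hit <- table$dataset == cr$dataset &
      as.character(table$taxon_id) == as.character(cr$taxon)
    if (is.numeric(col)) {
      orig <- suppressWarnings(as.numeric(cr$original))
      hit <- hit & !is.na(col) & !is.na(orig) &
        abs(col - orig) <= 1e-6 * pmax(1, abs(orig))
      new <- if (is.na(cr$corrected) || cr$corrected == "") NA_real_ else {
        v <- suppressWarnings(as.numeric(cr$corrected))
        if (is.na(v)) {
          ts_abort(sprintf("correction %d: non-numeric replacement '%s' for numeric trait %s",
                           i, cr$corrected, cr$trait),
                   class = "traitsynth_table_error")
        }
        v
      }
    } else {
      hit <- hit & !is.na(col) & as.character(col) == cr$original
      new <- if (is.na(cr$corrected) || cr$corrected == "") NA_character_ else cr$corrected
    }
    nm <- sum(hit, na.rm = TRUE)
    log$n_matched[i] <- nm
    if (nm == 0) {
      warn(sprintf("correction matched no cells: %s / taxon %s / %s = '%s'",
                   cr$dataset, cr$taxon, cr$trait, cr$original))
    } else {
      table[[cr$trait]][which(hit)] <- new
    }
  }
  list(table = table, log = log)
}

# Normalize every categorical trait column of a combined table against the
# schema vocabularies; multiset cells (comma-separated term lists) are
# normalized per term and re-rendered as a sorted unique ", " join.
normalize_table_terms <- function(table, schema) {
  reports <- list()
  if (!"row_id" %in% names(table)) table$row_id <- seq_len(nrow(table))
  for (trait in schema$traits$name) {
    if (!trait %in% names(table)) next
    dtype <- trait_dtype(schema, trait)
    if (!is_categorical_dtype(dtype)) next
    if (dtype == "multiset_categorical") {
      parts <- stringr::str_split(table[[trait]], stringr::fixed(","))
      res <- lapply(parts, function(p) {
        if (length(p) == 1 && is.na(p)) return(list(value = NA_character_, unmapped = character(0)))
        norm <- normalize_term(stringr::str_trim(p), trait, schema)
        un <- stringr::str_trim(p)[attr(norm, "unmapped")]
        kept <- sort(unique(norm[!is.na(norm)]))
        list(value = if (length(kept)) paste(kept, collapse = ", ") else NA_character_,
             unmapped = un)
      })
      new <- vapply(res, `[[`, character(1), "value")
      unmapped_terms <- lapply(res, `[[`, "unmapped")
      has_un <- lengths(unmapped_terms) > 0
      if (any(has_un)) {
        reports[[trait]] <- tibble(
          row_id = rep(table$row_id[has_un], lengths(unmapped_terms[has_un])),
          dataset = rep(table$dataset[has_un], lengths(unmapped_terms[has_un])),
          trait = trait,
          raw = unlist(unmapped_terms[has_un]))
      }
      table[[trait]] <- new
    } else {
      norm <- normalize_term(table[[trait]], trait, schema)
      un <- attr(norm, "unmapped")
      if (any(un)) {
        reports[[trait]] <- tibble(row_id = table$row_id[un],
                                   dataset = table$dataset[un],
                                   trait = trait,
                                   raw = table[[trait]][un])
      }
      table[[trait]] <- as.character(norm)
    }
  }
  list(table = table,
       unmapped = if (length(reports)) bind_rows(reports) else
         tibble(row_id = integer(), dataset = character(),
                trait = character(), raw = character()))
}

#' Build the deduplicated reference table
#'
#' Identical reference strings collapse to a single entry; `ref_id` is a
#' deterministic sequence over the sorted unique reference strings, so
#' reruns on identical inputs give identical ids.
#'
#' @param references Character vector of reference strings.
#' @param ref_type Character vector of reference types, parallel to
#'   `references`.
#' @return A tibble `(ref_id, reference, ref_type)`.
#' @export
build_reference_table <- function(references, ref_type) {
  stopifnot(length(references) == length(ref_type))
  u <- tibble(reference = references, ref_type = ref_type) |>
    distinct(.data$reference, .keep_all = TRUE) |>
    arrange(.data$reference)
  u$ref_id <- seq_len(nrow(u))
  u[, c("ref_id", "reference", "ref_type")]
}

#' Condense traits: normalize terms, translate environments, apply
#' corrections, attach reference ids
#'
#' The record-level condensation stage.  Categorical values are mapped onto
#' the controlled vocabularies (unmapped raw terms are blanked and reported,
#' never passed through), concatenated environment strings are translated
#' into hierarchical isolation-source labels, the corrections table is
#' applied on the normalized values, and each row's reference is replaced by
#' an id into the deduplicated reference table.
#'
#' @param table A combined tibble from [combine()].
#' @param schema A [trait_schema].
#' @param env_map Optional environment translation table `(string, label)`.
#' @param corrections Optional corrections table (see [apply_corrections()]).
#' @return A list of class `condensed_traits`: `table` (record-level tibble
#'   with `ref_id`), `references` (tibble `ref_id,reference,ref_type`) and
#'   `reports` (`unmapped_terms`, `untranslated_env`, `corrections_log`).
#' @export
condense_traits <- function(table, schema = default_schema(), env_map = NULL,
                            corrections = NULL) {
  if (nrow(table) > 0 && any(is.na(table$reference) | table$reference == "")) {
    ts_abort("record without a reference reached condense_traits",
             class = "traitsynth_integrity_error")
  }

  norm <- normalize_table_terms(table, schema)
  table <- norm$table

  untranslated <- tibble(string = character(), n = integer())
  if ("isolation_source" %in% names(table) && !is.null(env_map)) {
    tr <- translate_environment(table$isolation_source, env_map)
    table$isolation_source <- tr$label
    untranslated <- tr$untranslated
  } else if ("isolation_source" %in% names(table)) {
    # no translation table: raw strings must not leak through
    untranslated <- tibble(string = table$isolation_source[!is.na(table$isolation_source)]) |>
      dplyr::count(.data$string, name = "n")
    table$isolation_source <- NA_character_
  }

  corr <- apply_corrections(table, corrections)
  table <- corr$table

  refs <- build_reference_table(table$reference, table$ref_type)
  table$ref_id <- refs$ref_id[match(table$reference, refs$reference)]
  table <- select(table, -"reference", -"ref_type") |>
    relocate("ref_id", .after = dplyr::last_col())

  structure(
    list(table = table, references = refs,
         reports = list(unmapped_terms = norm$unmapped,
                        untranslated_env = untranslated,
                        corrections_log = corr$log)),
    class = "condensed_traits"
  )
}

#' @export
print.condensed_traits <- function(x, ...) {
  cat(sprintf("<condensed_traits> %d records, %d references; %d unmapped terms, %d untranslated environments, %d corrections\n",
              nrow(x$table), nrow(x$references),
              nrow(x$reports$unmapped_terms), nrow(x$reports$untranslated_env),
              sum(x$reports$corrections_log$n_matched)))
  invisible(x)
}
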