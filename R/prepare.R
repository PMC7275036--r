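#' Split number-range strings into min, max and unit
#'
#' Raw sources often encode measurements as ranges in free text, e.g.
#' `"10-20 µm"`.  Such strings are split into a minimum, a maximum and the
#' unit string; single values yield `min == max`, and the unit may be empty.
#' Hyphen and en-dash separators, decimals and surrounding whitespace are
#' accepted.  Unparseable strings are flagged (`ok = FALSE`) and keep their
#' original text so they can be logged and excluded downstream — they never
#' become silent `NA`s.
#'
#' @param raw Character vector.
#' @return A tibble with columns `raw`, `min`, `max`, `unit`, `ok`.
#' @export
#' @examples
#' split_range(c("10-20 µm", "3.5 µm", "big-ish"))
split_range <- function(raw) {
  raw <- as.character(raw)
  s <- stringr::str_trim(ifelse(is.na(raw), "", raw))
  num <- "[+-]?[0-9]*\\.?[0-9]+"
  m_range <- stringr::str_match(
    s, paste0("^(", num, ")\\s*[-–—]\\s*(", num, ")\\s*(.*)$"))
  m_single <- stringr::str_match(s, paste0("^(", num, ")\\s*(.*)$"))

  min <- as.numeric(m_range[, 2])
  max <- as.numeric(m_range[, 3])
  unit <- stringr::str_trim(m_range[, 4])
  single <- is.na(m_range[, 1]) & !is.na(m_single[, 1])
  min[single] <- as.numeric(m_single[single, 2])
  max[single] <- min[single]
  unit[single] <- stringr::str_trim(m_single[single, 3])

  ok <- !is.na(min) & !is.na(max) & nchar(s) > 0
  # a "unit" containing digits means the numeric part was not fully consumed
  ok[ok & stringr::str_detect(unit, "[0-9]")] <- FALSE
  min[!ok] <- NA_real_
  max[!ok] <- NA_real_
  unit[!ok] <- NA_character_
  tibble(raw = raw, min = min, max = max, unit = unit,
         ok = ok & !is.na(raw))
}

#' Read a per-source preparation spec
#'
#' Preparation of each raw source is declarative: a YAML file states the
#' dataset name, which column holds the organism label (or a ready taxon id),
#' how raw columns map onto schema traits (with their units), which columns
#' are range strings to be split, which columns carry environment
#' information, and where the reference comes from.
#'
#' @param path Path to a YAML preparation spec.
#' @return The spec as a named list (class `prep_spec`).
#' @export
read_prep_spec <- function(path) {
  if (!file.exists(path)) {
    ts_abort(sprintf("preparation spec not found: %s", path),
             class = "traitsynth_io_error")
  }
  spec <- yaml::read_yaml(path)
  as_prep_spec(spec)
}

#' @rdname read_prep_spec
#' @param spec A list with the same structure as the YAML file.
#' @export
as_prep_spec <- function(spec) {
  if (inherits(spec, "prep_spec")) return(spec)
  if (is.null(spec$dataset) || !nzchar(spec$dataset)) {
    ts_abort("preparation spec needs a 'dataset' name",
             class = "traitsynth_config_error")
  }
  if (is.null(spec$taxon$column) && is.null(spec$taxon$id_column)) {
    ts_abort("preparation spec needs taxon: column or taxon: id_column",
             class = "traitsynth_config_error")
  }
  if (is.null(spec$reference$column) && is.null(spec$reference$constant)) {
    ts_abort("preparation spec needs reference: column or reference: constant",
             class = "traitsynth_config_error")
  }
  structure(spec, class = c("prep_spec", "list"))
}

infer_ref_type <- function(reference) {
  dplyr::case_when(
    stringr::str_starts(reference, "10\\.") ~ "doi",
    stringr::str_starts(reference, stringr::regex("PRJ", ignore_case = TRUE)) ~ "bioproject",
    TRUE ~ "full_text"
  )
}

spec_columns <- function(spec) {
  cols <- c(spec$taxon$column, spec$taxon$id_column, spec$reference$column,
            unlist(spec$environment$columns))
  for (t in spec$traits) {
    cols <- c(cols, t$column, t$unit_column)
  }
  for (r in spec$ranges) cols <- c(cols, r$column)
  unique(cols)
}

#' Standardize one raw source table
#'
#' Applies a [preparation spec][read_prep_spec] to a raw table: renames raw
#' columns onto schema traits, splits range strings, converts numeric values
#' to canonical units, concatenates environment columns, resolves taxon
#' labels through the offline mapping table and attaches a reference (with
#' inferred type) to every record.  Rows whose taxon cannot be resolved, or
#' that lack a reference, are quarantined with a reason rather than silently
#' dropped; unparseable numeric values are logged in `parse_failures` and
#' excluded.
#'
#' @param raw A data frame (one row per observation).
#' @param spec A `prep_spec` (or list coercible via [as_prep_spec()]).
#' @param mapping Taxon mapping table `(label, taxon_id)`; not needed when
#'   the spec supplies ready ids via `taxon: id_column`.
#' @param schema A [trait_schema].
#' @return A list of class `prepared_dataset`: `records` (tibble with
#'   `dataset`, `source_row`, `taxon_id`, `reference`, `ref_type` and one
#'   column per covered trait, numeric traits in canonical units),
#'   `quarantine` (tibble `dataset,row,reason`) and `parse_failures`
#'   (tibble `dataset,row,column,value`).  `nrow(records) + nrow(quarantine)`
#'   equals `nrow(raw)`.
#' @export
prepare_dataset <- function(raw, spec, mapping = NULL, schema = default_schema()) {
  spec <- as_prep_spec(spec)
  raw <- as_tibble(raw)
  missing_cols <- setdiff(spec_columns(spec), names(raw))
  if (length(missing_cols) > 0) {
    ts_abort(sprintf("preparation spec for '%s' references absent column(s): %s",
                     spec$dataset, paste(missing_cols, collapse = ", ")),
             class = "traitsynth_config_error")
  }

  n <- nrow(raw)
  out <- tibble(dataset = rep(spec$dataset, n), source_row = seq_len(n))
  failures <- list()
  log_failure <- function(column, rows, values) {
    if (length(rows) == 0) return()
    failures[[length(failures) + 1]] <<- tibble(
      dataset = spec$dataset, row = rows, column = column,
      value = as.character(values))
  }

  # --- taxon ids -----------------------------------------------------------
  if (!is.null(spec$taxon$id_column)) {
    out$taxon_id <- as.character(raw[[spec$taxon$id_column]])
    out$taxon_id[out$taxon_id == ""] <- NA_character_
  } else {
    if (is.null(mapping)) {
      ts_abort("a taxon mapping table is required when the spec uses taxon: column",
               class = "traitsynth_config_error")
    }
    out$taxon_id <- resolve_taxon(raw[[spec$taxon$column]], mapping)
  }

  # --- reference -----------------------------------------------------------
  if (!is.null(spec$reference$constant)) {
    out$reference <- rep(as.character(spec$reference$constant), n)
  } else {
    out$reference <- stringr::str_trim(as.character(raw[[spec$reference$column]]))
    out$reference[is.na(out$reference)] <- ""
  }
  out$ref_type <- if (!is.null(spec$reference$type)) {
    rep(spec$reference$type, n)
  } else {
    infer_ref_type(out$reference)
  }

  # --- directly mapped trait columns --------------------------------------
  for (trait in names(spec$traits)) {
    tdef <- trait_def(schema, trait)  # errors on unknown trait
    tspec <- spec$traits[[trait]]
    vals <- raw[[tspec$column]]
    if (tdef$dtype == "numeric") {
      chr <- stringr::str_trim(as.character(vals))
      num <- suppressWarnings(as.numeric(chr))
      bad <- which(!is.na(chr) & chr != "" & is.na(num))
      log_failure(tspec$column, bad, chr[bad])
      unit <- if (!is.null(tspec$unit_column)) {
        as.character(raw[[tspec$unit_column]])
      } else {
        tspec$unit %||% ""
      }
      out[[trait]] <- convert_unit(num, unit, trait, schema)
    } else {
      v <- stringr::str_trim(as.character(vals))
      v[v == ""] <- NA_character_
      out[[trait]] <- v
    }
  }

  # --- range columns -------------------------------------------------------
  for (r in spec$ranges) {
    parts <- split_range(raw[[r$column]])
    present <- !is.na(raw[[r$column]]) & stringr::str_trim(as.character(raw[[r$column]])) != ""
    bad <- which(present & !parts$ok)
    log_failure(r$column, bad, raw[[r$column]][bad])
    unit <- ifelse(parts$ok & parts$unit != "", parts$unit, r$unit %||% "")
    out[[r$min]] <- convert_unit(parts$min, unit, r$min, schema)
    out[[r$max]] <- convert_unit(parts$max, unit, r$max, schema)
  }

  # --- environment columns -------------------------------------------------
  if (!is.null(spec$environment$columns)) {
    out$isolation_source <- concat_environment(
      raw[, unlist(spec$environment$columns), drop = FALSE])
  }

  # only schema traits (plus record metadata) are retained, in schema order
  trait_cols <- intersect(schema$traits$name, names(out))
  out <- out[, c("dataset", "source_row", "taxon_id", "reference", "ref_type",
                 trait_cols)]

  # --- quarantine ----------------------------------------------------------
  reason <- rep(NA_character_, n)
  reason[is.na(out$taxon_id)] <- "unresolved taxon"
  reason[is.na(reason) & out$reference == ""] <- "missing reference"
  quarantine <- tibble(dataset = spec$dataset,
                       row = which(!is.na(reason)),
                       reason = reason[!is.na(reason)])
  records <- out[is.na(reason), ]

  structure(
    list(records = records, quarantine = quarantine,
         parse_failures = if (length(failures)) bind_rows(failures) else
           tibble(dataset = character(), row = integer(),
                  column = character(), value = character())),
    class = "prepared_dataset"
  )
}

#' @export
print.prepared_dataset <- function(x, ...) {
  cat(sprintf("<prepared_dataset> %s: %d records, %d quarantined, %d parse failures\n",
              x$records$dataset[1] %||% "?", nrow(x$records),
              nrow(x$quarantine), nrow(x$parse_failures)))
  invisible(x)
}
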