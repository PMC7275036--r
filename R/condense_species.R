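#' Aggregate the record-level table to one row per species
#'
#' All records of a species — including its strain-level records, which map
#' upward through the lineage — are condensed into a single row.  Rows not
#' resolved to a recognised species (placeholder epithets such as `"sp."`,
#' or rows outside the active taxonomy) are excluded first.  Each trait is
#' then condensed by the operation its data type prescribes:
#' * numeric traits: mean, sample standard deviation and record count,
#'   written as `<trait>`, `<trait>.stdev`, `<trait>.count`
#'   ([aggregate_numeric()]);
#' * plain categorical traits: strict-majority consensus
#'   ([condense_binary()]);
#' * multilevel categorical traits: the specificity-aware cascade
#'   ([condense_multilevel()]);
#' * multiset traits: sorted union of observed terms;
#' * isolation source: per-level hierarchical consensus
#'   ([condense_isolation()]).
#'
#' `ref_ids` collects the reference ids of all contributing records.
#'
#' @param condensed A `condensed_traits` object, or its record-level tibble.
#' @param schema A [trait_schema].
#' @return A tibble of class `species_aggregate` with one row per species:
#'   the seven lineage columns, the condensed trait columns in schema order,
#'   and `ref_ids`.
#' @export
condense_species <- function(condensed, schema = default_schema()) {
  table <- if (inherits(condensed, "condensed_traits")) condensed$table else
    as_tibble(condensed)
  ts_stopifnot_cols(table, c("species", "dataset"), "record-level table")

  keep <- is_species_resolved(table$species)
  if ("in_taxonomy" %in% names(table)) keep <- keep & table$in_taxonomy
  table <- table[keep, ]

  lineage_cols <- intersect(lineage_ranks(), names(table))
  skeleton <- table |>
    arrange(.data$species) |>
    distinct(.data$species, .keep_all = TRUE) |>
    select(all_of(lineage_cols))

  if (nrow(table) == 0) {
    out <- skeleton
    for (trait in schema$traits$name) {
      dtype <- trait_dtype(schema, trait)
      if (dtype == "numeric") {
        out[[trait]] <- numeric(0)
        out[[paste0(trait, ".stdev")]] <- numeric(0)
        out[[paste0(trait, ".count")]] <- integer(0)
      } else {
        out[[trait]] <- character(0)
      }
    }
    out$ref_ids <- character(0)
  } else {
    groups <- split(table, table$species)
    rows <- lapply(groups, function(g) condense_one_species(g, schema))
    out <- bind_rows(rows)
    out <- left_join(skeleton["species"], out, by = "species") |>
      left_join(skeleton, by = "species") |>
      relocate(all_of(lineage_cols), .before = 1)
  }
  class(out) <- c("species_aggregate", class(out))
  out
}

condense_one_species <- function(g, schema) {
  row <- list(species = g$species[1])
  for (trait in schema$traits$name) {
    dtype <- trait_dtype(schema, trait)
    vals <- if (trait %in% names(g)) g[[trait]] else
      rep(NA, nrow(g))
    if (dtype == "numeric") {
      agg <- aggregate_numeric(as.numeric(vals))
      row[[trait]] <- agg$mean
      row[[paste0(trait, ".stdev")]] <- agg$stdev
      row[[paste0(trait, ".count")]] <- agg$count
    } else if (dtype == "binary_categorical") {
      row[[trait]] <- condense_binary(vals)
    } else if (dtype == "multilevel_categorical") {
      row[[trait]] <- condense_multilevel(vals, vocab_for(schema, trait))
    } else if (dtype == "multiset_categorical") {
      row[[trait]] <- condense_multiset(vals)
    } else if (dtype == "hierarchical_label") {
      row[[trait]] <- condense_isolation(vals)
    }
  }
  row$ref_ids <- if ("ref_id" %in% names(g)) {
    paste(sort(unique(g$ref_id)), collapse = "; ")
  } else {
    NA_character_
  }
  as_tibble(row)
}

#' Fill species-level gaps from a curated auxiliary table
#'
#' Reference works (Bergey's Manual and similar) hold trait detail that is
#' not stored as a dataset; a curated gap-fill table
#' `(species, trait, value, reference)` supplies such values at the final
#' stage.  Fills apply only to blank cells — observed values are never
#' overwritten — and every fill is logged with its reference.  Numeric fills
#' set the value with a count of 1 and a blank standard deviation.
#'
#' @param aggregates A `species_aggregate` tibble from [condense_species()].
#' @param fill_table Data frame `(species, trait, value, reference)`.
#' @param schema A [trait_schema].
#' @return A list: `aggregates` (filled tibble) and `log` (tibble
#'   `species,trait,value,reference,status` with status `filled`,
#'   `already_set` or `species_absent`).
#' @export
gap_fill <- function(aggregates, fill_table, schema = default_schema()) {
  empty_log <- tibble(species = character(), trait = character(),
                      value = character(), reference = character(),
                      status = character())
  if (is.null(fill_table) || nrow(fill_table) == 0) {
    return(list(aggregates = aggregates, log = empty_log))
  }
  fill_table <- as_tibble(fill_table)
  ts_stopifnot_cols(fill_table, c("species", "trait", "value", "reference"),
                    "gap-fill table", class = "traitsynth_table_error")
  logs <- fill_table
  logs$status <- NA_character_

  for (i in seq_len(nrow(fill_table))) {
    f <- fill_table[i, ]
    j <- match(f$species, aggregates$species)
    if (is.na(j)) {
      logs$status[i] <- "species_absent"
      warn(sprintf("gap fill for absent species ignored: %s / %s", f$species, f$trait))
      next
    }
    dtype <- trait_dtype(schema, f$trait)
    if (!is.na(aggregates[[f$trait]][j])) {
      logs$status[i] <- "already_set"
      next
    }
    if (dtype == "numeric") {
      v <- suppressWarnings(as.numeric(f$value))
      if (is.na(v)) {
        ts_abort(sprintf("gap fill %d: non-numeric value '%s' for numeric trait %s",
                         i, f$value, f$trait), class = "traitsynth_table_error")
      }
      aggregates[[f$trait]][j] <- v
      aggregates[[paste0(f$trait, ".count")]][j] <- 1L
      aggregates[[paste0(f$trait, ".stdev")]][j] <- NA_real_
    } else if (dtype == "hierarchical_label") {
      validate_env_labels(f$value)
      aggregates[[f$trait]][j] <- f$value
    } else {
      norm <- normalize_term(f$value, f$trait, schema)
      if (is.na(norm)) {
        ts_abort(sprintf("gap fill %d: value '%s' not in the %s vocabulary",
                         i, f$value, f$trait), class = "traitsynth_table_error")
      }
      aggregates[[f$trait]][j] <- as.character(norm)
    }
    logs$status[i] <- "filled"
  }
  list(aggregates = aggregates, log = logs)
}
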