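#' Union prepared sources into one sparse record-level table
#'
#' All prepared records are stacked into a single sparse table with zero
#' overlap: no rows are merged, observations of the same taxon from different
#' sources stay independent rows.  The dataset name and reference travel with
#' every row, and the seven-rank lineage of each record's taxon is mapped on
#' under the supplied taxonomy.  Rows are put into a canonical order (dataset
#' name, then source row) and numbered with `row_id`, so the output is
#' byte-reproducible regardless of the order sources are given in.
#'
#' Taxon ids the active taxonomy does not contain (e.g. NCBI taxa a
#' GTDB-style taxonomy does not accept) keep their trait values but get empty
#' lineages and `in_taxonomy = FALSE`; they are excluded later when that
#' taxonomy's data products are emitted.
#'
#' @param sources A list of prepared sources — `prepared_dataset` objects or
#'   bare record tibbles as produced by [prepare_dataset()].
#' @param taxonomy A [taxonomy] object.
#' @param schema A [trait_schema] (fixes trait column order).
#' @return A tibble with columns `row_id`, `dataset`, `source_row`,
#'   `taxon_id`, the seven lineage ranks, `in_taxonomy`, the trait columns in
#'   schema order, `reference` and `ref_type`.  Row count equals the sum of
#'   the input record counts.
#' @export
combine <- function(sources, taxonomy, schema = default_schema()) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  if (inherits(sources, "prepared_dataset") || is.data.frame(sources)) {
    sources <- list(sources)
  }
  records <- lapply(sources, function(s) {
    if (inherits(s, "prepared_dataset")) s$records else as_tibble(s)
  })
  tbl <- bind_rows(records)
  if (nrow(tbl) == 0) {
    tbl <- tibble(dataset = character(), source_row = integer(),
                  taxon_id = character(), reference = character(),
                  ref_type = character())
  }
  ts_stopifnot_cols(tbl, c("dataset", "source_row", "taxon_id", "reference",
                           "ref_type"), "prepared records")
  if (any(is.na(tbl$dataset) | tbl$dataset == "") ||
      any(is.na(tbl$reference) | tbl$reference == "")) {
    ts_abort("every combined row needs a dataset and a reference",
             class = "traitsynth_validation_error")
  }

  tbl <- arrange(tbl, .data$dataset, .data$source_row)
  tbl$row_id <- seq_len(nrow(tbl))
  if (anyDuplicated(tbl$row_id)) {
    ts_abort("internal error: duplicate row_id", class = "traitsynth_internal_error")
  }

  known <- tbl$taxon_id %in% taxonomy$taxon_id
  lin <- lineage_table(taxonomy)
  tbl <- left_join(tbl, lin, by = "taxon_id")
  tbl$in_taxonomy <- known

  trait_cols <- intersect(schema$traits$name, names(tbl))
  tbl[, c("row_id", "dataset", "source_row", "taxon_id", lineage_ranks(),
          "in_taxonomy", trait_cols, "reference", "ref_type")]
}
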