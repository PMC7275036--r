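#' Workflow configuration
#'
#' A workflow config names the raw sources (data CSV plus preparation spec),
#' the taxonomy node tables (NCBI-style and/or GTDB-style), the taxon
#' mapping table, and the curation tables (environment translation,
#' corrections, gap fill), with optional overrides for the shipped schema
#' files.  Paths in the YAML are resolved relative to the config file.
#'
#' @param path Path to a workflow config YAML.
#' @return A `workflow_config` list with absolute paths, validated to exist.
#' @export
load_workflow_config <- function(path) {
  if (!file.exists(path)) {
    ts_abort(sprintf("workflow config not found: %s", path),
             class = "traitsynth_io_error")
  }
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  }
  for (i in seq_along(cfg$sources)) {
    cfg$sources[[i]]$data <- resolve(cfg$sources[[i]]$data)
    cfg$sources[[i]]$spec <- resolve(cfg$sources[[i]]$spec)
  }
  cfg$taxonomies$ncbi <- resolve(cfg$taxonomies$ncbi)
  cfg$taxonomies$gtdb <- resolve(cfg$taxonomies$gtdb)
  cfg$mapping <- resolve(cfg$mapping)
  for (t in names(cfg$tables)) cfg$tables[[t]] <- resolve(cfg$tables[[t]])
  for (t in names(cfg$schema)) cfg$schema[[t]] <- resolve(cfg$schema[[t]])
  validate_workflow_config(cfg)
}

validate_workflow_config <- function(cfg) {
  if (length(cfg$sources) == 0) {
    ts_abort("workflow config lists no sources", class = "traitsynth_config_error")
  }
  if (is.null(cfg$taxonomies$ncbi) && is.null(cfg$taxonomies$gtdb)) {
    ts_abort("workflow config must name at least one taxonomy (ncbi and/or gtdb)",
             class = "traitsynth_config_error")
  }
  paths <- c(
    unlist(lapply(cfg$sources, function(s) c(s$data, s$spec))),
    cfg$taxonomies$ncbi, cfg$taxonomies$gtdb, cfg$mapping,
    unlist(cfg$tables), unlist(cfg$schema))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    ts_abort(sprintf("workflow config references missing file(s): %s",
                     paste(missing, collapse = ", ")),
             class = "traitsynth_config_error")
  }
  structure(cfg, class = c("workflow_config", "list"))
}

workflow_schema <- function(cfg) {
  load_schema(cfg$schema$traits, cfg$schema$vocabulary, cfg$schema$translations)
}

workflow_taxonomies <- function(cfg, taxonomy = "both") {
  choices <- c("ncbi", "gtdb")
  wanted <- if (taxonomy == "both") choices else taxonomy
  configured <- wanted[vapply(wanted, function(t) !is.null(cfg$taxonomies[[t]]),
                              logical(1))]
  skipped <- setdiff(wanted, configured)
  for (t in skipped) {
    message(sprintf("taxonomy '%s' not configured; its data products are skipped", t))
  }
  if (length(configured) == 0) {
    ts_abort("none of the requested taxonomies is configured",
             class = "traitsynth_config_error")
  }
  configured
}

# readr column specification for a prepared/combined table, from the schema
table_col_types <- function(schema) {
  cols <- list(row_id = readr::col_integer(),
               source_row = readr::col_integer(),
               ref_id = readr::col_integer(),
               in_taxonomy = readr::col_logical())
  for (i in seq_len(nrow(schema$traits))) {
    nm <- schema$traits$name[i]
    if (schema$traits$dtype[i] == "numeric") {
      cols[[nm]] <- readr::col_double()
      cols[[paste0(nm, ".stdev")]] <- readr::col_double()
      cols[[paste0(nm, ".count")]] <- readr::col_integer()
    } else {
      cols[[nm]] <- readr::col_character()
    }
  }
  do.call(readr::cols, c(cols, list(.default = readr::col_character())))
}

# read a pipeline table, applying the schema column spec only to the columns
# actually present (avoids spurious parser warnings on stage intermediates)
read_pipeline_csv <- function(path, schema) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               col_types = readr::cols(.default = readr::col_character())))
  spec <- table_col_types(schema)
  spec$cols <- spec$cols[intersect(names(spec$cols), hdr)]
  ts_read_csv(path, col_types = spec)
}

stage_paths <- function(out_dir) {
  list(
    stage = file.path(out_dir, "stage"),
    logs = file.path(out_dir, "logs"),
    prepared = function(ds) file.path(out_dir, "stage", sprintf("prepared_%s.csv", ds)),
    combined = function(tax) file.path(out_dir, "stage", sprintf("combined_%s.csv", tax)),
    traits = function(tax) file.path(out_dir, sprintf("condensed_traits_%s.csv", toupper(tax))),
    species = function(tax) file.path(out_dir, sprintf("condensed_species_%s.csv", toupper(tax))),
    references = file.path(out_dir, "references.csv")
  )
}

#' Pipeline stages
#'
#' The four stages of the workflow, each reading its upstream artifacts from
#' `out_dir` and writing its own there, so that composing
#' `stage_prepare() |> stage_combine() |> stage_condense_traits() |>
#' stage_condense_species()` is exactly what [run_workflow()] does.
#' Downstream stages raise a dependency error when an upstream artifact is
#' missing.
#'
#' @param config A `workflow_config` (or path to one).
#' @param out_dir Output directory.
#' @param taxonomy `"ncbi"`, `"gtdb"` or `"both"`.
#' @return Invisibly, the paths written.
#' @name stages
NULL

as_workflow_config <- function(config) {
  if (inherits(config, "workflow_config")) config else load_workflow_config(config)
}

#' @rdname stages
#' @export
stage_prepare <- function(config, out_dir) {
  cfg <- as_workflow_config(config)
  schema <- workflow_schema(cfg)
  mapping <- if (!is.null(cfg$mapping)) ts_read_csv(cfg$mapping)
  sp <- stage_paths(out_dir)
  quarantines <- list()
  failures <- list()
  written <- character(0)
  for (s in cfg$sources) {
    spec <- read_prep_spec(s$spec)
    raw <- ts_read_csv(s$data)
    prep <- prepare_dataset(raw, spec, mapping, schema)
    ts_write_csv(prep$records, sp$prepared(spec$dataset))
    written <- c(written, sp$prepared(spec$dataset))
    quarantines[[spec$dataset]] <- prep$quarantine
    failures[[spec$dataset]] <- prep$parse_failures
  }
  ts_write_csv(bind_rows(quarantines), file.path(sp$logs, "quarantine.csv"))
  ts_write_csv(bind_rows(failures), file.path(sp$logs, "parse_failures.csv"))
  invisible(written)
}

#' @rdname stages
#' @export
stage_combine <- function(config, out_dir, taxonomy = "both") {
  cfg <- as_workflow_config(config)
  schema <- workflow_schema(cfg)
  sp <- stage_paths(out_dir)
  datasets <- vapply(cfg$sources, function(s) read_prep_spec(s$spec)$dataset,
                     character(1))
  prepared_paths <- vapply(datasets, sp$prepared, character(1))
  if (!all(file.exists(prepared_paths))) {
    ts_abort(sprintf("stage 'combine' needs prepared records; missing: %s (run the prepare stage first)",
                     paste(prepared_paths[!file.exists(prepared_paths)], collapse = ", ")),
             class = "traitsynth_dependency_error")
  }
  records <- lapply(prepared_paths, read_pipeline_csv, schema = schema)
  written <- character(0)
  for (tax in workflow_taxonomies(cfg, taxonomy)) {
    taxset <- read_taxonomy(cfg$taxonomies[[tax]], dialect = tax)
    combined <- combine(records, taxset, schema)
    ts_write_csv(combined, sp$combined(tax))
    written <- c(written, sp$combined(tax))
  }
  invisible(written)
}

#' @rdname stages
#' @export
stage_condense_traits <- function(config, out_dir, taxonomy = "both") {
  cfg <- as_workflow_config(config)
  schema <- workflow_schema(cfg)
  sp <- stage_paths(out_dir)
  env_map <- if (!is.null(cfg$tables$env_map)) ts_read_csv(cfg$tables$env_map)
  corrections <- if (!is.null(cfg$tables$corrections)) ts_read_csv(cfg$tables$corrections)
  written <- character(0)
  for (tax in workflow_taxonomies(cfg, taxonomy)) {
    if (!file.exists(sp$combined(tax))) {
      ts_abort(sprintf("stage 'condense-traits' needs %s (run the combine stage first)",
                       sp$combined(tax)),
               class = "traitsynth_dependency_error")
    }
    combined <- read_pipeline_csv(sp$combined(tax), schema)
    ct <- condense_traits(combined, schema, env_map = env_map,
                          corrections = corrections)
    product <- ct$table |>
      filter(.data$in_taxonomy) |>
      select(-"in_taxonomy", -"source_row")
    ts_write_csv(product, sp$traits(tax))
    ts_write_csv(ct$references, sp$references)
    ts_write_csv(ct$reports$unmapped_terms,
                 file.path(sp$logs, sprintf("unmapped_terms_%s.csv", tax)))
    ts_write_csv(ct$reports$untranslated_env,
                 file.path(sp$logs, sprintf("untranslated_env_%s.csv", tax)))
    ts_write_csv(ct$reports$corrections_log,
                 file.path(sp$logs, sprintf("corrections_log_%s.csv", tax)))
    written <- c(written, sp$traits(tax), sp$references)
  }
  invisible(written)
}

#' @rdname stages
#' @export
stage_condense_species <- function(config, out_dir, taxonomy = "both") {
  cfg <- as_workflow_config(config)
  schema <- workflow_schema(cfg)
  sp <- stage_paths(out_dir)
  gap_tbl <- if (!is.null(cfg$tables$gap_fill)) ts_read_csv(cfg$tables$gap_fill)
  written <- character(0)
  for (tax in workflow_taxonomies(cfg, taxonomy)) {
    if (!file.exists(sp$traits(tax))) {
      ts_abort(sprintf("stage 'condense-species' needs %s (run the condense-traits stage first)",
                       sp$traits(tax)),
               class = "traitsynth_dependency_error")
    }
    records <- read_pipeline_csv(sp$traits(tax), schema)
    agg <- condense_species(records, schema)
    filled <- gap_fill(agg, gap_tbl, schema)
    ts_write_csv(filled$aggregates, sp$species(tax))
    ts_write_csv(filled$log, file.path(sp$logs, sprintf("gap_fill_log_%s.csv", tax)))
    written <- c(written, sp$species(tax))
  }
  invisible(written)
}

#' Run the full workflow
#'
#' Orchestrates prepare, combine, condense-traits and condense-species under
#' one config, emitting the data products — `condensed_traits_NCBI.csv`,
#' `condensed_traits_GTDB.csv`, `references.csv`,
#' `condensed_species_NCBI.csv`, `condensed_species_GTDB.csv` (per
#' configured taxonomy) — together with curation logs and a run manifest of
#' input/output checksums.  The pipeline itself has no randomness: reruns on
#' identical inputs produce byte-identical outputs.
#'
#' @param config A `workflow_config` or path to a config YAML.
#' @param out_dir Output directory (created if needed).
#' @param taxonomy Which taxonomy's products to build: `"both"` (default;
#'   taxonomies absent from the config are skipped with a notice), `"ncbi"`
#'   or `"gtdb"`.
#' @return A `workflow_result`: `products` (named list of output tibbles),
#'   `paths`, `reports` (log tibbles) and `manifest`.
#' @export
run_workflow <- function(config, out_dir, taxonomy = c("both", "ncbi", "gtdb")) {
  taxonomy <- match.arg(taxonomy)
  cfg <- as_workflow_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- stage_paths(out_dir)

  stage_prepare(cfg, out_dir)
  stage_combine(cfg, out_dir, taxonomy)
  stage_condense_traits(cfg, out_dir, taxonomy)
  stage_condense_species(cfg, out_dir, taxonomy)

  taxa <- workflow_taxonomies(cfg, taxonomy)
  paths <- c(
    setNames(vapply(taxa, sp$traits, character(1)),
             sprintf("condensed_traits_%s", toupper(taxa))),
    references = sp$references,
    setNames(vapply(taxa, sp$species, character(1)),
             sprintf("condensed_species_%s", toupper(taxa))))
  schema <- workflow_schema(cfg)
  products <- lapply(paths, read_pipeline_csv, schema = schema)

  input_paths <- c(unlist(lapply(cfg$sources, function(s) c(s$data, s$spec))),
                   cfg$taxonomies$ncbi, cfg$taxonomies$gtdb, cfg$mapping,
                   unlist(cfg$tables), unlist(cfg$schema))
  manifest <- list(
    tool = "traitsynth",
    version = as.character(utils::packageVersion("traitsynth")),
    taxonomies = taxa,
    inputs = as.list(tools::md5sum(sort(unname(input_paths)))),
    outputs = as.list(tools::md5sum(unname(paths)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  log_files <- list.files(sp$logs, full.names = TRUE)
  reports <- lapply(setNames(log_files, tools::file_path_sans_ext(basename(log_files))),
                    ts_read_csv)

  structure(
    list(products = products, paths = paths, reports = reports,
         manifest = manifest, out_dir = out_dir),
    class = "workflow_result"
  )
}

#' @export
print.workflow_result <- function(x, ...) {
  cat(sprintf("<workflow_result> %d data products in %s\n",
              length(x$products), x$out_dir))
  for (nm in names(x$products)) {
    cat(sprintf("  %-24s %6d rows\n", nm, nrow(x$products[[nm]])))
  }
  invisible(x)
}

#' Write a generated fixture to disk as workflow inputs
#'
#' Serialises a [fixture_set][generate_fixture] into the CSV/YAML files the
#' workflow consumes (raw sources, preparation specs, taxonomies, mapping,
#' curation tables, the planted truth for inspection) and a ready
#' `config.yaml`.
#'
#' @param fixture A `fixture_set`.
#' @param dir Directory to write into.
#' @return The path of the written config YAML.
#' @export
write_fixture_inputs <- function(fixture, dir) {
  stopifnot(inherits(fixture, "fixture_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rel_sources <- list()
  for (nm in names(fixture$sources)) {
    ts_write_csv(fixture$sources[[nm]], file.path(dir, "sources", paste0(nm, ".csv")))
    spec_path <- file.path(dir, "specs", paste0(nm, ".yaml"))
    dir.create(dirname(spec_path), recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(fixture$prep_specs[[nm]]), spec_path)
    rel_sources[[length(rel_sources) + 1]] <- list(
      data = file.path("sources", paste0(nm, ".csv")),
      spec = file.path("specs", paste0(nm, ".yaml")))
  }
  ts_write_csv(fixture$taxonomy_ncbi, file.path(dir, "taxonomy_ncbi.csv"))
  ts_write_csv(fixture$taxonomy_gtdb, file.path(dir, "taxonomy_gtdb.csv"))
  ts_write_csv(fixture$mapping, file.path(dir, "mapping.csv"))
  ts_write_csv(fixture$env_map, file.path(dir, "tables", "env_map.csv"))
  ts_write_csv(fixture$corrections, file.path(dir, "tables", "corrections.csv"))
  ts_write_csv(fixture$gap_fill, file.path(dir, "tables", "gap_fill.csv"))
  ts_write_csv(fixture$truth$species, file.path(dir, "truth", "truth_species.csv"))
  ts_write_csv(fixture$truth$records, file.path(dir, "truth", "truth_records.csv"))
  cfg <- list(
    sources = rel_sources,
    taxonomies = list(ncbi = "taxonomy_ncbi.csv", gtdb = "taxonomy_gtdb.csv"),
    mapping = "mapping.csv",
    tables = list(env_map = file.path("tables", "env_map.csv"),
                  corrections = file.path("tables", "corrections.csv"),
                  gap_fill = file.path("tables", "gap_fill.csv")))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
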