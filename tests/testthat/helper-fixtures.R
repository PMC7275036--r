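# Small hand-built taxonomy used across taxonomy/combine tests:
# root -> Bacteria -> Firmicutes -> Bacilli -> Bacillales -> Bacillaceae ->
# Bacillus -> {B. subtilis (+ strain 168), B. sp.}
test_taxonomy_nodes <- function() {
  tibble::tribble(
    ~taxon_id, ~parent_id, ~rank,          ~name,
    "1",       "1",        "no rank",      "root",
    "2",       "1",        "superkingdom", "Bacteria",
    "3",       "2",        "phylum",       "Firmicutes",
    "4",       "3",        "class",        "Bacilli",
    "5",       "4",        "order",        "Bacillales",
    "6",       "5",        "family",       "Bacillaceae",
    "7",       "6",        "genus",        "Bacillus",
    "8",       "7",        "species",      "Bacillus subtilis",
    "9",       "8",        "strain",       "Bacillus subtilis 168",
    "10",      "7",        "species",      "Bacillus sp."
  )
}

test_taxonomy <- function() taxonomy(test_taxonomy_nodes())

test_mapping <- function() {
  tibble::tibble(
    label = c("Bacillus subtilis", "Bacillus subtilis 168", "Bacillus sp."),
    taxon_id = c("8", "9", "10"))
}

# a minimal raw source + prep spec pair for prepare/combine tests
test_raw_source <- function() {
  tibble::tibble(
    organism = c("Bacillus subtilis", " bacillus subtilis 168 ",
                 "Bacillus sp.", "Unknownia fakeii"),
    cell_size = c("10-20 µm", "3.5 µm", "1-2 µm", "big-ish"),
    temp = c(37, 30, 25, 20),
    oxygen = c("aerobe", "obligate aerobic", "Anaerobe", "aerobic"),
    habitat = c("soil", "soil, rice paddy", "marine", "soil"))
}

test_prep_spec <- function() {
  as_prep_spec(list(
    dataset = "srcT",
    taxon = list(column = "organism"),
    reference = list(constant = "10.1000/test.doi"),
    environment = list(columns = list("habitat")),
    traits = list(growth_tmp = list(column = "temp"),
                  metabolism = list(column = "oxygen")),
    ranges = list(list(column = "cell_size", min = "d1_lo", max = "d1_up",
                       unit = "µm"))))
}

# One full-size fixture pipeline run, shared (lazily) across test files so
# the suite pays for it once.
.ts_test_cache <- new.env(parent = emptyenv())

fixture_pipeline_run <- function(seed = 1, config = list()) {
  key <- paste0("run_", seed, "_", paste(unlist(config), collapse = "_"))
  if (is.null(.ts_test_cache[[key]])) {
    fx <- generate_fixture(config, seed = seed)
    dir <- file.path(tempdir(), paste0("tsfix_", abs(seed)))
    unlink(dir, recursive = TRUE)
    cfg <- write_fixture_inputs(fx, dir)
    res <- suppressMessages(suppressWarnings(
      run_workflow(cfg, file.path(dir, "out"))))
    .ts_test_cache[[key]] <- list(fixture = fx, dir = dir, config_path = cfg,
                                  result = res)
  }
  .ts_test_cache[[key]]
}
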