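test_that("the workflow emits the five data products with the expected headers", {
  run <- fixture_pipeline_run(seed = 1)
  res <- run$result
  expect_setequal(names(res$products),
                  c("condensed_traits_NCBI", "condensed_traits_GTDB",
                    "references", "condensed_species_NCBI",
                    "condensed_species_GTDB"))
  expect_true(all(file.exists(unlist(res$paths))))
  traits_cols <- names(res$products$condensed_traits_NCBI)
  expect_true(all(c("dataset", "taxon_id", "species", "genus", "superkingdom",
                    "ref_id") %in% traits_cols))
  sp_cols <- names(res$products$condensed_species_NCBI)
  expect_true(all(c("species", "genome_size", "genome_size.stdev",
                    "genome_size.count", "metabolism", "isolation_source",
                    "ref_ids") %in% sp_cols))
  expect_equal(names(res$products$references),
               c("ref_id", "reference", "ref_type"))
  expect_true(file.exists(file.path(res$out_dir, "manifest.json")))
})

test_that("GTDB products are smaller because the taxonomy accepts fewer taxa", {
  res <- fixture_pipeline_run(seed = 1)$result
  expect_lt(nrow(res$products$condensed_traits_GTDB),
            nrow(res$products$condensed_traits_NCBI))
  expect_lt(nrow(res$products$condensed_species_GTDB),
            nrow(res$products$condensed_species_NCBI))
})

test_that("record reference ids resolve in the reference table with no orphans", {
  res <- fixture_pipeline_run(seed = 1)$result
  refs <- res$products$references
  expect_equal(anyDuplicated(refs$ref_id), 0L)
  for (p in c("condensed_traits_NCBI", "condensed_traits_GTDB")) {
    expect_true(all(res$products[[p]]$ref_id %in% refs$ref_id))
  }
  # no orphan references either way (every reference is used somewhere)
  used <- unique(res$products$condensed_traits_NCBI$ref_id)
  expect_setequal(refs$ref_id, used)
})

test_that("reruns on identical inputs are byte-identical", {
  run <- fixture_pipeline_run(seed = 1)
  rerun_dir <- file.path(run$dir, "out2")
  res2 <- suppressMessages(suppressWarnings(
    run_workflow(run$config_path, rerun_dir)))
  for (nm in names(run$result$paths)) {
    expect_identical(unname(tools::md5sum(run$result$paths[[nm]])),
                     unname(tools::md5sum(res2$paths[[nm]])),
                     label = nm)
  }
})

test_that("composing the four stages equals the end-to-end run", {
  run <- fixture_pipeline_run(seed = 1)
  staged_dir <- file.path(run$dir, "staged")
  cfg <- load_workflow_config(run$config_path)
  suppressMessages(suppressWarnings({
    stage_prepare(cfg, staged_dir)
    stage_combine(cfg, staged_dir)
    stage_condense_traits(cfg, staged_dir)
    stage_condense_species(cfg, staged_dir)
  }))
  for (nm in names(run$result$paths)) {
    staged_path <- file.path(staged_dir, basename(run$result$paths[[nm]]))
    expect_identical(unname(tools::md5sum(run$result$paths[[nm]])),
                     unname(tools::md5sum(staged_path)), label = nm)
  }
})

test_that("a config with only one taxonomy skips the other with a notice", {
  run <- fixture_pipeline_run(seed = 1)
  cfg <- yaml::read_yaml(run$config_path)
  cfg$taxonomies$gtdb <- NULL
  ncbi_cfg <- file.path(run$dir, "config_ncbi.yaml")
  yaml::write_yaml(cfg, ncbi_cfg)
  out <- file.path(run$dir, "out_ncbi_only")
  expect_message(
    res <- suppressWarnings(run_workflow(ncbi_cfg, out)),
    "gtdb.*skipped")
  expect_setequal(names(res$products),
                  c("condensed_traits_NCBI", "references",
                    "condensed_species_NCBI"))
})

test_that("downstream stages demand their upstream artifacts", {
  run <- fixture_pipeline_run(seed = 1)
  empty <- file.path(run$dir, "empty_out")
  expect_error(stage_condense_traits(run$config_path, empty),
               class = "traitsynth_dependency_error")
  expect_error(stage_combine(run$config_path, empty),
               class = "traitsynth_dependency_error")
})

test_that("every correction in the fixture applies exactly once", {
  res <- fixture_pipeline_run(seed = 1)$result
  log <- res$reports$corrections_log_ncbi
  expect_gt(nrow(log), 0L)
  expect_true(all(as.integer(log$n_matched) == 1L))
})

test_that("quarantine and curation logs are written", {
  res <- fixture_pipeline_run(seed = 1)$result
  expect_true(all(c("quarantine", "untranslated_env_ncbi",
                    "corrections_log_ncbi", "gap_fill_log_ncbi") %in%
                    names(res$reports)))
  fills <- res$reports$gap_fill_log_ncbi
  expect_true(all(fills$status == "filled"))
})

test_that("broom methods summarise runs and reports", {
  run <- fixture_pipeline_run(seed = 1)
  td <- tidy(run$result)
  expect_equal(nrow(td), 5L)
  gl <- glance(run$result)
  expect_equal(gl$products, 5L)
  expect_gt(gl$corrections_applied, 0L)
  sch_gl <- glance(default_schema())
  expect_equal(sch_gl$total, 23L)
})

test_that("plots build without error", {
  run <- fixture_pipeline_run(seed = 1)
  p1 <- plot_trait_coverage(run$result$products$condensed_species_NCBI)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_records_per_dataset(run$result$products$condensed_traits_NCBI)
  expect_s3_class(p2, "ggplot")
  rep <- verify_recovery(run$result$products$condensed_species_NCBI,
                         run$fixture)
  p3 <- ggplot2::autoplot(rep)
  expect_s3_class(p3, "ggplot")
})

test_that("the command-line wrapper runs a staged subcommand", {
  cli <- system.file("cli", "traitsynth.R", package = "traitsynth")
  expect_true(nzchar(cli))
  run <- fixture_pipeline_run(seed = 1)
  out <- file.path(run$dir, "cli_out")
  status <- system2("Rscript", c(cli, "prepare", "--config",
                                 shQuote(run$config_path),
                                 "--out", shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "logs", "quarantine.csv")))
  # bad subcommand exits non-zero
  status2 <- system2("Rscript", c(cli, "frobnicate"),
                     stdout = FALSE, stderr = FALSE)
  expect_false(status2 == 0L)
})
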