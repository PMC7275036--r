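small_cfg <- list(n_species = 8L, records_per_species = 4L,
                  unresolved_fraction = 0.25, gap_fill_species = 1L)

test_that("fixture generation is a pure function of config and seed", {
  f1 <- generate_fixture(small_cfg, seed = 5)
  f2 <- generate_fixture(small_cfg, seed = 5)
  expect_identical(f1$sources, f2$sources)
  expect_identical(f1$truth, f2$truth)
  expect_identical(f1$corrections, f2$corrections)
  f3 <- generate_fixture(small_cfg, seed = 6)
  expect_false(identical(f1$truth$species, f3$truth$species))
  # generation must not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_fixture(small_cfg, seed = 5)); after <- runif(3)
  expect_identical(before, after)
})

test_that("invalid fixture configs are rejected", {
  expect_error(generate_fixture(list(majority_fraction = 0.5)),
               class = "traitsynth_validation_error")
  expect_error(generate_fixture(list(n_sources = 0L)),
               class = "traitsynth_validation_error")
  expect_error(generate_fixture(list(error_rate = 2)),
               class = "traitsynth_validation_error")
})

test_that("no injected errors means an empty corrections table", {
  fx <- generate_fixture(c(small_cfg, list(error_rate = 0)), seed = 3)
  expect_equal(nrow(fx$corrections), 0L)
})

test_that("every injected error has a matching correction row", {
  fx <- generate_fixture(list(n_species = 20L, error_rate = 0.1), seed = 4)
  expect_gt(nrow(fx$corrections), 0L)
  # each correction keys a real record cell: dataset/taxon pairs exist
  recs <- fx$truth$records
  keys <- paste(fx$corrections$dataset, fx$corrections$taxon,
                fx$corrections$trait)
  have <- paste(recs$dataset, recs$taxon_id, recs$trait)
  expect_true(all(keys %in% have))
  # corrected values equal the clean planted draws
  expect_true(all(abs(as.numeric(fx$corrections$original) -
                        1000 * as.numeric(fx$corrections$corrected)) <
                    1e-6 * as.numeric(fx$corrections$original)))
})

test_that("a unanimous fixture recovers every planted categorical exactly", {
  run <- fixture_pipeline_run(seed = 21,
                              config = list(n_species = 10L,
                                            records_per_species = 4L,
                                            majority_fraction = 1.0,
                                            noise_sd = 0, error_rate = 0,
                                            untranslated_rate = 0,
                                            quarantine_rate = 0,
                                            unresolved_fraction = 0))
  rep <- verify_recovery(run$result$products$condensed_species_NCBI,
                         run$fixture)
  g <- glance(rep)
  expect_true(g$all_pass)
  # noiseless numeric means equal truth up to float round-trip
  expect_true(all(abs(rep$numeric$estimate - rep$numeric$truth) <=
                    1e-9 * abs(rep$numeric$truth)))
  expect_equal(g$categorical_agreement, 1)
})

test_that("placeholder species are excluded from the aggregated product", {
  fx <- generate_fixture(list(n_species = 6L, unresolved_fraction = 1,
                              records_per_species = 3L, quarantine_rate = 0),
                         seed = 9)
  expect_equal(sum(!fx$truth$species$resolved), 6L)
  dir <- withr::local_tempdir()
  cfg <- write_fixture_inputs(fx, dir)
  res <- suppressMessages(suppressWarnings(
    run_workflow(cfg, file.path(dir, "out"), taxonomy = "ncbi")))
  agg <- res$products$condensed_species_NCBI
  resolved <- fx$truth$species$species[fx$truth$species$resolved]
  expect_true(all(agg$species %in% resolved))
  expect_equal(nrow(agg), length(unique(agg$species)))
  # but the placeholder rows are present at record level
  traits <- res$products$condensed_traits_NCBI
  expect_true(any(grepl(" sp\\. ", traits$species)))
})
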