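env_map_fixture <- function() {
  tibble::tibble(
    string = c("soil", "soil, rice paddy", "marine"),
    label = c("soil", "soil_agricultural", "marine"))
}

combined_fixture <- function() {
  a <- prepare_dataset(test_raw_source(), test_prep_spec(),
                       test_mapping(), default_schema())
  combine(list(a), test_taxonomy())
}

test_that("environment strings translate through the curated table", {
  tr <- translate_environment(list(c("soil", "rice paddy")), env_map_fixture())
  expect_equal(tr$label, "soil_agricultural")
  expect_equal(env_label_depth(tr$label), 2L)

  one <- translate_environment(list(c("host", "", "")),
                               tibble::tibble(string = "host", label = "host"))
  expect_equal(one$label, "host")
  expect_equal(env_label_depth(one$label), 1L)

  missed <- translate_environment("deep subsurface brine", env_map_fixture())
  expect_true(is.na(missed$label))
  expect_equal(missed$untranslated$string, "deep subsurface brine")

  # a label deeper than four levels is rejected as a table error
  expect_error(
    translate_environment("x", tibble::tibble(string = "x", label = "a_b_c_d_e")),
    class = "traitsynth_table_error")
})

test_that("corrections replace exactly the keyed cells and log applications", {
  tbl <- combined_fixture()
  corr <- tibble::tibble(
    dataset = "srcT", taxon = "8", trait = "growth_tmp",
    original = "37", corrected = "36", comment = "typo", reference = "ref")
  out <- apply_corrections(tbl, corr)
  expect_equal(out$table$growth_tmp[out$table$taxon_id == "8"], 36)
  expect_equal(out$log$n_matched, 1L)
  # other cells untouched
  expect_equal(out$table$growth_tmp[out$table$taxon_id == "9"], 30)

  # zero-match corrections warn and leave the table unchanged
  nohit <- tibble::tibble(dataset = "srcT", taxon = "8", trait = "growth_tmp",
                          original = "999", corrected = "1",
                          comment = "", reference = "")
  expect_warning(out2 <- apply_corrections(tbl, nohit))
  expect_identical(out2$table, tbl)
  expect_equal(out2$log$n_matched, 0L)
})

test_that("corrections to different traits of one row apply independently", {
  tbl <- combined_fixture()
  corr <- tibble::tibble(
    dataset = "srcT", taxon = c("8", "8"),
    trait = c("growth_tmp", "metabolism"),
    original = c("37", "aerobe"), corrected = c("36", "anaerobic"),
    comment = "", reference = "")
  ab <- apply_corrections(tbl, corr)
  ba <- apply_corrections(tbl, corr[2:1, ])
  expect_identical(ab$table, ba$table)
  expect_equal(ab$table$growth_tmp[ab$table$taxon_id == "8"], 36)
  expect_equal(ab$table$metabolism[ab$table$taxon_id == "8"], "anaerobic")
})

test_that("corrections are idempotent when replacements are not keys themselves", {
  tbl <- combined_fixture()
  corr <- tibble::tibble(dataset = "srcT", taxon = "8", trait = "growth_tmp",
                         original = "37", corrected = "36",
                         comment = "", reference = "")
  once <- apply_corrections(tbl, corr)$table
  twice <- suppressWarnings(apply_corrections(once, corr)$table)
  expect_identical(twice, once)
})

test_that("condense_traits normalizes terms, blanks unmapped ones, and builds references", {
  tbl <- combined_fixture()
  ct <- condense_traits(tbl, default_schema(), env_map = env_map_fixture())
  # dialect spellings mapped onto the controlled vocabulary
  expect_setequal(unique(ct$table$metabolism),
                  c("aerobic", "obligate aerobic", "anaerobic"))
  # environment strings became hierarchical labels
  expect_true(all(ct$table$isolation_source %in%
                    c("soil", "soil_agricultural", "marine")))
  # one shared DOI deduplicates to a single reference row
  expect_equal(nrow(ct$references), 1L)
  expect_true(all(ct$table$ref_id == ct$references$ref_id))
})

test_that("reference ids are stable, dense and resolve both ways", {
  refs <- build_reference_table(
    c("b-doi", "a-doi", "b-doi", "c-doi", "a-doi"),
    c("doi", "doi", "doi", "doi", "doi"))
  expect_equal(nrow(refs), 3L)
  expect_equal(refs$ref_id, 1:3)
  expect_equal(refs$reference, sort(refs$reference))  # deterministic order
  again <- build_reference_table(
    c("c-doi", "b-doi", "a-doi"), rep("doi", 3))
  expect_equal(again$reference, refs$reference)
})

test_that("unmapped categorical terms are blanked and reported", {
  tbl <- combined_fixture()
  tbl$metabolism[1] <- "breatharian"
  ct <- condense_traits(tbl, default_schema(), env_map = env_map_fixture())
  expect_true(is.na(ct$table$metabolism[1]))
  expect_equal(ct$reports$unmapped_terms$raw, "breatharian")
  expect_equal(ct$reports$unmapped_terms$trait, "metabolism")
})

test_that("a zero-row table yields header-only outputs", {
  tbl <- combined_fixture()[0, ]
  ct <- condense_traits(tbl, default_schema(), env_map = env_map_fixture())
  expect_equal(nrow(ct$table), 0L)
  expect_equal(nrow(ct$references), 0L)
})
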