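test_that("numeric aggregation returns mean, sample stdev and count", {
  a <- aggregate_numeric(c(2, 4))
  expect_equal(a$mean, 3)
  expect_equal(a$stdev, sqrt(2), tolerance = 1e-12)  # 1.4142...
  expect_equal(a$count, 2L)

  single <- aggregate_numeric(5)
  expect_equal(single$mean, 5)
  expect_true(is.na(single$stdev))
  expect_equal(single$count, 1L)

  constant <- aggregate_numeric(c(3, 3, 3))
  expect_equal(constant$stdev, 0)

  none <- aggregate_numeric(numeric(0))
  expect_true(is.na(none$mean) && is.na(none$stdev))
  expect_equal(none$count, 0L)

  # blanks are dropped before aggregation
  expect_equal(aggregate_numeric(c(1, NA, 3))$count, 2L)
})

test_that("strict-majority consensus assigns the dominant term and blanks ties", {
  expect_equal(condense_binary(c("yes", "yes", "no")), "yes")
  expect_true(is.na(condense_binary(c("yes", "no"))))
  expect_equal(condense_binary(c("rod", "rod", "coccus", "rod")), "rod")
  expect_true(is.na(condense_binary(character(0))))
  expect_true(is.na(condense_binary(c(NA, NA))))
})

test_that("the multilevel cascade reproduces the worked metabolism cases", {
  v <- vocab_for(default_schema(), "metabolism")
  # mixed specificity within one category: most specific wins
  expect_equal(condense_multilevel(c("aerobic", "obligate aerobic"), v),
               "obligate aerobic")
  # equal specificity within one category: least specific form
  expect_equal(condense_multilevel(c("facultative aerobic", "obligate aerobic"), v),
               "aerobic")
  # cross-category conflict: nothing assigned
  expect_true(is.na(condense_multilevel(c("aerobic", "anaerobic"), v)))
  # a strict majority short-circuits the cascade
  m <- vocab_for(default_schema(), "motility")
  expect_equal(condense_multilevel(c("yes", "flagella", "flagella"), m),
               "flagella")
  # tie among distinct most-specific terms falls back to the generalization
  expect_equal(condense_multilevel(c("aerobic", "obligate aerobic",
                                     "facultative aerobic"), v),
               "aerobic")
  expect_error(condense_multilevel("levitating", v),
               class = "traitsynth_vocabulary_error")
})

test_that("majority and multilevel consensus agree with brute-force tallying", {
  sch <- default_schema()
  for (tr in c("sporulation", "gram_stain")) {
    terms <- vocab_for(sch, tr)$term
    for (ms in all_multisets(terms, 4)) {
      expect_identical(condense_binary(ms), oracle_majority(ms),
                       label = paste(tr, paste(ms, collapse = "+")))
    }
  }
  for (tr in c("metabolism", "motility")) {
    v <- vocab_for(sch, tr)
    for (ms in all_multisets(v$term, 3)) {
      expect_identical(condense_multilevel(ms, v), oracle_multilevel(ms, v),
                       label = paste(tr, paste(ms, collapse = "+")))
    }
  }
})

test_that("isolation-source condensation descends by per-level strict majority", {
  expect_equal(
    condense_isolation(c("host_animal_endotherm_blood",
                         "host_animal_ectotherm",
                         "host_animal_endotherm_intestinal")),
    "host_animal_endotherm")  # level-4 blood/intestinal tie stops the descent
  expect_equal(condense_isolation("soil"), "soil")
  expect_true(is.na(condense_isolation(c("soil", "host"))))  # level-1 tie
  expect_true(is.na(condense_isolation(character(0))))
  # vague labels neither support nor veto deeper levels
  expect_equal(condense_isolation(c("soil", "soil_agricultural",
                                    "soil_agricultural")),
               "soil_agricultural")
})

test_that("condensed isolation labels are supported prefixes on random multisets", {
  pool <- c("soil", "soil_agricultural", "soil_forest", "marine",
            "marine_sediment", "host", "host_animal",
            "host_animal_endotherm", "host_animal_endotherm_intestinal",
            "host_animal_endotherm_blood", "host_animal_ectotherm",
            "host_plant", "freshwater", "thermal_spring")
  set.seed(7)
  for (i in 1:300) {
    labels <- sample(pool, sample(1:6, 1), replace = TRUE)
    out <- condense_isolation(labels)
    expect_true(isolation_output_valid(labels, out),
                label = paste(paste(labels, collapse = "+"), "->", out))
    expect_lte(env_label_depth(out), 4L)
  }
})
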