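test_that("shipped registry partitions the traits as published", {
  sch <- default_schema()
  counts <- count_traits_by_kind(sch)
  expect_equal(nrow(sch$traits), 23L)
  expect_equal(sum(counts$n), 23L)
  expect_equal(counts$n[counts$kind == "phenotypic"], 14L)
  expect_equal(counts$n[counts$kind == "genomic"], 5L)
  expect_equal(counts$n[counts$kind == "environmental"], 4L)
  expect_setequal(
    sch$traits$name[sch$traits$kind == "genomic"],
    c("genome_size", "gc_content", "coding_genes", "rRNA16S_genes", "tRNA_genes"))
  expect_setequal(
    sch$traits$name[sch$traits$kind == "environmental"],
    c("isolation_source", "optimum_tmp", "optimum_ph", "growth_tmp"))
})

test_that("every numeric trait has a unit and every categorical one a vocabulary", {
  sch <- default_schema()
  num <- sch$traits[sch$traits$dtype == "numeric", ]
  expect_true(all(nzchar(num$unit)))
  cat_traits <- sch$traits$name[sch$traits$dtype %in%
    c("binary_categorical", "multilevel_categorical", "multiset_categorical")]
  expect_true(all(cat_traits %in% sch$vocabulary$trait))
})

test_that("an empty schema counts zero traits of every kind", {
  sch <- trait_schema(
    data.frame(name = character(), kind = character(), dtype = character(),
               unit = character()),
    data.frame(trait = character(), term = character(), category = character(),
               specificity = integer(), generalization = character()))
  counts <- count_traits_by_kind(sch)
  expect_equal(counts$n, c(0L, 0L, 0L))
})

test_that("schema validation rejects duplicates and structural defects", {
  traits <- data.frame(name = c("sporulation", "sporulation"),
                       kind = "phenotypic", dtype = "binary_categorical",
                       unit = "")
  vocab <- data.frame(trait = "sporulation", term = c("yes", "no"),
                      category = c("yes", "no"), specificity = 1L,
                      generalization = c("yes", "no"))
  expect_error(trait_schema(traits, vocab), class = "traitsynth_validation_error")

  # numeric trait without a unit
  expect_error(
    trait_schema(data.frame(name = "genome_size", kind = "genomic",
                            dtype = "numeric", unit = ""),
                 vocab[0, ]),
    class = "traitsynth_validation_error")

  # generalization of a specificity-1 term must be itself
  bad_vocab <- data.frame(trait = "sporulation", term = c("yes", "no"),
                          category = c("yes", "no"), specificity = 1L,
                          generalization = c("no", "yes"))
  expect_error(
    trait_schema(data.frame(name = "sporulation", kind = "phenotypic",
                            dtype = "binary_categorical", unit = ""),
                 bad_vocab),
    class = "traitsynth_validation_error")
})

test_that("term normalization folds case and whitespace and never passes unknowns through", {
  sch <- default_schema()
  expect_equal(as.character(normalize_term("Spore-forming", "sporulation", sch)), "yes")
  expect_equal(as.character(normalize_term("  YES ", "sporulation", sch)), "yes")
  res <- normalize_term("sometimes??", "sporulation", sch)
  expect_true(is.na(res))
  expect_true(attr(res, "unmapped"))
  # blanks are missing, not unmapped
  res2 <- normalize_term(c(NA, ""), "sporulation", sch)
  expect_false(any(attr(res2, "unmapped")))
  expect_error(normalize_term("x", "genome_size", sch),
               class = "traitsynth_usage_error")
})

test_that("term normalization is idempotent over every mapped spelling", {
  sch <- default_schema()
  for (tr in unique(sch$translations$trait)) {
    raws <- dplyr::filter(sch$translations, trait == tr)$from
    once <- as.character(normalize_term(raws, tr, sch))
    twice <- as.character(normalize_term(once, tr, sch))
    expect_equal(twice, once)
  }
})

test_that("generalization chains terminate at specificity 1 in one hop", {
  voc <- default_schema()$vocabulary
  gen <- voc[match(paste(voc$trait, voc$generalization),
                   paste(voc$trait, voc$term)), ]
  expect_true(all(gen$specificity == 1L))
  expect_equal(gen$category, voc$category)
})
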