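# record-level table built by hand: three strains/records of B. subtilis
# plus unresolved "sp." rows
species_records <- function() {
  tibble::tibble(
    row_id = 1:5,
    dataset = c("s1", "s1", "s2", "s2", "s2"),
    taxon_id = c("8", "9", "8", "10", "10"),
    species = c("Bacillus subtilis", "Bacillus subtilis", "Bacillus subtilis",
                "Bacillus sp.", "Bacillus sp."),
    genus = "Bacillus", family = "Bacillaceae", order = "Bacillales",
    class = "Bacilli", phylum = "Firmicutes", superkingdom = "Bacteria",
    in_taxonomy = TRUE,
    genome_size = c(4e6, 5e6, 6e6, 3e6, 3e6),
    metabolism = c("aerobic", "obligate aerobic", NA, "anaerobic", "anaerobic"),
    sporulation = c("yes", "yes", "no", NA, NA),
    isolation_source = c("soil", "soil_agricultural", "soil", NA, NA),
    pathways = c("fermentation", "fermentation, nitrogen_fixation", NA, NA, NA),
    ref_id = c(1L, 1L, 2L, 3L, 3L))
}

test_that("strain records condense into one species row with mean, stdev, count", {
  agg <- condense_species(species_records())
  expect_equal(nrow(agg), 1L)  # the "sp." rows are excluded
  expect_equal(agg$species, "Bacillus subtilis")
  expect_equal(agg$genome_size, 5e6)
  expect_equal(agg$genome_size.count, 3L)
  expect_equal(agg$genome_size.stdev, sd(c(4e6, 5e6, 6e6)))
  # categorical condensation by dtype
  expect_equal(agg$metabolism, "obligate aerobic")  # most specific, one category
  expect_equal(agg$sporulation, "yes")              # 2/3 majority
  # level 1 unanimous; at level 2 only one label is specific enough and vague
  # labels do not veto, so the deeper term is accepted
  expect_equal(agg$isolation_source, "soil_agricultural")
  expect_equal(agg$pathways, "fermentation, nitrogen_fixation")  # union
  expect_equal(agg$ref_ids, "1; 2")
  expect_equal(agg$genus, "Bacillus")
})

test_that("a table of only placeholder species condenses to zero rows", {
  recs <- species_records()
  recs <- recs[recs$species == "Bacillus sp.", ]
  agg <- condense_species(recs)
  expect_equal(nrow(agg), 0L)
  # header still carries the full column set
  expect_true(all(c("species", "genome_size", "genome_size.stdev",
                    "genome_size.count", "metabolism", "ref_ids") %in% names(agg)))
})

test_that("each species yields exactly one row regardless of record counts", {
  recs <- species_records()
  extra <- recs[1, ]
  extra$species <- "Bacillus cereus"
  extra$taxon_id <- "99"
  extra$row_id <- 6L
  agg <- condense_species(dplyr::bind_rows(recs, extra))
  expect_equal(sort(agg$species), c("Bacillus cereus", "Bacillus subtilis"))
  expect_equal(anyDuplicated(agg$species), 0L)
})

test_that("aggregates are invariant under row permutation and bounded by the data", {
  recs <- species_records()
  set.seed(11)
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(as.data.frame(condense_species(shuffled)),
               as.data.frame(condense_species(recs)))
  agg <- condense_species(recs)
  vals <- recs$genome_size[recs$species == "Bacillus subtilis"]
  expect_gte(agg$genome_size, min(vals))
  expect_lte(agg$genome_size, max(vals))
  # count equals the number of non-blank contributing records
  expect_equal(agg$metabolism %in% c(NA, recs$metabolism), TRUE)
})

test_that("gap fill writes only into blank cells and logs everything", {
  agg <- condense_species(species_records())
  fills <- tibble::tibble(
    species = c("Bacillus subtilis", "Bacillus subtilis", "Vanishia absentia"),
    trait = c("motility", "metabolism", "sporulation"),
    value = c("flagella", "anaerobic", "yes"),
    reference = "Bergey's (synthetic)")
  out <- suppressWarnings(gap_fill(agg, fills))
  expect_equal(out$aggregates$motility, "flagella")            # was blank
  expect_equal(out$aggregates$metabolism, "obligate aerobic")  # never overwritten
  expect_equal(out$log$status,
               c("filled", "already_set", "species_absent"))
  # numeric fills set count 1 and blank stdev
  numfill <- tibble::tibble(species = "Bacillus subtilis", trait = "gc_content",
                            value = "43.5", reference = "ref")
  out2 <- gap_fill(agg, numfill)
  expect_equal(out2$aggregates$gc_content, 43.5)
  expect_equal(out2$aggregates$gc_content.count, 1L)
  expect_true(is.na(out2$aggregates$gc_content.stdev))
  # invalid vocabulary fill is a table error
  bad <- tibble::tibble(species = "Bacillus subtilis", trait = "motility",
                        value = "teleportation", reference = "r")
  expect_error(gap_fill(agg, bad), class = "traitsynth_table_error")
})
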