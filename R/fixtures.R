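#' Fixture generation: synthetic sources with known ground truth
#'
#' The generator emulates the statistical shape of real trait compilations —
#' several sources with their own column layouts, units and term spellings,
#' overlapping taxa observed at species and strain level, conflicting
#' categorical reports, ranges encoded as strings, missing values, taxa that
#' cannot be resolved — while planting a known species-level truth, so the
#' whole pipeline can be exercised and checked offline.
#'
#' Numeric record values are drawn as `truth * (1 + N(0, noise_sd))` (the
#' noise standard deviation is relative to the true value).  Categorical
#' record values equal the planted truth with probability
#' `majority_fraction` and otherwise flip to a random other vocabulary term.
#' A fraction `error_rate` of numeric cells is corrupted by a factor-1000
#' magnitude error, and every injected error gets a matching row in the
#' generated corrections table.  A fraction of species carry only a
#' placeholder epithet (`"sp."`) to exercise species-level exclusion, and a
#' fraction of records carry organism labels absent from the mapping table
#' to exercise quarantine.
#'
#' @param config A named list overriding any of the defaults:
#'   `n_species` (50), `n_sources` (3), `records_per_species` (6),
#'   `majority_fraction` (0.8), `noise_sd` (0.1), `error_rate` (0.02),
#'   `unresolved_fraction` (0.1), `strain_fraction` (0.3),
#'   `quarantine_rate` (0.02), `untranslated_rate` (0.03),
#'   `gtdb_keep` (0.8), `gap_fill_species` (2).
#' @param seed Integer; fixes all randomness.  Generation is a pure function
#'   of `(config, seed)`.
#' @return A `fixture_set`: raw `sources` (named list of tibbles),
#'   `prep_specs` (named list), `taxonomy_ncbi` / `taxonomy_gtdb` node
#'   tibbles, `mapping`, `env_map`, `corrections`, `gap_fill`, `truth`
#'   (`species` wide truth tibble and `records` long realized-draw tibble),
#'   plus `config` and `seed`.
#' @export
generate_fixture <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(fixture_defaults(), config)
  validate_fixture_config(cfg)
  with_preserved_seed(seed, build_fixture(cfg, seed))
}

fixture_defaults <- function() {
  list(n_species = 50L, n_sources = 3L, records_per_species = 6L,
       majority_fraction = 0.8, noise_sd = 0.1, error_rate = 0.02,
       unresolved_fraction = 0.1, strain_fraction = 0.3,
       quarantine_rate = 0.02, untranslated_rate = 0.03,
       gtdb_keep = 0.8, gap_fill_species = 2L)
}

validate_fixture_config <- function(cfg) {
  if (!(cfg$majority_fraction > 0.5 && cfg$majority_fraction <= 1)) {
    ts_abort("majority_fraction must be in (0.5, 1]",
             class = "traitsynth_validation_error")
  }
  for (p in c("noise_sd", "error_rate", "unresolved_fraction", "strain_fraction",
              "quarantine_rate", "untranslated_rate", "gtdb_keep")) {
    if (cfg[[p]] < 0 || (p != "noise_sd" && cfg[[p]] > 1)) {
      ts_abort(sprintf("%s out of range", p), class = "traitsynth_validation_error")
    }
  }
  for (p in c("n_species", "n_sources", "records_per_species")) {
    if (cfg[[p]] < 1) {
      ts_abort(sprintf("%s must be >= 1", p), class = "traitsynth_validation_error")
    }
  }
  invisible(cfg)
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

fixture_numeric_ranges <- function() {
  list(
    d1_lo = c(0.3, 1.2), d2_lo = c(1, 4), doubling_h = c(0.5, 20),
    genome_size = c(2e6, 8e6), gc_content = c(30, 70),
    coding_genes = c(2000, 8000), optimum_tmp = c(15, 45),
    optimum_ph = c(5.5, 8.5), growth_tmp = c(10, 45),
    rRNA16S_genes = c(1, 15), tRNA_genes = c(30, 90)
  )
}

fixture_env_map <- function() {
  tibble::tribble(
    ~string,                                ~label,
    "soil",                                 "soil",
    "soil sample",                          "soil",
    "soil, rice paddy",                     "soil_agricultural",
    "agricultural soil",                    "soil_agricultural",
    "freshwater",                           "freshwater",
    "lake water",                           "freshwater",
    "freshwater, sediment",                 "freshwater_sediment",
    "lake sediment",                        "freshwater_sediment",
    "marine",                               "marine",
    "sea water, surface",                   "marine",
    "marine sediment",                      "marine_sediment",
    "sea floor, sediment",                  "marine_sediment",
    "host",                                 "host",
    "host-associated",                      "host",
    "host, animal",                         "host_animal",
    "host, animal, endotherm",              "host_animal_endotherm",
    "warm-blooded host",                    "host_animal_endotherm",
    "host, animal, endotherm, intestinal",  "host_animal_endotherm_intestinal",
    "gut, mammal",                          "host_animal_endotherm_intestinal",
    "blood, mammal",                        "host_animal_endotherm_blood",
    "host, plant",                          "host_plant",
    "plant tissue",                         "host_plant",
    "hot spring, water",                    "thermal_spring",
    "thermal spring",                       "thermal_spring"
  )
}

# How each source layout re-spells canonical terms (all spellings resolvable
# through the shipped term-translation table).
fixture_dialects <- function() {
  list(
    b = list(
      metabolism = c("aerobic" = "Aerobe", "anaerobic" = "Anaerobe",
                     "obligate aerobic" = "obligate aerobe",
                     "obligate anaerobic" = "obligate anaerobe",
                     "facultative aerobic" = "facultative aerobe",
                     "facultative anaerobic" = "facultative anaerobe",
                     "microaerophilic" = "microaerophile"),
      motility = c("yes" = "Motile", "no" = "non-motile",
                   "flagella" = "flagellated")
    ),
    c = list(
      gram_stain = c("positive" = "Gram-positive", "negative" = "Gram-negative",
                     "variable" = "gram-variable"),
      sporulation = c("yes" = "spore-forming", "no" = "non-spore-forming"),
      cell_shape = c("rod" = "rods", "coccus" = "cocci",
                     "spirillum" = "spiral", "filament" = "filamentous"),
      range_tmp = c("psychrophilic" = "psychrophile", "mesophilic" = "mesophile",
                    "thermophilic" = "thermophile",
                    "hyperthermophilic" = "hyperthermophile"),
      range_salinity = c("halophilic" = "halophile",
                         "halotolerant" = "halotolerant organism")
    )
  )
}

# trait coverage per source layout
fixture_layouts <- function() {
  list(
    a = list(
      numeric = c("d1_lo", "d1_up", "d2_lo", "d2_up", "doubling_h",
                  "genome_size", "gc_content", "coding_genes", "optimum_tmp",
                  "optimum_ph", "growth_tmp", "rRNA16S_genes", "tRNA_genes"),
      categorical = c("gram_stain", "metabolism", "sporulation", "motility",
                      "range_tmp", "range_salinity", "cell_shape"),
      multiset = c("pathways", "carbon_substrates")
    ),
    b = list(
      numeric = c("genome_size", "gc_content", "coding_genes", "rRNA16S_genes",
                  "tRNA_genes", "doubling_h", "optimum_tmp", "optimum_ph",
                  "growth_tmp"),
      categorical = c("metabolism", "motility"),
      multiset = c("pathways")
    ),
    c = list(
      numeric = c("d1_lo", "d1_up", "optimum_tmp", "growth_tmp"),
      categorical = c("gram_stain", "sporulation", "cell_shape", "range_tmp",
                      "range_salinity"),
      multiset = c("carbon_substrates")
    )
  )
}

build_fixture <- function(cfg, seed) {
  schema <- default_schema()

  # ---- taxonomy ----------------------------------------------------------
  n_unresolved <- round(cfg$unresolved_fraction * cfg$n_species)
  n_total_sp <- cfg$n_species + n_unresolved
  n_genus <- max(2L, ceiling(n_total_sp / 5))
  nodes <- list(
    tibble(taxon_id = "1", parent_id = "1", rank = "no rank", name = "root"),
    tibble(taxon_id = "2", parent_id = "1", rank = "superkingdom", name = "Bacteria")
  )
  next_id <- 3L
  new_node <- function(parent, rank, name) {
    id <- as.character(next_id)
    next_id <<- next_id + 1L
    nodes[[length(nodes) + 1L]] <<- tibble(taxon_id = id, parent_id = parent,
                                           rank = rank, name = name)
    id
  }
  phyla <- vapply(1:2, function(i) new_node("2", "phylum", sprintf("Phylum%02d", i)),
                  character(1))
  classes <- vapply(seq_along(phyla), function(i)
    new_node(phyla[i], "class", sprintf("Class%02d", i)), character(1))
  orders <- vapply(seq_along(classes), function(i)
    new_node(classes[i], "order", sprintf("Order%02d", i)), character(1))
  families <- unlist(lapply(seq_along(orders), function(i) {
    vapply(1:2, function(j)
      new_node(orders[i], "family", sprintf("Family%02d", (i - 1) * 2 + j)),
      character(1))
  }))
  genus_ids <- vapply(seq_len(n_genus), function(g) {
    new_node(families[((g - 1) %% length(families)) + 1], "genus",
             sprintf("Genus%02d", g))
  }, character(1))
  genus_names <- sprintf("Genus%02d", seq_len(n_genus))

  resolved <- c(rep(TRUE, cfg$n_species), rep(FALSE, n_unresolved))
  genus_of <- ((seq_len(n_total_sp) - 1) %% n_genus) + 1
  species_name <- ifelse(
    resolved,
    paste(genus_names[genus_of], sprintf("epitheton%03d", seq_len(n_total_sp))),
    # placeholder epithet with a strain-style suffix keeps labels unique
    paste(genus_names[genus_of], sprintf("sp. FX%03d", seq_len(n_total_sp)))
  )
  species_ids <- vapply(seq_len(n_total_sp), function(i) {
    new_node(genus_ids[genus_of[i]], "species", species_name[i])
  }, character(1))

  has_strain <- resolved & (runif(n_total_sp) < cfg$strain_fraction)
  strain_ids <- rep(NA_character_, n_total_sp)
  strain_names <- rep(NA_character_, n_total_sp)
  for (i in which(has_strain)) {
    strain_names[i] <- paste(species_name[i], sprintf("strain ST%03d", i))
    strain_ids[i] <- new_node(species_ids[i], "strain", strain_names[i])
  }
  tax_ncbi_nodes <- bind_rows(nodes)

  # GTDB-style taxonomy: a subset of the same id space, names carry rank
  # prefixes that the gtdb reader strips
  keep_sp <- runif(n_total_sp) < cfg$gtdb_keep
  drop_ids <- c(species_ids[!keep_sp], strain_ids[!keep_sp])
  drop_ids <- drop_ids[!is.na(drop_ids)]
  prefix <- c(superkingdom = "d__", phylum = "p__", class = "c__",
              order = "o__", family = "f__", genus = "g__", species = "s__")
  tax_gtdb_nodes <- tax_ncbi_nodes |>
    filter(!.data$taxon_id %in% drop_ids) |>
    mutate(name = ifelse(.data$rank %in% names(prefix),
                         paste0(prefix[.data$rank], .data$name), .data$name))

  # ---- mapping table -----------------------------------------------------
  mapping <- bind_rows(
    tibble(label = species_name, taxon_id = species_ids),
    tibble(label = strain_names[has_strain], taxon_id = strain_ids[has_strain])
  )

  # ---- species truth -----------------------------------------------------
  ranges <- fixture_numeric_ranges()
  env_map <- fixture_env_map()
  env_pool <- unique(env_map$label)
  truth <- tibble(species_id = species_ids, species = species_name,
                  genus = genus_names[genus_of], resolved = resolved)
  for (tr in names(ranges)) {
    truth[[tr]] <- signif(runif(n_total_sp, ranges[[tr]][1], ranges[[tr]][2]), 6)
  }
  truth$d1_up <- signif(truth$d1_lo + runif(n_total_sp, 0.2, 1.0), 6)
  truth$d2_up <- signif(truth$d2_lo + runif(n_total_sp, 0.5, 3.0), 6)
  cat_traits <- c("gram_stain", "metabolism", "sporulation", "motility",
                  "range_tmp", "range_salinity", "cell_shape")
  for (tr in cat_traits) {
    terms <- vocab_for(schema, tr)$term
    truth[[tr]] <- sample(terms, n_total_sp, replace = TRUE)
  }
  for (tr in c("pathways", "carbon_substrates")) {
    terms <- vocab_for(schema, tr)$term
    truth[[tr]] <- vapply(seq_len(n_total_sp), function(i) {
      paste(sort(sample(terms, sample(1:3, 1))), collapse = ", ")
    }, character(1))
  }
  truth$isolation_source <- sample(env_pool, n_total_sp, replace = TRUE)

  # species whose metabolism is withheld from every record and supplied via
  # the gap-fill table instead
  n_fill <- min(cfg$gap_fill_species, cfg$n_species)
  fill_idx <- which(resolved)[seq_len(n_fill)]
  gap_fill_tbl <- tibble(
    species = species_name[fill_idx],
    trait = "metabolism",
    value = truth$metabolism[fill_idx],
    reference = "Bergey's Manual (synthetic gap-fill reference)")

  # ---- records -----------------------------------------------------------
  layouts <- fixture_layouts()
  dialects <- fixture_dialects()
  layout_keys <- rep_len(names(layouts), cfg$n_sources)
  src_names <- sprintf("src_%s%s", layout_keys,
                       ifelse(seq_len(cfg$n_sources) > length(layouts),
                              as.character(ceiling(seq_len(cfg$n_sources) / length(layouts))),
                              ""))
  numeric_factors <- list(
    a = c(),
    b = c(genome_size = 1e-6, doubling_h = 60),  # raw units: Mbp, minutes
    c = c(d1_lo = 1e-3, d1_up = 1e-3)            # raw unit: mm
  )

  src_rows <- setNames(vector("list", cfg$n_sources), src_names)
  truth_records <- list()
  corrections <- list()
  rec_id <- 0L
  for (i in seq_len(n_total_sp)) {
    for (r in seq_len(cfg$records_per_species)) {
      rec_id <- rec_id + 1L
      s <- ((r - 1) %% cfg$n_sources) + 1
      key <- layout_keys[s]
      lay <- layouts[[key]]
      quarantined <- runif(1) < cfg$quarantine_rate
      use_strain <- has_strain[i] && runif(1) < 0.5
      taxon_label <- if (quarantined) {
        sprintf("Unlisted organism %d", rec_id)
      } else if (use_strain) strain_names[i] else species_name[i]
      taxon_id <- if (quarantined) NA_character_ else
        if (use_strain) strain_ids[i] else species_ids[i]
      # label casing/padding noise: exercised through fold_key on lookup
      shown_label <- taxon_label
      u <- runif(1)
      if (u < 0.15) shown_label <- paste0("  ", taxon_label, " ")
      else if (u < 0.3) shown_label <- toupper(taxon_label)

      row <- list(.label = shown_label)
      rec_truth <- list()
      for (tr in lay$numeric) {
        clean <- signif(truth[[tr]][i] * (1 + rnorm(1, 0, cfg$noise_sd)), 6)
        clean <- abs(clean)
        value <- clean
        is_err <- !quarantined && runif(1) < cfg$error_rate
        if (is_err) {
          value <- clean * 1000
          corrections[[length(corrections) + 1L]] <- tibble(
            dataset = src_names[s], taxon = taxon_id, trait = tr,
            original = as.character(value), corrected = as.character(clean),
            comment = "synthetic magnitude error (x1000)",
            reference = "fixture truth")
        }
        row[[tr]] <- value
        rec_truth[[tr]] <- clean
      }
      for (tr in lay$categorical) {
        if (tr == "metabolism" && i %in% fill_idx) next
        terms <- vocab_for(schema, tr)$term
        term <- if (runif(1) < cfg$majority_fraction) truth[[tr]][i] else
          sample(setdiff(terms, truth[[tr]][i]), 1)
        shown <- term
        dia <- dialects[[key]][[tr]]
        if (!is.null(dia) && term %in% names(dia)) shown <- unname(dia[term])
        if (runif(1) < 0.15) shown <- toupper(shown)
        row[[tr]] <- shown
        rec_truth[[tr]] <- term
      }
      for (tr in lay$multiset) {
        terms <- stringr::str_split_1(truth[[tr]][i], stringr::fixed(", "))
        row[[tr]] <- paste(sample(terms), collapse = ", ")
        rec_truth[[tr]] <- truth[[tr]][i]
      }
      # environment
      env_label <- if (runif(1) < cfg$majority_fraction) {
        truth$isolation_source[i]
      } else {
        sample(setdiff(env_pool, truth$isolation_source[i]), 1)
      }
      if (runif(1) < cfg$untranslated_rate) {
        row$.env <- "unclassified environmental sample"
        rec_truth$isolation_source <- NA_character_
      } else {
        variants <- env_map$string[env_map$label == env_label]
        row$.env <- if (length(variants) == 1) variants else sample(variants, 1)
        rec_truth$isolation_source <- env_label
      }

      row$.dataset <- src_names[s]
      row$.species <- species_name[i]
      row$.taxon_id <- taxon_id
      row$.quarantined <- quarantined
      row$.record_id <- rec_id
      src_rows[[src_names[s]]][[length(src_rows[[src_names[s]]]) + 1L]] <- row

      truth_records[[length(truth_records) + 1L]] <- tibble(
        record_id = rec_id, dataset = src_names[s],
        species = species_name[i], resolved = resolved[i],
        taxon_id = taxon_id %||% NA_character_, quarantined = quarantined,
        trait = names(rec_truth),
        value = vapply(rec_truth, as.character, character(1)))
    }
  }

  sources <- list()
  prep_specs <- list()
  for (s in seq_len(cfg$n_sources)) {
    nm <- src_names[s]
    rows <- src_rows[[nm]]
    built <- render_fixture_source(rows %||% list(), layout_keys[s], nm,
                                   numeric_factors[[layout_keys[s]]])
    sources[[nm]] <- built$table
    prep_specs[[nm]] <- built$spec
    # map record ids to the rows of this source for the truth table
    if (length(rows) > 0) {
      ids <- vapply(rows, `[[`, integer(1), ".record_id")
      for (k in seq_along(truth_records)) {
        if (truth_records[[k]]$dataset[1] == nm &&
            truth_records[[k]]$record_id[1] %in% ids) {
          truth_records[[k]]$source_row <- match(truth_records[[k]]$record_id[1], ids)
        }
      }
    }
  }

  corrections_tbl <- if (length(corrections)) bind_rows(corrections) else
    tibble(dataset = character(), taxon = character(), trait = character(),
           original = character(), corrected = character(),
           comment = character(), reference = character())

  structure(
    list(sources = sources, prep_specs = prep_specs,
         taxonomy_ncbi = tax_ncbi_nodes, taxonomy_gtdb = tax_gtdb_nodes,
         mapping = mapping, env_map = env_map,
         corrections = corrections_tbl, gap_fill = gap_fill_tbl,
         truth = list(species = truth, records = bind_rows(truth_records)),
         config = cfg, seed = seed),
    class = "fixture_set"
  )
}

# Render the collected record draws of one source into its raw table (layout
# specific column names, units and reference style) plus its prep spec.
render_fixture_source <- function(rows, key, dataset, factors) {
  n <- length(rows)
  get_col <- function(field, default = NA) {
    if (n == 0) return(character(0))
    vapply(rows, function(r) {
      v <- r[[field]]
      if (is.null(v)) as.character(default) else as.character(v)
    }, character(1))
  }
  get_num <- function(field, factor = 1) {
    if (n == 0) return(numeric(0))
    vapply(rows, function(r) {
      v <- r[[field]]
      if (is.null(v)) NA_real_ else as.numeric(v) * factor
    }, numeric(1))
  }
  f <- function(tr) if (!is.null(factors) && tr %in% names(factors)) factors[[tr]] else 1

  if (key == "a") {
    lo1 <- get_num("d1_lo"); up1 <- get_num("d1_up")
    lo2 <- get_num("d2_lo"); up2 <- get_num("d2_up")
    table <- tibble(
      organism = get_col(".label"),
      ref = sprintf("10.1000/%s.ref%d", dataset,
                    (vapply(rows, `[[`, integer(1), ".record_id") %% 3) + 1),
      habitat = get_col(".env"),
      gram_stain = get_col("gram_stain"),
      metabolism = get_col("metabolism"),
      pathways = get_col("pathways"),
      carbon_substrates = get_col("carbon_substrates"),
      sporulation = get_col("sporulation"),
      motility = get_col("motility"),
      range_tmp = get_col("range_tmp"),
      range_salinity = get_col("range_salinity"),
      cell_shape = get_col("cell_shape"),
      cell_width = sprintf("%s-%s µm", format(lo1, trim = TRUE), format(up1, trim = TRUE)),
      cell_length = sprintf("%s-%s µm", format(lo2, trim = TRUE), format(up2, trim = TRUE)),
      doubling_h = get_num("doubling_h"),
      genome_size = get_num("genome_size"),
      gc_content = get_num("gc_content"),
      coding_genes = get_num("coding_genes"),
      optimum_tmp = get_num("optimum_tmp"),
      optimum_ph = get_num("optimum_ph"),
      growth_tmp = get_num("growth_tmp"),
      rRNA16S_genes = get_num("rRNA16S_genes"),
      tRNA_genes = get_num("tRNA_genes"))
    spec <- list(
      dataset = dataset,
      taxon = list(column = "organism"),
      reference = list(column = "ref"),
      environment = list(columns = list("habitat")),
      traits = sapply(c("gram_stain", "metabolism", "pathways",
                        "carbon_substrates", "sporulation", "motility",
                        "range_tmp", "range_salinity", "cell_shape",
                        "doubling_h", "genome_size", "gc_content",
                        "coding_genes", "optimum_tmp", "optimum_ph",
                        "growth_tmp", "rRNA16S_genes", "tRNA_genes"),
                      function(tr) list(column = tr), simplify = FALSE),
      ranges = list(
        list(column = "cell_width", min = "d1_lo", max = "d1_up", unit = "µm"),
        list(column = "cell_length", min = "d2_lo", max = "d2_up", unit = "µm")))
  } else if (key == "b") {
    table <- tibble(
      organism_name = get_col(".label"),
      source_env = vapply(strsplit(get_col(".env"), ", ", fixed = TRUE),
                          function(p) p[1], character(1)),
      sample_type = vapply(strsplit(get_col(".env"), ", ", fixed = TRUE),
                           function(p) if (length(p) > 1)
                             paste(p[-1], collapse = ", ") else "", character(1)),
      metabolism = get_col("metabolism"),
      motility = get_col("motility"),
      pathways = get_col("pathways"),
      genome_mb = get_num("genome_size", f("genome_size")),
      gc_content = get_num("gc_content"),
      coding_genes = get_num("coding_genes"),
      rRNA16S_genes = get_num("rRNA16S_genes"),
      tRNA_genes = get_num("tRNA_genes"),
      doubling_min = get_num("doubling_h", f("doubling_h")),
      optimum_tmp = get_num("optimum_tmp"),
      optimum_ph = get_num("optimum_ph"),
      growth_tmp = get_num("growth_tmp"))
    spec <- list(
      dataset = dataset,
      taxon = list(column = "organism_name"),
      reference = list(constant = sprintf("10.1000/%s.collection", dataset)),
      environment = list(columns = list("source_env", "sample_type")),
      traits = c(
        list(genome_size = list(column = "genome_mb", unit = "Mbp"),
             doubling_h = list(column = "doubling_min", unit = "min")),
        sapply(c("metabolism", "motility", "pathways", "gc_content",
                 "coding_genes", "rRNA16S_genes", "tRNA_genes", "optimum_tmp",
                 "optimum_ph", "growth_tmp"),
               function(tr) list(column = tr), simplify = FALSE)))
  } else {
    table <- tibble(
      organism = get_col(".label"),
      accession = sprintf("PRJNA%06d",
                          10000 + (vapply(rows, `[[`, integer(1), ".record_id") %% 5)),
      environment = get_col(".env"),
      gram_stain = get_col("gram_stain"),
      sporulation = get_col("sporulation"),
      cell_shape = get_col("cell_shape"),
      range_tmp = get_col("range_tmp"),
      range_salinity = get_col("range_salinity"),
      carbon_substrates = get_col("carbon_substrates"),
      d1_lo_mm = get_num("d1_lo", f("d1_lo")),
      d1_up_mm = get_num("d1_up", f("d1_up")),
      optimum_tmp = get_num("optimum_tmp"),
      growth_tmp = get_num("growth_tmp"))
    spec <- list(
      dataset = dataset,
      taxon = list(column = "organism"),
      reference = list(column = "accession"),
      environment = list(columns = list("environment")),
      traits = c(
        list(d1_lo = list(column = "d1_lo_mm", unit = "mm"),
             d1_up = list(column = "d1_up_mm", unit = "mm")),
        sapply(c("gram_stain", "sporulation", "cell_shape", "range_tmp",
                 "range_salinity", "carbon_substrates", "optimum_tmp",
                 "growth_tmp"),
               function(tr) list(column = tr), simplify = FALSE)))
  }
  list(table = table, spec = as_prep_spec(spec))
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("<fixture_set> seed %d: %d species (%d unresolved), %d sources, %d records\n",
              x$seed, sum(x$truth$species$resolved),
              sum(!x$truth$species$resolved), length(x$sources),
              length(unique(x$truth$records$record_id))))
  invisible(x)
}
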