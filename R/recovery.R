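#' Check pipeline output against the planted fixture truth
#'
#' Compares a species-level aggregate table produced by the pipeline with
#' the ground truth a fixture was generated from:
#' * numeric traits: the species mean must fall within
#'   `3 * (noise_sd * truth) / sqrt(count)` of the planted truth — three
#'   standard errors under the generator's known noise model (with
#'   `noise_sd = 0` the means must equal the truth exactly, up to floating
#'   point);
#' * plain and multilevel categorical traits: wherever the planted term
#'   holds a realized strict majority (>50%) among the records that reached
#'   aggregation, the consensus must equal the planted truth;
#' * isolation source: wherever the planted label holds a realized strict
#'   majority, the condensed label must extend (or equal) the planted label;
#' * multiset traits: the aggregated term set must equal the planted set
#'   whenever the species has at least one contributing record.
#'
#' @param aggregates A `species_aggregate` tibble from [condense_species()],
#'   after [gap_fill()] if the fixture supplies a gap-fill table.
#' @param fixture The `fixture_set` the pipeline ran on.
#' @param schema A [trait_schema].
#' @return A `recovery_report`: tibbles `numeric`, `categorical`,
#'   `environment`, `multiset` with per species-trait checks, and `summary`
#'   (per-trait bias / coverage / agreement).
#' @export
verify_recovery <- function(aggregates, fixture, schema = default_schema()) {
  stopifnot(inherits(fixture, "fixture_set"))
  truth_sp <- fixture$truth$species
  cfg <- fixture$config

  alien <- setdiff(aggregates$species, truth_sp$species[truth_sp$resolved])
  if (length(alien) > 0) {
    ts_abort(sprintf("aggregated species not present in fixture truth: %s",
                     paste(head(alien, 5), collapse = ", ")),
             class = "traitsynth_alignment_error")
  }

  # realized record draws that reached aggregation (resolved species, not
  # quarantined)
  rec <- fixture$truth$records |>
    filter(.data$resolved, !.data$quarantined)

  numeric_traits <- schema$traits$name[schema$traits$dtype == "numeric"]
  num_rows <- list()
  for (tr in numeric_traits) {
    est <- aggregates[[tr]]
    cnt <- aggregates[[paste0(tr, ".count")]]
    tru <- truth_sp[[tr]][match(aggregates$species, truth_sp$species)]
    keep <- !is.na(est) & cnt >= 1
    bound <- 3 * (cfg$noise_sd * tru) / sqrt(pmax(cnt, 1))
    num_rows[[tr]] <- tibble(
      species = aggregates$species[keep], trait = tr,
      truth = tru[keep], estimate = est[keep], count = cnt[keep],
      bound = bound[keep],
      within = abs(est - tru)[keep] <= bound[keep] + 1e-9 * abs(tru[keep]))
  }
  numeric_tbl <- bind_rows(num_rows)

  cat_traits <- schema$traits$name[schema$traits$dtype %in%
                                     c("binary_categorical", "multilevel_categorical")]
  cat_rows <- list()
  for (tr in cat_traits) {
    draws <- filter(rec, .data$trait == !!tr, !is.na(.data$value))
    if (nrow(draws) == 0) next
    draws$planted <- truth_sp[[tr]][match(draws$species, truth_sp$species)]
    shares <- draws |>
      group_by(.data$species) |>
      summarise(n = n(), n_truth = sum(.data$value == .data$planted),
                .groups = "drop") |>
      mutate(share = .data$n_truth / .data$n)
    shares$truth <- truth_sp[[tr]][match(shares$species, truth_sp$species)]
    shares$consensus <- aggregates[[tr]][match(shares$species, aggregates$species)]
    shares$trait <- tr
    shares$checked <- shares$share > 0.5
    shares$pass <- !shares$checked |
      (!is.na(shares$consensus) & shares$consensus == shares$truth)
    cat_rows[[tr]] <- shares[, c("species", "trait", "truth", "consensus",
                                 "n", "share", "checked", "pass")]
  }
  categorical_tbl <- bind_rows(cat_rows)

  env_draws <- filter(rec, .data$trait == "isolation_source", !is.na(.data$value))
  environment_tbl <- tibble(species = character(), truth = character(),
                            consensus = character(), share = numeric(),
                            checked = logical(), pass = logical())
  if (nrow(env_draws) > 0) {
    env_draws$planted <- truth_sp$isolation_source[match(env_draws$species,
                                                         truth_sp$species)]
    environment_tbl <- env_draws |>
      group_by(.data$species) |>
      summarise(n = n(), n_truth = sum(.data$value == .data$planted),
                .groups = "drop") |>
      mutate(share = .data$n_truth / .data$n,
             truth = truth_sp$isolation_source[match(.data$species, truth_sp$species)],
             consensus = aggregates$isolation_source[match(.data$species, aggregates$species)],
             checked = .data$share > 0.5,
             pass = !.data$checked |
               (!is.na(.data$consensus) &
                  startsWith(paste0(.data$consensus, "_"), paste0(.data$truth, "_"))))
  }

  multiset_traits <- schema$traits$name[schema$traits$dtype == "multiset_categorical"]
  ms_rows <- list()
  for (tr in multiset_traits) {
    draws <- filter(rec, .data$trait == !!tr, !is.na(.data$value))
    if (nrow(draws) == 0) next
    sp <- unique(draws$species)
    ms_rows[[tr]] <- tibble(
      species = sp, trait = tr,
      truth = truth_sp[[tr]][match(sp, truth_sp$species)],
      consensus = aggregates[[tr]][match(sp, aggregates$species)]) |>
      mutate(pass = !is.na(.data$consensus) & .data$consensus == .data$truth)
  }
  multiset_tbl <- bind_rows(ms_rows)

  summary_tbl <- bind_rows(
    numeric_tbl |>
      group_by(trait = .data$trait) |>
      summarise(kind = "numeric", n = n(),
                bias = mean(.data$estimate - .data$truth),
                rate = mean(.data$within), .groups = "drop"),
    categorical_tbl |>
      group_by(trait = .data$trait) |>
      summarise(kind = "categorical", n = sum(.data$checked),
                bias = NA_real_,
                rate = mean(.data$pass[.data$checked]), .groups = "drop"),
    if (nrow(environment_tbl) > 0) {
      tibble(trait = "isolation_source", kind = "environment",
             n = sum(environment_tbl$checked), bias = NA_real_,
             rate = mean(environment_tbl$pass[environment_tbl$checked]))
    },
    multiset_tbl |>
      group_by(trait = .data$trait) |>
      summarise(kind = "multiset", n = n(), bias = NA_real_,
                rate = mean(.data$pass), .groups = "drop")
  )

  structure(
    list(numeric = numeric_tbl, categorical = categorical_tbl,
         environment = environment_tbl, multiset = multiset_tbl,
         summary = summary_tbl, config = cfg,
         n_species = nrow(aggregates)),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d aggregated species\n", x$n_species))
  cat(sprintf("  numeric: %d species-trait pairs, %.1f%% within 3 SE of truth\n",
              nrow(x$numeric), 100 * mean(x$numeric$within)))
  if (nrow(x$categorical) > 0) {
    ch <- x$categorical[x$categorical$checked, ]
    cat(sprintf("  categorical: %d majority cases, %.1f%% equal planted truth\n",
                nrow(ch), 100 * mean(ch$pass)))
  }
  if (nrow(x$environment) > 0) {
    ch <- x$environment[x$environment$checked, ]
    cat(sprintf("  isolation source: %d majority cases, %.1f%% extend planted label\n",
                nrow(ch), 100 * mean(ch$pass)))
  }
  invisible(x)
}
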