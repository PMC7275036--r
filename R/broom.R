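#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a recovery report
#'
#' One row per trait with the check kind, the number of species-trait pairs
#' checked, the mean bias (numeric traits) and the pass rate.
#'
#' @param x A `recovery_report` from [verify_recovery()].
#' @param ... Unused.
#' @return A tibble `(trait, kind, n, bias, rate)`.
#' @export
tidy.recovery_report <- function(x, ...) {
  x$summary
}

#' @rdname tidy.recovery_report
#' @return For `glance()`: a one-row tibble with `n_species`,
#'   `numeric_pairs`, `numeric_coverage`, `categorical_checked`,
#'   `categorical_agreement`, `environment_agreement`, `all_pass`.
#' @export
glance.recovery_report <- function(x, ...) {
  cat_checked <- x$categorical[x$categorical$checked, ]
  env_checked <- x$environment[x$environment$checked, ]
  tibble(
    n_species = x$n_species,
    numeric_pairs = nrow(x$numeric),
    numeric_coverage = mean(x$numeric$within),
    categorical_checked = nrow(cat_checked),
    categorical_agreement = if (nrow(cat_checked)) mean(cat_checked$pass) else NA_real_,
    environment_agreement = if (nrow(env_checked)) mean(env_checked$pass) else NA_real_,
    all_pass = all(x$numeric$within) && all(cat_checked$pass) &&
      all(env_checked$pass) && all(x$multiset$pass)
  )
}

#' Tidy a trait schema
#'
#' @param x A [trait_schema].
#' @param ... Unused.
#' @return For `tidy()`: the trait registry tibble.  For `glance()`: a
#'   one-row tibble of trait counts by kind.
#' @export
tidy.trait_schema <- function(x, ...) x$traits

#' @rdname tidy.trait_schema
#' @export
glance.trait_schema <- function(x, ...) {
  counts <- count_traits_by_kind(x)
  out <- as_tibble(as.list(setNames(counts$n, counts$kind)))
  out$total <- nrow(x$traits)
  out$vocabulary_terms <- nrow(x$vocabulary)
  out
}

#' Summarise a workflow run
#'
#' @param x A `workflow_result` from [run_workflow()].
#' @param ... Unused.
#' @return For `tidy()`: one row per data product with its row count and
#'   path.  For `glance()`: a one-row run summary.
#' @export
tidy.workflow_result <- function(x, ...) {
  tibble(product = names(x$products),
         rows = vapply(x$products, nrow, integer(1)),
         path = unname(x$paths[names(x$products)]))
}

#' @rdname tidy.workflow_result
#' @export
glance.workflow_result <- function(x, ...) {
  tibble(
    products = length(x$products),
    record_rows = sum(vapply(x$products[grepl("^condensed_traits", names(x$products))],
                             nrow, integer(1))),
    species_rows = sum(vapply(x$products[grepl("^condensed_species", names(x$products))],
                              nrow, integer(1))),
    references = nrow(x$products$references),
    corrections_applied = sum(vapply(
      x$reports[grepl("^corrections_log", names(x$reports))],
      function(r) sum(as.integer(r$n_matched)), integer(1)))
  )
}
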