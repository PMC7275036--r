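#' Plot trait coverage of a species-level table
#'
#' Fraction of species with a non-blank value per trait, coloured by trait
#' kind — the usual first look at how complete a condensed dataset is.
#'
#' @param aggregates A `species_aggregate` tibble (or any data frame with
#'   trait columns).
#' @param schema A [trait_schema].
#' @return A ggplot.
#' @export
plot_trait_coverage <- function(aggregates, schema = default_schema()) {
  traits <- intersect(schema$traits$name, names(aggregates))
  cov <- tibble(
    trait = traits,
    kind = schema$traits$kind[match(traits, schema$traits$name)],
    coverage = vapply(traits, function(tr) mean(!is.na(aggregates[[tr]])),
                      numeric(1)))
  ggplot2::ggplot(cov, ggplot2::aes(
    x = stats::reorder(.data$trait, .data$coverage),
    y = .data$coverage, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "species with a value", fill = "trait kind",
                  title = "Trait coverage") +
    ggplot2::theme_minimal()
}

#' Plot record counts per source dataset
#'
#' @param combined A combined record-level tibble (see [combine()]).
#' @return A ggplot.
#' @export
plot_records_per_dataset <- function(combined) {
  counts <- dplyr::count(combined, .data$dataset)
  ggplot2::ggplot(counts, ggplot2::aes(
    x = stats::reorder(.data$dataset, .data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "records", title = "Records per source") +
    ggplot2::theme_minimal()
}

#' Plot recovered species means against planted truth
#'
#' @param object A `recovery_report` from [verify_recovery()].
#' @param ... Unused.
#' @return A ggplot, faceted by numeric trait, with the identity line.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$numeric, ggplot2::aes(
    x = .data$truth, y = .data$estimate, colour = .data$within)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "planted truth", y = "recovered species mean",
                  colour = "within 3 SE") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
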