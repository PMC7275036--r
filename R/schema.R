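#' Trait schemas: the harmonized trait registry and controlled vocabularies
#'
#' A trait schema declares the traits every downstream stage recognises: the
#' trait name, its kind (`phenotypic`, `genomic` or `environmental`), its data
#' type, and — for numeric traits — the canonical unit all prepared values are
#' converted into.  Categorical traits additionally carry a controlled
#' vocabulary whose terms are grouped into categories of mutual compatibility
#' (e.g. aerobic-group vs anaerobic-group) and ordered by specificity within a
#' category (`"aerobic"` is less specific than `"obligate aerobic"`).  The
#' shipped default registry covers 23 traits: 14 phenotypic, 5 quantitative
#' genomic and 4 environmental characteristics.
#'
#' @param traits A data frame with columns `name`, `kind`, `dtype`, `unit`.
#' @param vocabulary A data frame with columns `trait`, `term`, `category`,
#'   `specificity`, `generalization`.
#' @param translations Optional data frame with columns `trait`, `from`, `to`
#'   mapping raw source spellings to canonical vocabulary terms.
#'
#' @return A `trait_schema` object: a list with tibbles `traits`,
#'   `vocabulary` and `translations`.
#' @export
#' @examples
#' sch <- default_schema()
#' count_traits_by_kind(sch)
trait_schema <- function(traits, vocabulary, translations = NULL) {
  traits <- as_tibble(traits)
  vocabulary <- as_tibble(vocabulary)
  translations <- if (is.null(translations)) {
    tibble(trait = character(), from = character(), to = character())
  } else {
    as_tibble(translations)
  }

  ts_stopifnot_cols(traits, c("name", "kind", "dtype", "unit"), "traits table")
  ts_stopifnot_cols(vocabulary,
                    c("trait", "term", "category", "specificity", "generalization"),
                    "vocabulary table")
  ts_stopifnot_cols(translations, c("trait", "from", "to"), "translation table")

  traits$unit <- ifelse(is.na(traits$unit), "", traits$unit)
  vocabulary$specificity <- as.integer(vocabulary$specificity)

  if (anyDuplicated(traits$name)) {
    ts_abort(sprintf("duplicate trait definition(s): %s",
                     paste(unique(traits$name[duplicated(traits$name)]), collapse = ", ")),
             class = "traitsynth_validation_error")
  }
  bad_kind <- setdiff(unique(traits$kind), trait_kinds())
  if (length(bad_kind) > 0) {
    ts_abort(sprintf("unknown trait kind(s): %s", paste(bad_kind, collapse = ", ")),
             class = "traitsynth_validation_error")
  }
  bad_dtype <- setdiff(unique(traits$dtype), trait_dtypes())
  if (length(bad_dtype) > 0) {
    ts_abort(sprintf("unknown trait dtype(s): %s", paste(bad_dtype, collapse = ", ")),
             class = "traitsynth_validation_error")
  }
  no_unit <- traits$name[traits$dtype == "numeric" & traits$unit == ""]
  if (length(no_unit) > 0) {
    ts_abort(sprintf("numeric trait(s) without a canonical unit: %s",
                     paste(no_unit, collapse = ", ")),
             class = "traitsynth_validation_error")
  }

  categorical <- traits$name[traits$dtype %in% c(
    "binary_categorical", "multilevel_categorical", "multiset_categorical")]
  no_vocab <- setdiff(categorical, unique(vocabulary$trait))
  if (length(no_vocab) > 0) {
    ts_abort(sprintf("categorical trait(s) without a vocabulary: %s",
                     paste(no_vocab, collapse = ", ")),
             class = "traitsynth_validation_error")
  }

  key <- paste(vocabulary$trait, fold_key(vocabulary$term))
  if (anyDuplicated(key)) {
    ts_abort("vocabulary terms must be unique within a trait",
             class = "traitsynth_validation_error")
  }
  if (any(is.na(vocabulary$specificity)) || any(vocabulary$specificity < 1)) {
    ts_abort("vocabulary specificity must be an integer >= 1",
             class = "traitsynth_validation_error")
  }
  multilevel <- traits$name[traits$dtype == "multilevel_categorical"]
  ml <- vocabulary[vocabulary$trait %in% multilevel, ]
  if (any(is.na(ml$category) | ml$category == "")) {
    ts_abort("every term of a multilevel categorical trait needs a category",
             class = "traitsynth_validation_error")
  }
  # generalization of a specificity-1 term must be itself; every
  # generalization must resolve to a specificity-1 term of the same category
  lvl1 <- vocabulary[vocabulary$specificity == 1L, ]
  if (any(fold_key(lvl1$generalization) != fold_key(lvl1$term))) {
    ts_abort("generalization of a specificity-1 term must be the term itself",
             class = "traitsynth_validation_error")
  }
  gen_key <- paste(vocabulary$trait, fold_key(vocabulary$generalization),
                   vocabulary$category)
  root_key <- paste(lvl1$trait, fold_key(lvl1$term), lvl1$category)
  if (!all(gen_key %in% root_key)) {
    ts_abort("every generalization must name a specificity-1 term of the same trait and category",
             class = "traitsynth_validation_error")
  }

  # translation targets must be canonical vocabulary terms
  if (nrow(translations) > 0) {
    tkey <- paste(translations$trait, fold_key(translations$to))
    known <- paste(vocabulary$trait, fold_key(vocabulary$term))
    bad <- translations[!(tkey %in% known) & translations$trait %in% categorical, ]
    if (nrow(bad) > 0) {
      ts_abort(sprintf("translation target(s) not in the vocabulary: %s",
                       paste(unique(paste0(bad$trait, ":", bad$to)), collapse = ", ")),
               class = "traitsynth_validation_error")
    }
  }

  structure(
    list(traits = traits, vocabulary = vocabulary, translations = translations),
    class = "trait_schema"
  )
}

trait_kinds <- function() c("phenotypic", "genomic", "environmental")

trait_dtypes <- function() {
  c("numeric", "binary_categorical", "multilevel_categorical",
    "multiset_categorical", "hierarchical_label")
}

#' Load a trait schema from CSV files
#'
#' Reads a trait registry, its controlled vocabularies and (optionally) a
#' term-translation table, and validates them.  With no arguments the schema
#' shipped with the package is loaded.
#'
#' @param traits_path Path to the traits CSV (`name,kind,dtype,unit`).
#' @param vocabulary_path Path to the vocabulary CSV
#'   (`trait,term,category,specificity,generalization`).
#' @param translations_path Optional path to a translation CSV
#'   (`trait,from,to`).
#' @return A validated [trait_schema] object.
#' @export
load_schema <- function(traits_path = NULL, vocabulary_path = NULL,
                        translations_path = NULL) {
  traits_path <- traits_path %||%
    system.file("extdata", "schema", "traits.csv", package = "traitsynth")
  vocabulary_path <- vocabulary_path %||%
    system.file("extdata", "schema", "vocabulary.csv", package = "traitsynth")
  if (is.null(translations_path)) {
    default_tr <- system.file("extdata", "schema", "term_translations.csv",
                              package = "traitsynth")
    translations_path <- if (nzchar(default_tr)) default_tr else NULL
  }
  traits <- ts_read_csv(traits_path)
  vocabulary <- ts_read_csv(vocabulary_path)
  translations <- if (!is.null(translations_path)) ts_read_csv(translations_path)
  trait_schema(traits, vocabulary, translations)
}

#' @rdname load_schema
#' @export
default_schema <- function() load_schema()

#' Count registered traits by kind
#'
#' @param schema A [trait_schema].
#' @return A tibble with one row per kind (`phenotypic`, `genomic`,
#'   `environmental`) and a count `n`; counts sum to the number of traits.
#' @export
count_traits_by_kind <- function(schema) {
  stopifnot(inherits(schema, "trait_schema"))
  tibble(kind = trait_kinds()) |>
    left_join(dplyr::count(schema$traits, .data$kind), by = "kind") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}

trait_def <- function(schema, trait) {
  i <- match(trait, schema$traits$name)
  if (is.na(i)) {
    ts_abort(sprintf("unknown trait: %s", trait), class = "traitsynth_usage_error")
  }
  schema$traits[i, ]
}

trait_dtype <- function(schema, trait) trait_def(schema, trait)$dtype

is_categorical_dtype <- function(dtype) {
  dtype %in% c("binary_categorical", "multilevel_categorical", "multiset_categorical")
}

#' Vocabulary of one trait
#'
#' @param schema A [trait_schema].
#' @param trait Trait name.
#' @return The vocabulary rows for `trait`.
#' @export
vocab_for <- function(schema, trait) {
  filter(schema$vocabulary, .data$trait == !!trait)
}

#' Map raw categorical values onto canonical vocabulary terms
#'
#' Lookup is case-folded and whitespace-trimmed: a raw value matching a
#' canonical term (in any case) maps to that term; otherwise the trait's
#' translation table is consulted.  Values with no mapping come back as `NA`
#' and are flagged in the `unmapped` attribute so callers can log them — raw
#' spellings are never passed through silently.
#'
#' @param raw Character vector of raw values.
#' @param trait Name of a categorical trait.
#' @param schema A [trait_schema].
#' @return A character vector the length of `raw`; canonical terms where a
#'   mapping exists, `NA` otherwise.  Attribute `unmapped` is a logical vector
#'   marking non-blank inputs that found no mapping.
#' @export
#' @examples
#' normalize_term("Spore-forming", "sporulation", default_schema())
normalize_term <- function(raw, trait, schema) {
  dtype <- trait_dtype(schema, trait)
  if (!is_categorical_dtype(dtype)) {
    ts_abort(sprintf("trait '%s' is not categorical (dtype %s)", trait, dtype),
             class = "traitsynth_usage_error")
  }
  voc <- vocab_for(schema, trait)
  tr <- filter(schema$translations, .data$trait == !!trait)
  keys <- fold_key(raw)
  out <- voc$term[match(keys, fold_key(voc$term))]
  miss <- is.na(out)
  if (any(miss) && nrow(tr) > 0) {
    out[miss] <- tr$to[match(keys[miss], fold_key(tr$from))]
  }
  blank <- is.na(raw) | keys == ""
  out[blank] <- NA_character_
  structure(out, unmapped = is.na(out) & !blank)
}

#' @export
print.trait_schema <- function(x, ...) {
  counts <- count_traits_by_kind(x)
  cat(sprintf("<trait_schema> %d traits (%s)\n",
              nrow(x$traits),
              paste(sprintf("%d %s", counts$n, counts$kind), collapse = ", ")))
  cat(sprintf("  vocabulary: %d terms over %d traits; %d translation entries\n",
              nrow(x$vocabulary), length(unique(x$vocabulary$trait)),
              nrow(x$translations)))
  invisible(x)
}
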