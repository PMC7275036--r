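#' Numeric aggregation: mean, standard deviation, count
#'
#' Species-level numeric condensation: the arithmetic mean, the sample
#' standard deviation (n - 1 denominator) and the number of contributing
#' records.  Blanks are dropped first; a single observation yields a blank
#' standard deviation, and no observations yield all three blank
#' (`count = 0`).
#'
#' @param values Numeric vector (canonical units).
#' @return A one-row tibble `(mean, stdev, count)`.
#' @export
#' @examples
#' aggregate_numeric(c(2, 4))
aggregate_numeric <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  tibble(
    mean = if (n > 0) mean(values) else NA_real_,
    stdev = if (n > 1) sd(values) else NA_real_,
    count = n
  )
}

drop_blank_terms <- function(terms) {
  terms <- as.character(terms)
  terms[!is.na(terms) & stringr::str_trim(terms) != ""]
}

#' Strict-majority consensus for plain categorical traits
#'
#' The term holding strictly more than 50% of the tally is assigned; ties or
#' the absence of a majority assign nothing.  Used for binary traits (gram
#' stain, sporulation) and for plain multi-term traits handled the same way
#' (cell shape, temperature and salinity preference).  Blanks are excluded
#' from the tally.
#'
#' @param terms Character vector of normalized terms.
#' @return The dominant term, or `NA` when no term exceeds 50%.
#' @export
#' @examples
#' condense_binary(c("yes", "yes", "no"))
#' condense_binary(c("yes", "no"))
condense_binary <- function(terms) {
  terms <- drop_blank_terms(terms)
  if (length(terms) == 0) return(NA_character_)
  tally <- table(terms)
  top <- names(tally)[tally > length(terms) / 2]
  if (length(top) == 1) top else NA_character_
}

#' Specificity-aware consensus for multilevel categorical traits
#'
#' For vocabularies with categories and levels of specificity (metabolism,
#' motility) the cascade is:
#' \enumerate{
#'   \item a term with a strict majority (>50% of the tally) wins outright;
#'   \item terms spanning different categories (aerobic vs anaerobic, motile
#'     vs non-motile) assign nothing;
#'   \item within one category, with mixed specificity, the most specific
#'     term present is selected ("obligate aerobic" over "aerobic"); a tie
#'     between distinct equally-most-specific terms falls through to the
#'     next rule;
#'   \item within one category at one specificity level, conflicting terms
#'     collapse to their shared least-specific form ("facultative aerobic"
#'     vs "obligate aerobic" becomes "aerobic").
#' }
#'
#' @param terms Character vector of normalized terms.
#' @param vocab Vocabulary rows for this trait (see [vocab_for()]).
#' @return The consensus term, or `NA`.
#' @export
#' @examples
#' v <- vocab_for(default_schema(), "metabolism")
#' condense_multilevel(c("aerobic", "obligate aerobic"), v)
#' condense_multilevel(c("facultative aerobic", "obligate aerobic"), v)
#' condense_multilevel(c("aerobic", "anaerobic"), v)
condense_multilevel <- function(terms, vocab) {
  terms <- drop_blank_terms(terms)
  if (length(terms) == 0) return(NA_character_)
  idx <- match(fold_key(terms), fold_key(vocab$term))
  if (anyNA(idx)) {
    ts_abort(sprintf("term(s) not in vocabulary: %s",
                     paste(unique(terms[is.na(idx)]), collapse = ", ")),
             class = "traitsynth_vocabulary_error")
  }
  terms <- vocab$term[idx]  # canonical casing

  # rule 0: strict majority
  tally <- table(terms)
  top <- names(tally)[tally > length(terms) / 2]
  if (length(top) == 1) return(top)

  info <- vocab[match(unique(terms), vocab$term), ]
  # rule 1: cross-category conflict
  if (length(unique(info$category)) > 1) return(NA_character_)
  # rule 2: one category, mixed specificity -> most specific present
  most <- info[info$specificity == max(info$specificity), ]
  if (nrow(most) == 1 && length(unique(info$specificity)) > 1) {
    return(most$term)
  }
  if (nrow(info) == 1) return(info$term)
  # rule 3: conflicting terms of one category -> shared generalization
  info$generalization[1]
}

#' Per-level consensus for hierarchical isolation-source labels
#'
#' Starting at level 1, the terms observed at each level are tallied among
#' the labels that match the accepted prefix so far and that specify that
#' level; the dominant term (strict majority, >50%) is accepted and combined
#' with the next level's dominant term.  When no level-k term dominates — or
#' no matching label specifies level k — the descent stops and the accepted
#' prefix is returned (blank when even level 1 is unresolved).  Labels that
#' stop earlier than the current level neither support nor veto deeper
#' levels.
#'
#' @param labels Character vector of rendered labels
#'   (`"host_animal_endotherm"`, ...); blanks are ignored.
#' @return The condensed label, or `NA`.
#' @export
#' @examples
#' condense_isolation(c("host_animal_endotherm_blood",
#'                      "host_animal_ectotherm",
#'                      "host_animal_endotherm_intestinal"))
condense_isolation <- function(labels) {
  labels <- drop_blank_terms(labels)
  if (length(labels) == 0) return(NA_character_)
  parsed <- env_label_parse(labels)
  accepted <- character(0)
  for (k in 1:4) {
    match_prefix <- vapply(parsed, function(p) {
      length(p) >= k && identical(p[seq_len(k - 1)], accepted)
    }, logical(1))
    if (!any(match_prefix)) break
    level_terms <- vapply(parsed[match_prefix], `[[`, character(1), k)
    tally <- table(level_terms)
    top <- names(tally)[tally > length(level_terms) / 2]
    if (length(top) != 1) break
    accepted <- c(accepted, top)
  }
  if (length(accepted) == 0) NA_character_ else env_label_render(accepted)
}

# Species-level union for multiset traits (metabolic pathways, carbon
# substrates): the sorted union of all terms observed for the species.
condense_multiset <- function(cells) {
  cells <- drop_blank_terms(cells)
  if (length(cells) == 0) return(NA_character_)
  terms <- unlist(stringr::str_split(cells, stringr::fixed(", ")))
  paste(sort(unique(terms)), collapse = ", ")
}
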