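# Independent brute-force oracles used to cross-check the consensus
# implementations.  These deliberately re-derive everything from raw counts
# rather than calling any package internals.

# share of each distinct term, by direct counting
term_shares <- function(terms) {
  terms <- terms[!is.na(terms) & terms != ""]
  if (length(terms) == 0) return(numeric(0))
  vapply(unique(terms), function(t) sum(terms == t) / length(terms),
         numeric(1))
}

oracle_majority <- function(terms) {
  shares <- term_shares(terms)
  winners <- names(shares)[shares > 0.5]
  if (length(winners) == 1) winners else NA_character_
}

oracle_multilevel <- function(terms, vocab) {
  terms <- terms[!is.na(terms) & terms != ""]
  if (length(terms) == 0) return(NA_character_)
  maj <- oracle_majority(terms)
  if (!is.na(maj)) return(maj)
  distinct <- unique(terms)
  cats <- vocab$category[match(distinct, vocab$term)]
  specs <- vocab$specificity[match(distinct, vocab$term)]
  if (length(unique(cats)) > 1) return(NA_character_)
  deepest <- distinct[specs == max(specs)]
  if (length(deepest) == 1 && length(unique(specs)) > 1) return(deepest)
  if (length(distinct) == 1) return(distinct)
  vocab$generalization[match(distinct[1], vocab$term)]
}

# validity check for a condensed isolation-source label: the output must be
# a prefix of some input label, and each accepted level must hold a strict
# majority among the labels that match the prefix above it and reach that
# level
isolation_output_valid <- function(labels, out) {
  labels <- labels[!is.na(labels) & labels != ""]
  if (length(labels) == 0) return(is.na(out))
  if (is.na(out)) return(TRUE)  # maximality is checked separately
  parts <- strsplit(out, "_", fixed = TRUE)[[1]]
  parsed <- strsplit(labels, "_", fixed = TRUE)
  is_prefix <- any(vapply(parsed, function(p) {
    length(p) >= length(parts) && all(p[seq_along(parts)] == parts)
  }, logical(1)))
  if (!is_prefix) return(FALSE)
  for (k in seq_along(parts)) {
    eligible <- Filter(function(p) {
      length(p) >= k && (k == 1 || all(p[seq_len(k - 1)] == parts[seq_len(k - 1)]))
    }, parsed)
    level_terms <- vapply(eligible, `[[`, character(1), k)
    if (!(sum(level_terms == parts[k]) * 2 > length(level_terms))) return(FALSE)
  }
  TRUE
}

# chain-walking lineage oracle: follow parent pointers one at a time
oracle_lineage <- function(id, nodes) {
  ranks <- c("species", "genus", "family", "order", "class", "phylum",
             "superkingdom")
  out <- setNames(rep(NA_character_, length(ranks)), ranks)
  seen <- character(0)
  while (!(id %in% seen)) {
    seen <- c(seen, id)
    i <- match(id, nodes$taxon_id)
    if (is.na(i)) break
    if (nodes$rank[i] %in% ranks && is.na(out[nodes$rank[i]])) {
      out[nodes$rank[i]] <- nodes$name[i]
    }
    if (is.na(nodes$parent_id[i]) || nodes$parent_id[i] == id) break
    id <- nodes$parent_id[i]
  }
  out
}

# all multisets (as sorted index combinations with repetition) of sizes
# 1..max_size from a term set
all_multisets <- function(terms, max_size) {
  out <- list()
  for (k in seq_len(max_size)) {
    grid <- do.call(expand.grid, c(rep(list(seq_along(terms)), k),
                                   stringsAsFactors = FALSE))
    keep <- apply(as.matrix(grid), 1, function(r) all(diff(r) >= 0))
    idx <- as.matrix(grid[keep, , drop = FALSE])
    out <- c(out, lapply(seq_len(nrow(idx)), function(i) terms[idx[i, ]]))
  }
  out
}
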