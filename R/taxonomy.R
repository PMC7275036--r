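#' Taxonomies: node tables, lineages and species resolution
#'
#' A taxonomy is a node table `(taxon_id, parent_id, rank, name)` whose parent
#' chains are acyclic and terminate at a root (a node that is its own parent
#' or has an empty parent).  NCBI-style and GTDB-style taxonomies are read
#' into the same internal model; the GTDB dialect strips rank prefixes such
#' as `s__` from names.  Ranks outside the seven reported ones (superkingdom,
#' phylum, class, order, family, genus, species) — strains, "no rank" nodes —
#' are carried but never appear as lineage columns; a strain inherits its
#' species ancestor when a lineage is built.
#'
#' @param nodes A data frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name`.
#' @param dialect `"ncbi"` or `"gtdb"`; the GTDB dialect strips `d__`/`p__`/
#'   .../`s__` prefixes from names.
#' @return A `taxonomy` object (validated tibble of nodes).
#' @export
taxonomy <- function(nodes, dialect = c("ncbi", "gtdb")) {
  dialect <- match.arg(dialect)
  nodes <- as_tibble(nodes)
  ts_stopifnot_cols(nodes, c("taxon_id", "parent_id", "rank", "name"),
                    "taxonomy table", class = "traitsynth_taxonomy_error")
  nodes <- mutate(nodes,
                  taxon_id = as.character(.data$taxon_id),
                  parent_id = as.character(.data$parent_id),
                  rank = fold_key(.data$rank),
                  name = as.character(.data$name))
  if (dialect == "gtdb") {
    nodes$name <- stringr::str_remove(nodes$name, "^[dkpcofgs]__")
  }
  if (anyDuplicated(nodes$taxon_id)) {
    ts_abort("duplicate taxon_id in taxonomy", class = "traitsynth_taxonomy_error")
  }
  # acyclicity: repeatedly contract parent pointers; every chain must reach a
  # root within n steps
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  at_root <- function(ids) is.na(parent[ids]) | parent[ids] == ids |
    !(parent[ids] %in% nodes$taxon_id)
  cur <- nodes$taxon_id
  for (i in seq_len(nrow(nodes) + 1L)) {
    done <- at_root(cur)
    if (all(done)) break
    cur[!done] <- unname(parent[cur[!done]])
  }
  if (!all(at_root(cur))) {
    ts_abort("taxonomy contains a parent cycle", class = "traitsynth_taxonomy_error")
  }
  structure(nodes, class = c("taxonomy", class(nodes)), dialect = dialect)
}

#' @rdname taxonomy
#' @param path CSV file with columns `taxon_id,parent_id,rank,name`.
#' @export
read_taxonomy <- function(path, dialect = c("ncbi", "gtdb")) {
  taxonomy(ts_read_csv(path), dialect = match.arg(dialect))
}

lineage_ranks <- function() {
  c("species", "genus", "family", "order", "class", "phylum", "superkingdom")
}

#' Resolve raw taxon labels through an offline mapping table
#'
#' Labels are matched exactly after case folding and whitespace trimming
#' against a curated `(label, taxon_id)` table — the offline stand-in for
#' interactive taxonomy lookups.  Unresolved labels return `NA`; the function
#' never guesses.
#'
#' @param labels Character vector of raw organism labels.
#' @param mapping Data frame with columns `label`, `taxon_id`.
#' @return Character vector of taxon ids, `NA` where unresolved.
#' @export
resolve_taxon <- function(labels, mapping) {
  mapping <- as_tibble(mapping)
  ts_stopifnot_cols(mapping, c("label", "taxon_id"), "taxon mapping table")
  as.character(mapping$taxon_id)[match(fold_key(labels), fold_key(mapping$label))]
}

#' Report labels a mapping table cannot resolve
#'
#' Companion to [resolve_taxon()] for curation: returns the distinct labels
#' that miss, so they can be looked up manually and appended to the table.
#'
#' @inheritParams resolve_taxon
#' @return A tibble with columns `label` and `n` (occurrences).
#' @export
taxon_misses <- function(labels, mapping) {
  hit <- !is.na(resolve_taxon(labels, mapping))
  tibble(label = labels[!hit & !is.na(labels)]) |>
    dplyr::count(.data$label, name = "n") |>
    arrange(dplyr::desc(.data$n), .data$label)
}

#' Lineage of one or more taxa
#'
#' Walks parent links from each taxon, recording the node name at each of the
#' seven reported ranks.  Strain and other below-species nodes inherit their
#' species ancestor; ranks never reached stay `NA`.
#'
#' @param taxon_id Character vector of taxon ids present in `taxonomy`.
#' @param taxonomy A [taxonomy] object.
#' @return A tibble with one row per input id: `taxon_id`, `species`, `genus`,
#'   `family`, `order`, `class`, `phylum`, `superkingdom`.
#' @export
lineage_of <- function(taxon_id, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  ids <- as.character(taxon_id)
  unknown <- setdiff(unique(ids), taxonomy$taxon_id)
  if (length(unknown) > 0) {
    ts_abort(sprintf("taxon id(s) not in taxonomy: %s",
                     paste(head(unknown, 5), collapse = ", ")),
             class = "traitsynth_lookup_error")
  }
  lt <- lineage_table(taxonomy)
  lt[match(ids, lt$taxon_id), ]
}

# Lineages for every node of a taxonomy, via iterative parent contraction
# (vectorized; one pass per tree depth).
lineage_table <- function(taxonomy) {
  ranks <- lineage_ranks()
  n <- nrow(taxonomy)
  out <- matrix(NA_character_, nrow = n, ncol = length(ranks),
                dimnames = list(NULL, ranks))
  parent <- setNames(taxonomy$parent_id, taxonomy$taxon_id)
  name_of <- setNames(taxonomy$name, taxonomy$taxon_id)
  rank_of <- setNames(taxonomy$rank, taxonomy$taxon_id)
  cur <- taxonomy$taxon_id
  active <- rep(TRUE, n)
  for (step in seq_len(n + 1L)) {
    r <- rank_of[cur]
    hit <- active & r %in% ranks
    if (any(hit)) {
      idx <- cbind(which(hit), match(r[hit], ranks))
      fill <- is.na(out[idx])
      out[idx[fill, , drop = FALSE]] <- unname(name_of[cur[hit]][fill])
    }
    nxt <- unname(parent[cur])
    stop_here <- is.na(nxt) | nxt == cur | !(nxt %in% taxonomy$taxon_id)
    active <- active & !stop_here
    if (!any(active)) break
    cur[active] <- nxt[active]
  }
  bind_cols_safe <- as_tibble(out)
  dplyr::bind_cols(tibble(taxon_id = taxonomy$taxon_id), bind_cols_safe)
}

#' Is a lineage resolved to a recognised species?
#'
#' A record only takes part in species-level aggregation when its species
#' rank is populated and the name is not a placeholder: any whitespace
#' token equal to `"sp."` or `"sp"` (case-insensitive, by default) marks a
#' genus-only identification and the row is excluded.
#'
#' @param species Character vector of species names (may contain `NA`).
#' @param placeholders Tokens that mark an unresolved epithet.
#' @return Logical vector.
#' @export
#' @examples
#' is_species_resolved(c("Bacillus subtilis", "Bacillus sp.", NA))
is_species_resolved <- function(species, placeholders = c("sp.", "sp")) {
  vapply(species, function(s) {
    if (is.na(s) || fold_key(s) == "") return(FALSE)
    tokens <- stringr::str_split_1(fold_key(s), stringr::fixed(" "))
    !any(tokens %in% fold_key(placeholders))
  }, logical(1), USE.NAMES = FALSE)
}
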