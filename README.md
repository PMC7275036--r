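# traitsynth

Bacterial and archaeal phenotypic trait data live scattered across culture
collections, genome repositories and one-off literature compilations, each
with its own column names, units, term spellings and taxonomic labels.
`traitsynth` implements a reproducible, table-driven workflow that merges
such heterogeneous sources into two harmonized products:

* a **record-level condensed-traits table** — the sparse union of every
  observation, with standardized trait columns, canonical units, a
  seven-rank lineage (species … superkingdom) under an NCBI- or GTDB-style
  taxonomy, and a reference id per row; and
* a **species-level aggregated table** — one row per recognised species,
  with every trait condensed by the rule its data type demands.

The package is aimed at microbial ecologists building or extending trait
syntheses: every curation decision (term mappings, environment-string
translations, datum corrections, gap fills) is a plain CSV input applied by
script, so the whole pipeline is transparent, re-runnable and extensible.

## The condensation rules

The trait registry covers 23 traits — 14 phenotypic, 5 quantitative genomic
and 4 environmental characteristics. At species level each trait is
aggregated over all records of the species (strains included, via the
lineage) as follows:

* **numeric traits** (cell diameters in µm, doubling time in h, genome size
  in bp, GC content, gene counts, temperatures, pH): arithmetic mean
  $\bar{x}$, sample standard deviation $s$ (denominator $n-1$) and record
  count $n$, written as `trait`, `trait.stdev`, `trait.count`;
* **plain categorical traits** (gram stain, sporulation, cell shape,
  temperature and salinity preference): *strict majority* — a term is
  assigned only when it holds more than 50 % of the tally; ties assign
  nothing;
* **multilevel categorical traits** (metabolism, motility), whose
  vocabularies group terms into categories of mutual compatibility
  (aerobic-group vs anaerobic-group; motile vs non-motile) with levels of
  specificity (`aerobic` < `obligate aerobic`): majority first, then —
  cross-category conflict ⇒ blank; one category with mixed specificity ⇒
  most specific term; one category, same specificity, different terms ⇒
  their shared least-specific form;
* **isolation source**, a hierarchical label of up to four
  underscore-joined levels (`host`, `host_animal`, `host_animal_endotherm`,
  `host_animal_endotherm_intestinal`): condensed level by level, accepting
  at each level the term with a strict majority among the labels that match
  the accepted prefix and are specific enough to vote, stopping at the
  first unresolved level;
* **multiset traits** (metabolic pathways, carbon substrates): the sorted
  union of observed terms.

Rows not resolved to a recognised species (placeholder epithets such as
`"sp."`) are excluded before aggregation. After aggregation, a curated
gap-fill table can supply values for still-blank cells — never overwriting
observed data — and every record's provenance is kept through a
deduplicated reference table.

## Worked example

The package ships a seeded fixture generator that emulates the shape of
real sources (three layouts with different column names, units, range
strings and term spellings; strain-level records; conflicting reports;
taxa that cannot be resolved) around a known species-level truth:

```r
library(traitsynth)

default_schema()
#> <trait_schema> 23 traits (14 phenotypic, 5 genomic, 4 environmental)
#>   vocabulary: 53 terms over 9 traits; 42 translation entries

split_range("10-20 µm")
#> # A tibble: 1 × 5
#>   raw        min   max unit  ok
#>   <chr>    <dbl> <dbl> <chr> <lgl>
#> 1 10-20 µm    10    20 µm    TRUE

fx  <- generate_fixture(seed = 1)
dir <- tempfile("demo")
cfg <- write_fixture_inputs(fx, dir)
res <- run_workflow(cfg, file.path(dir, "out"))
res
#> <workflow_result> 5 data products in .../out
#>   condensed_traits_NCBI       323 rows
#>   condensed_traits_GTDB       265 rows
#>   references                    7 rows
#>   condensed_species_NCBI       50 rows
#>   condensed_species_GTDB       41 rows
```

The five files are the workflow's data products: record-level and
species-level tables under each taxonomy, plus the shared reference table.
The GTDB-side products are smaller because that taxonomy accepts only a
subset of the taxa. Recovery of the planted truth:

```r
rep <- verify_recovery(res$products$condensed_species_NCBI, fx)
rep
#> <recovery_report> 50 aggregated species
#>   numeric: 650 species-trait pairs, 99.5% within 3 SE of truth
#>   categorical: 273 majority cases, 100.0% equal planted truth
#>   isolation source: 45 majority cases, 100.0% extend planted label
```

`glance(rep)` and `tidy(rep)` give the same numbers as one-row and
per-trait tibbles; `autoplot(rep)` plots recovered means against truth,
and `plot_trait_coverage()` shows per-trait completeness of any
species-level table. A thin command-line wrapper over the same functions is
installed at `inst/cli/traitsynth.R`
(`Rscript traitsynth.R run --config cfg.yaml --out DIR`).

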