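---
title: "Harmonizing microbial trait tables: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing microbial trait tables: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitsynth)
```

## The problem

Phenotypic and genomic trait observations for bacteria and archaea are
scattered across repositories and literature compilations that disagree on
column naming, units, categorical spellings, environment descriptions and
taxonomy. Merging them is mostly a curation problem: the scientific content
of the merger lives in small, auditable decisions — which raw spelling maps
to which controlled term, which datum is a known error, which species a
label refers to. `traitsynth` makes every one of those decisions a plain
CSV table applied by script, and condenses the merged records to species
level with explicit consensus rules.

The pipeline has four stages:

1. **prepare** — one raw source table plus a declarative YAML spec become
   standardized records: schema trait columns only, ranges split, units
   converted, organism labels resolved to taxon ids through an offline
   mapping table, and a reference attached to every row;
2. **combine** — all prepared records are stacked into one sparse table
   with zero overlap (no merging of rows), and the seven-rank lineage of
   each record's taxon is mapped on;
3. **condense traits** — categorical values are normalized against the
   controlled vocabularies, concatenated environment strings are translated
   into hierarchical labels, the corrections table is applied, and
   references are deduplicated into an id table;
4. **condense species** — records of each recognised species (strains
   included) collapse into one row per species, each trait by its data
   type's rule, followed by gap filling from a curated auxiliary table.

A core modelling assumption is inherited from the field's practice: records
of the same taxon in different sources are treated as *independent
observations* and are never deduplicated across sources. Conflicts are then
resolved statistically at species level rather than by source priority.

## Consensus rules and their edge cases

**Numeric traits** aggregate to mean, sample standard deviation
(`sd()`, denominator $n-1$ — the convention of the R scripts such mergers
are usually built from) and record count. A single observation yields a
blank standard deviation; no observations yield a blank triple with count
zero. Blanks never enter any denominator.

**Strict majority** (`condense_binary()`) assigns a term only when it
exceeds 50 % of the tally; a 50/50 tie assigns nothing. Cell shape and the
temperature/salinity preference traits are handled this way even though
they have more than two terms: they have no specificity structure, so
majority-or-nothing is the only defensible rule. A tie among more than two
shapes likewise yields a blank — we chose not to invent a generalization
for unstructured vocabularies.

**Multilevel vocabularies** (metabolism, motility) add two annotations per
term: a *category* of mutually compatible terms and an integer
*specificity* (1 = least specific), with each term pointing at its
specificity-1 generalization. The cascade is:

0. a strict majority wins outright;
1. terms from different categories (aerobic vs anaerobic) ⇒ blank;
2. one category, mixed specificity ⇒ the most specific term present;
3. one category, one specificity level, different terms ⇒ the shared
   generalization.

Two orderings here were genuinely open and are fixed as follows. First, the
majority short-circuit is applied *before* the category logic, because the
majority rule is the general condensation rule and the cascade is described
as the fallback when no term dominates. Second, a tie among distinct
equally-most-specific terms in rule 2 falls through to rule 3 (their shared
generalization) rather than to a blank: reducing conflicting same-category
terms to their least specific form is exactly what rule 3 does, and
blanking would discard information the category structure can still
support.

**Isolation source** labels are hierarchical, up to four underscore-joined
levels of increasing specificity. Condensation proceeds level by level:
at level $k$, the candidate terms are tallied over the labels that match
the accepted $(k-1)$-prefix *and* specify level $k$; the term with a strict
majority is accepted; otherwise the descent stops and the accepted prefix
is returned. "Dominant" is implemented as strict majority (>50 %) for
consistency with the categorical rule, so ties stop the descent. The
denominator choice — labels that stop above level $k$ neither support nor
veto deeper levels — maximizes the information extracted from vague
records without letting them block specific ones. A consequence worth
knowing: a species reported mostly as `soil` with a single
`soil_agricultural` record condenses to `soil_agricultural`, because the
single specific record is unopposed at level 2. The output is always a
prefix of at least one input label and never exceeds four levels.

**Multiset traits** (pathways, carbon substrates) have no printed
species-level rule in the tradition this package follows; record cells are
comma-separated term lists, and we take the sorted union of observed terms.
A majority rule would be ill-defined over sets observed with varying
completeness, and a union is the standard reading of "this species has been
observed to use X".

## Curation tables

*Term translations* `(trait, from, to)` map raw spellings onto vocabulary
terms; lookups are case-folded and whitespace-trimmed, and raw values with
no mapping are blanked and reported, never passed through. *Environment
translations* `(string, label)` are keyed by the exact concatenation
(separator `", "`, source column order, blanks dropped) of a source's
environment columns. *Corrections* `(dataset, taxon, trait, original,
corrected, comment, reference)` replace exactly the cells matching their
full key; zero-match corrections warn, because they usually mean an
upstream source changed under the table. Corrections are keyed on
*post-normalization* values: they run inside the condense-traits stage
after term mapping, so a correction targets what a curator sees in the
emitted record-level table, not a raw source spelling. For numeric traits
the value key is compared with a relative tolerance of 1e-6 so that a value
a curator read off an emitted CSV matches the unit-converted float in
memory. *Gap fills* `(species, trait, value, reference)` apply last, only
to blank species-level cells; a numeric fill gets count 1 and a blank
standard deviation, so filled and observed values remain distinguishable.

Reference ids are assigned by position in the sorted unique reference
strings — deterministic across reruns without any hashing — and the
reference table is shared by both taxonomies' products, since it is built
from the records before lineages are attached.

## Taxonomies

Both NCBI-style and GTDB-style taxonomies are consumed in one node-table
format `(taxon_id, parent_id, rank, name)`; the GTDB reader strips rank
prefixes (`s__`, `g__`, ...). Records outside the active taxonomy keep
their trait values but get empty lineages and are excluded from that
taxonomy's products — which is why GTDB-side products are smaller.
Species resolution excludes placeholder epithets: any whitespace token
equal to `sp.` or `sp` (case-insensitive) marks a genus-only record. The
token list is a parameter (`is_species_resolved(placeholders = ...)`)
because other placeholders (`cf.`, `aff.`) are curation conventions that
vary between sources. Label-to-id resolution is an exact normalized lookup
in an offline mapping table; unresolved labels are quarantined with a
reason and surfaced via `taxon_misses()` for manual curation, mirroring the
interactive lookups such tables are built from.

## Units

Canonical units are fixed in the schema: µm for cell diameters, hours for
doubling time, bp for genome size, percent (0–100) for GC content,
dimensionless counts for gene numbers, °C for temperatures, pH units for
optimum pH. The conversion registry ships exact multiplicative factors
(mm→µm ×1000, Mbp→bp ×10⁶, minutes→hours ÷60, fraction→percent ×100, ...)
and is extensible per call; temperatures accept only Celsius spellings
because an offset conversion has not been needed and silently accepting
Fahrenheit would be worse than erroring.

## The fixture generator

Real sources cannot be bundled, so the package generates synthetic ones
with known truth. Per species, numeric truths are drawn uniformly from
plausible ranges (genome size 2–8 Mbp, GC 30–70 %, optimum temperature
15–45 °C, ...), categorical truths uniformly from the vocabularies, and an
environment label from a fixed pool. Records are then drawn as:

* numeric: `truth × (1 + N(0, noise_sd))` — noise is *relative*, so
  `noise_sd = 0.1` means a 10 % coefficient of variation on every numeric
  trait regardless of scale. Gene-count traits are treated as continuous
  measurements (no rounding), keeping the noise model exact;
* categorical: the planted term with probability `majority_fraction`
  (default 0.8), otherwise a uniformly random other vocabulary term;
* environment: likewise, rendered through one of several raw strings per
  label so the translation table is genuinely exercised.

Three source layouts differ in column names, units (Mbp, minutes, mm),
range-string encodings and term spellings (resolved via the shipped
translation table). A fraction of records is emitted at strain level, a
fraction of species carries only a `sp.` placeholder, a fraction of labels
is absent from the mapping (exercising quarantine), and `error_rate` of
numeric cells receives a ×1000 magnitude error with a matching row in the
generated corrections table. Defaults — 50 species, 3 sources, 6 records
per species, majority fraction 0.8, relative noise 0.1, error rate 0.02 —
are the study conditions the recovery checks run under; they were chosen
once as a realistic small compilation and are not tuned.

`verify_recovery()` checks the pipeline against the planted truth. The
numeric criterion uses the *generator's known* noise standard deviation:
the species mean must fall within $3\,(\sigma_{\text{rel}}\,\mu)/\sqrt{n}$
of truth — the exact three-standard-error bound of the mean under the
noise model, with per-pair coverage $2\Phi(3)-1 \approx 99.7\%$.
(A bound built from the *sample* standard deviation would not be a
calibrated check at these counts: with $n \le 6$ the statistic is
t-distributed with heavy tails and three sample standard errors cover only
about 97 % of cases.) Categorical checks apply only where the planted term
holds a realized strict majority among the records that actually reached
aggregation; there the consensus must equal the truth. For isolation
sources the condensed label must *extend* the planted one, since an
unopposed more-specific record can legitimately deepen the label (see
above).

What the generator does not emulate: real sources' specific schemas,
correlated errors between sources, abundance-weighted sampling of taxa,
non-Gaussian measurement error, and multi-valued disagreement in multiset
traits (every record carries the species' full term set). Passing recovery
checks therefore demonstrates that the condensation machinery is correct
under independent noise — not that any particular real compilation is
error-free.

## Determinism and numerical choices

The pipeline itself has no randomness; all randomness lives in the fixture
generator and is fixed by `seed` (the generator also restores the caller's
RNG state). Rows are canonically ordered (dataset, source row) before ids
are assigned, so reruns on identical inputs are byte-identical — asserted
by checksum in the tests. Degenerate inputs are defined, not accidental:
empty term lists condense to blanks, a zero-row table emits header-only
products, unparseable range strings carry their original text into a log
and are excluded, and a correction whose replacement fails numeric parsing
is a table error rather than a silent `NA`.

The test suite runs the full pipeline on the default 50-species fixture
(330 records before quarantine), checks the consensus operations against
independent brute-force oracles over all multisets of size ≤ 5 from the
shipped vocabularies, and validates isolation-source outputs on 1,000
random label multisets — sizes chosen to exercise every rule branch while
keeping the suite quick on a laptop.

## Limitations

* The shipped vocabularies cover the terms needed to express the
  condensation rules (metabolism, motility, and the plain categorical
  traits); real compilations use far larger pathway and substrate
  vocabularies, which users supply as data.
* Environment translation is table-driven by exact string match; there is
  no fuzzy matching or ontology reasoning, by design.
* Corrections keyed on post-normalization values cannot target a raw
  source spelling that normalization already maps away; such fixes belong
  in the term-translation table instead.
* The workflow assumes per-record tallies; weighting sources equally
  (rather than records) is a defensible alternative the current
  implementation does not offer.
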