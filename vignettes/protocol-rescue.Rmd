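---
title: "Methods: homolog scoring and rule-based protocol mining in rescuerank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homolog scoring and rule-based protocol mining in rescuerank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rescuerank)
```

`rescuerank` automates the rescue of failed protein purifications: it
ranks purifiable homologs of the target, mines their purification
protocols from full-text articles, normalizes them into a standardized
table, and diffs the failed protocol against the successful ones. This
vignette is the package's own account of the methods: the model, the
parameters that matter, the numerical and design choices, and what the
test suite does and does not demonstrate.

## The composite similarity score

Candidate homologs arrive as tabular BLAST output. Retrieval applies
strict thresholds — percent identity above 20, e-value below 10⁻³,
query coverage above 75 — and caps the result at the 50 best hits by
bitscore (ties: smaller e-value, then subject id). The thresholds are
strict inequalities by a literal reading of "greater than"/"less than";
`filter_criteria(strict = FALSE)` switches to inclusive bounds for users
who prefer boundary hits to survive.

Each surviving hit receives two components on [0, 1]:

* `S_seq = pident / 100`, the normalized percent identity.
* `S_taxa`, derived from the rank-penalized distance between the query
  and subject organisms in a rooted taxonomy tree:
  `S_taxa = 0.5` at distance zero, else `1 − distance/maxdistance`.

The overall score is the weighted mean
`S_overall = w_seq · S_seq + w_taxa · S_taxa` with default weights 0.5
and 0.5, user-adjustable under the constraint `w_seq + w_taxa = 1`.
Ranking sorts by `S_overall` descending (ties: higher `S_seq`, then
subject id), drops hits below a user threshold, and truncates to a
limit. All tie-breaks are deterministic so identical inputs always give
identical rankings.

### The distance model

The taxonomy is an in-memory rooted tree loaded from a flat file
(4-column TSV or NCBI-taxdump dialect). The distance between two taxa
is computed on the unique up-to-LCA-and-down path: **every node on the
path except the lowest common ancestor contributes its rank penalty**
— equivalently, each edge charges its deeper endpoint. This convention
was chosen over the alternative "exclude the start node, include the
LCA and the end node" because the latter is asymmetric whenever the two
endpoints hold different ranks; the adopted rule is symmetric, yields
zero exactly for identical taxa and one penalty for a parent–child
pair, and coincides with the alternative under rank-uniform penalties.

The default penalty schedule rises with rank height:

| rank | species / strain / no_rank | genus | family | order | class | phylum | kingdom / domain |
|---|---|---|---|---|---|---|---|
| cost | 1 | 2 | 3 | 4 | 5 | 6 | 8 |

with a flat `domain_crossing_penalty = 16` added once when the two taxa
fall under different domain-rank ancestors. The magnitudes are package
choices, constrained to be monotone in rank height and to make the
domain surcharge dominate every per-rank cost; all are overridable via
`penalty_schedule()` or a key = value config file
(`read_penalty_schedule()`).

`maxdistance`, the normalizer that maps distances onto [0, 1], is
defined as the **penalized diameter of the tree** — the maximum
penalized distance over leaf pairs — so `S_taxa` is guaranteed
non-negative for in-tree pairs. It is computed exactly (all leaf pairs)
for trees up to `exact_limit = 500` nodes and by a
deepest-leaves-per-domain heuristic above that; a single-node tree
returns a floor of 1.0 so division is always defined.

Organisms absent from the tree are resolved by walking up a
caller-supplied lineage until a known ancestor is found
(`resolve_with_fallback()`); each hop subtracts
`missing_lineage_decrement = 0.05` from `S_taxa` (clamped to [0, 1]) —
a small, proportional, configurable price for the loss of resolution.
Same-organism hits (paralogs) have their finished taxonomic component
halved, *after* the fallback decrement and clamping, since the halving
is defined on the taxonomic similarity score as a whole. Whether to
clamp at zero when a distance exceeds the normalizer is not forced by
the formulas; the package clamps so `S_overall` stays interpretable as
a bounded score.

## Literature mining

Articles are parsed from JATS XML with namespaces ignored for tag
matching and no network access. Strict XML parsing is attempted first;
on failure the document is re-parsed leniently (stray entities,
mismatched inline tags), which downgrades the defect to a warning on
the document. Input is declared irrecoverable — a typed error carrying
the article id, logged by the batch loop and skipped — only when no
`<article>` element survives the repair. The methods section is every
section whose title contains the keyword `method` as a
**case-insensitive substring** (so "Materials and Methods",
"METHODS", "Experimental methods" all match); matched sections are
concatenated in document order, and a matched section nested inside an
already-matched ancestor is not double-counted. Substring matching and
the casing rule are package decisions — the keyword list is
configurable — chosen to capture the common title variants without
losing split methods subsections.

Citation accessibility is classified with fixed precedence: no primary
citation → not archived → no open license → accessible; exactly one
status per record.

## The rule-based agents

The three agent roles — extraction, summarization, optimization — are
contracts with schema-validated outputs. The tested default backend is
deterministic and rule-based; any remote model can be plugged in behind
the same interface (`callable_backend()`), in which case nonconforming
output is retried twice and then surfaced as a typed agent failure.
Prompt templates for remote backends ship as editable files under
`inst/templates/`; the lexicons below under `inst/extdata/lexicons/`.

* **Extraction** splits the methods text into sentences and keeps those
  containing at least one term of a purification lexicon (column,
  resin, buffer, elution, imidazole, dialysis, size-exclusion, lysis,
  …). The output is by construction a subset of the input sentences —
  nothing is synthesized — which is the mechanical analogue of
  hallucination-proofing: every downstream value must be traceable to
  the source article.
* **Summarization** segments the protocol text into steps on step
  keywords (lysis, equilibration/binding, wash, elution,
  dialysis/cleavage, size-exclusion), then fills the six standardized
  columns per step: the verbatim keyword occurrence as the step label,
  `"… buffer"` phrases as the buffer name, the verbatim span covering
  all recognized concentration mentions as the composition, `pH
  <number>` for pH, a salt lexicon for the salt type, and an additive
  lexicon for supplements. Every emitted value appears verbatim
  (whitespace-normalized) in the input; implausible pH values (outside
  0–14) become `NA` with a warning rather than silently corrected, and
  unsegmentable text yields a single warned step. Imidazole is
  deliberately absent from the supplement lexicon: it is the elution
  agent and belongs to the composition column.
* **Optimization** wraps the protocol diff and applies rule templates.
  Steps are aligned across protocols by a category lexicon (stage
  words — elution, wash, polish — take precedence over resin/column
  words, so "HisTrap column – Elution" is an elution step). Differences
  are reported per parameter: pH, salt type, named component
  concentrations parsed by a `number unit component` grammar (mM, M, %,
  mg/ml; molar units normalized to mM), and supplements present in
  successes but absent from the failed protocol. Numeric differences
  carry `delta` = successful median − failed value, so swapping the
  roles flips the sign. Each difference becomes a recommendation with a
  confidence label — high when ≥ 3 successful protocols exhibit it,
  medium for 2, low for 1, a package rule chosen for want of a
  published one. Target annotations add literature-independent advice
  (transmembrane span → mild detergent; signal peptide → construct
  truncation) at low confidence. The revised protocol is the failed
  protocol with numeric parameters moved to the successful median and
  missing supplements appended.

Missing cells render as `None` in the CSV and Markdown views, mirroring
the tabular summary convention; the CSV reader also repairs
decimal-comma pH values ("7,6") with a warning, as such transcription
artifacts occur in real summaries.

## The synthetic data generator

`make_fixture_bundle()` generates the full study input offline: a
balanced two-domain taxonomy (depth 3, binary branching, 31 nodes), a
35-row hit table (20 rows passing all filters; 5 violating each of the
identity/e-value/coverage thresholds; one paralog and one
lineage-fallback row among the survivors), three JATS articles each
planting a five-step His-tag purification rendered from rotated
sentence templates, a citation map with one planted inaccessible
record, and a failed protocol derived from the first article with two
planted deviations (elution imidazole halved to 250 mM; lysozyme
supplementation dropped from lysis). Every generator emits ground truth
alongside its files: pairwise leaf distances computed by a Dijkstra
oracle coded independently of the tree-walk implementation, exact
expected scores from a straight-line transcription of the scoring
formulas, and the six-column rows planted in each article. Identical
seed and spec give byte-identical fixtures.

The generator emulates the *structure* of real inputs — tabular hit
files with threshold violators, JATS section nesting, protocol prose in
varied phrasings, malformed downloads — not their content. Passing
tests therefore demonstrate that the machinery is faithful to its rules
and formulas on well-specified input; they do not demonstrate recall on
the long tail of real methods-section prose, where step phrasing,
unit spellings and buffer nomenclature are far more diverse than the
template rotation covers. The rule lexicons are editable text files
precisely so users can extend that coverage.

## Numerical choices and degenerate inputs

* Score components are clamped to [0, 1]; weights must sum to 1 within
  1e-9.
* Empty hit tables, empty filter results and zero mined protocols are
  all valid states: the pipeline completes and the report says what is
  missing; only misconfiguration (missing taxonomy file, out-of-range
  thresholds) fails before work starts.
* Malformed BLAST rows are skipped with a counted warning rather than
  failing the parse; malformed articles are logged per article and
  never abort the batch.
* All tie-breaks (bitscore → e-value → subject id for the retrieval
  cap; `S_overall` → `S_seq` → subject id for ranking) are fixed, and
  the rules backend is a pure function of its inputs, so a pipeline
  run is deterministic end to end — re-running on the same bundle
  yields byte-identical JSON reports.
* Test problem sizes: distance oracle equivalence is checked on 22
  random trees of 25–200 nodes over all node pairs; grounding on 100
  generated articles; these sizes exercise every code path while
  keeping the default suite fast.

## Known limitations

* The extraction and summarization rules are lexicon-bound: protocols
  described without the expected vocabulary (or in non-English prose)
  will be missed or under-filled. The remote-backend interface exists
  for exactly those cases, but its output quality is not evaluated
  here.
* Step alignment assumes one step per category per protocol; multi-step
  washes or two-stage affinity schemes collapse onto their first
  instance.
* The taxonomy penalties and the fallback decrement are heuristics; the
  score's ordinal behavior (closer relatives score higher) is tested,
  but the absolute magnitudes have no calibration target.
* Running BLAST and retrieving live articles or annotations are out of
  scope by design; the package consumes their file outputs.
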