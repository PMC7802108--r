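---
title: "Scoring cell types from immunohistochemistry staining: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cell types from immunohistochemistry staining: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellstainr)
```

## The data model

The unit of data is one pathologist-scored staining observation: a protein
(gene), a tissue, a cell type within that tissue, a categorical staining
level (`High`, `Medium`, `Low`, `Not detected`) and an antibody-reliability
label (`Enhanced`, `Supported`, `Approved`, `Uncertain`, in decreasing order
of evidence). Scores attach to the (tissue, cell type) pair — displayed as
`"TISSUE - cell type"` — because the same cell-type name (e.g. "glandular
cells") recurs across tissues with different biology.

Two normalization rules apply everywhere:

* **Closed vocabularies.** Level and reliability are matched
  case-insensitively after trimming; anything outside the vocabulary (real
  atlas files contain levels like `"N/A"`) is dropped at parse time and
  counted in the parse report, never silently lost and never an error.
  The report satisfies `retained + dropped = total` for every input.
* **Best level wins.** Several records can exist for one gene in one cell
  type (multiple antibodies, multiple samples). They are collapsed to the
  single strongest level (`High > Medium > Low > Not detected`) before any
  counting, so a heavily re-assayed protein is not double-counted.

Queries are matched on the upper-cased gene *symbol*, not the stable gene
identifier, because user lists are symbols; a symbol mapping to several
identifiers keeps all its records.

## The staining score

For a query and one cell type, with $t$ query proteins tested there (any
record, including `Not detected`) and $h$, $m$, $l$ of them at High, Medium,
Low:

$$S = \frac{100\,h + 50\,m + 25\,l}{t} \in [0, 100].$$

$S = 100$ exactly when every tested protein stains High, and $S = 0$ when
none stains. The geometric halving of the weights (100, 50, 25) encodes the
judgement that strong IHC staining is more robust and more cell-type-defining
than weak staining; it is a scoring convention, not an estimated quantity.

Two readings of $t$ are defensible and both are implemented:

* `t_mode = "tested"` (default): $t$ counts only query proteins *evaluated*
  in the cell type. Proteins absent from a cell type carry no information
  about it and do not dilute its score.
* `t_mode = "matched"`: $t$ is the full count of matched query proteins
  everywhere, so sparsely annotated cell types are penalized for missing
  data.

The default favours sparsely annotated cell types when their few tested
proteins stain; the confidence score exists precisely to counterbalance
that.

## The confidence score

$$C = \min(p, 50)\cdot S / 50,$$

with $p$ the number of proteins tested. $C \le S$ always, with equality when
$p \ge 50$ (the cap standardizes the range) or $S = 0$. It shrinks scores
built on thin evidence: a perfect $S = 100$ from a single tested protein
yields $C = 2$. Within a result table $p$ is the per-cell-type $t$.

## Enriched (rare) proteins and the per-cell-type test

A high staining score can simply reflect ubiquitously expressed proteins. The
complementary signal is whether the query over-represents proteins that are
*rarely* detected across cell types:

1. Filter records by stringency — `low` keeps all four reliability labels,
   `normal` (default) drops `Uncertain`, `high` keeps only
   `Enhanced`/`Supported`. The admitted sets nest, so high-stringency data is
   always a subset of normal, which is a subset of low.
2. For each protein, compute the fraction of cell types where it stains
   positively among those where it was evaluated. Proteins that never stain
   positively anywhere are excluded — their fraction would be 0 wherever
   they appear and they can never contribute a detected success.
3. The **enriched set** is every protein whose fraction lies at or below the
   first quartile of the observed fraction distribution. The cutoff is
   distribution-relative rather than a fixed 0.25, so it adapts as
   stringency shifts the distribution; the quartile uses linear interpolation
   between order statistics (`stats::quantile()` type 7) and the boundary is
   inclusive, making membership reproducible bit-for-bit. At least four
   proteins are required, otherwise the p-value columns are returned as `NA`
   with a warning rather than a meaningless cutoff.

For each scored cell type a 2×2 table is built over the proteins evaluated in
it (after filtering and deduplication): rows split query vs non-query,
columns split "enriched *and* positively stained here" vs everything else. A
query protein not evaluated in the cell type appears in no cell. The default
universe is the cell type's evaluated proteins; `background = "all"` widens
it to every protein in the filtered dataset, counting unevaluated proteins
as not detected — which construction the field's existing tools use is not
recoverable, so both are exposed and the local one is the default (it keeps
every margin well-defined per cell type).

The test is one-sided Fisher exact by default — enrichment is a directional
claim — computed as the hypergeometric tail $P(X \ge a)$; a two-sided option
and a chi-squared variant (1 df, continuity correction) exist. When any
expected cell count falls below 1 the chi-squared statistic is noise, so the
function warns and returns 1.0. P-values are Holm-adjusted across all cell
types scored in the run (the natural family for one query).

## Ordering and determinism

Results sort by staining score descending, then by more proteins tested,
then by display label, so equal-score rows have a fixed, reproducible order.
Scores are kept at full precision internally and rendered to two decimals
only in CSV output.

## The synthetic atlas generator

Real staining atlases cannot be redistributed with the package and their
download is a moving target, so the generator produces tables in the exact
TSV dialect with controllable structure: gene/cell-type counts, level and
reliability frequencies, evaluation coverage, optional planted marker blocks,
all deterministic from a seed. What it emulates deliberately:

* **Uneven evaluation depth.** Coverage classes produce the bimodal
  evaluated-proteins-per-cell-type histogram seen in curated atlases, where
  a few cell types are scored deeply and many sparsely.
* **Coverage–positivity coupling.** `heterogeneous_atlas_spec()` mixes "hot"
  cell types (coverage 0.9; levels 0.30/0.30/0.20/0.20 for
  High/Medium/Low/Not detected) with "cold" ones (coverage 0.03; levels
  0.02/0.05/0.08/0.85), defaulting to 100 cell types × 600 genes. A cold
  cell type only enters a result table when the sampled list happens to hit
  one of its few records, so small random lists over-represent hot,
  high-scoring cell types — the mechanism behind the downward drift of the
  null score with list size.

What it does *not* emulate: real gene symbols, biological co-expression
between markers of one cell type, antibody-specific artefacts, or
correlation between reliability and staining level. Passing tests on
generated atlases therefore validates the arithmetic, ordering, filtering
and invariances of the pipeline — not the biological accuracy of any real
atlas's annotations.

The worked-example fixture is hand-written, not sampled: three named cell
types with the published staining pattern of PRSS1/PNLIP/CELA3A/PRL plus six
fully negative distractors. Cells the textbook description leaves unstated
are filled with `Not detected` — the only completion under which all three
published scores (75, 25, 12.5) hold simultaneously with $t = 4$.

## The permutation null

`run_permutations()` samples gene lists uniformly without replacement from
the distinct symbols of the (stringency-filtered) atlas, scores every cell
type per list, and keeps the full score vector plus the top-*k* flags. The
full published profile is 1,000 runs at sizes 10/25/50/100 with top 10; the
package's own checks use 500 runs per size for the distribution-trend
property and 3–100 runs for exactness and determinism properties, sizes that
keep the whole suite fast while leaving the estimates far above their noise
floor. Scoring uses a precomputed gene × cell-type weight matrix; a test
pins its output to `score_query()` exactly, so the fast path cannot drift
from the reference implementation. Each (size, run) pair seeds its own
substream, `(seed + 1009·size + run) mod (2^31 - 1)`, so any slice of the
study reproduces independently.

## Numerical and degenerate-input choices

* Quartile: `stats::quantile()` type 7 (linear interpolation), inclusive
  boundary; stated so enriched sets are exactly reproducible.
* $t = 0$ cell types are excluded upstream; calling `staining_score()` with
  $t = 0$ is an explicit error, not `NaN`.
* Empty files, header-only files, missing columns, non-integer patient
  counts, queries with no tokens and queries matching nothing are distinct,
  classed error conditions (`cellstainr_error_*`), so pipelines and the CLI
  can react per cause.
* Cancer tables carry patient counts per level rather than one call. Counts
  become fractional level contributions ($h \mathrel{+}= \text{high}/N$,
  etc.), preserving within-cancer heterogeneity instead of flattening each
  gene–cancer pair to its modal level; duplicate gene×cancer rows are summed
  before normalizing. All-blank and all-zero count rows are dropped and
  reported.

## Known limitations

* Detection fractions are computed over (tissue, cell type) pairs; a
  protein specific to one cell type that recurs across many tissues will
  look less rare than it is within any one tissue.
* The enriched-set test conditions on the query's matched proteins; symbols
  absent from the atlas are silently unmatched (reported in `glance()`),
  which can weaken the test for lists with many aliases — no alias
  resolution is attempted.
* The confidence score is a heuristic re-weighting, not a calibrated
  probability; compare it only within a run.
* Nothing here validates antibodies: the stringency filter trusts the
  atlas's reliability labels as given.
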