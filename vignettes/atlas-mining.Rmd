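---
title: "Mining multi-tissue expression atlases for core and tissue-specific signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining multi-tissue expression atlases for core and tissue-specific signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasmine)
```

## The analysis problem

Multi-tissue expression atlases — Affymetrix-style signal matrices over many
tissues, several biological replicates each, with per-cell present/marginal/
absent detection calls — are usually consulted gene by gene. atlasmine
implements the meta-analysis workflow instead: given such an atlas, find the
*core signature* shared by a designated tissue set (the motivating case is
the eight transporting epithelia of *Drosophila melanogaster* — adult and
larval salivary gland, midgut, Malpighian tubule and hindgut — profiled by
FlyAtlas-style resources), rank the most tissue-specific genes per tissue,
profile curated gene lists across tissues, and check that tissue
transcriptomes carry the expected global structure.

Two entry points mirror how such studies are actually run:

* **hypothesis-led** — a curated gene list (e.g. V-ATPase subunits, cation/
  proton exchangers, ion channels) is mapped onto the atlas
  (`profile_gene_list()`), and within each paralog family the dominant
  isoform per tissue is identified (`dominant_isoform()`, `family_profile()`);
* **hypothesis-free** — every gene is scored by fold-change enrichment
  against a whole-organism reference, and genes consistently enriched across
  the tissue set are detected with no prior knowledge (`core_signature()`).

## The enrichment statistic

All detection is ratio-based; there is no variance model and no p-value,
because the upstream quantity is a per-tissue mean over a small, fixed number
of replicates.  For gene $g$ and tissue $t$,

$$\mathrm{FC}(g,t) \;=\; \frac{\max\{\bar s_{g,t},\, f\}}{\max\{\bar s_{g,r},\, f\}},$$

where $\bar s_{g,t}$ is the arithmetic mean signal over non-missing
replicates, $r$ is the reference tissue (a whole-organism sample), and $f$ is
a signal floor.

* **Aggregation is the arithmetic mean on the raw signal scale**, not a
  log-mean: published tissue-level tables print signal-scale values
  consistent with plain means, and the statistic is a ratio of such means.
* **The floor (default $f = 1$ signal unit)** is applied to *both* operands.
  Atlases contain exact zeros, and no imputation or pseudocount rule is
  inherited from upstream software; flooring both sides bounds the ratio,
  keeps it symmetric, and makes `FC` converge to the plain ratio as
  $f \to 0^+$ for strictly positive signals.  Because signals are in
  arbitrary fluorescence units, the floor is in the same units and should be
  scaled if the signals are rescaled (the tests verify exact scale
  invariance under this convention).
* **Missing cells stay missing.**  A blank cell in an input table is `NA`,
  never 0, is excluded from replicate means, and renders the fold change
  undefined rather than inventing a value.

## The consensus core criterion

A gene belongs to the core signature iff its fold change is *defined* and at
least $\tau$ in *every* tissue of the configured set; the default
$\tau = 2.5$ over eight epithelia is the published operating point of the
motivating study.  Requiring defined evidence in all tissues is deliberate:
consistent enrichment cannot be asserted on missing evidence.

`core_signature()` keeps all genes with per-tissue pass flags rather than
returning only the winners, and `criterion_audit()` lists every evidence
cell below $\tau$.  This matters in practice: published consensus tables can
print cells below their own stated threshold (typically because the
selection ran on unrounded replicate-level ratios while the table prints
rounded tissue-level ones).  The audit documents such discrepancies instead
of guessing author intent.  The same caution applies to the two routes to a
fold change: a ratio of printed tissue-level means and a published
replicate-level fold change for the same cell can differ by a few percent
(61.5 vs 63.1 for the bundled aquaporin example), so the package reports
both routes and never asserts their equality.

An alternative, stricter criterion is provided for comparison:
`strict_call_signature()` demands a present call in all inside tissues and
an absent call in all outside tissues (defaults `present_min = 1`,
`absent_max = 0`, matching the "present in all / absent in all" reading).
On realistic data this is typically so stringent that it returns few or no
genes, which is precisely why the fold-change consensus exists; the test
suite checks this relationship on simulated data.

## Tissue-specific rankings

`tissue_specific_top_n()` ranks genes by descending fold change in one
tissue and keeps the top $N$ (default 50, the published list size).
"Most specific in either larva or adult" is ambiguous, so both views are
available: per-tissue columns are ranked separately, and a merged
adult/larval view ranks the per-gene maximum over the cognate pair.  Ties
break by gene symbol then probe id, so output is reproducible.  An optional
`exclusive` flag drops genes whose enrichment elsewhere exceeds their
target-tissue enrichment; it is off by default because the published
procedure does not state an exclusivity rule.

Duplicate probe sets for one gene symbol are retained as distinct records
keyed by probe id (published tables print such duplicates).  Where a
gene-level summary is needed — symbol lookups in `max_enrichment()` /
`min_enrichment()`, family members in `dominant_isoform()` — the per-tissue
maximum across the symbol's probes is used, preserving "abundantly
expressed" semantics.

## Clustering and ordination

The structural sanity checks follow standard transcriptome practice, as the
motivating study cites general clustering literature without fixing a
metric:

* **Distance**: $1 - r$, Pearson's $r$ on $\log_2(\text{signal}+1)$ over
  genes defined in both tissues — scale-free and insensitive to the
  arbitrary signal units.  At least 3 shared genes are required.
* **Linkage**: average (UPGMA), giving ultrametric merge heights; tissues
  are processed in name order so ties resolve reproducibly.
* **PCA** operates on centered $\log_2(\text{signal}+1)$ tissue-mean
  vectors ("grouped replicates"); genes with any missing value are dropped.
  Component signs are fixed by making each component's largest-magnitude
  loading positive, so scores are bit-reproducible.
* **Cohesion reports** (`group_cohesion()`): mean silhouette of a tissue
  group in PC score space (direct formula, Euclidean distance) and whether
  the group forms a clade of the dendrogram.  `cognate_siblings()` checks
  the hallmark structure that each adult/larval cognate pair clusters
  together.

One deliberate choice: **the whole-organism reference is excluded from
tissue clustering** (`subset_tissues()`; the pipeline does this by
default).  A whole-organism sample is a mixture of tissues, not a tissue;
including it distorts tissue-to-tissue comparisons because it correlates
with everything.

## The synthetic atlas generator

Published atlas data cannot be redistributed with the package, and recovery
of *known* truth cannot be tested on real data at all, so `generate_atlas()`
draws atlases with the statistical structure the analysis assumes, plus a
ground-truth table for `evaluate_recovery()`.

The model, per gene: a log-normal baseline ($\log_2$ mean 5, sd 2;
housekeeping class: mean 11, sd 1 — high everywhere), one of four classes
(defaults: 10% housekeeping, 2.5% core, 10% tissue-specific, 77.5%
background; 2000 genes, i.e. 50 planted core genes), planted fold changes
(core: uniform 3–10 applied in all eight epithelial tissues; specific:
uniform 10–100 in one target tissue, targets cycling over the non-reference
tissues), and 4 replicates per tissue with multiplicative log-normal noise
of mean 1 and CV 0.2.  A present call is emitted when a signal exceeds the
detection threshold (default 50 units).  The defaults reproduce the gross
features of real tissue-level tables: strictly positive, heavily
right-skewed signals spanning roughly 0–14,000 units.

Correlation structure is carried by the background class only: paired
tissues share 80% of a log-normal tissue effect ($\log_2$ sd 0.5, the rest
being stage-specific perturbation), while unpaired non-reference tissues
(the neuronal and germline out-groups) receive a larger independent effect
($\log_2$ sd 1) — out-groups are more distinct from the epithelia than the
epithelia are from each other.  The whole-organism reference receives no
tissue effect at all: it *is* the organism-wide average that every planted
fold change is defined against.  An intermediate design that gave the
reference its own independent effect was rejected: a low reference draw
would fake enrichment in every tissue at once, which cannot happen with a
real whole-organism sample that physically contains its tissues.

Restricting tissue effects to the background class makes the construction
its own oracle: planted classes have deterministic tissue means, so in the
noise-free limit (CV = 0, floor $\to 0$) the pipeline fold change of a core
gene equals its planted fold change *exactly*, and precision and recall are
exactly 1.  The tests exploit this.

What the generator does **not** emulate: probe-level artifacts
(cross-hybridization, saturation), heteroskedastic noise at low signal,
marginal detection calls, correlated gene modules beyond the planted
classes, and compositional coupling between the reference and the tissues.
Passing recovery tests therefore demonstrates that the detectors implement
their criteria correctly under the stated model, not that the criteria are
optimal for any particular real platform.

## Numerical and degenerate-input conventions

* All rankings and pass sets use deterministic tie-breaks (gene symbol,
  then probe id; tissue order from the configuration for argmax ties).
* `evaluate_recovery()` defines precision as 0 (flagged) when nothing was
  detected; recall is 0 when the positive class is empty.
* Serialization (`write_table()` / `read_table()`) writes numeric values at
  6 significant digits with structural metadata in a single `#`-prefixed
  JSON header line; a write/read cycle reproduces tables exactly at that
  precision, including missing cells.
* Degenerate inputs error early with specific messages: duplicate probe
  ids, negative signals, sample/metadata mismatches, overlapping
  inside/outside tissue sets, empty tissue sets, non-positive floors or
  thresholds, fewer than 3 shared genes for a distance, fewer than 2
  tissues for clustering.

## Problem sizes used by the test suite

The bundled checks run on the two transcribed published tables (102 probes
by 11 tissues; 25 genes by 8 epithelia), on simulated atlases at the default
size (2000 genes, 11 tissues, 4 replicates) for recovery and clustering
structure, and on small randomized instances (tens of genes, hundreds of
repetitions) for the brute-force oracle equivalences and monotonicity
properties.  The full suite and the acceptance script each complete in well
under a minute on a single CPU.

## Known limitations

* The consensus detector is intentionally criterion-faithful: it applies
  the threshold to computed tissue-level fold changes and will therefore
  disagree with published gene sets that were selected on unrounded
  replicate-level values — the audit exists to surface exactly that.
* No differential-expression statistics: the workflow is ratio- and
  rank-based by design, matching its source methodology.
* Gene identity is symbol-based; no annotation database lookup or probe
  re-mapping is performed.
* PCA input is the tissue-mean profile; a replicate-level analysis can be
  emulated by passing a profile built from an atlas whose "tissues" are
  individual replicates.
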