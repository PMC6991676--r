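---
title: "Methods: dynamic signatures across ordered disease stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic signatures across ordered disease stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagenet)
```

This vignette is the package's account of the statistical procedure it
implements, the modelling choices that were genuinely open, and what the
synthetic-data validation does and does not demonstrate.

## The model

The input is a gene-by-sample matrix with each sample assigned to one of
three ordered disease stages (the machinery generalizes to two or more;
the d-PCC analysis assumes exactly three). Stage order is always explicit
user input — it is never inferred from label strings, because stage
labels carry no reliable ordering.

**Preprocessing.** Probe-level rows mapping to the same gene are averaged
(`collapse_probes_mean()`), then every gene is z-scored across *all*
samples jointly (`zscore_normalize()`, n−1 denominator). Joint rather
than per-stage scaling is deliberate: per-stage scaling would erase the
between-stage mean differences the transition tests estimate. Z-scoring
leaves Pearson correlations unchanged (asserted by a test), so the
co-expression analyses are unaffected by this choice. Zero-variance genes
are set to zero and flagged rather than dropped, so the gene universe is
stable; they are excluded from correlation-based statistics.

**Dynamic DEGs.** Each transition is tested per gene with a two-sided
pooled-variance Student *t* test, following the classical formulation
("Student's t") rather than Welch; Welch is available via a flag. The
tests default to running on the z-scored values (the pipeline's stated
order); a raw-scale option exists because pooled *t* on raw and z-scored
data are not identical. P-values are adjusted with Benjamini–Hochberg
within each transition, and a *dynamic* DEG must pass the FDR threshold
(default 0.05; a strict 0.01 tier feeds the hub table) in **both**
transitions. Direction codes are recorded per transition from the sign of
the mean difference; no sign consistency is imposed across transitions —
a gene that rises then falls is exactly the kind of dynamic behaviour the
analysis is after. Degenerate genes with zero pooled variance get p = 1
when the group means agree and p = 0 when they differ.

**Dynamic co-expression links.** Within each stage with at least three
samples, Pearson correlations are computed for every gene pair; the
transition statistic is the plain difference of correlations (d-PCC). A
pair is a differentially co-expressed link (DL) in a transition when
|d-PCC| lies in the **closed** interval [0.8, 2]. The lower bound is read
as inclusive ("ranging from 0.8 to 2"); since |d-PCC| ≤ 2 always, the
upper bound only matters as the theoretical ceiling. Dynamic DLs are the
pair-set intersection of the two transitions' DLs. Again no sign flip is
required by default — the definition is an overlap — but
`require_sign_flip = TRUE` implements the stricter reading. The pair
universe defaults to all non-degenerate genes; `gene_subset` (e.g. the
background-PPI node set) tames the O(G²) cost for large panels, and is
harmless for the final network because PPI projection would discard
outside pairs anyway. Correlations are computed with dense matrix
algebra in one pass; at the package's intended scales (up to ~20k genes)
one correlation matrix fits comfortably in memory, so no block scheme is
used.

**Dynamic PPI network.** Background interaction tables (2–3 column TSVs
from any database export) are canonicalized — lexicographic pair order,
self-loops dropped, duplicates collapsed to the maximum confidence with
source tags concatenated — and merged by union. Scored edges are kept
only with confidence **strictly** greater than 0.4 (the medium-confidence
convention); unscored edges (e.g. pathway-derived) pass the filter, since
confidence scores are only comparable within a scored source. Projection
of dynamic DLs uses edge-intersection semantics by default: a DL becomes
a network edge only if the same unordered pair is itself a background
interaction. The wording "mapped onto the background network" is
ambiguous, so a node-induced mode (`mode = "nodes"`: keep DLs whose both
endpoints are background nodes) is provided; the two differ exactly in
whether the interaction evidence must be pairwise. Edges carry both
d-PCC values, the background sources, and shared-neighbour scores (count
and Jaccard of common background neighbours, endpoints excluded). Hubs
are ranked by degree with lexicographic tie-breaks, by convention over
the strict (FDR < 0.01) dynamic-DEG universe. TRED-style directed
regulatory edges are treated as undirected, as the merge treats all
sources as one PPI.

**Weighted co-expression modules.** The core is the standard weighted
network construction: unsigned adjacency a_ij = |cor|^β (the field's
default when sign handling is unstated), connectivity k_i = Σ_j a_ij, and
the topological overlap measure

TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij).

The soft power β is chosen by a scan over 1..20: connectivities are split
into 10 equal-count bins, the empirical density p(k) per bin (bin
frequency divided by bin width) is regressed on mean k on log–log axes,
and the fit index is R² signed by the negated slope, so only a
*decreasing* approximate power law scores high. The lowest β reaching the
target (default 0.9) is chosen; if none reaches it the best-fitting β is
used with a warning. Equal-count binning with a density estimate was
chosen over equal-width binning after observing that the latter is
erratic when connectivities concentrate in a narrow range, which is
common for latent-factor data; with equal-count bins the index is stable
and still penalizes flat or increasing degree distributions.

Modules are detected by average-linkage hierarchical clustering of
1 − TOM with a static cut (default height 0.995) — a deliberately simpler
stand-in for dynamic-hybrid tree cutting, whose branch heuristics are out
of scope — followed by two standard refinements: clusters below
`min_module_size` (default 30) become grey/unassigned, and modules whose
eigengene dissimilarity 1 − cor(ME_i, ME_j) falls below `merge_height`
(default 0.25) are merged iteratively, closest pair first. Validation is
therefore planted-structure recovery (adjusted Rand index), never
label-for-label equality with any particular reference implementation.
Colour labels follow the conventional ordered palette (turquoise, blue,
brown, … by decreasing size; grey = unassigned) so reports are
deterministic.

The module eigengene is the first right singular vector of the
gene-standardized module submatrix (unit norm, sign oriented so the mean
correlation with member genes is positive). Module–trait association is
the Pearson correlation of eigengenes with numeric traits,
pairwise-complete over samples (no imputation), with two-sided p-values
from t = r√(n−2)/√(1−r²); gene significance is |cor(gene, trait)| and
module membership cor(gene, eigengene); intramodular connectivity k_IM
sums a gene's adjacency to its own module's members and defines module
hubs.

**Over-representation.** Exact one-sided hypergeometric tail
p = Σ_{i≥k} C(K,i)C(N−K,n−i)/C(N,n) per gene set, BH across sets. The
universe defaults to the measured genes after probe collapsing — the
conservative standard — not the genome; using the genome would inflate
every enrichment. Both raw-p and q thresholds are exposed in the output
so either convention can be applied.

## The synthetic-data generator

`generator_config()` defaults encode the study conditions the package is
designed around: three stages with 10/18/18 samples (a realistic small
discovery cohort), 500 genes, 30 dynamic-DE genes with 2-SD shifts per
transition (signs drawn per gene per transition), 20 rewired pairs with
per-stage correlations (0.8, −0.6, 0.6) — transition deltas −1.4 and
+1.2, both beyond the 0.8 DL threshold — four latent-factor modules of 50
genes with residual noise SD 0.5 (within-module correlation ≈ 0.8), and a
trait equal to module 1's factor plus N(0, 0.5²) noise (expected
|module–trait r| ≈ 0.9). Planted pools are disjoint, so every truth set
is unambiguous; rewired pairs *replace* baseline values, keeping
marginals standard normal. The synthetic background PPI covers a
configurable fraction of the planted pairs plus random edges, with
Uniform(0.2, 1) confidence so the >0.4 filter is exercised. All
randomness flows from one integer seed; the same seed reproduces the
dataset bit for bit.

What the generator does *not* emulate: microarray probe effects,
background correction, batch structure, count noise, heavy-tailed
expression, correlated trait panels. Passing the planted-recovery tests
therefore demonstrates the statistical machinery is correct at realistic
effect sizes and sample sizes — not that any particular real cohort will
yield stable signatures.

## Validation design and problem sizes

The test suite checks each operation against an independent oracle
(pairwise correlation formula, textbook BH step-up loop, triple-loop TOM,
combinatorial hypergeometric sum, brute-force scans and counting), null
behaviour (false-positive control for dynamic DEGs and DLs; KS uniformity
of t-test and correlation p-values), and planted recovery at the
conditions above: dynamic-DEG recall/precision ≥ 0.8 at 2-SD shifts with
n = 15/stage over 500 genes; dynamic-DL recall ≥ 0.8 for |Δρ| ≥ 1.2 with
n = 30/stage; module ARI ≥ 0.8 with the trait-linked module attaining the
top |module–trait r|. Module recovery is evaluated with the four planted
modules among 300 genes: the 100 unplanted background genes keep the
degree distribution heterogeneous, which is what real transcriptomes look
like and what a scale-free power scan requires — on an all-module universe
every gene has nearly the same connectivity and the scan's fit index is
uninformative. These sizes keep the whole suite within a few seconds
while leaving comfortable statistical margins.

Under the null (no planted structure, n = 30/stage), the sampling SD of a
correlation difference is ≈ √2/√(n−3) ≈ 0.27, so |d-PCC| ≥ 0.8 is a ≈ 3σ
event per transition and the both-transition rule makes false dynamic DLs
rare (observed fraction ≤ 0.5% of pairs, typically zero).

## Degenerate inputs and numerical conventions

* Constant genes: flagged by `zscore_normalize()`, `NA` rows in
  correlation matrices, excluded from pair statistics.
* Zero pooled variance in a t-test: p = 1 (equal means) or 0 (unequal).
* Edge canonicalization is idempotent; confidence `NA` means unscored and
  survives filtering.
* Eigengene sign: oriented by mean member correlation; a module whose
  members split evenly in sign keeps the SVD's arbitrary orientation.
* BH is the only FDR procedure offered (the convention throughout);
  q-values are monotone in p-rank, not per-gene ≥ p.
* Ties in hub ranking break lexicographically so output is reproducible.

## Interfaces

This package is a library, not a shell tool: the module surface is the
exported functions, with `run_all()` orchestrating the standard workflow
(normalize → dynamic DEGs → dynamic DLs → PPI projection/hubs → modules →
enrichment) and aborting with a stage-named error on failure. Readers and
writers cover tab-separated expression matrices, the GEO series-matrix
dialect (`read_series_matrix()` returns an unstaged dataset plus the
sample-characteristics lines so the caller can build the stage map
explicitly, then `set_stages()`), edge TSVs, GMT collections, and
SIF/GraphML/TSV network exports for external viewers. Reproducing a GEO
cohort analysis is therefore: download the series matrix, build the
probe→gene map and stage map from its annotation, then
`collapse_probes_mean()` and `run_all()` with the default thresholds.

## Known limitations

* The static cut plus eigengene merging approximates, but does not
  reproduce, dynamic-hybrid tree cutting; module boundaries on real data
  will differ from other implementations in the grey fringe.
* The d-PCC rule is a fixed threshold, not a significance test (no Fisher
  z); with very small stages the DL lists are noisy by construction, as
  the null-control analysis quantifies.
* No batch correction, no moderated statistics, no probe annotation
  retrieval, no ID mapping: gene identifiers are case-sensitive symbols
  taken as given.
* The all-pairs link table is restricted to pairs passing the DL rule in
  at least one transition; the full G² table is never materialized.
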