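---
title: "Models and methods behind sclymph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sclymph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclymph)
```

sclymph packages the bespoke computations used in single-cell studies of
primary CNS diffuse large B-cell lymphoma: malignancy evidence, cell-of-origin
calling, cross-sample expression-program discovery, clonality statistics, and
score-based survival stratification. This vignette records the models, the
parameter defaults and their rationale, the numerical choices, and what a
green test does and does not establish.

## The synthetic cohort: a stated world, not a fitted one

No public distributional description of the motivating patient cohorts
exists, so every generator choice is an explicit stand-in, chosen once to be
realistic for droplet scRNA-seq of lymphoma tissue and then left alone:

- **Counts.** `counts ~ NB(mean = s_c · exp(mu_g + Σ_p a_cp δ_p) · cnv_g(c),
  θ)` with `Var = m + m²/θ` (the standard mean/inverse-dispersion
  parameterization, because its moments are directly testable). Defaults:
  `mu_g ~ N(−1, 1)`, cell factor `s_c ~ logNormal(log 4, 0.3)`, `θ = 2` —
  together giving ~2–3 counts per gene per cell and a few thousand UMIs per
  cell, the magnitude of real droplet data at a ~1200-gene universe.
- **Scale.** 5 tumors × (300 malignant + 100 non-malignant B + 100 CD8 T)
  cells over ~1200 genes. Real cohorts are an order of magnitude larger in
  both cells and genes; the scale here is what a 1-CPU test budget affords,
  and every acceptance criterion is a property of the method, not of the
  cohort size.
- **Programs.** Binary per-cell activity `a_cp ~ Bernoulli(active_fraction)`
  restricted to malignant cells of the program's samples; activity shifts the
  log mean of the program's genes by `δ`. Defaults: three programs shared by
  all tumors plus two sample-private ones, `δ = 1`, `active_fraction = 0.25`,
  50-gene sets — mirroring the observation that recurrent meta-programs are
  expressed by minorities of malignant cells.
- **Light chains.** Two constant plus five variable genes per class. A
  restricted malignant cell multiplies its on-class gene means by 50 and
  draws every off-class gene from mean 0.01, producing the allelic-exclusion
  readout. Non-malignant B cells express both classes at comparable levels so
  their cluster statistic reads balanced; per-cell exclusion of *normal* B
  cells (a polyclonal mixture) is deliberately not emulated — the statistic
  under test is the cluster-level median, which a mixture of truly excluded
  cells would make unstable at test sizes.
- **CNV.** Contiguous blocks act multiplicatively on gene means before NB
  sampling, in a `clone_fraction` subclone — matching the detectability
  assumption of expression-based CNV inference (a 2× mean shift, not an
  integer copy-number model).
- **Repertoire.** Geometric (default p = 0.15) or power-law clone sizes;
  CDR3 nucleotide strings uniform over {A,C,G,T}^L with L ∈ [30, 45], where
  collisions are negligible (4^30 ≫ clone count); a `multi_chain_fraction`
  of cells receives a second same-locus contig to exercise the clonotyping
  filter. No V(D)J germline structure or somatic hypermutation.
- **Survival.** Exponential event times with hazard `1/baseline_scale`
  multiplied by `hazard_ratio` above the planted score cutpoint; censoring
  replaces a `censor_rate` fraction of observations by a uniform draw below
  the event time. Defaults (n = 200, cutpoint 0.5, HR = 4, 10% censoring)
  give the cutpoint-recovery tests ~90% power without being trivial.
- **Seeds.** One master seed; each stage derives an independent child seed
  (`child_seed()`, a fixed affine hash kept below 2³¹), so identical configs
  are byte-identical and stages are individually reproducible. R's default
  Mersenne-Twister stream is assumed.

A green recovery test therefore establishes that the implementation inverts
*this* generative model at desk scale. It does not establish performance on
real tissue: ambient RNA, doublets, batch effects, gene-length and capture
biases, and continuous (non-binary) program usage are all absent.

## Quality control and normalization

Thresholds follow the standard recipe exactly: genes expressed (count > 0)
in < 50 cells are removed first; cells are then kept when expressed genes
∈ [500, 6000] (inclusive — "from … to"), mitochondrial fraction < 0.15 and
total counts < 50,000 (both strict — "lower than", "less than"). The three
cell rules are a conjunction evaluated on the gene-filtered matrix, so their
order is immaterial. Mitochondrial genes are flagged by the configurable
id prefix `MT-`. Doublet detection and batch correction are intentionally
out of scope; the generator plants no doublets.

Normalization is per-cell: `log(1 + count · 10000 / total)`, with all-zero
cells passed through untouched. Highly variable genes are ranked by
dispersion (variance/mean) z-scored within 20 equal-width mean-expression
bins — the flavor is not specified by upstream descriptions, and this
standard choice is asserted only through its downstream recoveries.
Clustering is seeded Louvain on a symmetric kNN graph (k = 15) over 40 PCs;
only the resolution is considered contract, not the community algorithm.

## Malignancy evidence

**Allelic exclusion.** "Relative expression" is made concrete as
`kappa_max / (kappa_max + lambda_max)` on log-normalized values, with the
per-chain maximum over the chain's gene list (expression levels differ
widely across κ/λ genes, hence the max). Cells with both maxima zero are
flagged and excluded from cluster medians. Restriction thresholds 0.9/0.1
are configurable defaults; whether a formal test should back the call is
left open upstream, so the threshold rule stands in.

**Windowed CNV.** Per gene, expression relative to the mean over reference
cells; per cell, a centered moving average over 101 genes within each
chromosome (shrinking at edges), clipped to ±3, then centered per cell
(hence every profile has exactly zero mean — asserted to 1e−8). Chromosomes
with < window/4 genes are dropped with a warning. This reproduces only the
*detectability* of block events; the HMM state calling, subclustering and
tree building of full CNV-inference tools are out of scope. Ordering ties
are broken by gene id so the profile is invariant to input gene permutation.

**Hypergeometric overlap.** `P(X ≥ k)` summed exactly in log space
(`logsumexp` over `dhyper(·, log = TRUE)`), so p-values far below the
double-precision denormal range of a naive sum (e.g. 1e−252 and smaller)
remain finite and comparable.

## Cell of origin

The four steps — restrict to marker genes, quantile-normalize cells,
log2(x+1), per-gene z across cells, mean z per set — run on raw counts of
malignant cells. Choices the upstream description leaves open:

- *z across cells, not across genes*: per-gene standardization is the
  standard reading of "z-normalization across these genes" and makes the two
  set means comparable; the per-cell alternative was rejected because it
  couples the two scores through the cell's own distribution.
- sd uses ddof = 1; zero-variance genes get z = 0 (avoids NaN propagation).
- quantile-normalization ties receive the average of the reference values at
  the tied positions.
- normalization is applied to whatever cell set is passed; per-sample versus
  pooled application is thus the caller's choice (the worked examples pool).

Labels: ABC iff combined > 0.25 ∧ GCB score < 0.75; GCB iff combined
< −0.25 ∧ ABC score < 0.75; else Unclassified. Published ABC/GCB marker
lists are not redistributed; the package ships synthetic example sets wired
to the generator (`inst/extdata/coo_sets_synthetic.tsv`).

## Meta-programs

Per sample, consensus NMF: seeded multiplicative-update factorizations
(Frobenius objective) of the nonnegative HVG submatrix, restarted
`n_restarts` times; all spectra are pooled and L2-normalized; spectra whose
mean distance to their k nearest pooled neighbors falls in the top
`density_quantile` (default 0.25) tail are discarded as outliers; survivors
are k-means-clustered into k groups; consensus spectra are componentwise
medians, renormalized; usages are refit by Lawson–Hanson NNLS. The rank k is
nowhere specified upstream; the default 7 matches the scale of recurrent
programs reported in this disease, and tests override it per scenario.

Across samples, module spectra are correlated over the union gene space
(absent genes weighted 0 — module correlations on spectra rather than
usages, since usages do not share a space across samples), clustered with
average linkage on 1 − r and cut at height 0.7 (a deterministic stand-in
for the manual cut used in practice). Clusters recurring in ≥ 4 distinct
samples are retained; each meta-program's gene list is the top 50 genes by
mean within-module weight rank.

Signature scores are binned-control scores: 25 equal-frequency bins of mean
expression, 50 controls per set gene sampled without replacement from the
set gene's bin (set genes excluded, pooled controls deduplicated), seeded.
MP-positive cells are those with score above a threshold; the default
mean + 2 sd is a conservative stand-in for the manual per-program thresholds
used in practice (a worked threshold of 0.9 for the plasmablast-like program
is honored in the examples and tests).

## Heterogeneity and repertoire

DEPTH2 takes a pseudo-bulk matrix (per-sample mean expression), z-scores
each gene across samples (ddof = 1, zero-variance genes → 0) and reports the
per-sample sd of |z|. Hill numbers use the closed forms with the q → 1
Shannon limit taken analytically at |q − 1| < 1e−9.

Clonotypes are keyed by CDR3 nucleotide sequences of all chains (paired-chain
set key by default; a TRB-only switch exists because upstream practice is
ambiguous). "Multiple chains" means > 1 contig of the *same* locus — the
normal paired TRA+TRB cell is kept. "Clone size of more than 10" is size
≥ 11. Morisita–Horn and Berger–Parker follow their textbook forms.

## Outcomes

DEG: per-gene two-sided Mann–Whitney with tie-corrected variance and 0.5
continuity correction (equals `wilcox.test(exact = FALSE, correct = TRUE)`,
asserted against it), BH adjustment, and fold change on de-logged means with
an ε = 1e−9 guard (the fold-change base is unspecified upstream; this
natural-scale ratio is the documented default). The pass rule is adjusted
p ≤ 0.01 ∧ FC ≥ 1.5.

Survival: the log-rank statistic is computed directly from the risk-set
tables (needed per candidate in the cutpoint scan; cross-checked against
`survival::survdiff`). The maximally selected cutpoint scans midpoints of
sorted unique scores subject to minprop = 0.3 on both arms, maximizing |z|,
smallest cutpoint on ties; no selection-adjusted p-value is applied — the
selected split is reported with the plain log-rank p, as in the practice
this mirrors. Kaplan–Meier curves come from `survival::survfit`
(`type = "kaplan-meier"`, `error = "tsiatis"`). Multi-group comparisons
(Kruskal–Wallis with post hoc LSD) are out of scope; pairwise rank-sum
with BH is offered instead. Bulk survival scoring by single-sample GSEA is
deliberately replaced: any per-patient score column is accepted, with
mean-z signature scoring as the in-package default — a documented
divergence isolated behind one argument.

## Known limitations

- The generator's independence assumptions (genes conditionally independent
  given programs; binary program activity) understate real co-expression
  structure; consensus-NMF robustness claims beyond this model are untested.
- The windowed CNV profile has no calling layer; only planted-block
  detectability is validated.
- The spliced/unspliced DEG path is exercised on two independent NB layers,
  not on a kinetic splicing model.
- CLI coverage is a thin convenience wrapper over the R API, not a complete
  workflow runner.
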