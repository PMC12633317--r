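---
title: "Quantifying EMT states and the tumor immune landscape with emtscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EMT states and the tumor immune landscape with emtscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(emtscape)
```

## The scientific problem

Epithelial–mesenchymal transition (EMT) is not a binary switch: carcinoma
cells occupy a continuum between an adhesive, E-cadherin-high epithelial
state and a motile, vimentin-high mesenchymal state, with partial/hybrid
states in between. Where a tumor sits on this continuum matters for
immunity: along the spectrum, antigen presentation (MHC class I/II)
declines, cytotoxic CD8+ T-cell infiltration and effector gene expression
(*Gzmb*, *Ccr5*, *Cxcr6*) fall, regulatory T cells and regulatory-like
(Cd25+ Cd69+) B cells accumulate, IgG1-producing plasma cells disappear,
and NK effector programs are suppressed. `emtscape` provides a tested,
reusable implementation of the transcriptomic side of that analysis:
scoring EMT states from single-cell RNA-seq with three harmonized metrics,
placing tumors on a bulk reference panel, and quantifying graded immune
composition and effector changes along the spectrum — together with a
synthetic data generator that makes the whole pipeline testable without any
external download.

## The three EMT scoring metrics

All three are computed from a genes × units expression matrix, where a
"unit" is a single cell or a pseudobulk sample.

**76-gene signature score (`score_76gs`).** Each gene *i* of a 76-gene
EMT signature receives weight
$w_i = \mathrm{cor}(x_i, x_{\mathrm{Cdh1}})$, its Pearson correlation with
the canonical epithelial anchor *Cdh1* across the scored units; the score
of unit *u* is $\sum_i w_i x_{iu}$, mean-centered across units. Higher =
more epithelial. Weights are re-estimated on each dataset being scored
(the anchor correlation is dataset-specific); a per-sample estimation mode
is not provided because joint estimation across all scored units is the
simpler, sufficient choice at both the single-cell and pseudobulk levels.
The signature genes must include the anchor; genes missing from a matrix
are dropped with a warning, never imputed.

**Kolmogorov–Smirnov score (`score_ks`).** Within one unit, the empirical
distribution $F_E$ of the epithelial-signature expression values is
compared with the distribution $F_M$ of the mesenchymal-signature values:
$D_{mes} = \sup(F_E - F_M)$, $D_{epi} = \sup(F_M - F_E)$, and the raw
score is $D_{mes}$ if $D_{mes} \ge D_{epi}$, otherwise $-D_{epi}$. It is
bounded in $[-1, 1]$ with positive = mesenchymal, and is used as a
continuous score without a p-value gate. The exact tie
$D_{mes} = D_{epi} > 0$ (only possible for pathologically symmetric
inputs) resolves to $+D_{mes}$ with a logged message.

**Multinomial-regression score (`score_mlr`).** A three-class (epithelial
E / hybrid H / mesenchymal M) multinomial logistic model is fitted by
maximum likelihood on labelled training units, with two predictors per
unit: the mean z-scored expression of the epithelial genes and of the
mesenchymal genes. The raw score is the expected class
$0 \cdot P(E) + 1 \cdot P(H) + 2 \cdot P(M) \in [0, 2]$, 2 = mesenchymal.
Because the original method's fitted coefficients are not available, the
model is re-trainable: by default it is trained on the synthetic reference
panel labelled by theta tertiles (`theta_classes`), and the fitted
coefficients are attached to the result for reproducibility. A small ridge
penalty (`decay = 1e-3`) keeps the fit finite when the classes are nearly
linearly separable, which is the norm on clean gradients; without it the
maximum-likelihood coefficients diverge and the probabilities saturate to
0/1 at machine precision.

**Harmonization (`harmonize_scores`).** KS and MLR are flipped onto the
76GS scale so that higher always means more epithelial:
`harmonized_ks = -ks`, `harmonized_mlr = 2 - mlr` (a range-preserving
reflection, keeping the [0, 2] reading). Concordance between methods is
summarized as the 3 × 3 Pearson matrix of the harmonized columns.

## Reference-panel placement

`place_on_reference()` mimics scoring tumors against a broad panel of bulk
expression profiles (an 81-sample untreated murine mammary tumor panel in
the emulated design). Query pseudobulk and panel are restricted to shared
genes (at least `min_overlap = 50`), concatenated, and gene-wise z-scaled
*jointly*; all three scores are then computed on the combined matrix, with
the MLR model trained on the panel portion. Each query's rank among the
panel samples on the harmonized 76GS score is reported.

A scale subtlety matters here. Gene-wise z-scaling removes per-gene means
but **not per-sample offsets**: pseudobulk values formed as
`log2(1 + summed counts)` carry an arbitrary offset of roughly
`log2(total library size)` relative to a TPM-like bulk panel, which pushes
every query into the extreme tail of every gene and destroys the placement.
`pseudobulk(log2 = TRUE)` therefore library-size normalizes to counts per
million before the log2 transform by default (`scale = 1e6`), and the
synthetic panel is generated on the same per-million scale. Plain
`log2(1 + sum)` remains available via `scale = NULL`; raw summed counts
(`log2 = FALSE`) are untouched and conserve per-gene totals exactly.

## QC, normalization, variable genes

QC keeps a cell iff **all four strict inequalities** hold: UMI > 200
(`"cd45"` preset, for immune-enriched libraries) or > 500 (`"total"`
preset, for whole-tumor mixtures), detected features > 200, mitochondrial
fraction < 0.20, and complexity
$\log_{10}(\text{features})/\log_{10}(\text{UMI}) > 0.8$. Boundary cells
(exactly 200 UMIs, exactly 20 % mito) are removed, matching the printed
inequality directions. Complexity of a cell with UMI ≤ 1 is defined as 0.
Mitochondrial genes are recognized by a configurable name prefix
(`"mt-"`, the mouse convention).

Per-cell normalization is `ln(1 + 1e4 * count / total)` — the standard
scale factor and natural-log pseudocount of the common single-cell
workflow; the underlying study does not state an alternative, so the
default is documented rather than guessed differently. Gene-wise z-scaling
uses the population (divide-by-*n*) standard deviation; the choice is
arbitrary at the sample sizes involved, is stated here, and constant genes
map to zero rows rather than NaNs.

Variable genes are selected by the max-minus-min spread of per-group log2
means exceeding 1.5 (strictly). Whether the fold change should be
max-vs-min across groups or vs a designated baseline is genuinely open;
max-vs-min is chosen because it needs no baseline convention, and the
threshold is a parameter.

## Immune composition and enrichment

`annotate_by_markers()` assigns each cell the subtype whose marker genes
have the highest mean expression, provided that maximum exceeds a floor
(default 0; an all-zero cell is "unassigned"). This deliberately replaces
reference-based automated annotation — out of scope here — with a
transparent argmax rule whose behavior is fully testable.
`composition_table()` computes per-sample subtype proportions over
*assigned* cells only (the unassigned count is reported separately), and
`trend_test()` regresses any per-sample statistic on the integer EMT rank
(0 = most epithelial) with the usual two-sided t-test on the OLS slope —
rank, not theta, because real data only provides an ordering.

`dotplot_stats()` reports, per gene and group, the fraction of cells with
expression > 0 and the mean over all cells including zeros (the
mean-over-expressing variant is a flag away; zeros-included is the default
because it is the convention the enrichment statistic below also uses).

`wmw_enrichment_z()` produces a pathway × sample z-score matrix: per
sample, each gene is summarized by its mean expression over the sample's
cells, and the in-set gene means are compared against all out-of-set gene
means with a Mann–Whitney U statistic, converted to z with continuity
correction and tie-corrected variance under the normal approximation. The
alternative reading — testing a per-cell set score between samples — would
yield one statistic per sample *pair* rather than the pathway-by-sample
matrix this statistic is meant to fill, which is why the
in-set-vs-background-within-sample form was chosen. Degenerate all-tied
inputs yield z = 0 with a warning. `zscale_rows()` standardizes each
pathway across samples for display.

## The synthetic generator: what it emulates, and what it does not

`generate_truth()` fixes a gene universe of 2,000 genes: named analogs of
epithelial markers (*Cdh1*, *Epcam*, *Cldn4/7*, *Tacstd2*, MHC I/II), of
mesenchymal markers (*Vim*, *Snai1*, *Gpnmb*, *Mmp11*, ...), a 76-gene
signature containing the anchor, immune subtype markers, effector genes,
13 mitochondrial genes, and log-normal filler genes. Counts are negative
binomial with per-gene dispersion; the tumor-cell mean of gene *g* at EMT
parameter $\theta \in [0, 1]$ is
$\mu_g(\theta) = \mu_{g,0} \cdot 2^{\beta_g \theta}$ with
$\beta_g \in [-3, -2]$ for epithelial-program genes (including the MHC and
*Tacstd2* analogs) and $\beta_g \in [2, 3]$ for mesenchymal-program genes.
Per-cell size factors are log-normal with sd 0.3 — a standard
single-cell count model; the emulated study specifies none. Clone thetas
are evenly spaced on [0, 1] (five clones: E, EM1, EM2, EM3, M), encoding
only the ordering the design establishes, since no quantitative spacing is
reported.

Immune cells draw a subtype from a multinomial whose logits are linear in
theta, interpolating between configured endpoint mixes: cytotoxic CD8
falls 25 % → 5 %, plasma cells 10 % → 2 %, Tregs rise 5 % → 18 %, and
Cd25+ Cd69+ regulatory-like B cells 3 % → 12 %, with the remaining
subtypes near-flat. The endpoint mixes are chosen for statistical power at
desk-scale cell numbers, not as estimates of unpublished proportions —
the emulated study reports directions, not numbers. Effector genes in
cytotoxic CD8 and NK cells decline with slope $\in [-3, -2]$ log2-fold per
unit theta. A planted 2 % subpopulation of QC-failing cells (low UMI, high
mitochondrial fraction) keeps the QC stage honest. The bulk reference
panel samples 81 thetas evenly on [0, 1] with log-normal noise
(sd 0.25 on the log scale) around the CPM-normalized mean profile.

Not simulated: batch effects, doublets, ambient RNA, spatial structure,
read-level data, and cell-to-cell correlation beyond the size factor.
Passing tests on this generator therefore demonstrate that the statistics
recover the structure they claim to measure under a clean NB world — they
do not certify robustness to the artifacts real droplet data carries.

## Problem sizes and numerical choices

The test-suite and verification runs use five clones × 500 tumor cells,
five clones × 2,000 immune cells, a 31-clone × 100-cell gradient for
method concordance, and an 81-sample panel — sizes at which every
directional property of the generator is resolved far beyond sampling
noise while a full run stays in the tens of seconds. Exactness is enforced
where exactness is claimed: the KS score and the WMW z are tested for
equality against brute-force enumeration oracles (ECDF evaluation over the
pooled grid; exhaustive pairwise wins-plus-half-ties), not for approximate
agreement. Degenerate inputs have defined outcomes throughout: constant
genes z-scale to zero rows, constant anchors and constant correlation
inputs raise errors rather than NaNs, zero-total cells are a normalization
precondition error pointing at QC.

## Known limitations

* The MLR score is a re-trainable surrogate anchored to caller-supplied
  class labels, not a reproduction of the original method's fitted
  coefficients; its absolute values depend on the training panel.
* KS scores saturate at ±1 for pseudobulk profiles near the ends of a
  clean gradient (complete separation of the two signature distributions);
  ordering information at the extremes then comes from the other two
  metrics. At the single-cell level sampling noise prevents saturation.
* Marker-argmax annotation is only as good as the marker map; it assigns
  every cell to its best match above the floor and will not flag novel
  populations.
* Composition trend tests treat per-sample proportions as independent
  observations; with one sample per EMT state (the emulated design), the
  test has n = number of states.
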