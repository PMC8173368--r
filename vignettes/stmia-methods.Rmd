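---
title: "Methods: integrating spatial transcriptomics and scRNA-seq with stmia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating spatial transcriptomics and scRNA-seq with stmia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the models and rules
each stage implements, the parameters that matter and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where more than one reasonable option existed.

## Data model

Counts are UMI (deduplicated transcript) counts, genes × units, where a unit
is either a barcoded ST spot (a ~100 µm capture area pooling roughly 5–100
cells' worth of RNA) or a single cell. `CountMatrix` stores them sparsely
with unique gene and barcode identifiers and a `unit_kind` tag so QC can
dispatch the right filters. Gene identity is matched across datasets by
exact string equality only — no symbol/alias mapping — because any mapping
layer would import an external database and make results irreproducible.
Mitochondrial genes are recognized by the human "MT-" name prefix
(MT-CO1-style names).

## Quality control

Three filters, each with a strict boundary:

* spots detecting fewer than `min_genes_per_spot = 200` genes are removed
  (a spot at exactly 200 is kept);
* cells are removed when detecting fewer than `min_genes_per_cell = 200`
  genes **or** when the mitochondrial UMI fraction strictly exceeds
  `max_mito_frac = 0.20` (exactly 20% is kept);
* genes detected in fewer than `min_cells_per_gene = 3` units are removed.

The two cell criteria are combined with OR: a 20-gene cell is never worth
keeping just because its mitochondrial fraction is low. Filters are applied
once, units first, then genes, with detected-gene counts computed on the
matrix as passed in; `apply_qc(iterate = TRUE)` re-applies both to a fixed
point for the rare case where gene removal drops a unit back below
threshold.

## Normalization

Each unit's counts are divided by the unit's total, scaled by the median
total across units, and log2-transformed with a pseudocount of 1:

$$v_{gu} = \log_2\!\left(1 + c_{gu}\,\frac{\mathrm{median}_u\,T_u}{T_u}\right).$$

The pseudocount keeps the transform defined at zero and is the ubiquitous
convention. The pre-scaling median is recorded, and the linear-scale total
$\sum_g (2^{v_{gu}}-1)$ of every unit reproduces it exactly (tested to 1e-6
relative), which makes the normalization auditable after the fact.

## Variable genes and clustering

Genes are ranked by dispersion — variance over mean of linear-scale
expression $2^v-1$ — and the top `n_top` (pipeline default 500) are used for
clustering. Dispersion on the linear scale is the classic variable-gene
statistic; ties are broken lexicographically by gene id so selection is
deterministic. Zero-mean genes get dispersion 0 and are never selected
ahead of any varying gene.

Units are clustered by agglomerative hierarchical clustering with Ward
linkage on Euclidean distances (`hclust(method = "ward.D2")`, the Ward
criterion appropriate for unsquared Euclidean input), cut at a user-chosen
`k`. The cluster count is a config parameter with no claimed default-free
selection rule: the data this pipeline emulates were reported with specific
cluster counts per sample but no stated selection procedure, so `k` is
explicit. Labels are renumbered 0..k−1 by decreasing cluster size, which
makes outputs comparable across permutations of the input (the partition
itself is permutation-equivariant; label numbers on equal-sized clusters
are resolved by first occurrence).

For single-cell data the known cell-cycle gene sets are excluded from the
variable-gene set before clustering (`select_variable_genes(exclude = )`).
Cycling phase is a strong transcriptional program — in the simulator, as in
real data, it can dominate the top-variance genes and split cell types by
phase instead of identity. Excluding the known sets is the standard light
remedy and requires no regression model; on synthetic data it restores
perfect type recovery (adjusted Rand index 1.0 across seeds) where clustering
on the raw variable set reaches only ~0.2.

## The bimodal likelihood-ratio test

Marker detection uses a two-component model of normalized single-cell
expression: a value is 0 with probability $1-\pi$ (undetected), otherwise
drawn from $\mathcal{N}(\mu,\sigma^2)$. For a sample the maximized
log-likelihood uses $\hat\pi$ = fraction positive and $\hat\mu,\hat\sigma$ =
moments of the positive values ($\hat\sigma$ the maximum-likelihood,
denominator-$n$ form). The test statistic for groups $A$ and $B$ is

$$\Lambda = 2\left[L(A) + L(B) - L(A \cup B)\right] \sim \chi^2_3,$$

three degrees of freedom for the extra $(\pi, \mu, \sigma)$. Numerical
safeguards: $\hat\sigma$ is floored at 1 when a group has fewer than two
positive values or zero variance (preventing degenerate infinite
likelihoods); the statistic is clamped at 0 (the floor can make the split
fit nominally worse than the pooled fit in degenerate corners, where the
conservative answer is "no difference"); two all-zero groups short-circuit
to statistic 0, p 1. The implementation is validated against an independent
numerical maximization of the same likelihood (agreement to 1e-8 on the
frozen worked example) and calibrated under a simulated null: with both
groups drawn from one zero-inflated normal, the rejection rate at 0.05 over
5,000 replicate genes lies in [0.03, 0.07] and the Kolmogorov–Smirnov
distance of the p-values from uniform is below 0.05.

`find_all_markers` runs one-vs-rest per cluster with the conventional
gates: detection fraction at least `min_pct = 0.01` in the better-detected
group, and absolute natural-log fold change at least
`logfc_threshold = 0.1`, where

$$\mathrm{lnFC} = \ln\frac{\overline{2^x - 1} + 1}{\overline{2^y - 1} + 1},$$

the +1 pseudo-mean keeping the ratio finite at zero means and the natural
log making the 0.1 threshold meaningful. Benjamini–Hochberg adjustment is
applied within each cluster's tested set (the default family of the
reference marker-detection workflow); no test procedure was stated by the
source analysis, and BH is the conservative conventional choice. Records
sort by adjusted p, then decreasing |lnFC|, then gene id.

## Multimodal intersection analysis

Marker sets (adjusted p < 0.05, positive lnFC) from the single-cell side
(cell types) and the ST side (regions) are intersected pairwise against a
background universe. Choices made here:

* **Universe**: the intersection of gene ids present in both processed
  datasets, because an overlap is observable only there; a config switch
  allows the union for users who prefer the laxer background.
* **Tails**: both tails include the observed overlap —
  $p_{\mathrm{enr}} = P(X \ge k)$, $p_{\mathrm{dep}} = P(X \le k)$ — the
  standard one-sided exact-test convention; consequently
  $p_{\mathrm{enr}} + p_{\mathrm{dep}} \ge 1$ always.
* **Score**: $-\log_{10} p_{\mathrm{enr}}$ when enrichment is the smaller
  tail, $+\log_{10} p_{\mathrm{dep}}$ otherwise, i.e. positive = enriched
  ("red"), negative = depleted ("blue").
* **No multiple-testing adjustment on the displayed map** (the source
  figures show raw tails); BH-adjusted values are serialized alongside so
  users can threshold either way.

Tail probabilities come from `stats::phyper`, which is exact; the test
suite separately verifies every valid $(N \le 20, K, n, k)$ case against
direct combinatorial summation, to 1e-12, and spot-checks literal
enumeration of all $\binom{N}{n}$ draws on small universes.

`assign_regions` labels each region with its argmax-score cell type; a
region whose best score falls below `min_score` (default $-\log_{10} 0.05
\approx 1.30$) is "unassigned" — the floor is config-only because no
significance threshold was stated for composition read-outs. Score ties go
to the lexicographically first cell type, logged.

## Cell-cycle classification

The G1/S and G2/M scores of a cell are arithmetic means of normalized
expression over two gene sets (the packaged defaults have 43 and 54 genes —
the sizes of the core sets this scoring tradition uses). Classification:
both scores strictly below the threshold → quiescent (G1); otherwise
proliferative, assigned the phase with the larger score. The threshold
defaults to 2 and is applied on the same log2-normalized scale as the rest
of the pipeline; the scale was not stated by the source procedure, so the
threshold is a config parameter (`cc_classify(threshold = )`). At the
simulator's realistic operating point (~6,000 UMIs over 2,000 genes) a
quiescent cell's set average sits near 1.1 and an active program near 3.0,
so 2 separates them cleanly; on data of very different depth or gene count
the threshold must be revisited. An exact score tie among proliferative
cells is assigned G1/S and logged — the strict inequalities of the stated
rule leave ties undefined, and a deterministic resolution beats an
arbitrary one. The packaged GMT uses synthetic placeholder gene names
(`G1S.SYN.*`, `G2M.SYN.*`) understood by the simulator; for real data,
substitute a GMT in your annotation's namespace.

## Stage trends

"Gradually up-regulated" across an ordered stage series (e.g. early → mid →
late erythroblasts) is operationalized as: per-stage mean normalized
expression strictly increasing at every step (margin `epsilon`, default 0),
**and** a significant first-vs-last-stage bimodal LRT after BH adjustment
across all genes (`alpha = 0.05`). "Gradually down" is the mirror image, so
reversing the stage order swaps the two sets exactly — a property the test
suite asserts. Requiring per-adjacent-pair significance instead of
extremes-only was the open alternative; extremes-only was chosen because
adjacent stages can differ by less than the test can resolve at realistic
group sizes while the monotonicity constraint already enforces the shape.
Published counts of such genes from the motivating dataset depend on an
unstated cutoff and are not reproduction targets.

`balanced_stage_pca` draws an equal number of units per stage (default 50,
matching the balanced-subsampling design this analysis style uses) and
projects centered, unscaled log2 values onto the top two principal
components. Component signs are canonicalized — the largest-magnitude
loading of each component is made positive — so runs are comparable; PCA is
otherwise sign-ambiguous.

## The synthetic-data generator

The generator is the package's ground truth and encodes the study
conditions the analysis assumes:

* **Counts**: negative binomial (gamma-Poisson) with per-gene lognormal
  baseline rates (sdlog 1) and per-unit lognormal library sizes — the
  standard noise model for UMI data; the source analysis states none, so
  the standard model is used. Defaults `libsize_meanlog = log(6000)`,
  `libsize_sdlog = 0.3`, `nb_dispersion = 2` put a unit at ~6,000 UMIs and
  ~1,300 detected genes of 2,000 — the realism target of roughly a thousand
  genes and several thousand UMIs per spot.
* **Structure**: `n_groups = 5` regions/cell types × `units_per_group =
  200`, `markers_per_group = 50` disjoint marker genes per group with rate
  ×`marker_fold_change = 4` inside the group. ST regions are contiguous
  row-bands of a rectangular array (deterministic layout; randomness only
  in counts). Because rates are renormalized per unit, the realized marker
  fold is slightly below the nominal multiplier (≈3.7 at defaults) — the
  tests band it within 25% of nominal.
* **Cell cycle**: cycle genes get a fixed mid-range baseline (the median
  non-cycle rate); cells labelled S or G2M have the corresponding set's
  rate multiplied by `cc_fold = 6`, which at the default depth separates
  set-average scores by construction (inactive ≈ 1.1, active ≈ 3.0 around
  the threshold 2). Phase counts follow `phase_frac` (default 50/25/25)
  deterministically by largest remainder.
* **QC failures**: `frac_low_quality = 0.1` of units are made to fail QC —
  spots by repeated binomial halving of counts until fewer than 200 genes
  are detected (thinning preserves gene rank structure, unlike resampling),
  cells half by thinning and half by doubling mitochondrial counts until
  the fraction exceeds 20%. Healthy units are guaranteed to pass both
  gates, so QC outcomes are exact by construction.
* **Determinism**: identical parameters (including the seed) give
  bit-identical output; ST and SC runs under the same parameters share gene
  baselines and marker sets, planting a one-to-one region/cell-type
  correspondence for the end-to-end MIA experiment.

What it does **not** emulate: spatial autocorrelation within regions,
doublets, batch effects, ambient RNA, or realistic gene-gene correlation
beyond the group structure. Passing the recovery suites therefore shows the
pipeline implements its stated rules correctly and recovers structure under
its own noise model — not that it is robust to every artifact of real
tissue data.

## Validation problem sizes

The packaged validation suite runs at the generator defaults: 20 seeds × (5
regions × 200 spots + 5 cell types × 200 cells, 2,000 genes) for MIA
recovery, 20 × 1,000 cells for cell-cycle recovery, 5,000 replicate genes ×
two groups of 100 for null calibration, every hypergeometric case with
N ≤ 20 for oracle equivalence, and 3-stage series of 600 cells for trend
recovery — sizes chosen so the full suite completes in a few minutes on one
CPU while keeping the Monte-Carlo bands tight.

## Interfaces

The package's interface is its functions: `run_pipeline()` composes the
stages end to end from a config list (YAML/JSON loadable via
`read_pipeline_config`), writes all tables as TSV with a provenance header
(package version, seed, config hash) and gene sets as GMT, and re-runs
byte-identically under an identical config. `scripts/acceptance.R` is a
thin Rscript over these functions that recomputes the validation quantities
from scratch.

## Known limitations

* Clustering is hierarchical-only by design; graph-based (Louvain/Leiden)
  clustering is out of scope.
* The cell-cycle score is a plain set average; regression-based centering
  against expression-matched control bins is deliberately not implemented
  (a different algorithm than the stated average-and-threshold rule).
* The MIA universe choice (intersection vs union) changes tail magnitudes;
  both are supported but results should state which was used.
* The score threshold 2 for quiescence is depth-dependent (see above).
* No spot deconvolution or label transfer: MIA places cell types at the
  region level, not per spot.
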