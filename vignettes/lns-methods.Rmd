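---
title: "Local Network Similarity: model, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local Network Similarity: model, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnscomp)
```

## The model

`lnscomp` measures conservation of gene co-expression between two species
without aligning their experiments. The unit of comparison is the
one-to-one ortholog pair, and the quantity compared is each gene's position
in its own species' co-expression network.

Three normalization steps make networks comparable across heterogeneous
datasets:

1. **Per-dataset correlation.** Within each dataset, the Pearson
   correlation between every pair of gene expression vectors. Correlations
   of different datasets live on drastically different scales — a strong
   perturbation compresses correlations towards ±1, a weak one towards 0 —
   so raw values cannot be averaged.
2. **Fisher z-transform**, `z = atanh(rho)`, which stabilizes the variance
   of the correlation distribution so large-magnitude changes do not
   dominate.
3. **Standardization to N(0, 1)** per dataset, so each dataset contributes
   on the same scale regardless of its size and signal strength.

The *connection weight* between two genes is the average of these
normalized z-values over all datasets of a compendium, re-standardized (see
"Numerical choices"). For ortholog pair (j, j'), the weights from j to the
other N − 1 matched orthologs in species A and from j' to their orthologs
in species B form two vectors aligned by orthology; LNS is their Pearson
correlation. Because only matched orthologs enter the vectors, genes
without orthologs influence nothing, and because the correlation is over
genes rather than arrays, the two species' datasets never need to share
conditions, time points, or kinetics.

Key assumptions: orthology is strictly one-to-one (paralog families are
excluded upstream); expression values are log-ratio-like so Pearson
correlation is meaningful; each dataset has at least 3 (in practice many
more) arrays; and a gene's functional context is reflected in its
first-degree co-expression neighbourhood.

### The randomized null

Zero conservation is simulated by shuffling the ortholog assignment along
one species' axis with a uniform random permutation — the match is
destroyed, but both networks stay intact. Shuffling one axis only matters:
shuffling both would also destroy each network's internal structure, which
is not the hypothesis being tested. Pairs mapped back to themselves by
chance are kept; with N pairs this inflates the null mean by O(1/N) and is
negligible at the sizes used. The pooled null is centered at 0 and close to
normal (Kolmogorov–Smirnov distance to a fitted normal below 0.05 on ≥
10,000 pooled samples in the test suite), so "diverged" can be defined
relative to it. `count_diverged()` counts pairs below the null mean and
reports a two-sided Mann–Whitney U test of the real against the pooled null
distribution; the rank test was chosen because neither distribution is
exactly normal and no variance equality can be assumed.

### Condition-specific LNS

The same construction applied to a single matched dataset pair (one
perturbation per species) gives condition-specific LNS. It is noisier than
the global score but sensitive to divergence that only manifests under a
specific perturbation; profiles of condition-specific LNS across pairs of
matched datasets are the input to the clustering module. Which datasets of
the two species constitute a matched pair is user input — it is a
biological judgement, not something the package can infer.

## Tunable parameters

| Parameter | Default | Where | Why this default |
|---|---|---|---|
| `min_fraction` | 0.5 | coverage filter | genes observed in < 50% of arrays carry too little signal to impute reliably; a gene at exactly 50% is kept |
| `k` | 10 | KNN imputation | standard neighbourhood size for expression imputation; robust between over-smoothing (large k) and noise (small k) |
| `clip` | 1 − 1e−6 | Fisher transform | maps duplicated genes (rho = ±1) to a large finite z (~7.25) instead of infinity |
| `n_permutations` | 50 | null | with hundreds of orthologs this pools ≥ 10,000 samples, enough for stable mean/sd and tail quantiles |
| `n_top` | required | periodic calls | the number of cell-cycle genes is dataset-specific; `suggest_n_top()` offers a 1% threshold against time-permuted nulls |
| `conf_threshold` | 2 | period call | the dominant frequency must carry at least twice the uniform share of total power, else flagged low-confidence |
| `n_perm` | 1000 | association tests | permutation p resolution of ~1e−3 with add-one smoothing |
| `alpha` | 0.01 | enrichment | Bonferroni-corrected cutoff across all cluster × term tests jointly |
| `seed` | 17 | everywhere | all stochastic steps take an explicit seed; identical seeds give bit-identical results |

## The synthetic generator

`generate_compendium()` draws the two-species fixture every module is
validated on. Genes belong to co-expression modules; within each dataset a
module has a latent factor per array, `N(0, module_signal_sd^2)`, and a
gene's value is its module's factor plus `N(0, noise_sd^2)` noise. The
within-module correlation therefore approaches
`s^2 / (s^2 + n^2)` — about 0.67 at the defaults (signal 1, noise 0.7) —
which is verified against this closed form in the tests. Divergence is
planted as *module reassignment* in species B: the gene's co-expression
neighbourhood changes, which is exactly what LNS measures; amplitude
changes without neighbourhood changes would (correctly) not register.
Missing values (5%) and optional replicate arrays exercise the
preprocessing chain.

Defaults — 300 genes, 10 modules, 6 datasets of 12 arrays per species, 10%
divergent orthologs — are a desk-scale miniature of a multi-dataset
microarray compendium (real compendia run to hundreds of arrays over dozens
of datasets and thousands of genes). What the fixture does **not** emulate:
dye bias and spatial artifacts, heavy-tailed noise, overlapping module
membership, correlated modules, partial (rewired rather than reassigned)
divergence, and paralog interference. Passing tests therefore demonstrate
correctness of the computations and recoverability of clean planted signal,
not performance on real arrays.

`generate_timecourse()` plants cosines with known frequency and uniform
random phases among noise genes; the phase convention matches
`fourier_score()` (a gene following `cos(2*pi*f*t/T - phi)` is assigned
phase `phi`), so planted phases are recovered within one time-step's
angular resolution (2π/T) on noiseless data.

## Numerical choices

- **Standardization statistics** are computed on the off-diagonal upper
  triangle only — each unordered gene pair counted once — with the sample
  (n − 1) standard deviation, so the reported off-diagonal sd of a
  connection matrix is exactly 1. Diagonals are `NA` sentinels and never
  reach downstream vectors.
- **Aggregation re-standardizes.** The mean of D independent standard
  normal entries has sd 1/√D; averaging alone would compress the aggregate
  matrix (verified in the tests: two-dataset aggregates have sd ≈ 0.707
  before rescaling). Re-standardizing restores mean 0 / sd 1 exactly, which
  is what makes global and condition-specific weights comparable.
- **Gene universes** are aligned on the union of gene ids; each pair's
  weight averages over the datasets where both genes are present, and pairs
  never co-measured stay missing. Missing positions are dropped pairwise
  inside each LNS correlation, with a minimum of 3 aligned weights.
- **Self-entries are excluded** from both connection vectors: z(j, j) is a
  transformed correlation of 1 and would inflate every LNS towards +1.
- **Zero-variance genes** get correlation 0 (hence z = 0) and a flag
  instead of removal, keeping matrices aligned across datasets; their LNS
  is reported `NA` with a `constant-vector` flag.
- **Feature normalization** (log2, mean-subtract, divide by sd) uses the
  population (n) standard deviation; nonpositive divergence values (e.g.
  dN = 0) cannot be log-transformed and are dropped with a warning rather
  than pseudocounted, which would distort the normal shape the transform is
  meant to achieve.
- **KNN imputation** uses the unweighted mean of the k nearest neighbours,
  with gene–gene Euclidean distances computed on mutually observed arrays
  and rescaled by `sqrt(total arrays / shared arrays)` so genes sharing few
  arrays are not spuriously near. Distance-weighted averaging is a
  reasonable alternative; the unweighted form is simpler and the difference
  is far below the noise level of array data.
- **Ties in periodic-gene selection** break lexically by gene id, making
  top-N calls deterministic.
- **k-means** uses `stats::kmeans` (Hartigan–Wong) with 10 restarts; R's
  plain Lloyd implementation aborts on empty clusters, while Hartigan–Wong
  refines past them and satisfies the same contract (each gene assigned to
  its nearest center, best-of-restarts objective kept). Cluster centers are
  arranged by average-linkage hierarchical clustering with dendrogram
  leaves reordered by center magnitude (the standard heatmap convention),
  which makes collinear centers come out in monotone order.

## Open design decisions

- **Number of clusters.** The cluster-count criterion used on the original
  compendia is not recoverable; `choose_k()` uses the gap statistic
  (uniform reference, first-SE-max rule) and `k` is always overridable.
- **Overlap significance.** Significance of the cross-species overlap of
  periodic genes is computed as the exact hypergeometric upper tail, with a
  label-permutation p-value as a cross-check (the two agree within
  Monte-Carlo error in the tests). A t-test on an overlap count is not
  well-defined, so none is offered.
- **TATA encoding.** The three-level status (both / one / neither) enters
  the point-biserial test as both-vs-rest by default, with one-vs-neither
  as an explicit alternative contrast.
- **Enrichment universe.** Whether to test against all orthologs or all
  annotated genes changes hypergeometric tails substantially; the universe
  is an explicit argument rather than a hidden default.

## Problem sizes and determinism

The validation suite runs the full pipeline at 200–300 genes, 6–12 datasets
and 50-permutation nulls (≥ 10,000 pooled samples), sizes at which every
distributional property the method relies on — off-diagonal mean 0 / sd 1,
null centered at 0 and near-normal, LNS bounded in [−1, 1], vectorized
scores equal to a per-pair loop at 1e−10, planted divergence recovered at
AUC ≥ 0.9 — is checked in seconds. All stochastic functions are seeded;
rerunning any pipeline with the same seed reproduces outputs bit for bit.

## Limitations

- LNS needs compendia: a single weak dataset per species gives noisy
  condition-specific scores, and genes unperturbed in the available
  conditions can look "neutral" regardless of their true conservation.
- Only one-to-one orthologs are scored; divergence mediated by paralog
  turnover is invisible.
- A gene whose neighbourhood is conserved but whose expression *level*
  shifted registers as conserved: LNS is a network measure, not a level
  measure.
- The hypergeometric enrichment treats annotation terms as flat sets; no
  ontology propagation is performed.
- Two species only; extending the score to more species or other data
  types would require a different aggregation scheme.
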