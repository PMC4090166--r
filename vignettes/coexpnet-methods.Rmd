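---
title: "Methods: co-expression connectivity and the resampling eFDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression connectivity and the resampling eFDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexpnet)
```

## The model

`coexpnet` ranks candidate disease genes by their connectivity to a
reference set of established disease genes in expression-correlation
networks. The statistical object is the pairwise sample correlation
coefficient r of two genes' expression across the samples of one
individual. Pearson's r is the default — it is efficient when expression
is approximately bivariate normal and it keeps the sign, which matters
because negatively co-regulated genes are biologically informative;
Spearman's coefficient (Pearson on within-gene average ranks) is offered
as a robustness check. Nonlinear dependence measures are deliberately out
of scope: they lose substantial power when approximate normality and
linearity hold.

Three assumptions underlie the pipeline:

1. expression values are already normalized, on a log scale, with no
   missing cells (missing or non-numeric cells are parse errors, not
   imputed);
2. each individual's samples are exchangeable draws from that individual's
   expression state, so a per-individual correlation is meaningful with at
   least 3 samples;
3. reference genes co-express as a network, so connectivity to them is
   evidence of shared biology ("guilt by association").

### Combining individuals

Correlation matrices are computed per individual and combined within a
time period as the weighted sum `r = Σᵢ wᵢ rᵢ` of raw coefficients. The
weight of individual *i* is the normalized inverse of the sample variance
`vᵢ` of the off-diagonal entries of that individual's reference-panel
correlation matrix:

```
wᵢ = (1 / vᵢ) / Σⱼ (1 / vⱼ),   Σᵢ wᵢ = 1,  wᵢ ≥ 0.
```

Individuals whose correlation estimates wander more are down-weighted.
Two design points are worth making explicit, because the variance could be
defined in several ways:

* the variance is taken over **reference-set pairs**, not a genome-wide
  pair sample — the reference panel is the network being measured, and its
  stability is what the weights should reflect;
* **raw r values are combined, not Fisher-z transforms.** The combination
  is convex, so combined entries stay in [−1, 1] with unit diagonal, and
  the combined matrix remains directly interpretable as a correlation-scale
  quantity. Fisher averaging would weight extreme correlations more
  heavily; nothing downstream (quantile cutoffs, |r| sums) needs that.

One caveat follows from the definition: the off-diagonal variance mixes
sampling noise with genuine spread in the true correlations. For a
reference panel containing both a positively and a negatively correlated
cluster, the spread term dominates and *shrinkage* under high noise can
lower the variance. Weights remain a valid precision ordering for
reasonably coherent reference panels (and exactly track sampling noise for
single-sign panels), but they are not a pure noise estimate.

### Edge significance: the top-quantile cutoff

An edge is significant when combined |r| strictly exceeds the empirical
`quantile` (default 0.95) of the genome-wide combined |r| distribution —
the "top 5%" rule. The distribution is estimated from a seeded uniform
sample of distinct gene pairs over **all** genes in the dataset (reference
and candidates included; they are a negligible fraction of a genome-scale
universe and excluding them would make the cutoff depend on the query).
The quantile uses the nearest-rank rule, `sorted[⌈q·n⌉]`, so it is an
actual observed value and deterministic. The default sample of 10⁵ pairs
is capped at the total number of pairs, in which case the cutoff is exact;
fewer than 100 sampled pairs is refused as unstable.

### Connectivity

For candidate *c* with significant-edge set
`E(c) = {g ∈ reference : |r(c, g)| > cutoff}`:

* `K*(c) = |E(c)|` — discrete connectivity, the number of reference genes
  the candidate is significantly co-expressed with;
* `K(c) = Σ_{g ∈ E(c)} |r(c, g)|` — continuous connectivity, the
  magnitude-weighted version, satisfying `cutoff · K* ≤ K ≤ K*`.

K is defined as the sum of |r| over significant edges. Among the family of
"functions of the number of significant connections", this is the minimal
one that (a) reduces to K* when all edges are saturated, (b) is monotone
nonincreasing in the cutoff, and (c) rewards edge strength, which is what
gives K slightly more power than K* downstream. Absolute values are used
so negatively co-regulated candidates are not penalized. Candidates may
not appear in the reference set (self-edges would inflate scores);
leave-one-out connectivity — scoring each reference gene against the
remaining ones — cross-validates the premise that the reference set is a
network at all.

### The empirical FDR

Analytic per-gene p-values for K would need the joint null of 29 dependent
correlations; instead the false-discovery rate is estimated empirically.
`n_resamples` (default 1000) random gene sets, each the size of the
candidate list, are drawn from the expression universe **excluding both
reference and candidate genes** — resampled sets should be null, and
candidates are putative signal, so leaving them in would contaminate the
null. For each threshold T:

```
eFDR(T) = mean over resamples of #{random gene K > T}
          ---------------------------------------------
          #{observed candidate K > T}
```

Both exceedances are strict. Where no observed candidate exceeds T the
ratio is undefined and reported as missing rather than forced to a value.
For reporting, raw ratios are truncated at 1 (an estimated FDR above one
carries no extra information) and the curve is monotonized by a running
minimum in ascending T, making the estimate nonincreasing in the
threshold — raising the bar can only reduce the estimated error rate, and
the procedure "select at the smallest T whose eFDR reaches the target" is
then well defined. The curve is evaluated at every point where it can
change (zero plus the observed and resampled K values), so the chosen
threshold is exact for the resampling draw rather than an artifact of a
coarse grid. The default target rate is 0.25: the tool's purpose is
short-listing candidates for follow-up, where a quarter of false leads is
an acceptable price for sensitivity. Candidates with `K > chosen_T` are
flagged `prioritized`; ranks are by descending K with ties broken by gene
symbol.

### Ordering and networks

Cluster structure in a reference correlation matrix is exposed by
principal-component angular ordering: an eigendecomposition of the
(symmetric) correlation matrix itself — genes are the objects being
ordered, so the matrix's own axes are the right basis — followed by
sorting genes by `atan2(PC2 loading, PC1 loading)` mapped to [0, 2π).
Two conventions make this deterministic: each eigenvector's
largest-magnitude loading is forced positive (first index on ties), and
the sort key is rounded to 10⁻⁹ so genes with numerically degenerate
angles (exchangeable genes, repeated eigenvalues) fall back to the gene-
symbol tie-break instead of floating-point noise. An ordering derived from
one dataset can be applied to another (`cross_order()`) to ask whether
cluster structure replicates. Thresholded networks keep the signed r per
edge and are exported as TSV edge lists or GraphML with a node `role`
attribute; graph layout is left to downstream tools.

### Group comparisons

Whether externally flagged candidates (intolerant, previously implicated,
predicted damaging, high variant scores) have higher connectivity is
tested with a one-sided two-sample Mann–Whitney rank-sum test: the
asymptotic p-value uses the normal approximation with continuity and tie
corrections, and a label-permutation p-value (default 1000 permutations)
guards against the dependence among connectivity scores distorting the
null. The permutation estimator is add-one,
`(1 + #{permuted W ≥ observed W}) / (1 + B)`, so it is never exactly zero.
Genes not assessed by a resource are excluded from that test rather than
treated as unflagged — "not assessed" is not evidence of benignity.

## The synthetic generator

`synthetic_spec()` / `generate_panel()` implement a single-factor-per-
module linear model: within each individual and sample, module *m* draws a
latent factor `f ~ N(0,1)`; a member gene with loading λ takes
`λ·f + √(1−λ²)·ε` and a background gene is pure noise, with
`ε ~ N(0, noise_sd_i)`. At unit noise the population correlation of two
module genes is exactly `λ_a·λ_b`, giving closed-form oracles for the
tests; per-individual noise levels shrink observed correlations and
inflate their sampling variability, which is what makes the combination
weights genuinely differ across individuals. Only pairwise correlation
structure matters to any downstream stage, so a richer covariance model
would add nothing testable.

`planted_benchmark()` assembles the standard evaluation: a module holding
`n_reference = 29` reference genes (six of them negatively loaded, an
anti-correlated sub-cluster of the kind adult brain data shows) plus
`n_true_candidates` planted candidates at loading 0.9, `n_decoys = 50`
background genes posing as candidates, in a universe of 400 genes over 4
individuals with 490 samples each — the scale of a developing-brain atlas
panel (thousands of arrays over ~10 brains) — and `noise_sd` spread from
0.8 to 1.4 across individuals. With `n_true_candidates = 0` the benchmark
is fully null and the candidates are exchangeable with the eFDR's
resampled sets, which is the calibration scenario: over replicates, the
realized false-discovery proportion at the chosen threshold should sit
near the 0.25 target. The test suite runs 200 such replicates at 200
resamples each; the planted-recovery benchmark uses 1000 resamples.

What the generator does **not** emulate: probe-level artifacts,
normalization effects, heavy-tailed or skewed expression, spatially
structured samples within a brain, overlapping modules, and
correlation-strength gradients within a module. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated under
the factor model, not that any particular real resource satisfies its
assumptions. One behaviour of the factor model is worth knowing when
reading benchmark output: a background gene that happens to correlate with
the module's latent factor gains edges to *many* reference genes at once,
so null connectivity is bimodal (mostly zero, occasionally large). The
eFDR machinery sees the same tail in its resamples, so calibration is
unaffected, but individual decoys can score well — exactly the behaviour a
25% false-discovery target tolerates.

## Numerical choices and degenerate inputs

* **Strictness.** "Exceeds" is strict (`>`) for the |r| cutoff, for the
  connectivity threshold T, and in both eFDR exceedance counts.
* **Zero-variance genes** have undefined correlations; they are dropped
  from the panel with a warning rather than assigned r = 0 (silently
  inventing independence would bias the null sample).
* **Probe collapsing** keeps the probe with the highest median across the
  panel's samples, per individual panel (atlas data are normalized per
  brain, so medians are not pooled across individuals); ties break to the
  lexicographically smallest probe id.
* **Gene matching** is case-sensitive after whitespace trimming, with no
  alias resolution; absence from a panel is recorded data, not an error.
* **Seeds.** Every sampling operation takes an explicit integer seed and
  uses it through an isolated RNG scope, so a run never perturbs the
  caller's RNG state and identical seeds are bit-reproducible. The
  pipeline derives per-stage seeds from one master seed by fixed offsets.
* **Weight degeneracy.** Identical correlations within an individual
  (zero variance) make inverse-variance weights undefined; this errors as
  a degenerate panel.
* **eFDR degeneracy.** If no threshold attains the target rate, the
  prioritized set is empty with a warning — an honest "nothing passes" is
  a valid outcome.

## Problem sizes

The shipped tests and the acceptance script use 400-gene universes, 4
individuals × 490 samples, 29 reference genes, 50–60 candidates, 200–1000
resamples and 200 calibration replicates. These sizes were chosen so the
factor-model asymptotics are clearly in force (correlation standard errors
near 0.045 against planted correlations near 0.8) while a full run stays
in the minutes range on one CPU; the algorithms themselves are agnostic to
scale, and the genome-wide cutoff estimator is the only stage that needs
care (it samples pairs rather than forming an all-genes correlation
matrix).

## Known limitations

* The inverse-variance weights conflate true-correlation spread with
  sampling noise (discussed above).
* Connectivity is built from direct gene–gene correlations; a principal-
  component or module-eigengene formulation would be more robust to single
  noisy reference genes and is a natural refinement.
* The eFDR is a ratio of counts; with very few observed exceedances its
  variance is large, which the monotonization only partly smooths.
* Candidates absent from an expression resource are simply not scored —
  the method cannot speak to genes the platform does not measure, and
  prioritization misses genes acting in pathways unrelated to the
  reference network.
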