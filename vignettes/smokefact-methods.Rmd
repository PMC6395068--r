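---
title: "smokefact: models, calibration, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smokefact: models, calibration, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokefact)
```

## The problem

Inhalation-toxicology transcriptomics commonly uses a factorial design:
animals differ in exposure (smoke vs sham), genotype (wild type vs a
disease-model transgenic), and sex, and are profiled after one or after
several daily exposures. The questions are (i) which genes respond to
exposure once the other factors are accounted for, (ii) whether those
responses differ between a single and repeated exposure, and (iii) which
biological gene sets move coherently. `smokefact` implements that
analysis chain against normalized log2 intensity matrices, and ships a
ground-truth simulator so every stage can be validated without any
external data.

## The per-gene model

Within one exposure duration, each gene is fitted by ordinary least
squares on the additive design

$$y_{gs} = \beta_0 + \beta_E x_E(s) + \beta_G x_G(s) + \beta_S x_S(s)
  + \varepsilon_{gs},\qquad \varepsilon \sim N(0,\sigma_g^2),$$

with treatment coding (smoke, transgenic, male = 1). This is a plain
gaussian identity-link fit, gene by gene — deliberately *not* a
moderated-t / shrinkage variant: the estimator is the textbook one so
its behaviour is transparent, and the package's permutation machinery
(below) calibrates set-level inference empirically rather than through
variance moderation. Coefficient p values are two-sided t tests on
$n-4$ degrees of freedom; q values are Benjamini–Hochberg within each
factor across all genes.

A gene is a **response gene** for a factor when $q < 0.05$ *and*
$|\beta| > \log_2(1.3) \approx 0.379$ — an effect-size floor of a 1.3×
fold change on the intensity scale. Both cutoffs live in
`run_config()` / `significance_criteria()`.

Degenerate zero-residual fits (possible with noise-free synthetic data)
use the convention p = 1 for a zero coefficient and p = 0 for a nonzero
one, with a warning; this keeps exact-recovery tests runnable without
special-casing.

The exposure × duration interaction is a separate post-hoc fit over both
durations on $[1, x_E, x_{d5}, x_E x_{d5}]$, run for the supplied
response-gene list. BH for the interaction q is computed **over the
supplied list only** (the restriction implied by testing only
significant response genes); `scope = "all"` switches to array-wide
adjustment, since the narrower choice is a judgement call.

## Gene-set association score

For a chosen factor, each gene contributes
$s_g = \mathrm{sign}(\beta_g)\,(-\log p_g)$ — every gene, significant or
not. A set with $m$ matched members scores

$$S = \frac{1}{\sqrt m}\sum_{g \in \text{set}} s_g ,$$

the $\sqrt m$ denominator giving null scores a spread comparable across
set sizes. Member symbols are matched to expression identifiers
case-insensitively and exactly; sets reduced below 5 matched genes are
dropped by default (tiny $m$ makes the score erratic).

The null is built by shuffling whole design rows against expression
columns — all factor labels travel together, severing every
factor–expression link at once — and re-running `fit_gene_models()`
itself for each permutation, so any change to the model propagates to
the null by construction. The significance threshold per tail is the
plug-in estimate: the most inclusive observed score $t$ such that
(mean permutation exceedances of $t$) / (observed exceedances of $t$)
is at most the target FDR.

**Tail handling (a deliberate deviation).** Testing each tail at the
full 5% FDR makes the chance that *any* set is called on pure-noise
data roughly $2\,[1-(1-0.05/S)^S]\approx 9.5\%$ — the procedure would
fail its own 10% calibration bound almost half the time by chance. The
default therefore assigns each tail `fdr/2`, keeping the overall
false-call budget at the stated 5%; `tail_mode = "per-tail-full"`
restores the single-tail-at-full-budget rule for comparison. The
logarithm base for $-\log p$ is natural by default (base 10 available);
the choice rescales every score and threshold identically, so
significance calls are invariant to it.

## Overlap enrichment

List-vs-collection enrichment is the exact hypergeometric upper tail
$P(X \ge k)$ for drawing $k$ of a size-$K$ set in an $n$-gene query from
an $N$-gene universe, BH-adjusted across sets; list-vs-list testing is
the one-sided Fisher exact test (identical tail). The universe size $N$
is a **mandatory argument everywhere**: published overlap q values are
not reproducible without knowing $N$, and defaulting it silently would
manufacture significance. Recommended choices: the number of genes on
the measured platform for list-vs-list tests; the collection's declared
universe for GMT-based tests. Tests are one-sided toward enrichment;
degenerate margins return p = 1 with a warning (permutation loops can
generate them).

## Clustering choices

K-means uses R's stock `kmeans()` (Hartigan–Wong) with an explicit
best-of-`restarts` loop (default 50) under one seed; the elbow curve
reports best-of-restarts within-cluster sum of squares for k = 2..20.
Gene rows are **mean-centered by default** before clustering, so
clusters capture response pattern rather than baseline intensity — the
convention is not forced by the method, so `center`/`scale` are
arguments, and one test fixture (four 1-D points with wss = 0.01)
exercises the uncentered path. Heatmap structure: samples ordered by
hierarchical clustering on Pearson distance $1 - r$ (not $1-|r|$);
genes grouped by k-means cluster in index order and ordered within each
cluster by hierarchical clustering on Euclidean distance; complete
linkage throughout (configurable). Ties in distances break
deterministically by identifier because items are pre-sorted by name.

## The synthetic world

`generate_design()` builds the full 2×2×2 factorial per duration with
`n_per_cell` replicates (default 5, the study-scale group size — 80
samples over two durations). `generate_expression()` draws, per gene:

* baseline ~ Uniform(4, 12) log2 units — the typical normalized
  microarray intensity range; cosmetic, affects nothing downstream;
* per-factor effects: exactly `round(fraction × n_genes)` genes per
  factor (default 5%) get a β with random sign and magnitude Uniform on
  `effect_size_range` (default [0.4, 2.0] — most true effects clear the
  0.379 calling threshold, some straddle it, exercising the boundary);
* an interaction increment for a random 30% subset of exposure-affected
  genes (a minority of response genes being duration-dependent);
* i.i.d. Gaussian noise (default sd 0.3 log2 units, a realistic
  residual scale for normalized arrays).

Draws use per-stage substreams of a single seed, so the same seed gives
bit-identical data. `generate_gene_sets()` builds enriched sets whose
members are ≥80% same-signed exposure-response genes (topped up with
nulls) and null sets drawn from genes with no effect at all.

What the simulator does **not** emulate: probe-level effects, batch or
array artifacts, correlated noise between genes, missing values, and
count-based (RNA-seq) mean–variance structure. A green test suite
therefore establishes internal statistical correctness — estimator
accuracy, FDR and permutation calibration, power under the stated
world — not robustness to those real-data complications.

## What the acceptance tests establish

* exact agreement of the per-gene OLS path with a normal-equations
  oracle (1e-9) and exact recovery of all effects at zero noise;
* realized false-discovery proportion among called exposure genes
  ≤ 0.10 at nominal q < 0.05, averaged over 20 simulation seeds;
* GSA: on pure-noise data ≤ 10% of replicates produce any significant
  set at the 5% permutation FDR, per-set empirical p uniform (KS), and
  detection power ≥ 0.9 for enriched sets with m ≥ 20 members and
  effects ≥ 1 log2 unit at noise sd 0.3 (200 permutations, scaled down
  from the 1000-permutation default to fit a single-CPU budget);
* hypergeometric/Fisher agreement with exhaustive enumeration for every
  2×2 table with N ≤ 12;
* k-means: the enumerated optimum (wss = 0.01) on a 4-point fixture and
  a non-increasing elbow curve over k = 2..20 at 50 restarts;
* loss-free round trips for every reader/writer pair (values to 1e-9,
  identifiers exact).

## Numerical conventions and limitations

* p values are floored at 1e-300 before logs; BH clips to [0, 1].
* Rounded percentages use round-half-up (so 55.76% prints as 56%).
* Expression files must carry a `gene_id` header token — a transposed
  matrix is rejected rather than guessed at; NA tokens are errors, not
  imputation triggers.
* The per-gene model assumes additivity on the log2 scale and
  homoscedastic gaussian residuals within a gene; no cross-gene
  information sharing is attempted.
* Empirical p values have resolution 1/(n_permutations + 1); thresholds
  from 200 permutations are correspondingly coarse, and 1000 (the
  default) is recommended for production runs.
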