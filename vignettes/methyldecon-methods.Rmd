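---
title: "Methods: robust methylation deconvolution with trimmed regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust methylation deconvolution with trimmed regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methyldecon)
```

## The model

A bulk methylation profile is modelled as a convex mixture of cell-type
reference profiles, `m = B f`, where `m` holds Beta values (methylation
proportions in [0, 1]) for the `n` CpGs of a signature matrix `B` whose `p`
columns are mean Beta profiles of purified leukocyte populations, and `f`
are non-negative cell-type coefficients later normalised to relative
fractions. There is deliberately no intercept: the generative mixing model
has none, and an intercept would absorb signal from unmodelled content in an
uninterpretable way.

The model's central assumption — that `B` spans everything in the mixture —
fails in tumor tissue. Tumor and stromal methylation contributes to a subset
of signature CpGs (those where the unknown content happens to be
hypomethylated, mimicking a marker), turning them into outliers under any
full-data fit. Least Trimmed Squares addresses exactly this failure mode:
with `k = floor(n * alpha)`, the estimate minimises the sum of the `k`
smallest squared residuals, so up to `n - k` contaminated CpGs have zero
influence. `alpha = 1` reduces to ordinary least squares.

Signature CpGs follow the hypomethylated-marker convention: a marker is a
CpG with *low* Beta in its cell type and high Beta everywhere else,
including non-hematopoietic tissue (low methylation tracks cell-type-specific
activity, and requiring high methylation outside the leukocyte compartment
keeps tumor signal from leaking into markers).

## The Fast-LTS search

The trimmed objective is combinatorial; we search with the standard
concentration-step scheme:

1. draw `n_starts = 500` random elemental subsets of size `p`, fit OLS on
   each;
2. apply two concentration steps per start (fit, rank squared residuals over
   all `n` CpGs, retain the `k` smallest, refit) — the objective is provably
   non-increasing, and the code asserts this at every step;
3. refine candidates to convergence (objective change below 1e-12).

On problems with `n <= 50` every start is refined to convergence — full
refinement is cheap there and measurably improves search completeness (the
test suite verifies equality with exhaustive subset enumeration on 100
random small instances). On signature-scale problems (n of a few hundred)
only the best 10 candidates are refined, the usual Fast-LTS shortcut. Ties
at the k-th ranked residual break toward the lower row index, which together
with a fixed seed makes every fit bit-reproducible.

## Choosing the trimming fraction

Each sample is fitted at nine alphas, 0.50 to 0.90 in steps of 0.05. The
candidates are compared on the consistency-corrected trimmed scale

σ̂(α) = sqrt( S_k / (k · c_α) ),  c_α = E[Z² | |Z| ≤ q_α],  q_α = Φ⁻¹((1+α)/2),

the classical LTS scale estimate: under clean Gaussian residuals it is flat
in α, and it jumps sharply (typically an order of magnitude) at the α that
first forces contaminated CpGs into the retained set. We select the
**largest α within 1.5× of the minimum scale** — the least trimming
compatible with an uncontaminated retained set. The plateau tolerance 1.5
sits comfortably between sampling fluctuation of the scale across nested
subsets (well under 50%) and the contamination jump; the selection is
insensitive to its exact value.

Two alternatives were considered and rejected during design. Scoring by
reconstruction RMSE over *all* CpGs rewards fitting the contaminated rows
and systematically under-trims precisely when trimming matters (measured on
synthetic spike-ins at 90% tumor content, per-sample correlation with truth
drops from ~0.99 to ~0.75). Scoring by the retained-subset RMSE is
degenerate in the other direction: it decreases mechanically as α shrinks
and always selects 0.50. On exactly clean mixtures all candidates tie at
zero and the largest grid value (0.90) is returned.

## Non-negativity and normalisation

Negative coefficients are resolved by elimination-and-refit: the most
negative cell type is removed from the design and the engine's core solve is
repeated on the same retained CpG rows, until all coefficients are
non-negative (at most `p` rounds). The QP engine needs no handling (the
constraint is built in); ν-SVR follows its own convention of truncating
negatives to zero without refitting. Surviving coefficients are normalised
to sum to one — fractions are therefore *relative to the modelled leukocyte
compartment*, not absolute.

## Goodness of fit and significance

With relative fractions f̃, the reconstruction is m̃ = B f̃. R1 and RMSE1
are the Pearson correlation and RMSE between m and m̃ over all aligned
CpGs; R2 and RMSE2 are the same quantities restricted to the LTS-retained
subset. R2 is the significance score: a sample whose retained CpGs cannot
be explained by any leukocyte combination (R2 below the threshold) has too
little modelled content for its fractions to be trusted. Two presets are
analysed throughout: stringent 0.5 (very low false-positive rate on
leukocyte-free samples) and lenient 0.35 (higher sensitivity, more false
positives). We define R2 on observed-versus-reconstructed values; defining
it between the full and subset reconstructions (a literal alternative
reading) would compare a vector with its own subset and carry no
information about the data, so it is not offered.

Degenerate inputs are flagged, not fatal: zero variance in either
correlation argument yields R = 0 with a `degenerate` marker; a sample whose
regression fails outright (e.g. all values missing) becomes a `failed` row
in the result table while the run continues.

## Calibration of the threshold

`build_mixture_grid()` forms convex two-component mixtures
`(1−w)·positive + w·negative` over a w-grid; `significant_fraction_curve()`
computes the share of significant calls per (threshold, w), smooths it with
loess (span 0.25, degree 2, the referenced smoother's defaults; smoothing is
skipped below 20 w-levels where span 0.25 is undefined), and reads the
fitted value at w = 1 as the false-positive rate. `roc_at_unknown_content()`
sweeps the threshold 0→1 in steps of 0.001 over scores from a ±2.5% window
around a target unknown content (positives) and from negative-negative pair
mixtures with uniform random weight (negatives — the simplest faithful
reading of "random pairwise mixtures"), reporting trapezoid AUROC and the
Youden-optimal operating point. The full-scale grid (w step 0.1%, 200
replicates per level = 200,200 mixtures) is available but the package
defaults to a reduced grid (w step 1%, 20 replicates) sized for interactive
use; the count formula `(1/w_step + 1) * reps` is exact either way.

## Tumor purity

The purity model is a supervised random forest regressing known purity on
15 features: R1, R2, RMSE1, RMSE2 and the relative fractions (feature count
follows the signature's cell-type count; the order is fixed by the schema
recorded in the model). Hyperparameters: 500 trees, 5 candidate features
per split, minimum terminal node 5 — the standard `randomForest`
configuration, whose candidate draw at each split is without replacement.
Features are not standardised (forests are scale-invariant) and predictions
are clipped to [0, 1] since a regression forest can stray slightly off the
proportion scale. Purity-scaled fractions are `(1 − q)·f̃`; ratios between
cell types are preserved exactly and the scaled vector sums to `1 − q`.

## Signature building

Construction from purified profiles proceeds in fixed order: (1) bridging
batch correction — per study, the mean profile of a bridge cell type present
in every study is compared with the cross-study aggregate and the difference
subtracted from all of that study's samples, then values are clipped to
[0, 1]; pre-clip, the per-study bridge means agree with the aggregate
exactly. (2) Missingness filters: samples with >10% missing CpGs first, then
CpGs missing in >10% of remaining samples. (3) Contamination filters:
sex-associated and X/Y probes (supplied as probe-ID lists, since annotation
versions drift), CpGs with mean Beta < 0.8 across a cancer cell-line panel,
and CpGs below 0.8 in any non-hematopoietic tissue panel. (4) Welch t-tests
for every unordered cell-type pair plus named lineage contrasts, with
Bonferroni correction over the **global** family (CpGs × contrasts — the
stricter of the two readings the wording permits, recorded in the ranking
metadata). A CpG enters a cell type's list only if every contrast involving
that type is significant *and* it is hypomethylated in that type against
every other; lists are ranked by worst-contrast corrected p (a minimax
choice guaranteeing all-contrast separation, since no ranking rule is
prescribed), ties by larger hypomethylation margin. Lineage-contrast lists
accept either direction of difference, as they separate groups rather than
mark one type. (5) For each g in 20..200, the top-g CpGs per list (shorter
lists contribute everything — this is how an 11×35 + 34 reference geometry
arises when the lineage list holds only 34 qualifying CpGs) are pooled and
the per-type mean signature with the smallest 2-norm condition number wins.
Singular candidates are skipped with a warning.

## Synthetic data: what it emulates, and what not

The generators stand in for purified-leukocyte and cancer cell-line array
data. Purified profiles give each cell type a disjoint block of marker CpGs
at Beta 0.10 against a 0.85 baseline — the hypomethylated-marker shape —
with replicate noise on the logit scale (sd 0.15) so draws stay in (0, 1);
multi-study sets add per-study additive offsets (sd 0.05) to exercise the
bridge correction. Synthetic signatures contain only marker CpGs, as real
signatures contain only selected discriminative probes. The unknown
(tumor-like) profile sits at the baseline with small per-probe scatter
(logit sd 0.05) and is hypomethylated at a configurable fraction of marker
CpGs (`tumor_overlap_frac`, default 0.2 in the benchmarks): contamination
is structural and sparse, like a cell line's methylome relative to the
leukocyte baseline, rather than dense i.i.d. noise. Spike-in mixtures give
the spiked type a controlled share of the leukocyte budget `1 − t` and split
the remainder by a symmetric Dirichlet(1) draw (no distribution is
prescribed for "randomly distributed", so the uniform simplex is used).
Measurement noise multiplies each Beta by `2^ε`, `ε ~ N(0, λσ)` with σ = 1
so the λ grid maps directly onto the log2 sd, applied on the Beta scale and
clipped.

What the generators do **not** emulate: probe-type chemistry and detection
p-values, probe-level covariance, realistic between-subject biological
variability, or cell types with correlated (non-disjoint) marker sets.
Passing tests therefore demonstrate correctness of the algorithms under the
stated model and robustness mechanism — not performance on any particular
real cohort, where marker overlap and correlated noise make all engines
worse.

## Problem sizes and numerical choices

The test suite and the acceptance script run on desk-scale problems chosen
once: 6 cell types × 30 markers (180-CpG signatures), 50 spike-in replicates
per tumor-content level, 500-sample purity cohorts, 200 + 200 significance
cohorts, and a 21-level calibration grid with 10 replicates. Heavy
simulations use 100 elemental LTS starts: at 180 CpGs the search is
saturated far below that, and search quality itself is covered by the
enumeration-oracle suite at `n_starts = 500`. Other numerical choices:
Beta values outside [0, 1] by more than 1e-6 are errors, within it they are
clipped (absorbing float formatting noise without hiding corruption);
alignment follows the signature's CpG row order; CpGs missing in a sample
are dropped from that sample's regression only; the Huber constant defaults
to 1.345 with MAD scale; ν-SVR standardises signature columns and mixture
jointly and maps primal weights back to the Beta scale, with ν chosen from
{0.25, 0.5, 0.75} by reconstruction RMSE.

## Known limitations

Relative fractions are conditional on the signature's cell-type roster;
purity-scaled fractions are still not absolute (stromal and endothelial
content is neither modelled nor subtracted). The ν-SVR engine is a
regularized estimator and does not reproduce exact mixtures to numerical
precision even without noise (bias ~1e-3 at default cost) — visible in the
engine-recovery results. The purity model is supervised: it extrapolates
poorly to cohorts whose fit-metric-to-purity relationship differs from its
training distribution. The significance threshold calibrated on synthetic
cohorts transfers to real data only to the extent the positive/negative
cohorts resemble them.
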