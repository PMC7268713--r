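---
title: "By-person factor analysis of forced-distribution Q-sorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{By-person factor analysis of forced-distribution Q-sorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsortr)
```

## The model

Q methodology inverts the usual factor-analytic design: persons are the
variables and statements the observations. Each participant assigns all
S statements to ranks on a forced quasi-normal grid, so every sort is a
permutation of the same rank multiset — all sorts share one mean and
one variance, and a symmetric grid forces every sort to sum to zero.
The packaged instrument uses S = 42 statements on an 11-rank grid with
capacities 1, 2, 3, 5, 6, 8, 6, 5, 3, 2, 1 from −5 to +5; these
capacities are exactly the rank frequencies observed in each of the
five published factor arrays, which is the only machine-readable
witness of the grid (the count profile is identical across all five
columns, which is strong internal evidence).

The inference chain is: Pearson correlation between sorts → principal
components of the P × P correlation matrix → rule-based retention →
Varimax rotation → exemplar flagging → weighted factor scores → grid
quantization → cross-factor comparison. Because the correlation matrix
has unit diagonal, eigenvalues sum to P and `pct = 100 λ / P` converts
between a factor's eigenvalue and its share of study variance.

## Parameters that matter

* **`alpha` / loading threshold.** The standard error of a zero-order
  loading is taken as `1/√S`; a loading is significant at
  `z_α/√S` (z = 1.96 at 0.05, 2.58 at 0.01). For S = 42 at 0.01 this
  is 0.3981 — the "0.4" criterion familiar from applied Q studies. The
  raw value is used in computation; reports echo the rounded one.
* **Retention rules.** A factor is kept only if its eigenvalue exceeds
  1.00 *and* at least two participants load purely and significantly
  on it after rotating the leading candidates. Retention starts from
  the number of eigenvalue-passing components (capped at the
  extraction size, default `min(8, P − 1)`) and steps k down,
  re-rotating at each k, until all k factors carry enough exemplars.
  The scree table is produced for inspection but never drives the
  decision, since elbow-reading is a judgment call we refuse to
  automate silently.
* **`kaiser`.** Kaiser row normalization is on by default (the
  behaviour of the classic Q software this workflow descends from);
  rows with zero communality pass through unscaled.
* **Exemplar weights.** Merging uses `w = f/(1 − f²)`. Loadings are
  clamped at |f| = 0.999 (with a recorded warning) so weights stay
  finite; clamping only binds in degenerate panels such as duplicated
  or noiseless sorts, where all relative weights are equal anyway.
* **`bipolar`.** Negative exemplars are excluded from score estimation
  by default: the source study interpreted its single negative loader
  narratively rather than folding its mirror image into the factor
  array, and we follow that choice. `bipolar = "include"` negates such
  sorts' ranks and includes them with the magnitude of their weight;
  on a symmetric grid the two conventions coincide whenever positive
  and negative exemplars are exact mirrors.
* **Distinguishing statements.** Factor standard errors come from the
  composite reliability `r = 0.80 p/(1 + 0.80(p − 1))` with the
  conventional single-sort reliability of 0.80; a statement
  distinguishes a factor at a level when its z-score differs from
  *every* other factor by more than `z_α √(SE_f² + SE_g²)`.

## Numerical choices

* **Varimax** is implemented as classic pairwise planar sweeps with the
  closed-form quartic angle, converging when the criterion gain per
  sweep falls below `1e-8` (cap 1000 sweeps; exceeding it is recorded
  as a warning on the solution, not an error). The criterion is exposed
  (`varimax_criterion()`) and the test suite checks the two-factor case
  against an exhaustive 0.001° grid search over the rotation angle and
  against the reference rotation in the stats package.
* **Sign and order conventions.** Every loading column (unrotated and
  rotated) is signed so its largest-magnitude entry is positive, and
  rotated columns are reordered by explained variance; the returned
  rotation matrix folds both in, so `rotated = unrotated %*% rotmat`
  holds exactly. This makes solutions reproducible across linear
  algebra backends.
* **Quantization ties.** When two statements tie in z at a capacity
  boundary, the lower statement id takes the higher rank. Any fixed
  rule would do; this one is deterministic, easy to state, and shared
  between the analysis and the simulator so noiseless recovery is
  exact.
* **Degenerate inputs.** One-rank grids are rejected at correlation
  (zero variance); correlation matrices are symmetrized and checked
  for positive semi-definiteness up to `1e-6 · P` (panels with more
  sorts than statements are rank-deficient, so small negative
  eigenvalues are clipped to zero); a factor whose only exemplars are
  negative errors under the default bipolar policy rather than
  silently producing a mirrored array.

## The simulator, and what passing tests show

`simulate_qsorts()` draws K prototype arrays by permuting the grid's
rank multiset, rejecting draws until all pairwise |Spearman| ≤ 0.3
(budget 10,000 draws). Participants are realized as: standardized
prototype ranks, plus iid Gaussian noise of sd `noise_sd`, re-quantized
onto the grid — so panels are grid-valid by construction and the noise
has a single interpretable scale (in units of the standardized latent
score). Confounded participants average two prototypes 50/50 before
noise — the simplest generator of the two-factor loading pattern the
pure-loader rule must reject; negative participants realize a negated
prototype. A single seed drives all randomness.

Defaults mirror the packaged study's structure: the 42-statement grid,
K = 5 viewpoints with pure group sizes 19, 25, 16, 6, 4 (the published
exemplar counts), about one negative loader per hundred sorts, a fifth
of sorts confounded. The study reports no quantitative noise level —
the raw sorts are not deposited — so `noise_sd = 1` was fixed once as
the working value: it leaves individual sorts correlating roughly 0.7
with their prototype, comparable to the loading levels applied Q
studies report, while keeping recovery non-trivial.

The recovery experiments in the test suite use K = 4 prototypes and 15
pure sorts per factor over 50 seeds at this noise level; the retention
rules recover k = 4 and the matched arrays correlate ≥ 0.9 with the
prototypes in well over 95% of seeds, noiseless runs reproduce the
prototypes exactly, and injected mixture sorts are never flagged at
noise 0. These are checks of *internal* consistency: the generator
emulates forced-grid structure, cleanly separated viewpoints and
simple mixture confounding, but not response styles, partially shared
viewpoints, demographic covariance or item-level misunderstanding, so
passing them shows the machinery is correct, not that any real panel
will yield equally clean structure.

## Fixtures and their quirks

The packaged tables are stored as printed in the source study. Two
internal inconsistencies are preserved rather than repaired: the
whole-sample education block and self-rated health-score block sum to
109 of 110 (their printed percentages are consistent with a
denominator of 110, suggesting an unrecorded missing response), and
the factor-2 exemplar blocks for the EQ-5D profile and health score
sum to 24 of 25 (consistent with the one participant with missing
self-rated health loading on that factor). The validation tests
document both exceptions explicitly. `study_meta()` reconstructs a
per-participant table from the marginal counts with each column
expanded independently; it is synthetic — marginals match the
published table exactly, the joint distribution is arbitrary.

## Known limitations

* Only PCA extraction and Varimax rotation are provided — the
  workflow of the source study. No centroid extraction, manual
  rotation, or oblique rotations.
* The published study's rotated loadings are not printed and its raw
  sorts are undeposited, so the original five-factor solution cannot
  be reproduced numerically; fixture fidelity, analytic invariants,
  oracle equivalence and simulation recovery stand in for it.
* Problem sizes in the tests (panels of 8–72 sorts, 50-seed recovery
  sweeps) are chosen to make the full suite run in about a minute on a
  single core while still exercising every rule; they are an order of
  magnitude below a large applied Q study, which the pipeline handles
  without special treatment (the P × P eigendecomposition is the only
  super-linear step).
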