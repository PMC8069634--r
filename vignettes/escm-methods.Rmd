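---
title: "Eigenvalue-shrinkage one-class modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenvalue-shrinkage one-class modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escm)
```

## The problem

Untargeted metabolomics produces tables of relative abundances for hundreds
to thousands of metabolites (P) measured on few reference samples (N). A
one-class model trained on the references answers "does a new sample look
normal?" without ever seeing abnormal training data, which is exactly the
situation in crop-safety assessment (reference = varieties with a history of
safe use), screening for rare metabolic disease (reference = healthy
controls), or longitudinal instrument QC.

The natural distance statistic is the squared Mahalanobis distance
MD²(y) = (y − μ̂)ᵀ Σ̂⁻¹ (y − μ̂) on auto-scaled data, with an outlier
declared when MD² exceeds a critical limit. Everything difficult about the
problem is in Σ̂ and in the limit.

## Model and assumptions

We assume the reference class is, after transformation (log for LC-MS
intensities), approximately multivariate normal with mean μ and covariance
Σ, and that the training set contains no gross outliers. All data —
references and new observations alike — is auto-scaled with the training
means and standard deviations (divisor N − 1), so each variable enters
unit-free and the natural shrinkage target for the correlation-scale
covariance is the identity.

### Covariance estimation

The sample covariance S (divisor N − 1) has overdispersed eigenvalues for
N ≈ P and is singular for N ≤ P, so MD² is unusable exactly where
untargeted data lives. `escm` uses linear eigenvalue shrinkage

$$\hat\Sigma \;=\; (1-\lambda)\,S + \lambda I, \qquad \lambda\in[0,1],$$

whose spectrum is the affine map (1 − λ)·eig(S) + λ: positive definite for
any λ > 0, with the eigenvalue spread contracted by the factor (1 − λ).
Throughout the package **`intensity` = λ = the weight on the identity
target**, so 0 means "no shrinkage". (The field also writes the mixture
with the weight on S; we follow the convention in which an intensity of,
say, 0.6 reads as "considerable shrinkage", since that is how practitioners
discuss fitted values.)

Three analytic estimators of λ are provided:

* **`lt`** (default): the nonparametric Steinian estimator. With
  Y₁ = tr(S), Q = Σᵢ‖xᵢ − x̄‖⁴/(N−1) and the unbiased estimator
  Y₂ = (N−1)/(N(N−2)(N−3)) · [(N−1)(N−2) tr(S²) + tr(S)² − N·Q] of tr(Σ²),
  λ̂ = (Y₁² + Y₂) / (N·Y₂ + Y₁² + (N−1)(P − 2Y₁)), clipped to [0, 1]. It
  derives from minimising E‖Σ̂ − Σ‖²_F without distributional assumptions
  (only finite fourth moments), needs N ≥ 4, and plugging Σ = I into the
  population expression gives exactly 1 — the target-equals-truth limit.
* **`oas`**: the oracle-approximating estimator,
  ρ̂ = min(1, [(1 − 2/P)tr(S²) + tr(S)²] / [(N + 1 − 2/P)(tr(S²) − tr(S)²/P)]),
  derived under multivariate normality; when S is exactly spherical the
  denominator vanishes and 1 is returned with a warning.
* **`lw`**: the Ledoit–Wolf analytic estimator, b̄²/d² with
  d² = ‖S − mI‖²_F/P and b̄² = min(d², Σₖ‖xₖxₖᵀ − S‖²_F/(N²P)).

All three agree with independent line-by-line transcriptions of their source
formulas in the unit tests, and all are computed through the N × N Gram
matrix of the centered rows when P > N, so no P × P matrix is ever formed
during cross-validation. Raw optima above 1 are common when the target is
close to the truth and are clipped (set `options(escm.verbose = TRUE)` to
log clip events).

A ridge precision estimator
[(δI + 0.25(S − δI)²)^{1/2} + 0.5(S − δI)]⁻¹ — equivalent to a nonlinear
shrinkage of the sample eigenvalues — is included (`vw_ridge_precision()`,
with `select_vw_delta()` choosing δ by leave-one-out likelihood, ties broken
toward the larger penalty). It is not used by the default pipeline: inside
leave-one-out calibration the covariance is re-estimated N times per fit,
and nonlinear approaches are orders of magnitude more expensive for the P
of interest while linear shrinkage captures most of the attainable
improvement when P/N is large. For the same reason the spectral-density
nonlinear estimator is recognised by name but deliberately not implemented.

### The critical limit

Shrinkage changes the null distribution of MD², so the classical F-based
limit (available as `classical_md_limit()` for N > P) does not apply. The
limit is calibrated on the references themselves:

1. For each reference xₙ, hold it out; re-estimate the mean and the
   shrunken covariance (with its intensity) from the remaining N − 1 rows;
   record MD²(xₙ) about that fold's mean. The auto-scaling is fit once on
   all N references and held fixed across folds.
2. Moment-match a scaled chi-square g₁·χ²(g₂) to the N cross-validated
   distances: with m̂ their mean and s² their sample variance,
   g₁ = s²/(2m̂) and g₂ = 2m̂²/s², so that the fitted law has exactly mean
   m̂ and variance s². The limit is MD²crit = g₁ · χ²₁₋α(g₂).

Two design points deserve emphasis:

* **What is re-estimated per fold.** Re-estimating only the covariance
  while keeping the full-data mean makes the held-out scaled row equal to
  −(N − 1) times the fold mean — a vector *inside* the fold's row space,
  where the shrunken precision is smallest. The resulting limit is badly
  anti-conservative (the effect grows as P/N grows). Re-estimating the fold
  mean as well (the default here) removes that degeneracy while keeping the
  single global auto-scaling; the acceptance tests verify the resulting
  calibration (slightly above nominal at N = 25, inside the exact binomial
  band around 5% by N = 100, for P = 250). A strict variant that re-fits
  the entire scaler per fold (`refit_scaler = TRUE`) makes the held-out row
  fully out-of-sample and calibrates at or just below nominal; it is the
  better choice when a conservative limit is preferred.
* **The scale factor.** g₁ = s²/(2m̂) is the unique factor for which
  g₁·χ²(g₂) matches both moments; the variant g₁ = s²/m̂ (mode
  `"paper_printed"`, implied mean 2m̂) appears in print in the literature
  this package follows but yields a limit so large that essentially nothing
  is ever flagged; it is available for replication only.

A nonparametric alternative (`bootstrap_limit()`) averages the empirical
(1 − α) quantile (type-7 interpolation, the common default, fixed for
bit-reproducibility) over B bootstrap resamples of the cross-validated
distances.

Boundary rule: equality with the limit classifies as *inside* the class.
Degenerate inputs fail loudly: constant columns cannot be auto-scaled
(half-minimum imputation and the log transform must come first),
zero-variance cross-validated distances (duplicated references) are an
error, and a zero intensity with P ≥ N would leave a singular covariance
and is refused.

## The PCA (SIMCA) baseline

`simca()` implements the standard PCA-based one-class baseline used for
comparison. PCA of the auto-scaled references retains the smallest number A
of components explaining at least 80% of the variance (`var_target`,
capped at N − 2 so the T² limit exists). For a new observation with scores
t and residual z − Lt: T² = Σₐ tₐ²/λₐ, Q = ‖z − Lt‖², and the combined
statistic T²/T²crit + Q/Qcrit. Limits: T² from the prediction-form
Hotelling bound A(N² − 1)/(N(N − A)) · F₁₋α(A, N − A); Q and the combined
statistic from the same moment-matched scaled chi-square machinery as the
main model, fitted to the training statistics (no cross-validation —
common SIMCA practice). The exact calibration used by any given SIMCA
implementation varies; this choice reproduces the qualitative behavior that
matters for the comparison — a strongly conservative T² and a strongly
anti-conservative Q when P ≫ N — because training residuals live in the
(N − 1 − A)-dimensional remainder of the sample row space while fresh
observations have residuals in the full (P − A)-dimensional complement.

## The simulation framework

`sim_config()` + `run_type1()`/`run_power()` draw N references per
replicate from a P-variate normal (μ = 0), fit the requested models, and
classify 100 fresh test observations per replicate — null draws for type-I
error, or draws with a shifted mean for power. Flag rates are pooled over
replicates (defaults: 200 replicates × 100 tests) and reported with exact
Clopper–Pearson bands. Three covariance structures are provided:

* `block_fixed`: independent compound-symmetry blocks of 25 variables,
  within-block correlation 0.8, unit variances — each block contributes one
  eigenvalue 1 + 24·0.8 = 20.2 and 24 eigenvalues 0.2;
* `block_random`: within-block entries i.i.d. U[0.6, 0.9], between-block
  entries i.i.d. U[0, 0.4], repaired to the nearest positive-definite
  correlation matrix by an eigenvalue floor (10⁻⁶) plus diagonal rescale.
  I.i.d. entry draws are never positive definite at these sizes, so the
  repair is substantial and is announced by a warning when any entry moves
  by more than 0.2;
* `surrogate_real`: a synthetic stand-in for the correlation matrix of a
  large real LC-MS study (the original data is not redistributable):
  heterogeneous blocks (sizes log-uniform in [5, 50]) with per-block
  within-correlations U[0.4, 0.9], between-block correlations in [0, 0.3]
  induced by a single global factor, positive definite by construction.
  Blocks are ordered by within-correlation so the leading variables form
  the most tightly correlated cluster.

For the random structures a fresh correlation matrix is drawn per replicate
(`redraw_cov`), treating the stated ranges as an ensemble.

Mean-shift scenarios for power: `first12` (add γ to the first 12, highly
correlated, variables), `random12` (12 variables re-sampled per replicate),
`eigmax`/`eigmin` (shift along the extreme eigenvectors of Σ). For the
eigen-scenarios the printed shift size is ambiguous between γλ and γ√λ; the
default `eig_scale = "sqrt_lambda"` makes γ count standard deviations along
the eigen-direction (matching a "shift (STD)" axis), with
`eig_scale = "lambda"` for the literal reading.

### What the synthetic structures do and do not emulate

The generators emulate blocked correlation, non-detects, positive
abundances and designated reference/test groups. They do **not** reproduce
two properties of real untargeted LC-MS tables that materially affect
benchmark numbers:

* **Very low effective rank.** Real top-variance metabolite features
  (adducts, isotopes, in-source fragments of the same compounds) are far
  more strongly correlated than U[0.4, 0.9]; the residual variance beyond
  the leading directions is tiny. The PCA baseline's null Q flag rate is
  extremely sensitive to this: under the synthetic structures essentially
  every null test observation is flagged, whereas under a near-degenerate
  real correlation matrix the rate, while still an order of magnitude above
  nominal, stays below 1. Comparisons of the PCA baseline against published
  rates observed on real-data-derived structures are therefore qualitative.
* **A dispersed population spectrum.** The separation between the three
  intensity estimators (LW noticeably under-shrinking, hence a clearly
  worse type-I error) emerges when the population eigenvalues are strongly
  dispersed; under the synthetic structures the three estimated intensities
  lie within a few percentage points of each other and the three type-I
  errors nearly coincide. Passing or failing a strict ordering test of the
  three estimators on synthetic data says little about their ordering on
  real data.

Consequently, the acceptance tests treat level-of-calibration checks
(nominal band at moderate N/P, growth of the type-I error at P = 2000,
conservative T² vs anti-conservative Q, monotone power curves saturating at
1, eigmax ≫ eigmin) as the reproducible substance, and flag the
structure-bound quantities as approximate.

Problem sizes: the test suite and `scripts/acceptance.R` use 200
replicates × 100 tests at (N = 25, P = 250), 50 replicates at
(N = 100, P = 250), 50 replicates per power scenario, and 20–30 replicates
at P = 2000 (plus a 10-replicate N = 100 sensitivity run) — sizes chosen so
pooled rates have Monte-Carlo standard errors well inside the tolerances
being asserted while the whole study remains a desk-scale computation.

## Numerical choices

* MD² is computed as a quadratic form through a Cholesky/Woodbury
  factorisation, never by explicit matrix inversion; when P > N the
  precision of (1 − λ)S + λI is held implicitly via the N × N Gram matrix,
  making a leave-one-out fit O(N³ + N²P) instead of O(N P³).
* Matrix square roots and inverses of symmetric matrices go through
  symmetric eigendecompositions with eigenvalues floored at 0 — exact for
  symmetric input and safe for rank-deficient S.
* Intensities are clipped to [0, 1]; degenerate spectra (d² = 0, spherical
  S) return 1 with a warning.
* Tie-breaks: ridge-penalty selection prefers the larger δ among
  likelihood ties; classification treats equality with any limit as inside
  the class.
* Non-detect filtering is strict ("more than 40% zeros" drops a variable;
  exactly 40% is kept), imputation is half the minimum **positive** value
  per variable (a whole-table minimum is available via `scope = "global"`),
  and the chain order filter → impute → log → auto-scale is enforced —
  imputing first would hide the non-detect fractions the filter needs, so
  filtering an imputed table is an error. The log defaults to base e with
  other bases available.

## Known limitations

* The reference set is assumed outlier-free; no robust estimation of μ̂ or
  Σ̂ is provided. Cross-validated distances (`residuals()`) are the
  practical screening tool for suspect references.
* Only the identity (or a user-supplied diagonal) shrinkage target is
  supported — appropriate for auto-scaled data, not for raw covariances.
* The scaled chi-square is a two-moment approximation to the null
  distribution of the shrunken MD²; at very small N (≲ 10) its tail may be
  unreliable, and the bootstrap limit is no better there.
* Per-variable outlier-contribution diagnostics (which metabolites made a
  sample abnormal) are out of scope.
* With 50–100 references the type-I error degrades as P grows into the
  thousands (the acceptance suite quantifies this at P = 2000); more
  references, or variable filtering, is the remedy.
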