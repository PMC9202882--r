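---
title: "Estimating figure-ground responsive fields: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating figure-ground responsive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgfield)
```

## The problem

Mid-level visual neurons (area V4 is the motivating system) modulate their
firing depending on whether a *figure* or the *ground* of a scene covers
their receptive field. To map where, in and around the classical receptive
field (CRF), figure and ground regions drive a neuron, one pairs each
stimulus with a human-style segmentation mask — an *FG label*: a small
square grid whose cells are tagged +1 (figure) or −1 (ground), with the
figure/ground boundary passing through the patch center — and weights those
labels by the spike counts the corresponding stimuli evoked. The resulting
kernel, the *figure-ground responsive field* (RF-FG), is positive where a
figure increases the response and negative where a ground does.

`fgfield` implements the full estimation stack on this data model:

* a **bias-compensated spike-triggered average** (STA): the spike-weighted
  mean label minus the plain ensemble-mean label,
  \[
  K \;=\; \frac{\sum_i L_i\,s_i}{\sum_i s_i} \;-\; \frac{\sum_i L_i}{N},
  \]
  where \(L_i\) is label \(i\) and \(s_i\) its summed spike count. FG-label
  ensembles are far from white — every label is a large coherent bipartition
  — so the naive STA is biased by the ensemble mean; subtracting it makes a
  neuron that responds equally to every stimulus come out exactly flat.
  Whitening is deliberately *not* applied: decorrelating the labels would
  destroy the very spatial extent of figure and ground that the kernel is
  supposed to measure.
* **permutation significance** of the kernel magnitude (squared sum of
  elements) under shuffled stimulus-to-count assignment;
* a **convergence diagnostic** over label-subset size, with a saturating
  model fit whose asymptote estimates the kernel magnitude at infinite
  stimulus count;
* an **adaptive filter** (exponentially weighted recursive least squares)
  as an assumption-free linear cross-check on the STA;
* **spike-triggered covariance** (STC) for response-relevant variance
  directions invisible to any mean-based estimator (e.g. energy-type
  invariances), with a randomized eigenvalue-difference significance rule;
* **rectified response models** built from the estimated kernels, and a
  Bayesian binned-rate diagnostic of kernel linearity;
* **geometry metrics**: PR ratio, CRF overlap ratio, rotation and
  CRF-scale alignment, population averaging;
* a **synthetic-data module** generating label ensembles with the study's
  design constraints and virtual neurons with known ground truth, so every
  estimator is testable end to end without recordings.

## Study conditions emulated by the generators

The synthetic module reproduces the structural features of the stimulus
design that matter to the estimators, with these defaults:

* **Grid**: G = 25 cells in every estimator, so kernels from STA, AF and
  STC live on the same lattice (625 dimensions); the patch center is cell
  (12, 12). Cell indices are 0-based; continuous positions are in cell
  units.
* **Ensembles**: 105 boundary orientations (or base curves) × two
  figure sides = 210 labels, ten trials per stimulus, spike counts taken in
  a 160 ms stimulus window. Curved boundaries are a straight line through
  the center perturbed in the normal direction by a cubic polynomial of the
  tangent coordinate (SD 2 cells by default): this preserves the two
  design constraints the estimators rely on — boundary through the center,
  diverse shapes — while remaining seedable and valid by construction,
  unlike resampled natural contours. Every ensemble is closed under
  figure/ground swap, so its mean label is exactly zero; real filled-patch
  ensembles have a nonzero mean (peripheral bias up to ~16%), which is
  exactly what the compensation term absorbs.
* **Contrast pairs**: opposite-contrast filled stimuli share one label;
  their counts are summed trial-wise before estimation
  (`pool_contrast_pairs()`), making all kernels contrast-invariant.
* **Virtual neurons**: ideal FG cells (one spike whenever the preferred
  side covers the CRF-center cell), rectified-linear and purely linear
  cells (`max(0, <k, L>)`, `offset + <k, L>`), energy cells (`|<k, L>|`,
  invisible to the STA by symmetry), and non-FG cells (constant rate).
  Optional Poisson trial noise; with noise off, expected counts are rounded
  to the nearest integer so the deterministic path still produces
  integer spike counts (use large gains where near-exact rates matter).
* **Dot probes**: the exhaustive set of 2·G² single-cell ±1 stimuli. It is
  white by construction and the identity
  `max(x,0) − max(−x,0) = x` makes the dot-derived STA of a noiseless
  rectified-linear cell exactly proportional to its kernel — the analytic
  anchor of the validation module. The exhaustive set (rather than random
  placement) is used for determinism; a random subset can be taken
  downstream.

What the generators do *not* emulate: luminance, color and texture of
natural patches, the Gaussian contrast aperture, convexity/closure/symmetry
balancing of the stimulus selection (approximated only through the
curvature SD), and attentional or anesthesia effects. Passing tests
therefore validate the *estimators* under the stated stimulus geometry, not
the biology of any recorded population.

## Numerical and statistical choices

**Per-stimulus drive.** Estimators weight labels by the per-stimulus sum of
counts over trials. The STA is invariant to positive scaling of the counts,
so summing versus averaging is immaterial; summing keeps integers.

**Permutation test.** Stimulus-level totals are shuffled (not trial-level
counts), 1000 permutations by default, with the add-one estimator
\(p = (1 + \#\{m^* \ge m\})/(n+1)\) so p is never 0; degenerate tables
(equal counts everywhere) give p = 1 by construction.

**Convergence.** Kernel magnitude is averaged over 100 random subsets per
size, sizes in multiples of 20 up to N; the subset's own mean label is used
for compensation (the bias term must match the ensemble actually
averaged). The curve is fit by the saturating family
\(y(x) = a\,(1 - b e^{-(x/c)^d} + be)^f\) under box constraints
(\(b \in [0,1]\), \(e \ge 0\) small, \(d, f > 0\)) with multi-start
Levenberg–Marquardt; \(a\) is the magnitude at infinite stimulus count and
the convergence ratio is \(y(N)/a\), clamped to (0, 1]. A kernel is
**effective** when p < 0.05 *and* ratio ≥ 0.9. The family is monotone
increasing; a pure-noise kernel whose magnitude *decays* with subset size
is fit by a flat curve (ratio ≈ 1) and is screened out by the magnitude
test instead — the two criteria are deliberately complementary.

**Adaptive filter.** Canonical exponentially weighted RLS on flattened
labels: inverse-correlation matrix initialized at \((1/\delta)\,I\) with
\(\delta = 10^{-5}\), forgetting \(\beta = 0.99\), leakage \(\mu = 0\), and
a periodic guard every Q = 100 updates (re-symmetrization plus adding
\(\delta I\) to the information matrix, which caps the gain at its initial
scale and is a no-op for well-conditioned updates). Rates are counts over
the 160 ms window in Hz; pairs are duplicated to 4200 and presented in a
randomized order with no stimulus repeated back-to-back. With
\(\beta = 1\), \(\mu = 0\) the final kernel equals the ridge least-squares
solution with regularization \(\delta\) — the oracle the tests check to
1e-6. An important caveat discovered while validating: with
\(\beta = 0.99\) the effective memory (~100 pairs) is shorter than the
~210-pair stimulus revisit cycle, so the exponentially weighted LS problem
is dominated by the most recent labels and the estimate decorrelates from
the STA (covariance wind-up under poor excitation — a failure of the
objective, not of the recursion). Estimator-agreement analyses should
therefore run the filter in its consistent growing-window regime
(\(\beta = 1\)), where the AF–STA cosine on rectified-linear virtual
neurons is ≈ 0.85; the wind-up behaviour at \(\beta = 0.99\) is itself
covered by a test.

**STC.** The spike-weighted covariance of STA-centered labels minus their
unweighted covariance, with per-stimulus weights normalized to mean 1:
uniform weights give the exact zero matrix, the null the significance rule
leans on. (A literal reading that multiplies each label by its weight
*inside* the outer product is available behind `literal = TRUE` for
comparison; it scales with squared counts and is not the default.) All G²
eigenpairs are kept, ranked 1⁺, 2⁺, … from the largest positive and 1⁻,
2⁻, … from the smallest negative eigenvalue. Significance: 1000 shuffled
spectra yield per-rank means and SDs of consecutive eigenvalue differences;
an eigenvector is significant if its rank-local gap exceeds the null mean
+ 1 SD at that rank *and* its neighbor nearer the spectrum extreme is also
significant (chaining; the per-rank rather than pooled null matches the
rank-resolved error bands the rule was designed around). Eigenvector sign
is arbitrary; comparisons use |cosine|. Because the estimated subspace is
confined to the span of the label ensemble (~210 of 625 dimensions),
recovery of an energy cell's kernel is only near-perfect for kernels inside
that span — the ideal-kernel profile is used as the canonical in-span test
case.

**Response models.** Model drive is the inner product of kernel and label
(the summed Hadamard product), half-wave rectified. The STA model optimizes
one non-negative weight (closed-form for the rectified 1-D problem, then a
bracketed polish). The STA+STC model adds the significant STC kernels,
positive-eigenvalue terms added and negative subtracted, all weights
optimized jointly by L-BFGS-B from the STA optimum with STC weights zero —
so its RMSE can never exceed the STA model's. On swap-closed ensembles that
starting point is a stationary point of the symmetric numerical gradient
(every label's negation is also in the set), so a second start at
coordinate-wise rectified-LS scales is tried and the better fit kept; the
no-regression guarantee is preserved. The rectification condition is the
model's own drive being positive.

**Linearity diagnostic.** Stimuli are ranked by normalized projection onto
the kernel and split into 10 equal-count bins; the ratio of the
spike-weighted to the plain bin probability is proportional to the
predicted rate per bin. The headline statistic is the R² of that curve
regressed on bin rank. Note a structural ceiling: even for an exactly
linear cell the bin-mean projection is a sigmoidal function of bin *rank*
whenever the projection distribution is unimodal, capping R² near 0.91;
the uniform-orientation half-plane ensemble comes closest to the linear
ideal and is the reference condition for this diagnostic. Energy cells
produce the diagnostic U-shape and R² near 0.

**CRF geometry.** The CRF is fit to a 5×5 grating spike-count map as a
rotated elliptical 2D Gaussian (7 parameters including baseline) by
bounded Levenberg–Marquardt with up to 5 starts seeded from the peak cell
and second moments. The CRF extent is the 1-SD ellipse, rasterized by the
cell-center-inside rule. Stimulus classification (figure vs ground at the
CRF) reads the label at the nearest cell — sub-cell interpolation would
invent label values the data model does not define. The responsiveness
screen is Student's or Welch's t-test on pooled pre-stimulus versus
stimulus-window counts, the branch chosen by a two-sided F-test at
α = 0.05 (the variance-screen rule is an explicit package choice); FG
modulation is a one-way ANOVA on per-stimulus mean counts.

**Geometry metrics.** The support of an estimated (noisy) kernel is the
set of cells with |value| above ε·max|value|, ε = 0.05 by default and
exposed everywhere — no universal threshold exists for noisy kernels. The
PR ratio is the preferred-sign share of the support (0.5 = balanced
antagonism; the ideal kernel on a uniform half-plane ensemble measures
exactly 0.50). The overlap ratio is |AND|/|OR| between the rasterized CRF
ellipse and the preferred subregion. Rotation alignment turns the
value-weighted center of gravity of the preferred subregion onto the
reference axis (figure→left, ground→right) about the patch center;
CRF scaling is isotropic about the CRF center to a common geometric-mean
SD; population means normalize each kernel by its own maximum before
aligning and averaging. All warps are bilinear with zero fill outside the
grid: inverse compositions recover smooth in-grid kernels to within ~1–2%
of the maximum, but content warped off-grid is irrecoverable and sharp
boundaries interpolate with proportionally larger local error — round-trip
guarantees are therefore stated for smooth, compact kernels.

**Tie-breaks and degeneracies.** Cells whose center lies exactly on a
generated boundary go to the figure side of the primary label; its mirror
partner is the exact negation (keeping swap-closure exact). Half-plane
orientations use `cospi`/`sinpi` so axis-aligned boundaries are exact.
Linearity bins break projection ties by stable stimulus order. Flat CRF
maps are flagged degenerate; zero-norm kernels are errors in similarity
metrics and flagged (not scored) in validation reports.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use the native 25-cell grid for
everything that depends on it (dot recovery over the 1250-stimulus
exhaustive set, 625-eigenpair STC with 1000-shuffle nulls, 100-cell
permutation type-I studies at 1000 permutations each) and smaller grids
(G = 5–15) for oracle comparisons where the substance is scale-free, e.g.
the RLS-vs-ridge identity. A full pipeline run on the default synthetic
configuration completes in minutes on one core.

## Known limitations

* Kernels inherit the autocorrelation of the label ensemble; the package
  reports this honestly via the patch-vs-dot validation module rather than
  attempting whitening.
* The convergence family cannot flag *decaying* magnitude curves as
  non-converged (see above); effectiveness relies on the joint criterion.
* The adaptive filter's short-memory regime is statistically unreliable on
  repeating, highly collinear ensembles (documented wind-up); treat
  \(\beta < 1\) results on such designs with suspicion.
* STC recovery is limited to the label span; out-of-span structure is
  unobservable in principle with these stimuli.
* The rectified models are linear-in-kernels before rectification; they
  cannot represent multiplicative interactions between subregions.
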