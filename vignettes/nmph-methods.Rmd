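---
title: "Methods: correlation-targeted synthesis and the constrained cubic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-targeted synthesis and the constrained cubic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nmphtools)
```

This vignette is the package's own account of its two methods — the image
synthesis engine that manufactures stimulus similarity, and the
nonmonotonic-plasticity (NMPH) analysis pipeline that measures what
learning does to it — together with the design decisions that were
genuinely open and the reasons we settled them the way we did.

## 1. The synthesis engine

### The objectives

Synthesis treats an image as a free variable: an H x W x 3 array of pixel
intensities in [0, 1], updated by gradient steps through a differentiable
feature extractor. Three phases run in order.

**Endpoint channel selection.** For every channel of the deepest target
layer we run classic activation maximization: ascend the mean channel
activation from seeded uniform noise. The optimized channel images are fed
back through the extractor, their activation patterns at the target taps
are correlated, and the k = 16 least inter-correlated images are kept and
paired into 8 *endpoint pairs*. Subset selection is exhaustive whenever
`choose(n, k)` is at most 10,000 subsets (so small configurations are
provably optimal and testable against brute force), and greedy backward
elimination — repeatedly dropping the image with the largest mean absolute
correlation to the remainder — otherwise, since 128-choose-16 is far beyond
enumeration. Survivors are paired by sweeping all within-survivor pairs in
ascending |r| and greedily taking disjoint ones; ties resolve by index
order, so the whole step is deterministic.

**Initialization.** Each image of a pair ascends a weighted sum of two
channel-mean objectives: its own endpoint channel at weight 1 and its
pairmate's channel at weight t, the level's intended correlation. At t = 0
the images express only their own channels; at t = 1 the two objectives
coincide and the images differ only through their noise seeds.

**Correlation tuning.** The pair is then optimized directly on the summed
squared deviation of its per-layer feature correlations from their
targets: sum over tapped layers of (r_l − t_l)^2, with t_l = 0.25 at every
constrained tap and t_l equal to the level's scheduled value at the target
taps. The gradient of a Pearson correlation with respect to one feature
vector has the closed form (b~ / |a~||b~|) − r a~ / |a~|^2 (tildes denote
centred vectors), which is chained through the extractor's backward pass.
Images A and B are updated on alternating iterations.

### Numerical choices

- **Optimizer.** Plain gradient steps with the gradient first re-weighted
  by a Laplacian pyramid (each band scaled to unit RMS energy, which stops
  high-frequency bands from dominating) and then normalized to unit mean
  absolute value; the step size (default 0.05 in pixel units) multiplies
  that normalized direction. Because both normalizations erase the
  objective's scale, the tuning phase additionally multiplies the step by
  min(1, sum |r_l − t_l|): steps shrink in proportion to the remaining
  error, so the pair settles onto its targets instead of orbiting them. In
  practice this converges to within a few thousandths of the target in
  about a hundred iterations.
- **Best-so-far tracking.** The tuning cost is recorded every iteration
  and the best images seen are returned, so the reported cost trace is
  non-increasing by construction even if a late step overshoots.
- **Pixel domain.** Pixels are clipped to [0, 1] after every step (no
  sigmoid reparameterization); it is the simplest contract and the box
  constraint is what makes the all-ones image the analytic maximizer of an
  averaging kernel, which the tests exploit.
- **Degenerate inputs.** A tap whose activation vector has zero variance
  (for example a dead layer) makes the correlation undefined; the engine
  raises an error naming the tap rather than returning NaN. Flat
  objectives for ten consecutive iterations return the best-so-far image
  with a warning.

### The multi-scale loop

The full procedure runs `volleys` times (default 3), magnifying the image
by 40% (bilinear, sizes rounded half-up) between volleys, and computes
gradients through a square moving window whose side is 90% of the image
side, positioned uniformly at random each iteration. Both images of a pair
share each iteration's window position; pixels outside the window are not
updated and not counted. After the last volley, boundary rows and columns
whose mean update count falls below the 0.1 quantile of the per-row/column
distribution are peeled off, and the achieved correlations are reported on
the cropped images. The crop is derived from the *pooled* update counts of
A and B so the pairmates are always cropped identically — correlations are
only defined between equal-length feature vectors. A crop that would
remove more than half the pixels is refused with diagnostics. With one
volley, a full-width window, and a zero crop quantile the loop reduces
bit-for-bit to initialization followed by tuning, which the tests assert.

Whether initialization should re-run in every volley or only in the first
is ambiguous; we run both phases every volley, which keeps each volley
self-contained after magnification.

### The toy extractor

The bundled extractor is a stack of fixed random-weight 3 x 3
convolutions (weights N(0, 1/sqrt(9 C_in)), seeded) with a softplus
nonlinearity and 2x average pooling between layers; every layer is tapped,
shallow taps are constrained and the deepest tap(s) are targets. Softplus
keeps the forward map smooth, so analytic gradients agree with central
finite differences to better than 1e-4 relative error — an oracle the test
suite runs on 6 x 6 images.

One property of random-weight networks matters enormously here: every
image evokes nearly the same deep activation *profile* (dominated by
biases and filter norms), so raw inter-image feature correlations are
close to 1 regardless of content. The extractor therefore reports
activations relative to its response to a uniform mid-gray image. This
per-unit baseline centering leaves gradients untouched (the baseline is
constant) but makes inter-image correlations measure input-driven
structure, which is what the synthesis schedule manipulates. Trained
networks need no such centering, but any extractor satisfying the
forward/gradient contract — including one wrapping a pretrained model —
can be substituted.

## 2. Experiment design generation

Templating runs concatenate seeded random permutations of the 16 images,
rejection-sampled so no image repeats back-to-back, including across block
boundaries (80 trials, five per image). Statistical-learning runs permute
the 8 pairs per block under the same no-repeat rule and always present A
immediately followed by its B. Rejection sampling is provably uniform over
the valid orders, which the tests verify against exhaustive enumeration at
tiny sizes.

Timing allocates inter-stimulus intervals of 1, 3 and 5 s at a 40:40:20
ratio by largest-remainder counts (then shuffled) rather than i.i.d.
draws: an exact allocation is the only way to *guarantee* that an 80-trial
run fits the fixed 203-volume, TR 1.5 s scan (304.5 s), and the realized
ISI histogram is exactly the intended one. Catch trials are an exact
round(10%) subset drawn uniformly without replacement, for the same
reason: a fixed, testable count. Events round-trip through BIDS-style TSV
files.

## 3. The synthetic-data generator

The generator plants ground truth at three levels.

**Patterns.** Voxel patterns are unit-variance Gaussians. For the pair at
level i, pattern B is the mixture alpha A + sqrt(1 − alpha^2) eps, and
per-run measurement noise of sd sigma (default 0.5) is added to both.
Under this model the measured pairmate correlation is alpha / (1 +
sigma^2) exactly, so alpha is set to target x (1 + sigma^2): the *planted*
correlation is the one an experimenter would measure, and the generator
refuses targets that would need |alpha| >= 1. Pre- and post-learning
patterns share the same A pattern and the same independent component of B
(a stable item code); only the mixing weight changes between runs, by the
planted change curve. Baseline pairmate correlations default to a linear
0 to 0.3 ramp across levels — a reduced-magnitude stand-in for the
correspondence between model similarity and visual-cortex pattern
similarity; per-level hippocampal baselines are not known quantities, so
these defaults are placeholders for calibration work, clearly not
estimates of any real region.

The default planted change curve, c(0, 0.01, 0, −0.03, −0.09, −0.09,
−0.01, 0.06), encodes the NMPH signature at desk-scale magnitude: nothing
at low similarity, a differentiation trough at levels 5-6 of about −0.09,
and integration at level 8. `planted_cubic()` generates exact cubic curves
on the same standardized-level convention the fitting code uses.

**BOLD.** Time series are the GLM forward model run forwards: onset delta
functions convolved with a double-gamma HRF (gamma shapes 6 and 16, rate
1, undershoot ratio 6; analytic peak latency 5 s), sampled at the TR,
multiplied by the pattern matrix, plus i.i.d. Gaussian noise. At zero
noise the package's GLM recovers the planted patterns to 1e-6 — forward
model and inverse are tested as an exact identity. The generator makes no
attempt at realistic fMRI noise: no autocorrelation, drift, motion, or
hemodynamic nonlinearity. Passing tests therefore show the *estimator* is
correct, not that it is robust to every artifact of real scanner data.

**Behavior.** Arrangement trials place all 16 images in a circular arena
(radius 350 px): each pair's distance is drawn with mean intercept +
slope x level (defaults 360 − 40 x level px) plus participant- and
trial-level Gaussian noise, then realized as coordinates about a random
midpoint and orientation, resampled until both images fall inside the
arena. Real arrangement data couples all items' positions on screen;
simulated pairs are placed independently, which preserves exactly the
quantity the analysis consumes (pairmate distances) and nothing else.

## 4. The analysis pipeline

Per-image patterns come from a voxelwise OLS GLM with one
HRF-convolved regressor per image plus an intercept (no high-pass
filtering or autocorrelation correction — preprocessing is out of scope;
catch trials share their image's regressor). Pairmate similarity is the
Pearson correlation of the two pattern vectors per pair; model-brain
correspondence is the Fisher-transformed correlation between similarity
level and that profile, with |r| clamped at 1 − 1e-7 so a perfect profile
stays finite. Representational change is post minus pre, positive meaning
integration.

Inference is non-parametric throughout:

- `bootstrap_ci()` resamples participants with replacement (percentile
  95% CI; resamples on which the statistic fails are excluded and
  counted).
- `shuffle_null()` re-pairs A and B images uniformly at random; the true
  pairing is deliberately *not* excluded, which makes the null
  conservative. p-values use the add-one rule (k + 1)/(n + 1), so a
  finite-permutation p is never exactly zero. The one-tailed direction
  follows the sign of the hypothesis (positive correspondence, positive
  cubic fit).
- `searchlight_map()` applies any pattern statistic over radius-2,
  125-voxel cube neighborhoods intersected with the mask (centres with
  fewer than 2 in-mask voxels are skipped and logged; radius 0 degrades
  to a per-voxel map). Cluster-level family-wise correction is out of
  scope.

## 5. The constrained cubic model

`fit_constrained_cubic()` fits Δr = a x^3 + b x^2 + c x + d by least
squares on centred, unit-SD levels, subject to a >= a_min (default 1e-6).
The positivity of the leading coefficient is the *entire* theoretical
constraint — a dip followed by a positive inflection — and no additional
constraint forces the critical points inside the observed range. The
solver is exact: if the unconstrained solution satisfies the bound it is
returned unchanged; otherwise the single active constraint pins a = a_min
and the remaining coefficients are re-estimated by least squares, which is
the KKT solution of this one-inequality problem. The tests confirm
equality with an independent box-constrained quasi-Newton solver, and that
the constrained SSE never beats the unconstrained one. Standardizing x is
purely for conditioning; coefficients are reported on both scales, and the
fit is invariant to affine relabelling of the levels.

Cross-validation leaves one participant out, fits the model to the
*level-wise mean* of the remaining curves, and correlates the prediction
with the held-out curve; per-fold correlations are averaged raw (not
Fisher-transformed). Fitting the training mean rather than the pooled
points was an open choice; the two coincide for balanced designs up to
weighting, and the averaged-curve form matches how the statistic is
described. Zero-variance held-out curves are skipped and logged.
`dip_contrasts()` reports the change at levels 5 and 6 and the flanking
peaks at levels 4 and 8 relative to the trough (the mean of levels 5-6);
their inference is delegated to the bootstrap and permutation machinery.

`a_min` has no canonical value; it is exposed as a parameter. Any a_min
small relative to the coefficient scale (here ~0.05) gives identical
results when the constraint is inactive, and when it is active the fit
degrades gracefully toward the best near-degenerate cubic.

## 6. Problem sizes and calibration checks

The test suite validates the statistical machinery at sizes chosen to
finish in minutes on one CPU while keeping Monte-Carlo error well inside
the asserted tolerances: the synthesis fidelity check runs the full 8 x 8
grid at 64 x 64 pixels with 100 + 100 iterations and a single volley;
permutation calibration uses 200 replicate null datasets of 8 participants
x 40 voxels at 500 permutations; bootstrap coverage uses 300 simulated
datasets of 25 participants at 600 resamples; end-to-end recovery uses 36
participants x 2000 voxels, with 50 replicate null simulations at 199
permutations. Production analyses should raise the resampling counts (the
`paper` profile uses 50,000).

One calibration check deserves a note: the empirical Kolmogorov-
Smirnov distance between 200 null p-values and the uniform distribution
has expectation about 0.87/sqrt(200) = 0.06 even under perfect
calibration, so a fixed threshold of 0.05 at that sample size would fail
most perfectly calibrated runs. The suite therefore applies the standard
5% KS critical value, 1.36/sqrt(200) = 0.096.

## 7. Known limitations

- The toy extractor is a fixture, not a vision model: it demonstrates the
  algorithm's contracts, fidelity and calibration, and says nothing about
  what its images look like perceptually.
- Achieved correlations at level 8 approach but do not reach 1.0 (the
  images are distinct and finite); with cropping enabled, final
  correlations are measured on the cropped images and can drift slightly
  from the tuned values — the package reports achieved values rather than
  asserting a post-crop tolerance.
- The GLM is plain OLS; autocorrelation-aware estimators would be needed
  for real scanner noise.
- Bootstrap CIs are percentile CIs; they moderately undercover at small
  participant counts, which the coverage test brackets rather than hides.
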