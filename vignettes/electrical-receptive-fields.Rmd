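---
title: "Estimating electrical receptive fields with a Generalized Quadratic Model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating electrical receptive fields with a Generalized Quadratic Model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Retinal prostheses drive retinal ganglion cells (RGCs) with current pulses
delivered through an electrode array. To design stimulation patterns one
needs a forward model: given the recent history of pulse amplitudes on every
electrode, how many spikes will a given cell fire? `erfield` implements such
a model — the *electrical receptive field* (ERF) — for the white-noise
multi-electrode stimulation paradigm: all electrodes pulse simultaneously at
a fixed rate (10–30 Hz), each pulse amplitude drawn independently from a
zero-mean Gaussian (SD 150 µA) truncated by rejection at the stimulator
limits (±300 µA); positive amplitudes denote anodic-first biphasic pulses.
The response is the spike count in the inter-pulse bin following each pulse.

## The model

Let $S_t$ be the concatenated stimulus history over the 300 ms preceding the
response bin: $L = \mathrm{round}(0.3 f)$ lag frames of $n_e$ electrode
amplitudes each, lag 0 being the most recent pulse. The Generalized
Quadratic Model (GQM) maps this history to a scalar *generator signal*

$$g(S_t) = \vec v_0 \cdot S_t + \sum_{i=1}^{N} w_i\, (\vec v_i \cdot S_t)^2,$$

where $\vec v_0$ is a linear filter, the $\vec v_i$ are quadratic component
filters, and $w_i = \pm 1$ marks each component as excitatory ($+1$, raising
the drive regardless of stimulus polarity) or suppressive ($-1$). The
expected spike count is a saturating sigmoid of the generator,

$$E(S_t) = \frac{a}{1 + e^{-b\,(g(S_t) - c)}},$$

with saturation $a$ (spikes/bin), gain $b$ and threshold $c$ (the generator
value at half saturation). Spiking is modelled as inhomogeneous Poisson, so
parameters are estimated by maximizing
$\mathcal L = \sum_t R(t)\log E(S_t) - E(S_t)$ (the count-factorial constant
is dropped).

The quadratic form $\sum_i w_i \vec v_i \vec v_i^{\mathsf T}$ is what the
data identify — individual components only up to rotations among
equal-strength same-sign components. Fitted models are therefore
*canonicalized*: the form is eigendecomposed, components are replaced by
eigenvectors scaled to $\sqrt{|\lambda_i|}$ with $w_i = \mathrm{sign}\,
\lambda_i$, excitatory first, strongest first. This leaves $g$ unchanged for
every stimulus (verified numerically in the tests) and makes component
comparisons well defined.

## Estimation pipeline

1. **STA/STC.** The spike-triggered average (count-weighted mean history)
   initializes $\vec v_0$; the eigenvectors of the spike-triggered
   covariance about the STA initialize the components (top ranks →
   excitatory, bottom ranks → suppressive). Because the stimulus is white
   with equal per-electrode variance, no whitening is applied.
2. **Eigenvalue significance.** The null distribution of the STC spectrum is
   built by circularly time-shifting the response vector (random offset of
   at least $L$ rows, preserving response autocorrelation while destroying
   stimulus alignment) and recomputing the spectrum; per-rank 2.5/97.5
   percentiles form the 95% band. Eigenvalues above the band are significant
   excitatory directions, below it suppressive ones. Rank-wise bands imply a
   multiple-comparison caveat: at $\alpha = 0.05$ roughly $\alpha d$ noise
   ranks are flagged in expectation across a $d$-dimensional spectrum, so
   counts of significant eigenvalues should be read with that in mind (a
   smaller `alpha` gives family-wise control when needed).
3. **Maximum likelihood.** Optimization works in a scaled stimulus space
   (amplitudes divided by their global SD, so filter coefficients are O(1))
   and alternates two analytic-gradient quasi-Newton blocks — the sigmoid
   $(\log a, \log b, c)$ and all filter coefficients — until the relative
   log-likelihood gain falls below $10^{-6}$ or 200 outer iterations. Both
   blocks maximize the same likelihood, so the outer iteration ascends;
   each block rejects a step that would lose likelihood. The sigmoid block
   is box-constrained: $a$ may not exceed a few times the largest observed
   count and $b$ is bounded relative to the spread of $g$. Without the
   bound, the likelihood admits degenerate optima in which a razor-thin
   sigmoid lets the filter norms blow up; these fits predict poorly and
   destroy the calibration of the significance bootstrap.
4. **Model order.** Components are added greedily from $(0,0)$, one
   excitatory or one suppressive at a time, each candidate warm-started
   from the current fit plus the next unused STC eigenvector, until the
   held-out improvement falls below tolerance (contiguous-fold validation
   set). The selection metric is the held-out Poisson log-likelihood per
   bin (tolerance 0.002). We implemented the binned-$R^2$ variant first
   (tolerance 0.01; it remains available via `metric = "r2"`) and found it
   unreliable on synthetic ground truth: binned $R^2$ saturates once the
   dominant excitatory component is present, and a spurious third
   excitatory component can raise it more than the cell's genuine
   suppressive component, while predictive likelihood ranks the true order
   far ahead. Likelihood is the natural criterion for a Poisson model;
   $R^2$ is kept for the reporting conventions. Candidate fits use a
   shortened optimizer schedule and at most 25 000 training rows — the
   search needs only the relative ranking — and the selected order is then
   refit at full settings.
5. **Electrode significance.** The fitted coefficients are compared with a
   null distribution obtained by circularly shifting the responses and
   re-estimating the filters from a warm start at the fitted parameters
   (1000 shifts by default). A coefficient is significant when it exceeds
   `threshold_sd` (default 2) null standard deviations in magnitude; a
   quantile-band variant is available (`method = "ci"`). Warm-started
   re-estimation approximates full refitting at a fraction of the cost; the
   refits run to a loosened L-BFGS convergence criterion, which matters —
   stopping them early underestimates the null spread and inflates false
   positives (the calibration checks in the test suite guard this).
   Coefficients on constant stimulus columns are unidentifiable and are
   masked insignificant.

## Validation and baselines

Data are split into five *contiguous* folds (neighbouring design rows share
overlapping stimulus histories, so random interleaving would leak training
information into validation). Held-out predictions are sorted (stable sort;
tied predictions keep temporal order) and grouped into bins of 200 stimuli,
dropping the final partial bin. Reported per fold and averaged: the
coefficient of determination $R^2$ between binned observed means and mean
predictions; a *best-case* $R^2$ ceiling obtained by simulating Poisson
counts at the predicted means and re-binning (20 simulations); the mean
absolute bin error in spikes and as a percentage of the maximum response;
and the slope of observed bin variance against mean prediction, both
normalized by the maximum prediction — near 1 for Poisson-like spiking.

Two reference models gauge what the quadratic structure buys:

* **STC₁** — project onto the first STC eigenvector and fit a double-sided
  sigmoid to the 200-binned means: independent saturating sigmoids on the
  positive and negative half-axes sharing a common floor at zero (the
  published form of this baseline does not fully specify the
  parameterization; ours is continuous at the origin and monotone in
  |projection| on each side, which is the property that matters).
* **STC₂** — project onto the two components whose eigenvalues depart most
  from the null band (first and last eigenvector when no band is attached)
  and fit a 2-D response surface by locally weighted linear regression:
  tricube weights, span 0.05 of the sample, evaluated on a 50 × 50 grid,
  bilinear interpolation for prediction, queries outside the grid clamped
  to the nearest fitted value. The local fits cap the sample at 20 000 rows
  (deterministic thinning) to bound cost.

## The synthetic ground-truth generator

No recordings accompany this package, so every stage is exercised against
synthetic cells with known structure (`make_ground_truth()`). The generator
emulates the recorded preparation:

* **Components** concentrate 2–4 strong same-polarity electrodes in a
  single lag frame — excitatory at lag 0, suppressive at earlier lags — on
  a weak Gaussian background (SD 5% of peak) that provides true negatives
  for the significance tests. Directions are orthonormalized.
* **Strengths** decay geometrically within each class (factor 0.85), with
  the leading suppressive component at full strength. Distinct strengths
  are not cosmetic: equal-strength same-sign components are only
  identified up to rotation, so recovery would be ill-posed without them.
* **Scale**: filters are expressed so that the projection of a truncated
  white-noise stimulus (SD ≈ 131.9 µA) onto a unit-strength component has
  SD 0.5 in generator units. With the default sigmoid $(a, b, c) = (3, 2,
  1)$ — a ceiling of ~3 spikes/bin — this yields roughly 0.5 spikes/bin,
  i.e. ~30 000 spikes per 60 000 pulses, the spike budget of a well-driven
  recorded cell.
* **The linear filter** is weak by default (projection SD 0.15) and mostly
  contained in the span of the quadratic components, as observed for real
  cells.
* **`mode = "direct"`** emulates synaptic blockade (CdCl₂): the cell
  collapses to at most one excitatory component with $\vec v_0$ aligned to
  it — a one-dimensional stimulus subspace, which is the structural
  signature of removing network-mediated input.

What the generator does **not** emulate: spike-history dependence
(refractoriness, bursting), non-Poisson count dispersion, electrode
crosstalk, stimulus artefacts, non-orthogonal or drifting subunits, and any
temperature or pharmacology effects beyond the structural direct-mode
collapse. Passing tests therefore demonstrate correct *recovery of the
model class from data generated by that class* under realistic geometry and
spike budgets — not robustness to every way real recordings violate the
model.

## Structured stimuli

To test generalization beyond Gaussian inputs, `render_structured_image()`
generates 500 × 500 images of 10 µm pixels (5 × 5 mm): up to four blurred
spots (diameter ≤ 1.5 mm before blurring) or lines (length ≥ 1 mm),
stationary sinusoidal gratings (orientation 0–179° in 1° steps, spatial
frequency below the 0.5 cycles/mm Nyquist limit of the 1 mm pitch), and
moving gratings drifting at 0.1–2 Hz in 0.1 Hz steps for 300 ms, one frame
per pulse. Static images are scaled so the extreme pixel is exactly
±250 µA; a moving set is scaled jointly. The pixel under each electrode
centre (nearest-pixel lookup; array centroid on the image centre, origin
top-left, +y upward) becomes that electrode's pulse amplitude. Choices the
protocol leaves open, fixed here once: Gaussian blur SD 100 µm
(configurable) for a smooth appearance at the 1 mm electrode scale; each
spot/line gets an independent random polarity; grating spatial frequency is
uniform on [0.05, 0.5) cycles/mm with uniform random phase; static images
are held for 180 ms (rounded to whole pulses).

## Post-fit characterization

* **Integration time**: per class, the largest lag (in ms) carrying any
  significant electrode — from the bootstrap mask, not raw amplitudes; a
  multiple of the inter-pulse interval by construction.
* **ERF size**: amplitude-weighted mean distance of a component's
  significant electrodes from the recording site, in mm (the geometry is a
  1 mm-pitch array, so mm is the natural unit), invariant to rescaling.
* **Polarity preference**: responses binned along the projection onto a
  uniform-polarity component; the maximum mean response on each half-axis,
  normalized by the larger of the two. The statistic is a max over noisy
  bin means in the distribution tails, so it carries binning noise of
  order several percent even for a perfectly symmetric cell; mixed-polarity
  components are flagged non-applicable.
* **Linear-filter reconstruction**: with orthonormalized components $V$,
  $\vec b = V^{\mathsf T}\vec v_0$, $\vec u_0 = V \vec b$, and the cosine
  similarity $\|\vec u_0\|/\|\vec v_0\|$ measures how much of the linear
  filter lives inside the quadratic subspace.

## Numerical choices and degenerate inputs

Ties in every binning operation are broken by a stable sort. The shuffle
null uses circular (not i.i.d.) shifts with a minimum offset of $L$ rows to
avoid residual alignment. A zero rate with a positive count yields a
log-likelihood of $-\infty$ (documented sentinel). Zero-variance observed
bins make $R^2$ undefined (`NA` with a warning), as do constant
predictions for the best-case ceiling. All-zero stimulus columns are
retained but their coefficients are masked insignificant. One master seed
fans out deterministically to every random stage (stimulus, cell, spikes,
shuffles, bootstrap), so identical configurations reproduce identical
artifacts bit for bit.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run the standard cell at the
recorded scale (60 000 pulses × 20 electrodes at 20 Hz, L = 6, ~30 000
spikes) for fitting, order selection, ceiling and structured-stimulus
checks, and smaller cells (3 000–20 000 pulses, 6–10 electrodes at 10 Hz)
for the repeated-seed calibration and baseline studies — sizes at which the
statistical properties under test are already stable.

## Known limitations

* The GQM assumes a symmetric quadratic nonlinearity per component;
  rectified or otherwise asymmetric subunits are only approximated (the
  likelihood-based order selection will sometimes spend an extra component
  on such structure).
* Spike timing within a bin is not modelled; everything is per-bin counts.
* The significance bootstrap's warm-started re-estimation is an
  approximation to full refitting; its calibration is checked empirically
  on null data rather than guaranteed analytically.
* Rank-wise eigenvalue bands do not control the family-wise error across
  ranks (see above).
* With components of (near-)equal strength and equal sign, individual
  component identities are not estimable — only their span. The canonical
  form makes this explicit rather than hiding it.
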