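---
title: "Simulating closed-loop fMRI neurofeedback with rtnfb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop fMRI neurofeedback with rtnfb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(rtnfb)
```

## The problem

Real-time fMRI neurofeedback (rtfMRI-NFB) closes a loop around a person in
a scanner: every repetition time (TR) a new brain volume arrives, a summary
of activity in target regions is computed, and a sensory display — here,
the color saturation of a virtual environment, orange for tenderness and
purple for anguish — is updated so the participant can learn to regulate
their own brain activity. Developing and validating such an engine on a
scanner is slow and expensive, and the interesting failure modes (baseline
drift, motion, autocorrelated noise, marginally separable activity
patterns) are exactly the ones that are hard to produce on demand.

`rtnfb` implements the full engine — block scheduling, training-run voxel
mapping, two feedback computations, feedback-to-saturation mapping, and an
offline quality-control stage — against a synthetic BOLD generator with
known ground truth, so that every stage can be tested quantitatively at a
desk.

## The session design

A session is four runs of 304 volumes at TR = 2 s (10 min 8 s each,
1,216 volumes in total), preceded by 5 dummy volumes per run that are
discarded. Each run holds 16 blocks: 8 neutral blocks of 30 s (no music)
and 4 + 4 emotion blocks of 46 s (one of four music excerpts per emotion).
Two arrangements are supported:

* **ROI design** — emotions alternate: `N,E1,N,E2` repeated four times.
* **SVM design** — each emotion's four blocks are grouped: `N,E1` four
  times, then `N,E2` four times.

`E1` is the session's start emotion in odd runs and the other emotion in
even runs, so block order is counterbalanced across runs 1–4. Both
arrangements place a neutral block before every emotion block, which the
feedback computations require (their baselines come from the immediately
preceding neutral block). These are the only arrangements consistent with
the printed durations, the 304-volume run length, and that baseline
requirement; where the published design figure is not fully reproducible
from text, we fixed this one realization and kept it deterministic.

Condition labels are shifted by a configurable number of volumes
(default 2, i.e. 4 s) before being used for baselines and training labels,
to compensate for hemodynamic delay; this is the conventional BOLD lag, a
free choice of this implementation.

## The feedback computations

**ROI method.** From the training run, the per-voxel statistic inside an
a-priori ROI is the mean over that emotion's four blocks of
\[(block mean − preceding-neutral mean) / preceding-neutral mean\], and the
top 10% most-positive voxels are selected (ties broken by ascending voxel
index for determinism; "most active" is one-sided because both targets are
activation hypotheses). During feedback runs the per-volume value is

$$ f_t = \frac{\overline{ROI}_{t} - m}{m}, \qquad
   m = \frac{\sum_{k=1}^{B} \mathrm{sig}(k)\,\overline{ROI}_k}
            {\sum_{k=1}^{B} \mathrm{sig}(k)}, $$

where $\overline{ROI}_k$ is the selected-voxel mean of the $k$-th volume of
the previous neutral block ($B$ volumes) and
$\mathrm{sig}(k) = 1/(1+e^{-(k-B/2)})$. The logistic weighting down-weights
early baseline volumes still contaminated by the previous block's
hemodynamic decay; its exact parameters are a design choice of this
package (the weighting is named in the literature without parameters), and
the normalized weighted mean $\sum w x / \sum w$ is the reading we adopt of
the (typographically ambiguous) published expression.

**SVM method.** Every emotion-block volume yields a feature vector of
per-voxel PSC relative to the previous neutral block (per-voxel
sigmoid-weighted means, same weights as above), restricted to a
feature-selection mask that excludes designated sensorimotor/visuospatial
voxels. A linear soft-margin SVM ($C = 1$, no scaling beyond PSC — PSC
already normalizes per-voxel amplitude) separates tenderness from anguish;
feedback is the hyperplane projection $x^\top w + b$, sign-oriented so that
engagement of the current block's emotion is positive. Training is
*cumulative*: at each run boundary the model is refitted from scratch on
all labeled volumes observed so far. Batch refitting is the specified
semantics — an incremental solver would only approximate it — so the
cumulative-equals-batch property holds by construction and is verified
end-to-end in the tests. Neutral volumes are never training examples; they
define the baselines. The fit is delegated to libsvm (via \pkg{e1071});
because libsvm orients its decision function by order of class appearance,
the hyperplane is deterministically re-oriented after fitting so that
tenderness projects positive.

**Saturation mapping.** The displayed value is
$s = \mathrm{clip}(f / f_{max},\, 0,\, 1)$, optionally quantized to $n$
equal levels. $f_{max}$ defaults to 0.02 for the ROI method (a 2% PSC
fills the scale, matching the planted-effect magnitude regime of interest)
and to twice the median absolute training projection for the SVM method,
fixed after initial training; the published system does not state its
scaling, so these defaults are ours. During neutral blocks the display
stays at the baseline hue (saturation 0) and no sample is logged; during
emotion blocks exactly one sample per TR is logged. The log schema is
identical for both methods.

## The synthetic generator

Each voxel's series is

$$ y_v(t) = \beta_0\Big(1 + \sum_c \pi_c(v)\, (x_c * h)(t)\Big)
   + d(t) + \varepsilon_v(t), $$

with baseline $\beta_0 = 1000$ (arbitrary units), per-condition boxcars
$x_c$ convolved with a canonical double-gamma HRF $h$ (peak delay 6 s,
undershoot delay 16 s, ratio 1/6 — the field-standard parameters), planted
fractional amplitudes $\pi_c(v)$, a linear-plus-sinusoidal drift $d$
(amplitude 5 units per run, sinusoid period 200 s), and Gaussian AR(1)
noise ($\phi = 0.3$; `noise_sd` is the *innovation* SD, so the stationary
SD is $\mathrm{noise\_sd}/\sqrt{1-\phi^2}$). The HRF kernel is sampled at
the TR and normalized to unit sustained response, so a planted amplitude
of 0.02 produces exactly a 2% plateau PSC. Dummy volumes carry baseline,
drift and noise but no task signal. A rigid-motion trace (6-parameter
random walk, innovation SDs 0.02 mm and 5×10⁻⁴ rad) is generated per run.

The default test conditions mirror the printed acquisition: 304 volumes +
5 dummies per run at TR 2 s, a 16×16×10 voxel grid carrying a 1,000-voxel
septo-hypothalamic box (tenderness target), a 90-voxel right-amygdala box
(anguish target) and a broad feature mask, with 2% planted PSC and noise
calibrated so the voxelwise contrast-to-noise ratio is about 1. For the
SVM method the ground truth is two disjoint voxel sets inside the feature
mask with opposite condition preferences, which makes linear separability
controllable.

What the generator does **not** emulate: anatomy, susceptibility and
slice-timing artifacts, physiological (cardiac/respiratory) noise, spatial
autocorrelation, and signal consequences of the motion trace (motion only
feeds the QC stage). Tests passing on this phantom therefore validate the
engine's arithmetic, selection, decoding and calibration behavior — not
robustness to everything real scanners produce.

## The closed-loop harness

`simulate_closed_loop()` replaces the participant with a synthetic
responder: within each feedback run, an emotion block's planted amplitude
is the base amplitude times
$1 + \mathrm{gain} \times (\text{mean saturation of the previous block of
the same emotion in that run})$. The previous *same-emotion* block is used
because in the alternating design the immediately preceding block of any
emotion block is neutral, whose saturation is 0 by contract — linking to
it would make the gain inert. Generation is block-by-block with a strictly
causal (one-sided moving-sum) HRF convolution, so amplitudes chosen at a
block's onset cannot influence earlier samples; with gain 0 the simulation
reduces *bit-exactly* to generating the session open loop and replaying
it. Noise-free and with positive gain, block-mean saturation is
nondecreasing across same-emotion blocks by induction on the update rule;
we verify this at label shift 0, where every block's samples cover the
same 23 volumes (a nonzero shift truncates the run's final block at the
run boundary, which lowers that block's mean for reasons unrelated to the
update rule).

## Offline quality control

* **Motion flagging** — a volume is flagged iff any |translation| > 3 mm
  or any |rotation| > 0.02 rad, strictly ("over" the threshold), on
  absolute parameters by default; a frame-to-frame `delta` mode is
  provided since artifact tools differ on this reading.
* **High-pass filtering** — SPM-style regression on a discrete-cosine
  basis with $K = \lfloor 2\,N\,\mathrm{TR}/\mathrm{cutoff} \rfloor$
  columns; the basis is zero-mean so the series mean is preserved. The
  cutoffs 152 s (ROI design) and 456 s (SVM design) — twice the maximum
  spacing between repetitions of the same stimulus — are configuration
  constants. Note that attenuation at the cutoff is only meaningful when
  the series spans a few cycles; a 304-volume run is shorter than two
  periods of the 456 s cutoff's neighborhood.
* **GLM validation** — voxelwise OLS with intercept, HRF-convolved
  condition regressors, the DCT basis, optional centered motion covariates
  and per-flagged-volume indicator columns; contrasts are reported as
  $t = c^\top\hat\beta / \sqrt{\hat\sigma^2 c^\top (X^\top X)^{-1} c}$.
  Recovered amplitude is reported as $\hat\beta_c / \hat\beta_0$, which on
  noise-free phantoms equals the planted PSC to machine precision. Where
  residual variance is exactly zero or pure rounding noise relative to the
  data scale, the t-statistic is defined as 0 for a (numerically) zero
  estimate and ±∞ otherwise, so noise-free fixtures behave sensibly.

The type-I-error calibration is run on *white-noise* null phantoms
(`ar1_coef = 0`): the GLM is plain OLS with no prewhitening, whose nominal
error rate presumes serially independent noise; under AR(1) noise OLS
t-statistics are anticonservative by construction, and prewhitening is
outside this package's scope. This is a known limitation, not a bug: the
calibration check validates the OLS/contrast arithmetic, and the AR(1)
setting is exercised by the recovery and ranking tests instead.

## Problem sizes used in the test suite

Unit and property tests run on an 8×8×4 grid (full 304-volume runs, small
masks), which keeps a generated session under a second while preserving
every structural property of the printed design. The acceptance-level
checks use the full 16×16×10 grid with the 1,000-voxel ROI for voxel
recovery (20 seeded phantoms) and SVM decoding (20 seeded sessions), and
200 seeded 6×6×4 white-noise phantoms for the type-I calibration; the
reproduction script (`scripts/acceptance.R`) uses 10, 5 and 100 seeds for
the same three quantities. These sizes are the package's choice of a
desk-scale experiment: large enough that the binomial noise on the
reported rates is small compared to the margins being tested.

## Known limitations

* No online realignment: incoming volumes are assumed registered to the
  mask grid (the published pipeline realigns in the vendor chain).
* One ROI per emotion; simultaneous multi-ROI feedback is not modeled.
* The SVM retrains only at run boundaries (the specified semantics), so
  run 2 always runs on the training-run model.
* Wall-clock pacing is not simulated; "real time" here means one volume
  processed per step with no lookahead.
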