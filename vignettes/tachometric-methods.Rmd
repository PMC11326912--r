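---
title: "Time-resolved analysis of urgent antisaccades: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved analysis of urgent antisaccades: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tachometric)
library(dplyr)
```

## The scientific problem

In an urgent antisaccade task a subject must look *away* from a salient
visual cue under time pressure. Two processes compete for control of the
eye movement: an involuntary, exogenous pull toward the cue, and the
voluntary, endogenous rule "look at the diametrically opposite location".
Which one wins depends on how long the cue has been visible when the
saccade is committed. That interval — from cue onset to saccade onset — is
the **raw processing time (rPT)**. Plotting the proportion of correct
responses as a function of rPT yields the **tachometric curve**: accuracy
sits at chance for very short rPTs (guesses), dips *below* chance when the
exogenous signal captures the saccade (~100 ms), and then recovers toward a
lapse-limited asymptote as endogenous control takes over.

This package implements the full analysis chain for such experiments —
behavioral (tachometric estimation, model fitting, derived metrics,
bootstrap inference), neural (spike density functions, visuomotor-neuron
selection, pooled ROC neurometrics over rPT), and the superposition
conflict model that links the two — together with generators for synthetic
trial tables and spike trains so that every stage can be validated against
known ground truth.

## Behavioral model

### rPT and classification

RT is measured from the go signal (fixation offset); rPT from cue onset.
The two differ by the timing variant: `rpt = rt + 100` (overlap),
`rpt = rt` (zero gap), `rpt = rt - 100` / `rt - 200` (gap variants).
Saccades are classified with a spatial criterion of full width 90° by
default: correct within ±45° of the target, capture errors within ±45° of
the cue, intermediate otherwise. Intermediate trials enter neither the
numerator nor the denominator of the proportion correct. All circular
arithmetic reduces angles to (−180°, 180°] and the classification bound is
inclusive; the proportion of correct to valid trials is insensitive to the
window width over a broad range.

### The two-sigmoid tachometric model

The curve is summarised by
$$v(x) = \max\{L(x),\, R(x),\, 0\},$$
$$L(x) = B + \frac{A_L - B}{1 + e^{(x - C_L)/D_L}}, \qquad
  R(x) = B + \frac{A_R - B}{1 + e^{-(x - C_R)/D_R}},$$
with the chance level fixed, $A_L = 0.5$. $B$ is the capture minimum,
$A_R$ the asymptote, $C_L$/$C_R$ the half-transition times (ms) and
$D_L$/$D_R$ the transition widths (ms). Three derived quantities
characterise performance: the rPT at which 75% correct is first reached on
the rising branch; the asymptote $A_R$; and the **probability of capture**
$$P(\text{capture}) = \frac{A_\text{under}}{A_\text{under} + A_\text{over}},$$
the fraction of the area between the fitted curve and the chance line that
lies *below* chance, integrated over 0–300 ms on a 1-ms trapezoidal grid.
It is 0 for a curve that never dips below chance and 1 for one that never
rises above it; the degenerate flat-at-chance curve (both areas zero) is
defined as 0.

### Fitting

The six free parameters minimise the mean absolute error (MAE) between the
binned proportions (20-ms running bins shifted every 1 ms; 40 ms for
single-subject curves) and the model, using a Nelder–Mead simplex over
box-transformed coordinates: $B \in [0, 0.5]$, $A_R \in [0.5, 1]$,
midpoints within the observed rPT range, widths in $[1, 100]$ ms. Several
deterministic starts are derived from the data (curve minimum for $B$,
half-crossing locations for $C_L$/$C_R$, widths at 10 ms), and the best
solution is polished with a tighter tolerance. Bins holding fewer than 10
valid trials (configurable) are excluded from the objective.

One numerical choice deserves emphasis. A running-bin proportion estimates
the *average* of the true curve over the bin, not its value at the bin
center; fitting center values to 20-ms bins therefore leaves a small but
systematic smoothing bias (about +1 ms in the recovered rPT-at-75%, with
matching distortions of the slopes). The MAE objective here evaluates the
model's *bin average* (2-point Gauss–Legendre quadrature per bin), which
removes this bias exactly for curves up to cubic within a bin. The fitted
object still is the continuous $v(x)$; only the objective accounts for the
binning. Parameter-recovery simulations in the test suite confirm that the
derived metrics are then recovered essentially without bias.

### Inference

Confidence intervals for the three derived metrics come from trial-wise
resampling with replacement: each of 500 replicates is re-binned and
re-fitted (warm-started from the full-sample solution), and the 95% and
68% intervals are the (2.5, 97.5) and (16, 84) percentiles of the
replicate distributions. The 68% percentile convention is a package
choice; only the 95% convention is standard. Replicate fit failures are
dropped and counted. Per-bin intervals on the raw curve are Wilson score
intervals ("binomial statistics" admits several intervals; Wilson behaves
well at extreme proportions).

## Neural analysis

### Spike density functions

Firing-rate traces are obtained by convolving spike trains, aligned to cue
or saccade onset, with a Gaussian kernel of σ = 21 ms, truncated at ±4σ.
The kernel is *not* renormalized after truncation: each spike then carries
mass $1 - 6.3\times10^{-5}$ (well under the 1e-4 documentation threshold)
and the single-spike peak is exactly $1/(\sigma\sqrt{2\pi})$. Population
traces average the per-neuron trial averages, with across-neuron SEM
bands; no padding or reflection is applied at trace edges.

### Visuomotor neuron selection

A neuron enters the analysis population only if it is **visuomotor (VM)**:

* *visual* — mean rate during the 500-ms cue presentation of the
  memory-guided (ODR) task exceeds the preceding 1000-ms fixation rate at
  one or more of the eight cue locations (paired t-test, p < 0.05); the
  response field (RF) is the significant location with the largest
  elevation;
* *presaccadic* — rate in the 250-ms window after the go signal exceeds
  the fixation rate at one or more locations;
* *consistent* — in the antisaccade task, the 250-ms post-cue rate with
  the cue in the RF exceeds the fixation rate (a check that the same unit
  stayed isolated across tasks).

The t-tests are one-sided (greater): elevation is what the criteria
describe, and a one-sided test keeps the per-test null false-positive rate
exactly at α, which is what the calibration tests verify on simulated
Poisson neurons. Locations with fewer than two trials are skipped.
Windows are half-open, `[start, end)`; a spike exactly at the window end
belongs to the next window.

### The pooled ROC neurometric

On correct antisaccade trials, presaccadic spike counts (−50 to 0 ms from
saccade onset) are compared between trials with the **cue in the RF**
(saccade away) and trials with the **saccade into the RF** (cue away). The
spatial signal $S_{ROC}$ is the area under the ROC curve between the two
count distributions — equivalently the probability that a random cue-in
count exceeds a random saccade-in count, ties credited ½ (Mann–Whitney
convention). $S_{ROC} > 0.5$ means cue-dominant presaccadic activity.

Counts are pooled across neurons after centering each neuron's counts by
its constant $\theta = (\mu_{cue} + \mu_{sac})/2$, the midpoint of its two
condition means — like subtracting the neuron's overall mean but immune to
unequal trial counts between conditions. Centered counts are real numbers
and are pooled as such. Neurons observed in only one condition have no
$\theta$ and are excluded (reported in diagnostics). The neurometric curve
computes $S_{ROC}$ in 80-ms rPT bins shifted every 1 ms over 70–300 ms;
bins under 20 pooled trials (configurable) are flagged. Summary contrasts
use a short range, 70 ≤ rPT < 170 ms (capture-prone), and a long range,
170 ≤ rPT ≤ 300 ms (mostly correct); note the half-open/closed convention
at 170. Uncertainty comes from resampling the two pooled distributions
with replacement (1000 iterations; 68% and 95% percentile bands).
Significance tests for paired data use sign-flip permutation tests and for
unpaired data label-shuffle randomization tests, enumerated exhaustively
when at most 20,000 rearrangements exist (exact p, observed arrangement
included) and otherwise Monte-Carlo with the add-one correction, so p is
always in (0, 1].

## The superposition conflict model

The model predicts presaccadic antisaccade activity from two profiles
measured in the ODR task: a cue-aligned response (the visual transient)
and a saccade-aligned response (the motor buildup). Its premise is that
during antisaccade trials the two signals superpose without interacting —
the cue-driven profile is simply shifted by the trial's rPT onto the
saccade-aligned axis — and what matters downstream is their relative
intensity just before movement. The **spatial bias** at a given rPT is the
mean difference (shifted cue profile minus saccade profile) in the 50-ms
presaccadic window; sweeping rPT traces a bias curve that is the model's
neurometric prediction: positive bias ↔ $S_{ROC} > 0.5$.

Shifted profiles are linearly interpolated onto the saccade-aligned grid;
outside the cue profile's support its baseline (first grid value) is used,
and post-saccadic dynamics are deliberately not modeled. Profiles may be
empirical (population averages) or closed-form generator shapes
(`generator_profiles()`); both go through the same operations. The bias
curve is exactly linear in each input profile, which the tests exploit.

## The synthetic-data generators

The generators exist so that every analysis stage can be exercised against
known ground truth; they emulate the statistical structure the analyses
assume, not any particular dataset.

**Behavior.** Each trial draws a timing variant uniformly (overlap,
zero-gap, 100-ms gap; a 200-ms gap variant is optional), a cue at one of
eight locations (cardinal with probability 0.75), and an RT from a
truncated normal on [50, 600] ms. Per-variant RT means of 130/200/250 ms
(SD 70 ms) were chosen so that the pooled rPT distribution covers roughly
0–400 ms, the range over which the tachometric curve unfolds; no RT
distribution family is implied by the task itself. The saccade is aimed at
the target with probability $v_\text{true}(rPT)$, at the cue otherwise
(capture), or — on lapse trials — in a uniformly random direction; aimed
saccades get von Mises angular scatter (Best–Fisher sampler; concentration
20 ≈ 13° SD by default, lower values emulate less precise, younger-stage
endpoints). This produces the characteristic trimodal direction histogram
(target, cue, diffuse). The default lapse rate is 0 because the asymptote
$A_R$ of the generative curve already encodes lapse-limited performance;
setting both would double-count lapses.

**Neurons.** Spike trains are inhomogeneous Poisson (thinning algorithm).
The rate is a baseline plus: an alpha-like cue transient — a difference of
exponentials parameterised by onset latency (50 ms), peak time (125 ms,
within the typical 100–150 ms range) and post-cue half-decay time
(400 ms), with the two time constants solved numerically from those
landmarks; a sustained delay-period elevation (ODR task only); and a
presaccadic linear ramp rising over the 200 ms before saccade onset (and
released over 100 ms after it). Landmark combinations the
difference-of-exponentials family cannot realise (half-decay too close to
the peak) are rejected with an explanatory error. In the ODR generator,
out-of-RF trials have all evoked components scaled by `out_of_rf_gain`.
The antisaccade generator is the superposition model made generative: the
cue transient is driven only when the cue falls in the RF, the ramp only
when the saccade lands in it, and trials engaging neither fire at
baseline. The conflict model's bias prediction is therefore the exact
ground truth of the generated spike counts, which enables the end-to-end
consistency test (neurometric sign vs model bias sign). The delay
component is excluded from the antisaccade generator so that this identity
is exact.

All generators are pure functions of (parameters, seed); a single integer
seed drives every stream.

### What the generators do not emulate

Real recordings have non-Poisson spike-count dispersion, rate drift,
cross-neuron and cross-trial correlations, RT distributions with heavier
right tails, express-saccade contamination, and aborted trials. Passing
the parameter-recovery and calibration tests therefore demonstrates that
the *pipeline* is correct and well calibrated under its stated
assumptions — not that those assumptions hold for any particular dataset.

## Numerical choices and degenerate inputs

* Classification bounds inclusive; ties at exactly ±window/2 are correct
  (target precedence) — the generator produces continuous angles, so ties
  have measure zero.
* A curve with no valid trials is an empty (zero-row) curve, not an error;
  fitting requires at least 6 occupied bins (6 free parameters).
* `rpt_at_criterion()` scans only the rising branch, starting at the
  fitted curve's minimum, on a 0.1-ms grid; it returns `NA` when the
  asymptote does not reach the criterion (including exact equality, which
  a finite grid never attains). The curve minimum location is read from
  the fitted curve, not the raw binned data.
* The ROC of an empty sample is `NA`; permutation tests reject empty or
  unequal-length paired samples.
* The bootstrap seed fully determines both resampling streams; bootstrap
  replicates that fail to fit are dropped and counted.
* Problem sizes in the validation suite were chosen to give the
  statistical power each check needs at desk scale: 20,000-trial
  behavioral simulations for parameter recovery and bootstrap coverage,
  1000 simulated null neurons for selection calibration, and a
  200-neuron synthetic population for the end-to-end neurometric
  comparison.

## Known limitations

* The short/long-range contrast p-value uses the bootstrap difference
  distribution rather than a permutation scheme; for pooled, centered
  counts with unequal bin occupancy this is the more direct resampling
  statement, but it is approximate.
* Only θ-centering is implemented for pooling; other normalization
  schemes (e.g. z-scoring per neuron) are reported elsewhere to behave
  similarly but are not provided.
* The conflict model is forward-only: it is never fitted to antisaccade
  spikes, and no interaction/suppression between the two signals is
  modeled (their weak interaction is the model's null premise).
* Whether 200-ms-gap trials should be pooled with 100-ms-gap trials in
  rPT-distribution figures is ambiguous in the underlying designs; both
  are possible here since the gap label is retained per trial.

## A worked demonstration

```{r, eval = FALSE}
cfg <- list(seed = 7, simulate = list(n_trials = 3000, n_neurons = 6),
            behavior = list(n_boot = 200))
res <- run_pipeline(cfg)
tidy(res$young$boot)          # metric CIs for the young-like dataset
autoplot(res$young$curve, fit = res$young$fit)
autoplot(res$young$neurometric)
autoplot(res$young$bias)
```
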