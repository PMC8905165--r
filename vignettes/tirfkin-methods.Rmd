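---
title: "Models and methods behind tirfkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tirfkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirfkin)
```

# Scope

`tirfkin` packages the quantitative core of a single-molecule TIRF motility
study of kinesin motors (the construct series shipped with the package is a
CENP-E truncation panel plus a kinesin-1 control): a generative simulator of
motors landing on immobilized microtubules, kymograph-based event
measurement, the statistical estimators used to summarise such assays, and
automated photobleaching step counting. The package's central claim is that
every estimator can be validated by *parameter recovery*: the simulator is a
first-class, tested component whose parameters are exactly the quantities
the analysis is supposed to estimate.

# The generative model

## Landing

Motor landing on each microtubule is a homogeneous Poisson process with
intensity $\lambda_i = r \cdot L_i$ events per minute, where $r$ is the
construct's landing rate in events per micrometre per minute and $L_i$ the
microtubule length. Landing times are uniform over the observation window
and landing positions uniform along the segment. Each event is independently
*processive* with probability $p$ (the construct's active fraction) and
otherwise a *static* binder that dwells at a fixed position for an
exponential time (default mean 1 s, matching short-lived electrostatic
interactions) before detaching.

## Motion and detachment

A processive motor draws one instantaneous speed $v$ from the construct's
Gaussian mixture — velocity heterogeneity is modelled at the motor level,
not the step level, because the analysis fits motor-level velocity
histograms. Motion alternates between *moving* and *paused* states as a
two-state continuous-time Markov chain with entry/exit rates
(`pause_entry_rate`, `pause_exit_rate`; default 0, i.e. pause-free, for
estimator-recovery fixtures, since the study constructs pause with unknown
kinetics).

Run length and residency time cannot both be exactly exponential once they
are coupled through a random speed. The simulator therefore supports two
detachment modes and fixtures pick the one matching the estimator under
test:

* `per_distance` — the motor detaches when its cumulative moving distance
  reaches $D \sim \mathrm{Exp}(\bar L)$; run lengths are exactly exponential
  with scale `run_length_mean`.
* `per_time` — the motor detaches at $T \sim \mathrm{Exp}(\bar\tau)$ after
  landing; residencies are exactly exponential with scale `residency_mean`.

Each of the motor's `n_fluorophores` fluorophores bleaches independently at
`bleach_rate` per second (single-exponential photophysics; no blinking or
dark states), with the bleach clock starting at landing.

## Reproducibility

One root seed governs an experiment. Every motor, and every auxiliary stage
(field placement, landing draws, rendering noise), receives a
deterministically derived child stream (`child_seed()`), so simulations are
bit-for-bit reproducible and — because a trajectory's *first* random draw is
its unit-exponential detachment quantile — two constructs simulated under
the same root seed share detachment quantiles motor-for-motor. Paired
comparisons (e.g. the fold change of run lengths between constructs) exploit
this common-random-numbers coupling.

## Imaging

Positions are recorded on the acquisition frame grid (default one frame per
0.12 s with 100 ms exposure; the interval is configurable). Rendering places
a 2-D Gaussian point-spread function (default $\sigma$ = 130 nm) at the
motor's pixel position, with integrated intensity
`photons_per_fluorophore_per_frame` $\times$ unbleached count — the discrete
kernel is normalised so photometry is exact before noise. Pixel values are
Poisson shot noise on signal plus background (default 100 counts) with
additive Gaussian read noise (s.d. 3 counts), clipped at zero and quantised
to 16 bits. Defaults describe a typical EMCCD TIRF setup: 160 nm
back-projected pixels, a ~130 nm PSF sigma for green emission at high NA.
Drift, astigmatism and 3-D PSF structure are deliberately out of scope;
simulated data are drift-free.

# Event measurement

Kymographs are built by sampling each movie frame along the microtubule axis
(bilinear interpolation, maximum over a 3-px perpendicular band). Spots are
detected per time column above a global `median + 5 MAD` threshold and
linked frame-to-frame by nearest neighbour *around a constant-velocity
prediction* within 4 px per frame, closing single-frame gaps. Prediction
(rather than plain nearest-neighbour) keeps identities through track
crossings. The original analysis measured kymographs manually; automation is
our choice so the pipeline is testable, and a truth mode
(`events_from_truth()`) measures events directly from simulator ground truth
with identical definitions so estimator tests never depend on tracking
quality.

Measurement definitions, applied identically in both modes:

* run length = net start-to-end displacement (not path length), matching a
  kymograph line measurement;
* residency = time between the first and last frame of the track;
* velocity = run length / residency, an average over the whole run
  *including pauses*;
* events spanning fewer than 5 frames are excluded from analysis;
* an event is *motile* if its net displacement is at least 320 nm (2 px,
  below which a manual kymograph call could not distinguish it from a
  static binder; configurable) and at least 80% of its frame-to-frame
  displacements share the net direction or are zero.

Tracks still present at the movie end are flagged right-censored but kept.
All track terminations are treated as detachment; detachment cannot be
distinguished from photobleach loss of the last fluorophore, which slightly
deflates residency scales when bleaching is fast relative to detachment
(negligible at the default rates).

Two discretisation facts matter for recovery tests. First, with a landing
phase uniform within one frame interval, the expected first-to-last-frame
span equals the true attachment duration exactly, so frame-grid measurement
is unbiased. Second, the 5-frame filter left-truncates the measured
exponential distributions; by memorylessness this rescales the survival
curve without changing its decay, which is exactly why the exponential fit
keeps a free amplitude (below).

A consequence worth knowing: because static binders dwell ~1 s while
processive events last seconds, the 5-frame filter removes static events
preferentially and thereby *enriches* the motile fraction relative to the
generative processive probability. This is a property of the measurement
itself (shared by the real assay), not an estimator defect; motile-fraction
recovery tests therefore use fixtures whose dwells are long enough for every
binding event to be seen.

# Statistical layer

**Velocity histograms** are fitted by least squares with one or two
Gaussians on 20 nm/s bins. Component means are reported with standard errors
from the fit covariance; $r^2$ is computed on the bin counts. The
two-component fit is initialised from a 2-means split of the raw values and
all parameters are box-constrained to the histogram support (free, not
shared, variances — the choice is conventional and the published fit does
not state its constraint). For unimodal symmetric samples the fitted mean
agrees with the sample mean to within half a bin.

**Run lengths and residencies** are summarised by the decay constant $\tau$
of $A e^{-x/\tau}$ fitted by least squares to the empirical survival curve
$1 - \mathrm{ecdf}$, evaluated at the sorted unique values. The amplitude is
free because the minimum-detectable-event filter depresses early survival;
for exponential data a free amplitude absorbs left truncation exactly. No
truncation correction is applied to $\tau$ itself (none was applied in the
source analysis); the recovery tests quantify the residual bias instead
(median relative error under 2% at n = 289, under 3% at n = 61, over 200
seeds).

**Confidence intervals** are percentile bootstrap (1000 resamples, seeded;
the published analysis reports CI95 without stating a method). Coverage of
the interval for the exponential scale, measured over 500 simulations at
n = 289, is ~95%.

**Landing rates** are per-microtubule counts normalised by length and time,
summarised as mean ± s.e.m. over microtubules; the processive rate counts
only motile events (a thinned Poisson process, so the processive/total ratio
converges to the processive fraction). Construct comparisons use Welch's
unequal-variance *t*-test with Welch–Satterthwaite degrees of freedom; no
multiple-testing correction is applied because only single pairwise
comparisons are made.

**Motile fractions** carry Wilson 95% score intervals.

# Photobleaching

The intensity pipeline reimplements a standard ROI macro: the signal is the
mean of a 4×4-pixel block anchored at the picked point (the point is the
upper-left-of-centre pixel, rows/columns $p-1..p+2$ — the original macro's
convention is unrecoverable, so ours is documented precisely), the local
background is the surrounding 10×10 block minus the 4×4 core (84 pixels),
and the corrected trace is their difference, which is invariant to any
constant added to the whole movie. Initial intensity is the mean of the
first five corrected frames. Aggregates are excluded above
`median + 5 MAD` of the population's initial intensities (the original
threshold is unstated; a robust rule stands in).

Step counting replaces manual reading of plotted traces with greedy binary
change-point segmentation minimising within-segment squared error under a
Schwarz penalty ($2\log n$ per change point, at most 8), counting downward
level transitions of at least `min_step` — by default half the robust unit
step (median detected drop), which is scale-free across laser settings. The
automation is itself validated against an exhaustive dynamic-programming
segmentation oracle: identical on all noiseless ≤ 32-frame traces and on
≥ 95% of noisy ones, and exact on noiseless staircases of 1–8 steps.

# Packaged construct configurations

Five YAML configs ship with the package (`construct_config()`):

| config | velocity (nm/s) | run length (nm) | residency (s) | fluorophores |
|---|---|---|---|---|
| cenpe483 | 144.2 ± 143.2 | 407.3 | 5.41 | 4 |
| cenpe483lz | 179.9 ± 100.2 | 685.2 | 6.36 | 4 |
| cenpe754 | 180.0 ± 40.8 | 703.3 | 5.3 | 4 |
| cenpefl | 0.75·N(46.4, 12.7) + 0.25·N(158.0, 42.1) | 1258.9 | 37.1 | 2 |
| k560 | 550 ± 100 (nominal) | 1100 (nominal) | 2.0 (nominal) | 4 |

Generative velocity s.d.s are the published s.e.m. scaled by $\sqrt{n}$ of
the published sample (per component, by $\sqrt{w_i n}$, for the mixture);
the full-length slow/fast weights are 0.75/0.25 (the slow population is
described only as the majority, so the split is a package choice). Landing
rates are 0.392 (754) and 0.147 with processive fraction 0.061 (full
length); constructs without a published landing rate carry nominal values.
The kinesin-1 control's kinetics are nominal — only its photophysics (same
tag count as the 754 construct) matter, for the initial-intensity
comparison. The broad 483 velocity s.d. implies a heavy negative tail in
the raw mixture; histogram fixtures use the raw draws (the fit target is
the mixture itself), while trajectory simulation truncates its speed draw
at > 0, where the truncation is a negligible perturbation for every
construct except 483, whose trajectory speeds are accordingly biased
slightly high — run-length and residency fixtures are unaffected because
they are measured in the detachment domain.

# Problem sizes and numerical choices

Recovery tests run at the published sample sizes (n = 61, 289, 346, 774;
100/98 microtubules for landing rates; 200 seeds for median-bias checks;
500 simulations for bootstrap coverage) — sizes chosen to mirror the study
while keeping the whole suite a few minutes on one CPU. Nonlinear fits use
Levenberg–Marquardt (`minpack.lm`) with data-driven starts (sample moments;
2-means split for mixtures) and box constraints; survival fits start at
$A = 1$, $\tau$ = sample mean. Degenerate inputs (single occupied bin,
non-positive values, < 20 observations, zero-length microtubules,
both-constant Welch samples) raise structured errors rather than returning
numbers.

# Known limitations

* The simulator emulates the statistical structure the estimators assume
  (Poisson landings, exponential detachment and bleaching, Gaussian
  mixtures, Gaussian PSF with shot/read noise). Passing recovery tests
  demonstrates estimator correctness under that structure — not robustness
  to aggregates on the lattice, uneven illumination, drift, or non-Markov
  pausing, none of which are modelled.
* Gliding assays are simulated as rigid 1-D translocation of a bar; no
  pivoting or flexural dynamics.
* Automated tracking degrades when multiple motors occupy the same
  microtubule position simultaneously (tracks merge); at the study's
  landing rates such collisions are rare, and truth-mode measurement is the
  reference path for estimator validation.
* At n = 61 the minority velocity component's fitted mean has a sampling
  s.d. comparable to 10% of its value; single-seed estimates of it, and of
  ratios of decay constants between constructs, scatter accordingly. The
  suite therefore distinguishes per-seed checks from median-over-seeds
  checks.
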