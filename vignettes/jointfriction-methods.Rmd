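---
title: "Measuring whole-joint friction from pendulum decay: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring whole-joint friction from pendulum decay: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointfriction)
```

This vignette records the scientific and numerical decisions behind the
package: the generative model under which the estimator is exact, the
defaults and why they were chosen, what the synthetic study does and does
not emulate, and the known limitations.

## The measurement model

A limb mounted in the passive pendulum is a compound pendulum whose fulcrum
is the knee. With a Coulomb (dry) frictional torque of magnitude
$\mu W r$ at the fulcrum and an optional viscous term, the equation of
motion integrated by `simulate_free_oscillation()` is

$$ I\,\ddot\theta \;=\; -\,m g L \sin\theta \;-\; \operatorname{sgn}(\dot\theta)\,\mu W r \;-\; c\,\dot\theta , $$

where $\theta$ is the deviation from the vertical equilibrium, $I$ the
moment of inertia about the pivot, $mgL$ the restoring-torque coefficient,
$W$ the normal load across the joint and $r$ the effective frictional
moment arm. This is the standard stick–slip oscillator; we adopt it because
it is the generative model under which a *linear* amplitude decay — the
Stanton model used to read friction off the envelope — is exact in the
small-angle limit. Energy balance over a half cycle between successive
extrema $\theta_1, \theta_2$ gives

$$ mgL\left[\cos\theta_2 - \cos\theta_1\right] = \mu W r\,(\theta_1+\theta_2)
\quad\Rightarrow\quad \theta_1 - \theta_2 \approx \frac{2\mu W r}{mgL}, $$

so `estimate_cof()` inverts the fitted per-half-cycle decrement as
$\hat\mu = \text{slope}\cdot mgL/(2Wr)$. The factor of 2 (rather than 4) is
pinned by defining the fit over half cycles, i.e. over successive extrema.
The exact relation shows the leading bias: at a 12° release the
$\cos$-expansion correction is of order $\theta^2/12 \approx 0.4\%$, which
is why noise-free round trips close to within about 0.3% — comfortably
inside the 2% self-consistency band the test suite enforces — and why the
model validity region is capped at $|\theta_0| \le 30^\circ$.

Anatomical knee flexion at equilibrium (about 70° in ambulating rodents) is
carried as metadata only: only deviations from equilibrium enter the decay
model.

### Stick termination and event-based integration

The sign discontinuity $\operatorname{sgn}(\dot\theta)$ is not smoothed.
Doing so (e.g. a $\tanh$ regularisation) would bend the decay away from
exactly linear, i.e. bias the very quantity being estimated. Instead the
trajectory is integrated piecewise between velocity zero crossings with
`deSolve::lsodar` root finding (`rtol = 1e-10`, `atol = 1e-12`); within a
half cycle the friction torque is constant and the right-hand side smooth.
At each turning point the static condition
$|mgL\sin\theta| \le \mu W r$ is re-evaluated; once it holds the pendulum
is held at that angle (stick) and `stopped_at` is set. Each half cycle is
started from rest with a tiny second-order Taylor step ($10^{-6}$ s) so the
root finder does not fire on the rest point itself. The integrator's exact
turning points are stored on the trajectory; the peak-detection tests use
them as an internal oracle.

## Geometry defaults

The arm mass (50 g, roughly twice the body weight of a 10-week-old mouse)
and the 60 Hz sampling rate and ~12° release are the measurement protocol's
values; the remaining geometry is not published anywhere usable, so
mouse-scale defaults were chosen once: pivot-to-centre-of-mass distance
$L = 12$ mm, slender-arm inertia $I = \tfrac{4}{3} m L^2$, joint load
$W = mg$, frictional moment arm $r = 1$ mm. Every acceptance-level check is
a round trip in which simulator and estimator share the configuration, so
the recovered $\mu$ is insensitive to these choices; they set only the
oscillation frequency (~4 Hz here) and the decay rate per half cycle
($\Delta\theta = \mu/6$ rad with the defaults). Treating $(W, r)$ as
calibration inputs rather than literature constants is deliberate: the
package guarantees simulator–estimator self-consistency, not agreement
with any particular rig's conversion constant.

## Marker rendering and angle recovery

Eight markers are rendered per frame: four rigid to the arm (pivot-relative
references rotated by the frame's angle) and four static on the base.
Marker noise is isotropic Gaussian per coordinate with configurable
standard deviation, default 0.05 mm — a typical optical motion-capture
residual at this working volume; no tracking-noise figure is published for
the original rig.

`estimate_angles()` solves two closed-form 2-D registrations per frame:
a full rigid (Kabsch) transform of the base markers onto their references,
which removes drift of the whole apparatus, followed by a rotation-only
orthogonal Procrustes fit of the drift-corrected arm markers about the
pivot, $\hat\theta = \operatorname{atan2}(\sum \mathbf{x}^{ref}\times
\mathbf{x}, \sum \mathbf{x}^{ref}\cdot\mathbf{x})$. Closed forms were
chosen over iterative registration because they are exactly testable: the
noise-free round trip must close to $10^{-9}$ rad. The first-order error
prediction for rotation about a known pivot,
$\sigma_\theta \approx \sigma / (r_m \sqrt{n})$ for $n$ markers at radius
$r_m$, is verified by Monte Carlo in the tests; note it holds cleanly only
when the arm-marker centroid sits at the pivot (otherwise the base-
translation error couples in), which the test layout respects. Tracking is
planar: the pendulum swings in a plane, and 3-D kinematics would add
nothing to the measurement model. Frames with fewer than three visible
markers on either body are interpolated linearly (isolated dropouts) and
the run aborts if more than 5% of frames are affected. Arm-marker layouts
that are collinear through the pivot are rejected as ill-conditioned.

## Peak detection and the decay fit

Extrema are located by sign changes of the discrete derivative and refined
by a quadratic through the three straddling samples; at 60 Hz and ~4 Hz
oscillation, unrefined samples alias peak heights by up to ~1%, an error
larger than the bias budget of the whole chain. Exactly equal neighbouring
samples take the earlier sample as the vertex (ties occur only in
degenerate synthetic input). Extrema with amplitude below `min_amplitude`
(default 1°) are discarded and the sequence truncated there: near stick the
creep regime sets in and the envelope is no longer linear; the stick angle
itself ($\le \arcsin(\mu W r / mgL) \approx \mu/12$ rad with the defaults)
always falls below the default threshold. At least four alternating-sign
extrema are required for a fit. Zero-variance amplitude sequences return
slope 0 with $R^2 = 1$ by convention and a `"no-decay"` flag. The viscous
extension ($c > 0$, exponential envelope) exists as a simulator option and
internal diagnostic only — log-amplitude linearity beating raw-amplitude
linearity flags model misspecification — and is never a reported output.

## The synthetic study generator

The generator's defaults *are* the study conditions: 3 genotypes × 12
animals; paired limbs (one loaded, one unloaded control); 16 experimental
measurement occasions spanning baseline, a 2-h loading block, a point after
the 12-h unloaded gap and the 24-h loading block; 2 control occasions (0
and 38 h wall clock); 3 pendulum trials per measurement. The exact
measurement times inside the loading blocks are not published ("frequently"
during the 2-h block); the default schedule places six points in the 2-h
block and eight in the 24-h block, which reproduces the printed total of 16
and the 0/16/18/38-h wall-clock anchors, and is configurable.

Genotype CoF trajectories are flat at the group baseline mean until a wear
onset, then rise linearly in *cumulative loading hours* to the group final
mean at 26 h — the simplest shape consistent with every stated anchor
(steady rise under load, no change while unloaded, no change in controls).
Onsets are 0 h (null), 5 h (heterozygous; flat through 4 h, mild rise by
6 h — the midpoint of that bracket, configurable) and 7 h (wild-type; flat
through at least 6 h). Intermediate figure-read values are deliberately not
targeted. Noise is multiplicative at two levels, consistent with the
log-scale analysis: a log-normal animal effect shared by both limbs of an
animal (CV defaulting to the group baseline CV: 0.27, 0.15, 0.12) and
log-normal trial noise (default SD 10% of baseline, a typical replicate
repeatability for pendulum trials). Both multipliers have mean one, so
group means are preserved by construction and the calibration checks
(baseline within 5%, final within 10% over 200 replicate studies) follow.
A consequence of the single shared animal effect is that the generated
final-time dispersion is *not* separately matched to the printed final SDs
(which are larger, especially for wild-type); modelling per-animal wear
heterogeneity was judged out of scope for the questions the package tests.

At `fidelity = "physics"` every trial value is produced by the full
simulate → render → track → estimate chain with the Coulomb coefficient set
to the animal-level truth and the release angle drawn uniformly from
10–14°, the stated spread of the manual release. This is ~0.2 s per trial,
so physics fidelity is intended for reduced designs; the default design at
summary fidelity generates in well under a second.

Histology scores are generated per joint, per tibial plateau and per
category (structure 0–4, surface morphology 0–3, Safranin O loss 0–4) as a
latent Gaussian at the genotype × treatment cell mean/SD, clamped to the
category range and rounded to the nearest 0.5 — the consensus scale on
which multi-observer scores are reported. The five observers and their
group adjustment are collapsed into this single consensus draw; with cell
means well inside their ranges the clamp-and-round shifts are small
relative to the 3 SD/√n calibration band the tests check. What the
generator does *not* emulate: mechanistic wear or lubricin depletion,
recovery during unloading, inter-rater disagreement, or any coupling
between a joint's realised friction and its histology beyond genotype —
so a passing correlation null says the *analysis* is calibrated, not that
real joints cannot couple the two.

## The statistical stage

The response is the natural log of the 3-trial mean CoF per measurement.
One Gaussian mixed model covers both described analyses (a normal model on
log values per time point, and a log-normal model across all time points —
most parsimoniously one likelihood): fixed effects genotype + limb + time
(categorical) with all two-way interactions, random intercept per animal,
REML via `lmerTest`. Time is categorical because the trajectory shape is
not the inferential target; the exact fixed-effect structure is not
published and is recorded here as the package's choice. Control limbs are
observed at only two of the time levels, so inestimable limb × time columns
are silently dropped from the fixed-effect basis; contrasts are built on
the reduced basis and verified not to touch dropped columns. Genotype
contrasts at baseline (averaged over limbs) and at the final time point
(loaded limb) use Satterthwaite degrees of freedom, which the test suite
shows keeps the baseline-contrast type-I error inside [0.03, 0.07] at
$\alpha = 0.05$ over 500 null replicate studies. Contrasts are reported
unadjusted at the a priori $\alpha = 0.05$. A zero animal-variance fit is
allowed to proceed with a `singular` flag rather than fail: the degenerate
zero-noise dataset is a supported test input.

Histology is analysed by per-category and total two-way ANOVA
(genotype × treatment) after plateau aggregation; `aov` on the balanced
design gives the classical decomposition, and sums of squares are checked
to add to the total. The CoF–histology association uses Spearman rank
correlation because the scores are ordinal; the method is not named in the
protocol this mirrors, and rank correlation is the conservative default.
Constant scores make the correlation undefined and are flagged, not tested.

## Problem sizes and numerical tolerances

The test suite uses: round-trip grids of 5 friction values; 200-replicate
Monte Carlo for tracking noise, histology calibration and study
calibration; 500 replicates for the estimator-bias and type-I checks; and
100 replicates for power and correlation nulls. These sizes put binomial
and Monte Carlo standard errors a factor of ~3 below the margins being
asserted while keeping the full suite around four minutes. Integrator
tolerances are `rtol = 1e-10` / `atol = 1e-12`; energy monotonicity is
asserted to `1e-8` of the initial energy; noise-free registration and
round trips to `1e-9` rad; file round trips to `1e-12` relative (reals are
written with 17 significant digits).

## Known limitations

* The conversion constant $mgL/(2Wr)$ is self-consistent by construction,
  not calibrated to any physical rig; absolute CoF values from real marker
  files would require measured geometry.
* Planar tracking, labelled markers, no camera model: marker
  identification, calibration and lens distortion are out of scope.
* The wear trajectory is phenomenological (onset + ramp); it encodes the
  printed anchors, not tissue mechanics.
* Histology is a consensus-scale draw; ordinal mixed models and
  inter-rater statistics are out of scope.
* The active (loading) pendulum is represented only through its effect on
  the CoF trajectory; its motor and linkage mechanics are not modelled.
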