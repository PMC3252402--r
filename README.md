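# jointfriction

Whole-joint friction testing of small-animal knees with a passive pendulum,
as a fully synthetic, testable measurement chain in R.

In ex vivo studies of joint lubrication — for example of lubricin (PRG4)
gene dosage, where mice carry 2, 1 or 0 functional alleles of the boundary
lubricant — the coefficient of friction (CoF) of an intact knee is measured
by letting the limb swing as a pendulum about the joint and watching the
oscillation die out. Dry (Coulomb) friction at the fulcrum removes a fixed
amount of energy per swing, so the amplitude envelope decays *linearly*;
the decay slope is proportional to the friction coefficient (the Stanton
linear decay model). This package implements every step of that chain,
plus a calibrated generator for the surrounding longitudinal study and its
statistical analysis, so the whole procedure can be validated end to end
without any laboratory data.

## The model

The passive pendulum obeys the compound-pendulum equation with Coulomb and
(optionally) viscous damping at the fulcrum:

```
I θ̈ = − m g L sin θ − sgn(θ̇) μ W r − c θ̇
```

with `I` the moment of inertia about the pivot, `m g L` the restoring
torque coefficient, `W` the joint load, `r` the effective frictional moment
arm, and `μ` the coefficient of friction. Motion stops (stick) the first
time the pendulum comes to rest with `|m g L sin θ| ≤ μ W r`. At small
angles, energy balance over one half cycle gives a constant amplitude
decrement

```
Δθ = 2 μ W r / (m g L)   per half cycle,
```

so an ordinary least-squares fit of extremum amplitude against half-cycle
index (the Stanton fit) recovers `μ = slope · m g L / (2 W r)`.

The chain mirrors the physical measurement: the simulated swing is rendered
as eight reflective markers (four on the arm, four on the base), the angle
is recovered per frame by rigid registration (base-marker Kabsch drift
correction, then an orthogonal Procrustes rotation of the arm markers about
the pivot), extrema are detected with sub-sample quadratic refinement, and
the decay fit converts to `μ`.

The study generator reproduces the design of a paired-limb loading
experiment: 3 genotypes × 12 animals, one knee cyclically loaded for 26 h
(with a 12-h unloaded gap) and measured at 16 time points, the contralateral
knee unloaded and measured twice, three pendulum trials per measurement,
genotype-specific CoF trajectories (flat until a wear onset, then a linear
ramp), multiplicative animal- and trial-level noise, and ordinal cartilage
histology scores (structure 0–4, surface 0–3, Safranin O loss 0–4; total
≤ 11) on a half-point consensus scale. The analysis stage fits a Gaussian
mixed model to log CoF (genotype, limb, time and two-way interactions;
random intercept per animal; Satterthwaite tests), a two-way ANOVA on the
histology scores, and a Spearman correlation of final CoF with total score.

## Worked example

Measure a lubricin-null baseline joint (`μ = 0.077`) exactly as the rig
does:

```r
library(jointfriction)

cfg  <- pendulum_config()                       # 50 g arm, 12°, 60 Hz
traj <- simulate_free_oscillation(cfg, friction_params(mu = 0.077))
traj
#> Pendulum trial: 182 samples at 60 Hz (3.02 s)
#>   start angle 12 deg, mu = 0.077, c = 0 N m s/rad
#>   stuck at t = 2.032 s (angle 0.206 deg)
#>   16 turning points detected by the integrator

frames <- render_markers(traj, noise_sd = 0.05, seed = 42)  # 0.05 mm noise
series <- estimate_angles(frames)
estimate_trial(series, cfg)
#> CoF estimate: mu = 0.07702 (slope 0.01284 rad/half-cycle, R^2 = 0.99725, 14 peaks)
```

The recovered 0.07702 agrees with the true 0.077 to 0.03% despite marker
noise; the near-unity R² is the linear-decay signature of dry friction.
Replicate trials average per protocol:

```r
average_trials(lapply(1:3, function(i)
  estimate_trial(estimate_angles(render_markers(traj, noise_sd = 0.05,
                                                seed = i)), cfg)))
#> Joint CoF: mean mu = 0.07646 over 3 trials
```

Generate and analyse a full synthetic study:

```r
ds  <- generate_study(seed = 1)
eff <- fit_cof_mixed_model(ds)
subset(eff$contrasts, at == "baseline")
#>            contrast       at estimate     se   df     t        p
#> 1 Prg4+/- - Prg4+/+ baseline   -0.256 0.0695 40.4 -3.69 6.62e-04
#> 3 Prg4-/- - Prg4+/+ baseline    0.682 0.0695 40.4  9.81 3.06e-12
#> 5 Prg4-/- - Prg4+/- baseline    0.938 0.0695 40.4 13.50 1.49e-16
```

The null-vs-wild-type baseline log-ratio of 0.682 corresponds to a CoF
ratio of `exp(0.682) ≈ 1.98`, close to the generating ratio
0.077 / 0.036 ≈ 2.1 and overwhelmingly significant, while the heterozygous
joints sit near the wild-type level — the gene-dosage pattern the generator
encodes. `run_pipeline(default_run_config(seed = 1))` runs the whole chain
(generation, model, ANOVA, correlation) and writes all tables plus a
reproducibility manifest.

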