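---
title: "Physiology-constrained distributional RL for sepsis treatment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiology-constrained distributional RL for sepsis treatment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `sepsisrl`, the choices
behind their parameters, the synthetic cohort that the package uses as its
test substrate, and the limits of what the included checks can show.

## The problem

Septic patients in the ICU are monitored hourly and treated with
intravenous fluids and vasopressors. The treatment decision depends on
quantities that are not directly observable — whether low blood pressure is
driven by vasodilation (low systemic vascular resistance, calling for
vasopressors) or hypovolemia (low stroke volume, calling for fluids).
`sepsisrl` implements a pipeline that (i) infers a latent cardiovascular
state from the observation history under a mechanistic constraint, (ii)
learns the full distribution of a survival-oriented return for each of nine
discrete treatment intensities by offline reinforcement learning, (iii)
quantifies how much of its answer is an artifact of limited data, and (iv)
arbitrates between the learned agent, a clinician behavior model and that
uncertainty when recommending an action.

## Windkessel decoder

The two-element Windkessel model treats the arterial tree as a resistor
`R` (systemic vascular resistance, mmHg·s/mL) in parallel with a capacitor
`C` (arterial compliance, mL/mmHg). With impulsive ejection of one stroke
volume `SV` at the start of each cardiac cycle of length `T = 60/F`,
pressure decays exponentially between beats and the cycle-periodic solution
gives closed forms for the observables:

- systolic: `Psys = (SV/C) / (1 - exp(-T/RC))`
- diastolic: `Pdias = (SV/C) exp(-T/RC) / (1 - exp(-T/RC))`
- mean: `Pmap = SV * R / T = SV * F * R / 60`

Pulse pressure is exactly `SV/C`, and `Pmap` equals the exact time average
of the waveform. These equations are the **fixed decoder** of the
autoencoder: they contain no trainable parameters, so everything the
encoder outputs must be expressible as a physiologically interpretable
state `(R, C, SV, F, T)`. Both `F` and `T` are carried redundantly
(`F * T = 60` is enforced at construction) because the reconstruction
target includes the heart rate directly while the pressure formulas use the
filling time.

The map from state to observables is not one-to-one: scaling `(SV, C)` by
`k` and `R` by `1/k` leaves all four outputs unchanged. The identifiable
combinations are the time constant `RC`, pulse pressure `SV/C` and the
product `SV*R` (equivalently `Pmap*T`); `wk_invert()` recovers exactly this
maximal set, and all recovery claims in the package are stated on these
combinations rather than on `R`, `C`, `SV` individually.

`wk_simulate()` integrates the impulse-driven dynamics with per-cycle
analytic decay plus an instantaneous `SV/C` jump, rather than placing the
delta impulse on a finite-difference grid — the latter contaminates the
peak value at any finite step size. The test suite cross-checks both the
closed forms and the simulator against Runge–Kutta integration with
`deSolve`.

## Physiology-driven denoising autoencoder

The encoder is three networks trained end to end by backpropagation
through the decoder:

1. a *patient encoder* (2-layer perceptron) mapping demographics to an
   initial latent-state estimate,
2. a single-layer GRU summarizing the vitals/scores history up to the
   current hour,
3. a *transition network* (2-layer perceptron) mapping the previous latent
   state, the current action (one-hot over the 9 treatments) and the GRU
   summary to the next latent state.

The latent state is parameterized as deviation from fixed baselines:
`param_i = softplus(offset_i + scale_i * z_i)`, with offsets chosen so that
`z = 0` reproduces textbook adult values `R0 = 1.0`, `C0 = 2.0`,
`SV0 = 70`, `F0 = 75`. Softplus guarantees the positivity the decoder
requires; the per-component scales (0.5, 0.5, 20, 0.2) put the deviations
for all four components on a comparable numeric footing. The baselines are
a package default, configurable through `fit_physio_encoder()`.

Training corrupts the standardized vitals/scores inputs by element-wise
zeroing with a probability drawn uniformly in 10–25% per batch (zeroing a
standardized value replaces it with the channel mean). Actions and
demographics are never corrupted: the point of the denoising scheme is that
the network cannot invert the decoder from the current observation alone
and must integrate history and treatments. The loss is the squared error
summed over the four reconstructed observables and averaged per
patient-hour, so reported losses are in (mmHg or bpm) squared per time
step. The corruption probability is not annealed for this autoencoder; a
fixed range was sufficient for stable training in our experiments.

Because the synthetic cohort has ground truth, recovery is checked on the
identifiable combinations: on held-out patients, the correlation between
inferred and true `SV/C` and `SV*R` must reach 0.8, and evaluation-time
corruption at 0%, 25% and 50% must produce strictly increasing
reconstruction error.

## Lab-history autoencoder

Labs arrive roughly every 12 hours and are carried forward in between, so
the raw per-hour lab vector is a step function that carries no information
about trends. A stacked denoising recurrent autoencoder (three GRU layers
with strictly decreasing widths, 64 → 32 → 10 by default, reduced in the
bundled checks) compresses the 12 channels into a 10-dimensional per-hour
representation read from the last hidden layer; a linear head reconstructs
the full 12-channel window. Training corruption ramps linearly from 0 to
50% over the epochs — the ramp form is a package decision, the endpoints
are the method's. The reconstruction target is the full uncorrupted input
window at every step; inference never corrupts.

## POMDP assembly

The state is the 41-dimensional concatenation of 3 demographics, 7 vitals,
5 scores, 12 (forward-filled) labs, the 4 inferred cardiovascular latents
`(R, C, SV, T)` and the 10 lab-representation components, z-scored with
moments estimated on the training split only (z-scoring is a package
decision; the choice is recorded with the dataset so states can be mapped
back to physical units). Actions discretize the hourly fluid total at
{0, ≤500, >500} mL and the hourly maximum norepinephrine-equivalent rate
at {0, ≤0.15, >0.15} mcg/kg/min; the scalar index is vasopressor-major
(`3*vaso + fluid`), a convention the package fixes because nothing
downstream depends on it beyond consistency. Rewards are ±15 at the
terminal transition (survival/death) and, in between,
`-0.025·1[SOFA unchanged and positive] - 0.125·(ΔSOFA)` — the SOFA
difference enters linearly, with the indicator reading reserved for the
no-change penalty, consistent with the coefficient pattern of the reward's
published antecedents. Non-terminal rewards are therefore bounded by
3.025 in magnitude, far below the terminal signal.

Preprocessing mirrors standard ICU-cohort hygiene: last-value carried
forward imputation, exclusion of patients with more than 25% missing
values or no recorded weight, and exclusion of patients discharged from
the ICU who die later in hospital (neither survivors nor ICU deaths; kept
would corrupt the terminal labels).

## Distributional Q-learning (C51)

The return distribution for each state-action pair is categorical over 51
equally spaced atoms. The support is `[-16, 16]`: terminal rewards are
±15 and the discounted sum of intermediate penalties is small, so ±16
covers the attainable range with headroom; the atom spacing is 0.64. The
discount is γ = 0.99 by default. Both are package decisions exposed in
`fit_c51()`.

Each update projects the target `r + γ z` onto the atom grid (clipping to
the support, splitting mass linearly between neighboring atoms — mass is
conserved exactly and the mean is preserved up to one atom spacing when
nothing clips), with double-Q action selection: the online network chooses
the argmax action at the successor state, the target network supplies its
distribution. The target network is hard-updated periodically. Terminal
transitions use the projected point mass at the terminal reward and never
bootstrap. The loss is the cross-entropy between the online distribution
at the taken action and the projected target.

Batches of 100 are drawn by outcome-weighted sampling: weights are
calibrated in closed form so that an average batch contains one terminal
death and one terminal survival record, with transitions of non-survivors
within 24 hours of death (a package choice of horizon) upweighted at an
intermediate level. The weighting changes the sampling distribution, not
the fixed point: on a tabular toy chain the weighted and uniform runs
converge to the same values, which the suite checks against independent
dynamic-programming value iteration.

## Uncertainty and decision support

Model (epistemic) uncertainty is the Monte-Carlo estimate
`u(s,a) = mean_m KL(θ_m(s,a) ‖ θ̄(s,a))` over an ensemble of 25 members
(reduced in the bundled checks) trained on patient-level bootstrap
resamples at 30% of the training patients — "substantially smaller" than
the full set so that members actually disagree where data are thin.
Patient-level resampling keeps each trajectory intact within a member;
transition-level resampling would leak information across members. The
reference θ̄ is the ensemble mean by default, or the full-data model's
distribution; probabilities are floored at 1e-8 before the divergence. The
environment (aleatoric) component is read separately from the entropy of
the value distributions themselves.

Recommendations combine three ingredients through the preference score
`P(s,a) = β·softmax(Q̃(s,·))_a + (1-β)·G(s,a) - λ·u(s,a)` with `Q̃` the
expected values of the patient-weighted ensemble mixture, `G` the behavior
cloner's action probabilities and `u` the model uncertainty. β = 1, λ = 0
recovers the pure expected-value policy and β = 0, λ = 0 the pure cloner —
these limits pin down the placement of β against the two probability-like
terms. The softmax uses temperature 1 and `u` enters unrescaled; λ is the
user's exchange rate between nats of disagreement and probability mass,
and the affine structure means a constant shift of `u` across actions can
never change the argmax.

## Synthetic cohort

Real ICU data of this kind are credentialed-access; the package instead
ships a seeded simulator whose ground truth makes the pipeline testable
end to end. Its defaults define the study conditions used throughout the
checks: 2000 patients, 72-hour horizon, and roughly 20% ICU mortality —
calibrated once to sepsis-scale figures before any downstream component
was evaluated.

A latent severity in [0, 1] drives vasodilation (R down, 45% at maximal
severity), hypovolemia (SV down, 35%) and compensatory tachycardia (F up,
50%) around per-patient lognormal baselines with AR(1) fluctuations.
Observed pressures are the Windkessel decode of the true state plus 3 mmHg
noise (2 bpm on heart rate). Severity follows a random walk with a
per-patient constant drift (SD 0.015 around a mean recovery of
-0.008/hour, giving a progressive-illness subset), amplified by the mean
pressure deficit below 65 mmHg and damped by treatment during hypotensive
hours. Vasopressor bins add (0, 0.1, 0.3) to R within the treated hour;
fluid bins add (0, 3, 8) mL to SV. Death fires through a logistic hazard
in severity; discharge after six consecutive hours below severity 0.15.
SOFA combines five integer component walks biased by severity and
perfusion deficit with a rule-based cardiovascular component; labs are
drawn 12-hourly with severity- and renal-coupled means and forward-filled.
The behavior policy administers vasopressors with probability increasing
in SOFA and in the previous hour's hypotension, mimicking the clinician
pattern the decision module must clone.

What the simulator deliberately does not emulate: pharmacokinetics,
ventilation and respiratory coupling, measurement artifacts beyond i.i.d.
Gaussian noise and missingness-at-random, informative lab ordering, and
inter-current events (surgery, transfers). Consequently, passing checks
show that the pipeline recovers structure *of the kind the model class
assumes*; they say nothing about model misspecification on real patients,
and reconstruction-error magnitudes are not comparable to values reported
on real cohorts.

## Numerical choices and degenerate inputs

- `1 - exp(-T/RC)` is computed via `expm1` for accuracy at small `T/RC`;
  at very large `T/RC` the decoder degrades gracefully to
  `Psys = SV/C, Pdias = 0`.
- All networks are trained with Adam; gradients of every hand-written
  backward pass (dense, GRU-through-time, and the chain through softplus
  and the Windkessel Jacobian) are verified against central finite
  differences in the test suite.
- The encoder perceptrons use tanh hidden units (bounded activations keep
  backpropagation through the decoder stable); the value network and
  behavior cloner use ReLU hidden units, whose unbounded response keeps
  ensemble members disagreeing away from the data — with saturating units
  the epistemic-uncertainty signal collapses far from the training
  distribution. Autoencoder gradients are clipped to a global norm of 5.
- Greedy and preference argmaxes break ties toward the lowest action
  index, making recommendations deterministic.
- Projection handles atoms hit exactly (integer grid positions) by
  assigning full mass to the atom instead of a 0/0 split.
- Missingness injection uses exact per-patient cell counts
  (`floor(rate * cells)`), so a configured rate is an upper bound.
- Bootstrap resamples that lose a terminal class are redrawn (with a
  warning); the KL floor prevents infinities from confident members.
- `density_vs_uncertainty()` retries a singular Gaussian-mixture fit on a
  jittered copy and reports that it did so.

## Problem sizes used by the bundled checks

Unit tests run on a 150-patient, 40-hour cohort with reduced network
widths; they exercise structure, invariants and gradient correctness. The
acceptance-style end-to-end checks train the physiology autoencoder on the
full 2000-patient default cohort at GRU width 32 for 70 epochs, the lab
encoder at widths 24 → 16 → 10, the agent for 4000 steps with batches of
100, and a 5-member bootstrap ensemble; these sizes are the package's
documented reference configuration for desk-scale reproduction.

## Known limitations

- The encoder resolves only the identifiable combinations; individual
  `R`, `C`, `SV` estimates inherit one scale degree of freedom anchored
  only by the baselines.
- Offline RL on observational data identifies the value of actions only
  within the support of the behavior policy; the synthetic cohort is
  constructed to have overlap, real cohorts may not.
- Off-policy evaluation is deliberately out of scope; no claim about
  policy value on held-out data is made anywhere in the package.
- The uncertainty estimate captures disagreement across bootstrap
  replicas under one architecture and training algorithm; uncertainty due
  to the architecture choice itself is not represented.
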