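# sepsisrl

Uncertainty-aware fluid and vasopressor treatment policies for septic ICU
patients, learned offline from hourly trajectories.

Sepsis management requires deciding, every hour, whether to give
intravenous fluids, vasopressors, both, or neither. The right choice
depends on cardiovascular quantities that are not directly observable:
low blood pressure may reflect vasodilation (low systemic vascular
resistance `R`, calling for vasopressors) or hypovolemia (low stroke
volume `SV`, calling for fluids). `sepsisrl` is an R implementation of a
pipeline that addresses this for researchers in computational critical
care:

1. **Physiology-constrained latent states.** A denoising recurrent
   autoencoder infers the hidden cardiovascular state
   `(R, C, SV, F, T)`. Its decoder is *fixed*: the two-element Windkessel
   model, which with impulsive ejection `Q(t) = SV·δ(t)` and dynamics
   `dP/dt = −P/(RC) + Q(t)/C` yields

   `Psys = (SV/C)/(1 − e^(−T/RC))`,  `Pdias = (SV/C)·e^(−T/RC)/(1 − e^(−T/RC))`,  `Pmap = SV·R/T`.

   Training reconstructs `(Psys, Pdias, Pmap, F)` from histories whose
   entries are randomly zeroed (10–25%), forcing the encoder to integrate
   history and treatments instead of inverting the current observation.
   A second stacked recurrent autoencoder compresses the 12-channel lab
   history into 10 dimensions.
2. **Distributional offline RL.** A categorical (51-atom) Q-learning agent
   is trained on 41-dimensional states (demographics, vitals, scores,
   labs, and both latent representations) over a 9-action space (3 fluid
   × 3 vasopressor bins; cutoffs 500 mL/h and 0.15 mcg/kg/min
   norepinephrine-equivalent). Rewards are ±15 at the survival/death
   terminal and small SOFA-based penalties in between. Batches are drawn
   with outcome-weighted sampling calibrated so an average batch of 100
   holds one death and one survival terminal.
3. **Epistemic uncertainty.** `u(s,a) = mean_m KL(θ_m ‖ θ̄)` across a
   bootstrap ensemble trained on patient-level resamples.
4. **Decision support.** An action preference score
   `P(s,a) = β·softmax(Q̃(s,·))_a + (1−β)·G(s,a) − λ·u(s,a)` arbitrates
   between the agent, a clinician behavior cloner `G`, and the
   uncertainty; `β = 1, λ = 0` recovers the greedy agent, `β = 0, λ = 0`
   the pure cloner.

Real cohorts of this kind are credentialed-access, so the package ships a
seeded synthetic ICU simulator (`simulate_cohort()`) with ground-truth
hemodynamics, treatment responses, SOFA dynamics, labs, missingness and
absorbing death/discharge terminals; every claim the package makes is
validated end to end against that ground truth. All neural networks
(GRUs, perceptrons, the backward pass through the Windkessel decoder) are
implemented in base R inside the package, with gradients verified against
finite differences in the test suite.

## Worked example

```r
library(sepsisrl)

## 300 synthetic patients, 48-hour horizon
coh <- simulate_cohort(sim_config(n_patients = 300, horizon_h = 48), seed = 7)
coh
#> <icu_cohort> 300 patients, 8447 patient-hours
#>
#> excluded_hospital_death             nonsurvivor                survivor
#>                       4                      41                     255

pp <- preprocess_trajectories(coh)   # LVCF imputation + exclusion filters

## latent cardiovascular state via the Windkessel-constrained autoencoder
ph <- fit_physio_encoder(pp, gru_hidden = 16, mlp_hidden = 16, epochs = 30,
                         seed = 1)
lb <- fit_lab_encoder(pp, widths = c(16, 12, 10), epochs = 6, seed = 1)

## held-out recovery of the identifiable combination SV/C (pulse pressure)
pr  <- predict(ph, pp$obs[pp$obs$patient_id %in% ph$val_pid, ])
tru <- pp$truth[pp$truth$patient_id %in% ph$val_pid, ]
m <- merge(pr[c("patient_id", "hour", "SV_over_C")], tru,
           by = c("patient_id", "hour"), suffixes = c("_hat", ""))
cor(m$SV_over_C_hat, m$SV_over_C)
#> [1] 0.652

## assemble the 41-dim POMDP and train the distributional agent
ds <- assemble_transitions(pp, ph, lb, seed = 1)
agent <- fit_c51(ds, steps = 2000, hidden = c(64, 64),
                 replay_weights = calibrate_replay_weights(ds), seed = 1)
qv <- predict(agent, ds$states[ds$split == "validation", ])
round(head(qv$Q[, 1:3], 2), 2)  # returns for actions 0-2 (vaso-free bins)
#>      [,1] [,2] [,3]
#> [1,] 0.29 0.22 0.35
#> [2,] 0.24 0.18 0.29
```

The held-out correlation of 0.65 between inferred and true pulse pressure
is what this deliberately small configuration (300 patients, width-16
networks, 30 epochs) achieves; at the reference configuration — the
default 2000-patient cohort, GRU width 32, 70 epochs — the same
measurement reaches about 0.89 (`scripts/acceptance.R` recomputes it).
Expected returns differ only mildly between actions in non-critical
states, as they should: an hourly decision is cheap to revise next hour.
The separation appears where it matters — in hypotensive validation
states the best vasopressor action's value exceeds "no treatment", and
the greedy policy recommends vasopressors more often the closer a
non-survivor is to death.

A thin command-line wrapper over the same functions lives in
`inst/cli/sepsisrl.R`:

```sh
Rscript inst/cli/sepsisrl.R simulate --n 2000 --seed 7 --out cohort/
Rscript inst/cli/sepsisrl.R train-ae --cohort cohort/ --epochs 70 --seed 1
```

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "sepsisrl",
                               load_package = "installed")'
```

The suite covers the closed-form decoder against Runge–Kutta integration
of the Windkessel ODE, finite-difference checks of every hand-written
gradient, the categorical projection's conservation laws, convergence of
the C51 agent to tabular value iteration on a toy chain MDP, replay
calibration, preference-score limits, and the end-to-end latent-state
recovery and policy trends on the synthetic cohort.

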