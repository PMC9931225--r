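test_that("action discretization follows the 500 mL / 0.15 mcg cutoffs", {
  expect_equal(discretize_action(0, 0)$action, 0L)
  expect_equal(discretize_action(800, 0.2)$action, 8L)
  expect_equal(discretize_action(c(0, 200, 500, 501), c(0, 0, 0, 0))$fluid_bin,
               c(0L, 1L, 1L, 2L))
  expect_equal(discretize_action(0, c(0.001, 0.15, 0.1501))$vaso_bin,
               c(1L, 1L, 2L))
  # index convention is vasopressor-major
  d <- discretize_action(300, 0.3)
  expect_equal(d$action, 3L * d$vaso_bin + d$fluid_bin)
  expect_error(discretize_action(-1, 0), "non-negative")
  # idempotent under re-binning: bin midpoints map to themselves
  reps <- expand.grid(f = c(0, 250, 900), v = c(0, 0.05, 0.4))
  d1 <- discretize_action(reps$f, reps$v)
  expect_equal(sort(unique(d1$action)), 0:8)
  expect_true(all(action_has_vaso(d1$action) == (d1$vaso_bin > 0)))
})

test_that("SOFA reward has the published terminal and intermediate values", {
  expect_equal(sofa_reward(5, 5, "survival"), 15)
  expect_equal(sofa_reward(5, 5, "death"), -15)
  expect_equal(sofa_reward(0, 0), 0)
  expect_equal(sofa_reward(10, 10), -0.025)
  expect_equal(sofa_reward(8, 10), -0.25)
  expect_equal(sofa_reward(10, 8), 0.25)
  # bounds over the whole grid
  g <- expand.grid(a = 0:24, b = 0:24)
  r <- sofa_reward(g$a, g$b)
  expect_true(all(abs(r) <= 0.125 * 24 + 0.025))
  expect_error(sofa_reward(25, 3), "0..24")
})

test_that("preprocessing forward-fills and applies the exclusion filters", {
  coh <- small_cohort()
  pp <- preprocess_trajectories(coh)
  excl <- attr(pp, "exclusions")
  ## hospital-death patients excluded
  hosp <- coh$outcomes$patient_id[coh$outcomes$outcome == "excluded_hospital_death"]
  expect_true(!any(pp$obs$patient_id %in% hosp))
  ## >25% missingness excluded (the generator plants a high-missingness subset)
  vit <- c("hr", "sbp", "dbp", "map", "temp", "spo2", "rr")
  frac <- tapply(rowMeans(is.na(coh$obs[vit])), coh$obs$patient_id, mean)
  high <- as.numeric(names(frac))[frac > 0.25]
  expect_true(length(high) > 0)
  expect_true(!any(pp$obs$patient_id %in% high))
  expect_setequal(excl$too_missing, high)
  ## no NAs remain
  expect_false(anyNA(pp$obs[vit]))
  expect_false(anyNA(as.matrix(pp$labs[sepsisrl:::lab_channels])))
})

test_that("forward fill copies the last value across a gap", {
  coh <- simulate_cohort(sim_config(n_patients = 1, horizon_h = 8,
                                    miss_rate = 0, frac_high_miss = 0,
                                    frac_no_weight = 0, hazard_scale = 0,
                                    frac_hospital_death = 0), seed = 4)
  coh$obs$sbp[3:5] <- NA   # 3-hour gap
  pp <- preprocess_trajectories(coh)
  expect_equal(pp$obs$sbp[3:5], rep(pp$obs$sbp[2], 3))
  ## fully observed channels pass through unchanged
  expect_equal(pp$obs$map, coh$obs$map)
})

test_that("assembled states are 41-dimensional with correct transition counts", {
  ds <- small_dataset()
  expect_equal(ncol(ds$states), 41L)
  expect_equal(length(ds$feature_names), 41L)
  expect_true(all(is.finite(ds$states)))
  ## one transition per patient-hour; exactly one terminal per patient
  pp <- small_cohort_pp()
  expect_equal(nrow(ds$states), nrow(pp$obs))
  n_pat <- length(unique(ds$patient_id))
  expect_equal(sum(ds$terminal_type != "none"), n_pat)
  ## terminal records carry no successor
  expect_true(all(is.na(ds$next_state[ds$terminal_type != "none"])))
  expect_true(all(!is.na(ds$next_state[ds$terminal_type == "none"])))
  ## successor rows stay within the same patient
  nt <- which(ds$terminal_type == "none")
  expect_true(all(ds$patient_id[ds$next_state[nt]] == ds$patient_id[nt]))
  ## rewards: terminals are +/-15, intermediates bounded
  expect_true(all(ds$reward[ds$terminal_type == "death"] == -15))
  expect_true(all(ds$reward[ds$terminal_type == "survival"] == 15))
  expect_true(all(abs(ds$reward[ds$terminal_type == "none"]) <= 3.025))
  ## time to event counts down to 0 at the terminal
  expect_true(all(ds$time_to_event[ds$terminal_type != "none"] == 0))
})

test_that("state scaling uses training-split moments only", {
  ds <- small_dataset()
  tr <- ds$split == "train"
  mu_tr <- colMeans(ds$states[tr, ])
  expect_equal(unname(mu_tr), rep(0, 41), tolerance = 1e-8)
  sd_tr <- apply(ds$states[tr, ], 2, sd)
  expect_equal(unname(sd_tr), rep(1, 41), tolerance = 1e-6)
  ## validation moments are close to but not exactly standardized
  expect_false(isTRUE(all.equal(unname(colMeans(ds$states[!tr, ])),
                                rep(0, 41), tolerance = 1e-8)))
})

test_that("a two-hour trajectory yields one non-terminal and one terminal", {
  coh <- simulate_cohort(sim_config(n_patients = 3, horizon_h = 2,
                                    miss_rate = 0, frac_high_miss = 0,
                                    frac_no_weight = 0,
                                    frac_hospital_death = 0), seed = 6)
  pp <- preprocess_trajectories(coh)
  ph <- fit_physio_encoder(pp, gru_hidden = 6, mlp_hidden = 6, epochs = 1,
                           batch_patients = 4, seed = 1, val_frac = 0.34)
  lb <- fit_lab_encoder(pp, widths = c(12, 10), epochs = 1, seed = 1)
  ds <- assemble_transitions(pp, ph, lb, seed = 1)
  for (p in unique(ds$patient_id)) {
    tt <- ds$terminal_type[ds$patient_id == p]
    expect_equal(sum(tt == "none"), sum(ds$patient_id == p) - 1L)
    expect_equal(sum(tt != "none"), 1L)
  }
})
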