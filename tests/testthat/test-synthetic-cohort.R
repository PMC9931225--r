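test_that("same config and seed give an identical cohort", {
  cfg <- sim_config(n_patients = 40, horizon_h = 24)
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a, b)
  c <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(a$obs, c$obs))
})

test_that("zero effects, zero noise and no hazard give a fixed point", {
  cfg <- sim_config(n_patients = 10, horizon_h = 12,
                    delta_R_vaso = c(0, 0, 0), delta_F_vaso = c(0, 0, 0),
                    delta_SV_fluid = c(0, 0, 0),
                    sev_coef_R = 0, sev_coef_SV = 0, sev_coef_F = 0,
                    obs_sd_pressure = 0, obs_sd_hr = 0,
                    ar_sigma = 0, sev_sigma = 0,
                    sev_gain_deficit = 0, sev_recovery = 0, sev_drift_sd = 0,
                    sev_treat_benefit = 0, hazard_scale = 0,
                    miss_rate = 0, frac_high_miss = 0, frac_no_weight = 0,
                    frac_hospital_death = 0)
  coh <- simulate_cohort(cfg, seed = 3)
  for (p in unique(coh$obs$patient_id)) {
    o <- coh$obs[coh$obs$patient_id == p, ]
    expect_equal(diff(range(o$sbp)), 0, tolerance = 1e-10)
    expect_equal(diff(range(o$map)), 0, tolerance = 1e-10)
    expect_equal(diff(range(o$hr)), 0, tolerance = 1e-10)
  }
  ## observed vitals equal decode of the per-patient baseline state
  tru1 <- coh$truth[coh$truth$hour == 1, ]
  dec <- wk_decode(cardio_state(R = tru1$R, C = tru1$C, SV = tru1$SV,
                                T = tru1$T))
  o1 <- coh$obs[coh$obs$hour == 1, ]
  expect_equal(o1$sbp, dec$Psys, tolerance = 1e-10)
  expect_equal(o1$map, dec$Pmap, tolerance = 1e-10)
})

test_that("ground truth table satisfies the decoder identities", {
  coh <- small_cohort()
  tru <- ground_truth_export(coh)
  expect_equal(nrow(tru), nrow(coh$obs))
  expect_equal(tru$SV_over_C, tru$Psys - tru$Pdias, tolerance = 1e-9)
  expect_equal(tru$SV_times_R, tru$Pmap * tru$T, tolerance = 1e-9)
  expect_equal(tru$CO, tru$SV * tru$F, tolerance = 1e-9)
})

test_that("sustained high vasopressor raises mean pressure by about SV*dR*F/60", {
  base <- list(n_patients = 400, horizon_h = 8,
               sev_gain_deficit = 0, sev_treat_benefit = 0,
               sev_sigma = 0, sev_recovery = 0, sev_drift_sd = 0,
               hazard_scale = 0, obs_sd_pressure = 0, obs_sd_hr = 0,
               ar_sigma = 0, delta_F_vaso = c(0, 0, 0),
               miss_rate = 0, frac_high_miss = 0, frac_no_weight = 0,
               frac_hospital_death = 0)
  ctl <- simulate_cohort(do.call(sim_config, c(base, forced_vaso_bin = 0,
                                               forced_fluid_bin = 0)), seed = 21)
  trt <- simulate_cohort(do.call(sim_config, c(base, forced_vaso_bin = 2,
                                               forced_fluid_bin = 0)), seed = 21)
  ## same seed + same draw counts -> identical severity paths; the only
  ## difference is the within-hour treatment effect on R
  m <- merge(ctl$truth, trt$truth, by = c("patient_id", "hour"))
  rise <- mean(m$Pmap.y - m$Pmap.x)
  predicted <- mean(m$SV.x * 0.30 * m$F.x / 60)
  expect_equal(rise, predicted, tolerance = 0.05)
})

test_that("death rate is monotone in the hazard scale", {
  rates <- vapply(c(0.01, 0.07, 0.4), function(hs)
    mean(simulate_cohort(sim_config(n_patients = 300, horizon_h = 48,
                                    hazard_scale = hs, frac_hospital_death = 0),
                         seed = 5)$outcomes$outcome == "nonsurvivor"),
    numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("non-survivors are hypotensive relative to survivors near the end", {
  coh <- small_cohort()
  m <- merge(coh$truth, coh$outcomes, by = "patient_id")
  m <- m[m$terminal_hour - m$hour < 12, ]
  expect_lt(mean(m$Pmap[m$outcome == "nonsurvivor"]),
            mean(m$Pmap[m$outcome != "nonsurvivor"]))
})

test_that("injected missingness never exceeds the configured rate", {
  coh <- small_cohort()
  vit <- c("hr", "sbp", "dbp", "map", "temp", "spo2", "rr")
  frac <- tapply(rowMeans(is.na(coh$obs[vit])), coh$obs$patient_id, mean)
  cfg <- coh$config
  expect_true(all(frac <= cfg$miss_rate_high + 1e-12))
  expect_gt(mean(frac > 0), 0.5)   # most patients do have gaps
})

test_that("cohort round-trips through CSV files", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(sim_config(n_patients = 12, horizon_h = 10), seed = 2)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$obs$sbp, coh$obs$sbp, tolerance = 1e-9)
  expect_equal(back$outcomes$outcome, coh$outcomes$outcome)
  expect_equal(nrow(back$truth), nrow(coh$truth))
})
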