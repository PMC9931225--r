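#' Configuration for the synthetic ICU cohort simulator
#'
#' Returns the full set of simulator parameters with defaults chosen to
#' produce a sepsis-like cohort: roughly 20% ICU mortality over a 72-hour
#' horizon, hypotension driven by vasodilation (falling `R`) and hypovolemia
#' (falling `SV`), compensatory tachycardia, vasopressor and fluid responses
#' of realistic magnitude, 12-hourly labs and mild missingness.
#'
#' @param n_patients number of patients.
#' @param horizon_h trajectory horizon in hours (>= 2).
#' @param delta_R_vaso additive rise in `R` (mmHg·s/mL) for vasopressor bins
#'   0/1/2 within the treated hour.
#' @param delta_F_vaso additive rise in heart rate (bpm) per vasopressor bin.
#' @param delta_SV_fluid additive rise in `SV` (mL) per fluid bin.
#' @param sev_coef_R,sev_coef_SV,sev_coef_F fractional change of `R`, `SV`,
#'   `F` at maximal severity (vasodilation, hypovolemia, tachycardia).
#' @param obs_sd_pressure,obs_sd_hr observation noise SD on pressures (mmHg)
#'   and heart rate (bpm).
#' @param ar_rho,ar_sigma AR(1) autocorrelation and innovation SD of the
#'   multiplicative log-fluctuations on the true cardiovascular state.
#' @param sev_sigma innovation SD of the latent severity walk.
#' @param sev_gain_deficit severity drift per unit fractional mean-pressure
#'   deficit below 65 mmHg.
#' @param sev_recovery mean hourly severity decay (resolution under care).
#' @param sev_drift_sd SD of the per-patient constant severity drift around
#'   `-sev_recovery`; patients in the upper tail have progressive illness.
#' @param sev_treat_benefit severity reduction per treated hypotensive hour
#'   (vasopressors full weight, fluids half weight); set 0 to decouple
#'   treatment from the severity process.
#' @param hazard_scale,hazard_mid,hazard_slope death hazard per hour is
#'   `hazard_scale * plogis(hazard_slope * (sev - hazard_mid))`.
#' @param discharge_threshold,discharge_hours discharge fires after severity
#'   stays below the threshold for this many consecutive hours.
#' @param miss_rate fraction of vital-sign cells blanked per patient
#'   (exact count `floor(rate * cells)`, so the configured rate is never
#'   exceeded); `miss_rate_high` applies to a `frac_high_miss` subset used to
#'   exercise the >25%-missingness exclusion filter.
#' @param frac_no_weight fraction of patients with missing weight.
#' @param frac_hospital_death fraction of ICU survivors flagged as dying
#'   later in hospital (excluded by preprocessing).
#' @param policy_vaso,policy_fluid length-3 numeric: intercept, SOFA slope
#'   and pressure-deficit slope of the clinician (behavior) policy logits.
#' @param forced_vaso_bin,forced_fluid_bin fix all actions to one bin
#'   (`NA` = behavioral policy); used for controlled treatment-effect arms.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 2000,
                       horizon_h = 72,
                       delta_R_vaso = c(0, 0.10, 0.30),
                       delta_F_vaso = c(0, 1, 3),
                       delta_SV_fluid = c(0, 3, 8),
                       sev_coef_R = 0.45,
                       sev_coef_SV = 0.35,
                       sev_coef_F = 0.50,
                       obs_sd_pressure = 3,
                       obs_sd_hr = 2,
                       ar_rho = 0.8,
                       ar_sigma = 0.02,
                       sev_sigma = 0.04,
                       sev_gain_deficit = 0.20,
                       sev_recovery = 0.008,
                       sev_drift_sd = 0.015,
                       sev_treat_benefit = 0.012,
                       hazard_scale = 0.07,
                       hazard_mid = 0.88,
                       hazard_slope = 12,
                       discharge_threshold = 0.15,
                       discharge_hours = 6,
                       miss_rate = 0.05,
                       miss_rate_high = 0.35,
                       frac_high_miss = 0.02,
                       frac_no_weight = 0.01,
                       frac_hospital_death = 0.03,
                       policy_vaso = c(-4.0, 0.25, 0.05),
                       policy_fluid = c(-2.5, 0.15, 0.03),
                       forced_vaso_bin = NA,
                       forced_fluid_bin = NA) {
  cfg <- as.list(environment())
  stopifnot(cfg$horizon_h >= 2, cfg$n_patients >= 1,
            length(cfg$delta_R_vaso) == 3, length(cfg$delta_SV_fluid) == 3)
  rates <- c(cfg$miss_rate, cfg$miss_rate_high, cfg$frac_high_miss,
             cfg$frac_no_weight, cfg$frac_hospital_death)
  if (any(rates < 0 | rates > 1)) stop("sim_config: rates must lie in [0,1]")
  class(cfg) <- "sim_config"
  cfg
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Simulate a synthetic ICU cohort with ground-truth hemodynamics
#'
#' Generates hourly patient trajectories whose observable vitals are the
#' Windkessel decoder applied to a hidden cardiovascular state plus noise.
#' Severity is a latent walk driven by mean-pressure deficit; vasopressors
#' raise `R` (and mildly heart rate) within the treated hour, fluids raise
#' `SV`; SOFA components follow integer walks biased by perfusion; death
#' fires through a severity hazard and discharge after a sustained low
#' severity; labs are drawn 12-hourly and forward-filled. The clinician
#' (behavior) policy administers vasopressors with probability increasing in
#' SOFA and hypotension.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the same config and seed give an identical
#'   cohort.
#' @return an `icu_cohort` list with elements `obs` (hourly observations,
#'   actions and demographics), `labs` (hourly forward-filled 12-channel
#'   labs), `outcomes` (per-patient outcome:
#'   survivor / nonsurvivor / excluded_hospital_death), `truth` (per-hour
#'   true cardiovascular state, identifiable combinations and severity) and
#'   `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 20, horizon_h = 24), seed = 1)
#' table(coh$outcomes$outcome)
#' @export
simulate_cohort <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_cohort_impl(config, seed))
}

simulate_cohort_impl <- function(cfg, seed) {
  n <- cfg$n_patients; H <- cfg$horizon_h

  ## per-patient constants
  age <- pmin(95, pmax(18, stats::rnorm(n, 66, 14)))
  gender <- stats::rbinom(n, 1, 0.55)
  weight <- pmin(150, pmax(40, stats::rnorm(n, 80, 16)))
  base_R <- exp(stats::rnorm(n, log(1.05), 0.12))
  base_C <- exp(stats::rnorm(n, log(2.0), 0.10))
  base_SV <- exp(stats::rnorm(n, log(78), 0.12))
  base_F <- pmax(50, stats::rnorm(n, 72, 7))
  sev <- stats::rbeta(n, 2, 3)
  sev_drift_p <- stats::rnorm(n, -cfg$sev_recovery, cfg$sev_drift_sd)

  eR <- eC <- eSV <- eF <- numeric(n)
  comp <- matrix(pmin(4L, stats::rpois(n * 5L, 0.8 + 1.5 * rep(sev, 5L))),
                 n, 5L)  # resp, coag, liver, renal, cns
  low_streak <- integer(n)
  active <- rep(TRUE, n)
  terminal_hour <- rep(NA_integer_, n)
  died <- rep(FALSE, n)

  v0 <- wk_decode(data.frame(R = pmax(0.2, base_R * (1 - cfg$sev_coef_R * sev)),
                             C = base_C,
                             SV = pmax(15, base_SV * (1 - cfg$sev_coef_SV * sev)),
                             T = 60 / (base_F * (1 + cfg$sev_coef_F * sev))))
  prev_map <- v0$Pmap
  prev_sofa <- rowSums(comp) + pmin(4, (v0$Pmap < 70) + (v0$Pmap < 55))

  ## hourly storage
  M <- function() matrix(NA_real_, n, H)
  st <- list(hr = M(), sbp = M(), dbp = M(), map = M(), temp = M(),
             spo2 = M(), rr = M(), sofa = M(), liver = M(), renal = M(),
             cns = M(), cardio = M(), fluid_ml = M(), vaso_rate = M(),
             vaso_bin = M(), fluid_bin = M())
  tr <- list(R = M(), C = M(), SV = M(), F = M(), sev = M(),
             Psys = M(), Pdias = M(), Pmap = M())
  lab_names <- c("anion_gap", "bicarbonate", "creatinine", "chloride",
                 "glucose", "hematocrit", "hemoglobin", "platelet",
                 "potassium", "sodium", "bun", "wbc")
  labs <- lapply(stats::setNames(lab_names, lab_names), function(nm) M())

  draw_labs <- function(sev, renal) {
    rf <- renal / 4
    cbind(anion_gap  = 12 + 6 * sev + stats::rnorm(n, 0, 1.5),
          bicarbonate = 24 - 8 * sev + stats::rnorm(n, 0, 2),
          creatinine = pmax(0.3, 0.9 + 2.2 * rf + stats::rnorm(n, 0, 0.2)),
          chloride   = 104 + 2 * sev + stats::rnorm(n, 0, 2),
          glucose    = 115 + 60 * sev + stats::rnorm(n, 0, 20),
          hematocrit = 33 - 4 * sev + stats::rnorm(n, 0, 2),
          hemoglobin = 11 - 1.5 * sev + stats::rnorm(n, 0, 0.7),
          platelet   = pmax(10, 230 - 130 * sev + stats::rnorm(n, 0, 35)),
          potassium  = 4.0 + 0.8 * sev + stats::rnorm(n, 0, 0.3),
          sodium     = 139 + 2 * sev + stats::rnorm(n, 0, 2.5),
          bun        = pmax(4, 18 + 32 * rf + stats::rnorm(n, 0, 5)),
          wbc        = pmax(1, 10 + 10 * sev + stats::rnorm(n, 0, 2)))
  }
  lab_cur <- draw_labs(sev, comp[, 4L])

  for (t in seq_len(H)) {
    ## clinician policy from last hour's observables (draws are made for all
    ## patients every hour so paired arms under a common seed stay aligned)
    deficit_prev <- pmax(0, 65 - prev_map)
    pv <- stats::plogis(cfg$policy_vaso[1] + cfg$policy_vaso[2] * prev_sofa +
                          cfg$policy_vaso[3] * deficit_prev)
    give_v <- stats::runif(n) < pv
    high_v <- stats::runif(n) < stats::plogis(-1.5 + 3 * sev)
    vaso_bin <- ifelse(give_v, 1L + high_v, 0L)
    pf <- stats::plogis(cfg$policy_fluid[1] + cfg$policy_fluid[2] * prev_sofa +
                          cfg$policy_fluid[3] * deficit_prev)
    give_f <- stats::runif(n) < pf
    high_f <- stats::runif(n) < stats::plogis(-1 + 2 * sev)
    fluid_bin <- ifelse(give_f, 1L + high_f, 0L)
    if (!is.na(cfg$forced_vaso_bin)) vaso_bin <- rep(as.integer(cfg$forced_vaso_bin), n)
    if (!is.na(cfg$forced_fluid_bin)) fluid_bin <- rep(as.integer(cfg$forced_fluid_bin), n)
    u1 <- stats::runif(n); u2 <- stats::runif(n)
    vaso_rate <- c(0, 0.02, 0.16)[vaso_bin + 1L] +
      u1 * c(0, 0.12, 0.44)[vaso_bin + 1L]
    fluid_ml <- c(0, 50, 510)[fluid_bin + 1L] +
      u2 * c(0, 440, 990)[fluid_bin + 1L]

    ## true cardiovascular state this hour
    R_t <- pmax(0.2, base_R * (1 - cfg$sev_coef_R * sev) * exp(eR) +
                  cfg$delta_R_vaso[vaso_bin + 1L])
    C_t <- pmax(0.5, base_C * exp(eC))
    SV_t <- pmax(15, base_SV * (1 - cfg$sev_coef_SV * sev) * exp(eSV) +
                   cfg$delta_SV_fluid[fluid_bin + 1L])
    F_t <- pmin(200, pmax(35, base_F * (1 + cfg$sev_coef_F * sev) * exp(eF) +
                            cfg$delta_F_vaso[vaso_bin + 1L]))
    T_t <- 60 / F_t
    dec <- wk_decode(data.frame(R = R_t, C = C_t, SV = SV_t, T = T_t))
    deficit <- pmax(0, 65 - dec$Pmap)

    ## SOFA: five component walks biased by severity and perfusion deficit,
    ## plus a rule-based cardiovascular component
    p_up <- stats::plogis(-2.6 + 0.06 * deficit + 2.6 * sev)
    p_dn <- stats::plogis(-1.4 - 2.5 * sev)
    step <- (matrix(stats::runif(n * 5L), n) < p_up) -
      (matrix(stats::runif(n * 5L), n) < p_dn)
    comp <- pmin(pmax(comp + step, 0L), 4L)
    cardio <- pmin(4, (dec$Pmap < 70) + (dec$Pmap < 55) +
                     (vaso_bin >= 1) + (vaso_bin >= 2))
    sofa <- rowSums(comp) + cardio

    ## observations
    obs_hr <- F_t + stats::rnorm(n, 0, cfg$obs_sd_hr)
    obs_sbp <- dec$Psys + stats::rnorm(n, 0, cfg$obs_sd_pressure)
    obs_dbp <- dec$Pdias + stats::rnorm(n, 0, cfg$obs_sd_pressure)
    obs_map <- dec$Pmap + stats::rnorm(n, 0, cfg$obs_sd_pressure)
    obs_temp <- 36.8 + 1.8 * sev + stats::rnorm(n, 0, 0.3)
    obs_spo2 <- pmin(100, 98 - 6 * sev + stats::rnorm(n, 0, 1))
    obs_rr <- pmax(6, 14 + 9 * sev + stats::rnorm(n, 0, 1.5))

    ## labs drawn at hours 1, 13, 25, ... then carried forward
    lab_new <- draw_labs(sev, comp[, 4L])
    if ((t - 1L) %% 12L == 0L) lab_cur <- lab_new

    idx <- which(active)
    for (nm in names(st))
      st[[nm]][idx, t] <- switch(nm,
        hr = obs_hr, sbp = obs_sbp, dbp = obs_dbp, map = obs_map,
        temp = obs_temp, spo2 = obs_spo2, rr = obs_rr, sofa = sofa,
        liver = comp[, 3L], renal = comp[, 4L], cns = comp[, 5L],
        cardio = cardio, fluid_ml = fluid_ml, vaso_rate = vaso_rate,
        vaso_bin = vaso_bin, fluid_bin = fluid_bin)[idx]
    for (nm in names(tr))
      tr[[nm]][idx, t] <- switch(nm,
        R = R_t, C = C_t, SV = SV_t, F = F_t, sev = sev,
        Psys = dec$Psys, Pdias = dec$Pdias, Pmap = dec$Pmap)[idx]
    for (nm in lab_names) labs[[nm]][idx, t] <- lab_cur[idx, nm]

    ## severity update (treatment shortens hypotensive spirals)
    treat <- ((vaso_bin > 0) + 0.5 * (fluid_bin > 0)) * (deficit > 0)
    drift <- cfg$sev_gain_deficit * deficit / 65 + sev_drift_p -
      cfg$sev_treat_benefit * treat
    sev <- clip01(sev + stats::rnorm(n, 0, cfg$sev_sigma) + drift)

    ## AR(1) fluctuations
    eR <- cfg$ar_rho * eR + stats::rnorm(n, 0, cfg$ar_sigma)
    eC <- cfg$ar_rho * eC + stats::rnorm(n, 0, cfg$ar_sigma)
    eSV <- cfg$ar_rho * eSV + stats::rnorm(n, 0, cfg$ar_sigma)
    eF <- cfg$ar_rho * eF + stats::rnorm(n, 0, cfg$ar_sigma)

    ## terminals
    p_death <- cfg$hazard_scale *
      stats::plogis(cfg$hazard_slope * (sev - cfg$hazard_mid))
    u_death <- stats::runif(n)
    die_now <- active & (u_death < p_death)
    low_streak <- ifelse(sev < cfg$discharge_threshold, low_streak + 1L, 0L)
    disc_now <- active & !die_now & (low_streak >= cfg$discharge_hours)
    if (t == H) disc_now <- disc_now | (active & !die_now)
    terminal_hour[die_now | disc_now] <- t
    died[die_now] <- TRUE
    active[die_now | disc_now] <- FALSE

    prev_map <- obs_map
    prev_sofa <- sofa
    if (!any(active)) {
      H_used <- t
      break
    }
    H_used <- t
  }

  ## assemble long tables
  L <- terminal_hour
  pid <- rep.int(seq_len(n), L)
  hour <- unlist(lapply(L, seq_len), use.names = FALSE)
  take <- cbind(pid, hour)

  obs <- data.frame(patient_id = pid, hour = hour)
  for (nm in c("hr", "sbp", "dbp", "map", "temp", "spo2", "rr",
               "sofa", "liver", "renal", "cns", "cardio",
               "fluid_ml", "vaso_rate"))
    obs[[nm]] <- st[[nm]][take]
  obs$action <- 3L * as.integer(st$vaso_bin[take]) + as.integer(st$fluid_bin[take])
  obs$age <- age[pid]; obs$gender <- gender[pid]; obs$weight <- weight[pid]

  ## inject missingness on the 7 vitals (never the first hour; exact counts,
  ## so the realized per-patient rate never exceeds the configured rate)
  high <- stats::runif(n) < cfg$frac_high_miss
  vital_cols <- c("hr", "sbp", "dbp", "map", "temp", "spo2", "rr")
  rate_p <- ifelse(high, cfg$miss_rate_high, cfg$miss_rate)
  row_ofs <- c(0L, cumsum(L))
  na_rows <- vector("list", n)
  na_cols <- vector("list", n)
  for (p in seq_len(n)) {
    cells <- (L[p] - 1L) * 7L
    k <- min(floor(rate_p[p] * L[p] * 7L), cells)
    if (k < 1L) next
    pick <- sample.int(cells, k)         # cells over hours 2..L x 7 vitals
    na_rows[[p]] <- row_ofs[p] + 1L + ((pick - 1L) %/% 7L) + 1L
    na_cols[[p]] <- ((pick - 1L) %% 7L) + 1L
  }
  vit_mat <- as.matrix(obs[vital_cols])
  vit_mat[cbind(unlist(na_rows), unlist(na_cols))] <- NA_real_
  obs[vital_cols] <- vit_mat
  obs$weight[obs$patient_id %in% which(stats::runif(n) < cfg$frac_no_weight)] <- NA_real_

  lab_df <- data.frame(patient_id = pid, hour = hour)
  for (nm in lab_names) lab_df[[nm]] <- labs[[nm]][take]

  outcome <- ifelse(died, "nonsurvivor", "survivor")
  surv_idx <- which(!died)
  flip <- surv_idx[stats::runif(length(surv_idx)) < cfg$frac_hospital_death]
  outcome[flip] <- "excluded_hospital_death"
  outcomes <- data.frame(patient_id = seq_len(n), outcome = outcome,
                         terminal_hour = terminal_hour)

  truth <- data.frame(patient_id = pid, hour = hour,
                      R = tr$R[take], C = tr$C[take], SV = tr$SV[take],
                      F = tr$F[take], T = 60 / tr$F[take],
                      sev = tr$sev[take],
                      Psys = tr$Psys[take], Pdias = tr$Pdias[take],
                      Pmap = tr$Pmap[take])
  truth$RC <- truth$R * truth$C
  truth$SV_over_C <- truth$SV / truth$C
  truth$SV_times_R <- truth$SV * truth$R
  truth$CO <- truth$SV * truth$F

  structure(list(obs = obs, labs = lab_df, outcomes = outcomes,
                 truth = truth, config = cfg, seed = seed),
            class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat("<icu_cohort> ", nrow(x$outcomes), " patients, ",
      nrow(x$obs), " patient-hours\n", sep = "")
  print(table(x$outcomes$outcome))
  invisible(x)
}

#' Per-hour ground truth table of a synthetic cohort
#'
#' Returns the hidden cardiovascular state and its identifiable combinations
#' (`RC`, `SV/C`, `SV*R`, `CO`) aligned to the observed hours — the reference
#' for encoder-recovery checks.
#'
#' @param cohort an `icu_cohort` from [simulate_cohort()].
#' @return data frame with one row per patient-hour.
#' @export
ground_truth_export <- function(cohort) {
  stopifnot(inherits(cohort, "icu_cohort"))
  cohort$truth
}

#' Write / read a synthetic cohort as CSV files
#'
#' @param cohort an `icu_cohort`.
#' @param dir output directory (created if needed). Files: `cohort.csv`,
#'   `labs.csv`, `outcomes.csv`, `truth.csv`, `config.json`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "icu_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$obs, file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(cohort$labs, file.path(dir, "labs.csv"), row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- unclass(cohort$config)
    cfg$seed <- cohort$seed
    jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  out <- list(obs = utils::read.csv(file.path(dir, "cohort.csv")),
              labs = utils::read.csv(file.path(dir, "labs.csv")),
              outcomes = utils::read.csv(file.path(dir, "outcomes.csv")),
              truth = utils::read.csv(file.path(dir, "truth.csv")),
              config = NULL, seed = NA_integer_)
  class(out) <- "icu_cohort"
  out
}
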