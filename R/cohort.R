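#' Discretize fluid and vasopressor doses into the 9-action space
#'
#' Hourly treatments are binned into 3 fluid levels crossed with 3
#' vasopressor levels. Bin 0 is exactly zero dose; bin 1 is a dose up to the
#' cutoff; bin 2 exceeds it. The cutoffs are 500 mL for the within-hour
#' fluid total and 0.15 mcg/kg/min for the within-hour maximum
#' norepinephrine-equivalent rate. The scalar action index is
#' `3 * vaso_bin + fluid_bin` (vasopressor-major), in `0..8`; index 0 is
#' "no treatment".
#'
#' @param fluid_ml within-hour total fluid volume, mL (vectorized).
#' @param vaso_rate within-hour maximum norepinephrine-equivalent rate,
#'   mcg/kg/min.
#' @param fluid_cutoff,vaso_cutoff bin-1/2 boundaries.
#' @return data frame with `fluid_bin`, `vaso_bin`, `action`.
#' @examples
#' discretize_action(c(0, 800), c(0, 0.2))  # actions 0 and 8
#' @export
discretize_action <- function(fluid_ml, vaso_rate,
                              fluid_cutoff = 500, vaso_cutoff = 0.15) {
  if (any(fluid_ml < 0, na.rm = TRUE) || any(vaso_rate < 0, na.rm = TRUE))
    stop("discretize_action: doses must be non-negative")
  bin3 <- function(x, cut) ifelse(x == 0, 0L, ifelse(x <= cut, 1L, 2L))
  fb <- bin3(fluid_ml, fluid_cutoff)
  vb <- bin3(vaso_rate, vaso_cutoff)
  data.frame(fluid_bin = fb, vaso_bin = vb, action = 3L * vb + fb)
}

#' Actions that include a vasopressor
#'
#' @param action scalar action index in `0..8`.
#' @return logical; `TRUE` when the vasopressor bin is positive.
#' @export
action_has_vaso <- function(action) (action %/% 3L) > 0L

#' SOFA-based reward
#'
#' Terminal transitions pay +15 on survival and -15 on death. Non-terminal
#' transitions combine a small penalty for remaining at an unchanged
#' positive SOFA with a linear penalty on the SOFA increment:
#' `r = -0.025 * 1[sofa_next == sofa & sofa_next > 0] - 0.125 * (sofa_next - sofa)`.
#'
#' @param sofa_t,sofa_next integer SOFA totals in 0..24 (vectorized).
#' @param terminal_type `"none"`, `"survival"` or `"death"`.
#' @return numeric reward(s) in `[-15, 15]`.
#' @examples
#' sofa_reward(8, 10, "none")        # -0.25
#' sofa_reward(10, 10, "none")       # -0.025
#' sofa_reward(5, 5, "death")        # -15
#' @export
sofa_reward <- function(sofa_t, sofa_next, terminal_type = "none") {
  if (any(sofa_t < 0 | sofa_t > 24 | sofa_next < 0 | sofa_next > 24, na.rm = TRUE))
    stop("sofa_reward: SOFA must lie in 0..24")
  terminal_type <- match.arg(terminal_type, c("none", "survival", "death"),
                             several.ok = FALSE)
  if (terminal_type == "survival") return(rep_len(15, length(sofa_t)))
  if (terminal_type == "death") return(rep_len(-15, length(sofa_t)))
  -0.025 * as.numeric(sofa_next == sofa_t & sofa_next > 0) -
    0.125 * (sofa_next - sofa_t)
}

#' Preprocess raw trajectories: forward-fill and exclusion filters
#'
#' Applies the cohort filters: missing vitals and labs are imputed by
#' carrying the last value forward (per patient); patients with more than
#' `max_missing` missing values, with no recorded weight, or flagged as
#' dying in hospital after ICU discharge are excluded.
#'
#' @param cohort an `icu_cohort` (observations + labs + outcomes).
#' @param max_missing maximum tolerated fraction of missing vital cells.
#' @return an `icu_cohort` with imputed tables, filtered patients and an
#'   `exclusions` attribute recording why patients were dropped.
#' @export
preprocess_trajectories <- function(cohort, max_missing = 0.25) {
  stopifnot(inherits(cohort, "icu_cohort"))
  obs <- cohort$obs[order(cohort$obs$patient_id, cohort$obs$hour), ]
  vital_cols <- c("hr", "sbp", "dbp", "map", "temp", "spo2", "rr")
  miss_frac <- tapply(rowMeans(is.na(obs[vital_cols])), obs$patient_id, mean)
  too_missing <- as.numeric(names(miss_frac))[miss_frac > max_missing]
  no_weight <- unique(obs$patient_id[is.na(obs$weight)])
  hosp_death <- cohort$outcomes$patient_id[
    cohort$outcomes$outcome == "excluded_hospital_death"]
  drop <- union(union(too_missing, no_weight), hosp_death)
  keep <- !(obs$patient_id %in% drop)
  obs <- obs[keep, ]
  if (nrow(obs) == 0) stop("preprocess_trajectories: empty cohort after filtering")

  ## last-value-carried-forward per patient on vitals; labs analogously
  pid <- obs$patient_id
  len <- as.integer(table(factor(pid, levels = unique(pid))))
  ends <- cumsum(len); starts <- ends - len + 1L
  M <- as.matrix(obs[vital_cols])
  for (p in which(vapply(seq_along(len), function(p)
    anyNA(M[starts[p]:ends[p], ]), logical(1))))
    M[starts[p]:ends[p], ] <- ffill_matrix(M[starts[p]:ends[p], , drop = FALSE])
  obs[vital_cols] <- M

  labs <- cohort$labs[cohort$labs$patient_id %in% unique(pid), ]
  labs <- labs[order(labs$patient_id, labs$hour), ]
  Lm <- as.matrix(labs[lab_channels])
  lpid <- labs$patient_id
  llen <- as.integer(table(factor(lpid, levels = unique(lpid))))
  lends <- cumsum(llen); lstarts <- lends - llen + 1L
  for (p in which(vapply(seq_along(llen), function(p)
    anyNA(Lm[lstarts[p]:lends[p], ]), logical(1))))
    Lm[lstarts[p]:lends[p], ] <- ffill_matrix(Lm[lstarts[p]:lends[p], , drop = FALSE])
  labs[lab_channels] <- Lm

  out <- cohort
  out$obs <- obs
  out$labs <- labs
  out$outcomes <- cohort$outcomes[!cohort$outcomes$patient_id %in% drop, ]
  if (!is.null(cohort$truth))
    out$truth <- cohort$truth[!cohort$truth$patient_id %in% drop, ]
  attr(out, "exclusions") <- list(too_missing = too_missing,
                                  no_weight = no_weight,
                                  hospital_death = hosp_death)
  out
}

#' Assemble the 41-dimensional transition dataset
#'
#' Builds the POMDP training set: for each patient-hour a 41-dimensional
#' state (3 demographics, 7 vitals, 5 scores, 12 labs, 4 latent
#' cardiovascular states `R, C, SV, T`, 10 lab-representation components),
#' z-scored with moments fitted on the training split only, paired with the
#' taken action, the SOFA-based reward, the successor state, the terminal
#' type and the hours to the eventual event.
#'
#' @param cohort a preprocessed `icu_cohort`.
#' @param physio_model a fitted [fit_physio_encoder()] model.
#' @param lab_model a fitted [fit_lab_encoder()] model.
#' @param train_frac fraction of patients whose moments define the scaling
#'   and which are marked as the training split.
#' @param seed seed for the patient-level split.
#' @return a `transition_dataset`: list with `states` (matrix n x 41),
#'   `action`, `reward`, `next_state` (row index into `states`, NA at
#'   terminals), `terminal_type`, `time_to_event`, `outcome`, `patient_id`,
#'   `hour`, `split`, `scaling`, `feature_names`.
#' @export
assemble_transitions <- function(cohort, physio_model, lab_model,
                                 train_frac = 0.8, seed = 1) {
  stopifnot(inherits(cohort, "icu_cohort"),
            inherits(physio_model, "physio_encoder"),
            inherits(lab_model, "lab_encoder"))
  obs <- cohort$obs[order(cohort$obs$patient_id, cohort$obs$hour), ]
  cs <- predict(physio_model, obs)
  lr <- predict(lab_model, cohort$labs[cohort$labs$patient_id %in%
                                         unique(obs$patient_id), ])
  stopifnot(nrow(cs) == nrow(obs), nrow(lr) == nrow(obs))

  feat <- cbind(as.matrix(obs[c("age", "gender", "weight")]),
                as.matrix(obs[c("hr", "sbp", "dbp", "map", "temp", "spo2", "rr")]),
                as.matrix(obs[c("sofa", "liver", "renal", "cns", "cardio")]),
                as.matrix(cohort$labs[match(paste(obs$patient_id, obs$hour),
                                            paste(cohort$labs$patient_id,
                                                  cohort$labs$hour)),
                                      lab_channels]),
                as.matrix(cs[c("R", "C", "SV", "T")]),
                as.matrix(lr[paste0("l", 1:10)]))
  colnames(feat) <- c("age", "gender", "weight",
                      "hr", "sbp", "dbp", "map", "temp", "spo2", "rr",
                      "sofa", "liver", "renal", "cns", "cardio",
                      lab_channels,
                      "cv_R", "cv_C", "cv_SV", "cv_T",
                      paste0("lab_l", 1:10))
  if (ncol(feat) != 41L) stop("assemble_transitions: state dimension != 41")
  if (any(!is.finite(feat))) stop("assemble_transitions: non-finite feature")

  pid <- obs$patient_id
  upid <- unique(pid)
  split <- with_seed(seed, {
    tr <- sample(upid, max(1L, round(train_frac * length(upid))))
    ifelse(upid %in% tr, "train", "validation")
  })
  split_row <- split[match(pid, upid)]
  mu <- colMeans(feat[split_row == "train", , drop = FALSE])
  sd_ <- scale_sd(feat[split_row == "train", , drop = FALSE])
  states <- sweep(sweep(feat, 2, mu), 2, sd_, "/")

  ## transitions: one per patient-hour; the last hour of each patient is the
  ## terminal transition (no successor used in the backup)
  len <- as.integer(table(factor(pid, levels = upid)))
  ends <- cumsum(len)
  is_last <- seq_len(nrow(obs)) %in% ends
  outcome <- cohort$outcomes$outcome[match(pid, cohort$outcomes$patient_id)]
  terminal_type <- ifelse(!is_last, "none",
                          ifelse(outcome == "nonsurvivor", "death", "survival"))
  nxt <- ifelse(is_last, NA_integer_, seq_len(nrow(obs)) + 1L)
  sofa_t <- obs$sofa
  sofa_n <- ifelse(is_last, sofa_t, obs$sofa[pmin(nrow(obs), seq_len(nrow(obs)) + 1L)])
  reward <- ifelse(terminal_type == "survival", 15,
                   ifelse(terminal_type == "death", -15,
                          -0.025 * as.numeric(sofa_n == sofa_t & sofa_n > 0) -
                            0.125 * (sofa_n - sofa_t)))
  term_hour <- ends[match(pid, upid)]
  last_hour <- obs$hour[term_hour]
  time_to_event <- last_hour - obs$hour

  structure(list(states = states, action = as.integer(obs$action),
                 reward = reward, next_state = nxt,
                 terminal_type = terminal_type,
                 time_to_event = time_to_event,
                 outcome = outcome,
                 patient_id = pid, hour = obs$hour,
                 split = split_row,
                 scaling = list(mu = mu, sd = sd_),
                 feature_names = colnames(feat)),
            class = "transition_dataset")
}

#' @export
print.transition_dataset <- function(x, ...) {
  cat("<transition_dataset> ", nrow(x$states), " transitions, ",
      length(unique(x$patient_id)), " patients\n", sep = "")
  cat("  terminals:", sum(x$terminal_type == "survival"), "survival /",
      sum(x$terminal_type == "death"), "death\n")
  invisible(x)
}
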