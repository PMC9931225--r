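# Shared fixtures, trained once per test run and memoized. Sizes are kept
# small: these exercise structure and invariants; the acceptance suite
# trains at full scale.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

small_cohort <- function() memo("small_cohort", {
  simulate_cohort(sim_config(n_patients = 150, horizon_h = 40), seed = 11)
})

small_cohort_pp <- function() memo("small_cohort_pp", {
  preprocess_trajectories(small_cohort())
})

small_physio <- function() memo("small_physio", {
  fit_physio_encoder(small_cohort_pp(), gru_hidden = 12, mlp_hidden = 12,
                     epochs = 4, batch_patients = 64, lr = 3e-3, seed = 2)
})

small_lab <- function() memo("small_lab", {
  fit_lab_encoder(small_cohort_pp(), widths = c(16, 12, 10), epochs = 4,
                  batch_patients = 64, lr = 3e-3, seed = 2)
})

small_dataset <- function() memo("small_dataset", {
  assemble_transitions(small_cohort_pp(), small_physio(), small_lab(),
                       seed = 3)
})

small_agent <- function() memo("small_agent", {
  fit_c51(small_dataset(), hidden = c(32, 32), steps = 300, lr = 2e-3,
          target_every = 100, seed = 4)
})

small_cloner <- function() memo("small_cloner", {
  fit_behavior_cloner(small_dataset(), hidden = c(32, 32), steps = 400,
                      seed = 4)
})

small_ensemble <- function() memo("small_ensemble", {
  fit_c51_ensemble(small_dataset(), n_members = 3, fraction = 0.4,
                   hidden = c(16, 16), steps = 120, lr = 2e-3,
                   target_every = 60, seed = 5)
})

# independent tabular value-iteration oracle for the 5-state chain MDP
chain_mdp <- function(gamma = 0.99, step_reward = -0.1, n_states = 5) {
  Q <- matrix(0, n_states, 2)     # col 1 = left, col 2 = right
  repeat {
    Qn <- Q
    for (s in seq_len(n_states)) {
      Qn[s, 1] <- if (s == 1) -15 else step_reward + gamma * max(Q[s - 1, ])
      Qn[s, 2] <- if (s == n_states) 15 else step_reward + gamma * max(Q[s + 1, ])
    }
    if (max(abs(Qn - Q)) < 1e-12) break
    Q <- Qn
  }
  Q
}

# the same chain as a transition_dataset (one record per state-action)
chain_dataset <- function(step_reward = -0.1, n_states = 5) {
  S <- diag(n_states)
  rows <- list(); action <- reward <- nxt <- integer(0); term <- character(0)
  k <- 0
  idx_of_state <- function(s) (s - 1) * 2 + 1
  for (s in seq_len(n_states)) for (a in 0:1) {
    k <- k + 1
    rows[[k]] <- S[s, ]
    action[k] <- a
    if (a == 0 && s == 1) {
      reward[k] <- -15; term[k] <- "death"; nxt[k] <- NA
    } else if (a == 1 && s == n_states) {
      reward[k] <- 15; term[k] <- "survival"; nxt[k] <- NA
    } else {
      reward[k] <- step_reward; term[k] <- "none"
      nxt[k] <- idx_of_state(if (a == 0) s - 1 else s + 1)
    }
  }
  structure(list(states = do.call(rbind, rows), action = as.integer(action),
                 reward = reward, next_state = nxt, terminal_type = term,
                 time_to_event = rep(10, k), outcome = rep("survivor", k),
                 patient_id = seq_len(k), hour = seq_len(k),
                 split = rep("train", k), scaling = NULL,
                 feature_names = paste0("s", seq_len(n_states))),
            class = "transition_dataset")
}

# parameter grid used by the Windkessel equivalence checks
wk_grid <- function(n_R = 5, n_C = 5, n_SV = 5, n_F = 4) {
  g <- expand.grid(R = seq(0.5, 2, length.out = n_R),
                   C = seq(1, 3, length.out = n_C),
                   SV = seq(40, 100, length.out = n_SV),
                   F = seq(50, 130, length.out = n_F))
  cardio_state(R = g$R, C = g$C, SV = g$SV, F = g$F)
}

`%||%` <- sepsisrl:::`%||%`

# steady-state peak/trough/mean of the simulated waveform over one cycle,
# with the exact cycle-end sample and a trapezoidal time average
wk_cycle_stats <- function(s, n_cycles = NULL, k = 400) {
  ## run until the start-up transient has decayed below machine noise
  n_cycles <- n_cycles %||% max(60, ceiling(30 * s$R * s$C / s$T))
  dt <- s$T / k
  w <- wk_simulate(s, n_cycles = n_cycles, dt = dt, include_cycle_end = TRUE)
  last <- w[w$time >= (n_cycles - 1) * s$T - dt / 4, ]
  last <- last[-1, ]                    # drop the previous cycle's end sample
  list(peak = max(last$P), trough = min(last$P),
       mean = (sum(last$P) - (last$P[1] + last$P[nrow(last)]) / 2) /
         (nrow(last) - 1))
}
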