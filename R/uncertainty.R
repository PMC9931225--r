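#' Train a bootstrap ensemble of distributional Q-learning agents
#'
#' Epistemic (model) uncertainty is estimated from the spread of agents
#' trained on patient-level bootstrap resamples, each substantially smaller
#' than the full training set. All of a patient's transitions travel
#' together into a member's dataset (transition-level resampling would leak
#' trajectories across members). Members share architecture and algorithm
#' but differ in data and initialization seeds.
#'
#' @param dataset a `transition_dataset`.
#' @param n_members ensemble size (default 25; must be >= 2).
#' @param fraction bootstrap size as a fraction of training patients.
#' @param seed base seed; member `m` uses `seed + m` for its resample and
#'   initialization.
#' @param ... passed to [fit_c51()] (steps, hidden, lr, ...).
#' @return a `c51_ensemble`: list of `c51_agent`s with `n_patients` each.
#' @export
fit_c51_ensemble <- function(dataset, n_members = 25, fraction = 0.3,
                             seed = 1, ...) {
  if (n_members < 2) stop("fit_c51_ensemble: need at least 2 members")
  if (fraction <= 0 || fraction >= 1) stop("fit_c51_ensemble: fraction in (0,1)")
  tr_pid <- unique(dataset$patient_id[dataset$split == "train"])
  n_boot <- max(2L, round(fraction * length(tr_pid)))
  members <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    for (try in 1:20) {
      pick <- with_seed(seed + m + 1000L * (try - 1L),
                        sample(tr_pid, n_boot, replace = TRUE))
      rows <- dataset$patient_id %in% pick & dataset$split == "train"
      sub <- dataset
      sub$states <- dataset$states[rows, , drop = FALSE]
      for (f in c("action", "reward", "terminal_type", "time_to_event",
                  "outcome", "patient_id", "hour", "split"))
        sub[[f]] <- dataset[[f]][rows]
      ## remap successor pointers into the subset (terminal if successor
      ## row was not drawn -- cannot happen within a patient's block)
      sub$next_state <- match(dataset$next_state[rows], which(rows))
      sub$next_state[sub$terminal_type != "none"] <- NA_integer_
      if (any(sub$terminal_type == "death") &&
          any(sub$terminal_type == "survival")) break
      if (try == 20) stop("fit_c51_ensemble: resample lost a terminal class")
      warning("fit_c51_ensemble: member ", m,
              " resample lost a terminal class; resampling")
    }
    ag <- fit_c51(sub, seed = seed + m, split = "train", ...)
    ag$n_patients <- length(unique(pick))
    members[[m]] <- ag
  }
  structure(list(members = members, fraction = fraction, seed = seed),
            class = "c51_ensemble")
}

#' @export
print.c51_ensemble <- function(x, ...) {
  cat("<c51_ensemble> ", length(x$members), " members, fraction ",
      x$fraction, "\n", sep = "")
  invisible(x)
}

#' Model (epistemic) uncertainty of the ensemble at given states
#'
#' The per-state-action uncertainty is the Monte-Carlo estimate
#' `u(s,a) = mean_m KL( theta_m(s,a) || theta_ref(s,a) )` in nats, where the
#' reference is either the ensemble mean distribution or the value
#' distribution of a model trained on the full training set. Probabilities
#' are floored at `eps` before the divergence. `u` is zero iff all members
#' agree exactly, and is invariant to member ordering.
#'
#' @param ensemble a `c51_ensemble`.
#' @param states scaled state matrix (rows = states).
#' @param reference `"ensemble_mean"` or `"full_model"`.
#' @param full_model the full-data `c51_agent` (required for
#'   `reference = "full_model"`).
#' @param eps probability floor.
#' @return matrix `[n, 9]` of uncertainties in nats.
#' @export
model_uncertainty <- function(ensemble, states,
                              reference = c("ensemble_mean", "full_model"),
                              full_model = NULL, eps = 1e-8) {
  reference <- match.arg(reference)
  stopifnot(inherits(ensemble, "c51_ensemble"))
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  M <- length(ensemble$members)
  dists <- lapply(ensemble$members, c51_distributions, states = states)
  ref <- if (reference == "ensemble_mean") {
    Reduce(`+`, dists) / M
  } else {
    if (is.null(full_model)) stop("model_uncertainty: full_model required")
    c51_distributions(full_model, states)
  }
  ref <- pmax(ref, eps)
  u <- 0
  for (d in dists) {
    dm <- pmax(d, eps)
    u <- u + apply(dm * (log(dm) - log(ref)), c(1, 2), sum)
  }
  u / M
}

#' Patient-weighted ensemble value distributions
#'
#' Mixes the member distributions with weights proportional to the number
#' of distinct patients each member was trained on, and summarizes the
#' mixture with [q_view()].
#'
#' @param ensemble a `c51_ensemble`.
#' @param states scaled state matrix.
#' @param weights optional member weights (default: `n_patients`).
#' @return list with the mixture `dist` array and the `q_view` summary.
#' @export
ensemble_q <- function(ensemble, states, weights = NULL) {
  stopifnot(inherits(ensemble, "c51_ensemble"))
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  w <- weights %||% vapply(ensemble$members, function(m)
    m$n_patients %||% 1, numeric(1))
  stopifnot(length(w) == length(ensemble$members), all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  mix <- 0
  for (i in seq_along(ensemble$members))
    mix <- mix + w[i] * c51_distributions(ensemble$members[[i]], states)
  list(dist = mix, qv = q_view(mix, ensemble$members[[1]]$atoms))
}

#' Voting vasopressor policy over the ensemble
#'
#' Prescribes a vasopressor-containing action only when at least `p`
#' percent of the members' greedy actions include a vasopressor; otherwise
#' the greedy action among vasopressor-free actions under the
#' patient-weighted mixture is taken.
#'
#' @param ensemble a `c51_ensemble`.
#' @param states scaled state matrix.
#' @param p agreement threshold in percent, `(0, 100]`.
#' @return list with `action` (0-based index per state), `vaso` (logical)
#'   and `agree_pct` (percent of members voting for vasopressors).
#' @export
voting_vaso_policy <- function(ensemble, states, p = 50) {
  stopifnot(p > 0, p <= 100)
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  votes <- vapply(ensemble$members, function(m)
    action_has_vaso(predict(m, states)$greedy - 1L), logical(nrow(states)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(states))
  agree <- 100 * rowMeans(votes)
  eq <- ensemble_q(ensemble, states)
  Q <- eq$qv$Q
  vaso_cols <- which(action_has_vaso(0:8))
  novaso_cols <- which(!action_has_vaso(0:8))
  act <- integer(nrow(states))
  for (i in seq_len(nrow(states))) {
    cols <- if (agree[i] >= p) vaso_cols else novaso_cols
    act[i] <- cols[which_max_first(Q[i, cols])] - 1L
  }
  list(action = act, vaso = action_has_vaso(act), agree_pct = agree)
}
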