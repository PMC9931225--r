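#' Train the clinician behavior cloner
#'
#' A feed-forward classifier from the 41-dimensional state to the 9 action
#' probabilities, trained by minimizing the negative log-likelihood of the
#' observed clinician actions with weight-decay regularization. The output
#' head is a softmax, so predictions are a valid simplex even untrained.
#'
#' @param dataset a `transition_dataset`.
#' @param hidden hidden-layer widths.
#' @param steps gradient steps.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param weight_decay L2 regularization strength.
#' @param split rows to train on (`"train"` or `"all"`).
#' @param seed RNG seed.
#' @return a `behavior_cloner` with `params` and `loss_trace`.
#' @export
fit_behavior_cloner <- function(dataset, hidden = c(128, 128), steps = 3000,
                                batch_size = 256, lr = 1e-3,
                                weight_decay = 1e-4, split = "train",
                                seed = 1) {
  keep <- if (split == "all") rep(TRUE, nrow(dataset$states))
          else dataset$split == split
  S <- dataset$states[keep, , drop = FALSE]
  a <- dataset$action[keep] + 1L
  with_seed(seed, {
    params <- mlp_init(c(ncol(S), hidden, 9L), out_scale = 0.01)
    opt <- adam_init(params)
    losses <- numeric(steps)
    for (stp in seq_len(steps)) {
      b <- sample.int(nrow(S), min(batch_size, nrow(S)))
      fw <- mlp_forward(params, S[b, , drop = FALSE], activation = "relu")
      p <- softmax_rows(fw$out)
      tgt <- one_hot(a[b], 9L)
      losses[stp] <- -sum(tgt * log(pmax(p, 1e-12))) / length(b)
      if (!is.finite(losses[stp]))
        stop("fit_behavior_cloner: non-finite loss at step ", stp)
      bk <- mlp_backward(params, fw, (p - tgt) / length(b))
      upd <- adam_step(params, bk$grads, opt, lr = lr,
                       weight_decay = weight_decay)
      params <- upd$params; opt <- upd$state
    }
    structure(list(params = params, loss_trace = losses, hidden = hidden,
                   seed = seed), class = "behavior_cloner")
  })
}

#' @export
print.behavior_cloner <- function(x, ...) {
  cat("<behavior_cloner> hidden ", paste(x$hidden, collapse = "x"),
      "; final NLL ", sprintf("%.4f", mean(utils::tail(x$loss_trace, 100))),
      "\n", sep = "")
  invisible(x)
}

#' Clinician action probabilities G(s, a)
#'
#' @param object a `behavior_cloner`.
#' @param states scaled state matrix.
#' @param ... unused.
#' @return matrix `[n, 9]` of action probabilities (rows sum to 1).
#' @export
predict.behavior_cloner <- function(object, states, ...) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  softmax_rows(mlp_forward(object$params, states, activation = "relu")$out)
}

#' Uncertainty-aware action preference score
#'
#' Arbitrates between the RL agent, the clinician behavior cloner and the
#' ensemble's epistemic uncertainty:
#' `P(s,a) = beta * softmax(Q(s,.))_a + (1 - beta) * G(s,a) - lambda * u(s,a)`.
#' `beta = 1, lambda = 0` recovers the expected-value criterion;
#' `beta = 0, lambda = 0` recovers the pure behavior cloner. Ties in the
#' argmax break toward the lowest action index.
#'
#' @param Q matrix `[n, 9]` of expected values (e.g. from the ensemble
#'   mixture).
#' @param G matrix `[n, 9]` of cloner probabilities.
#' @param u matrix `[n, 9]` of model uncertainties (nats); 0 disables.
#' @param beta agent-vs-cloner confidence in `[0, 1]`.
#' @param lambda uncertainty penalty, `>= 0`.
#' @return a `recommendation` list: `P` (score matrix), `action` (0-based
#'   chosen action per state), and the three components.
#' @examples
#' preference_score(matrix(c(1, 0), 1), matrix(c(0.2, 0.8), 1),
#'                  matrix(0, 1, 2), beta = 1, lambda = 0)$action  # 0
#' @export
preference_score <- function(Q, G, u = NULL, beta = 0.5, lambda = 0) {
  if (length(beta) != 1 || beta < 0 || beta > 1)
    stop("preference_score: beta must lie in [0, 1]")
  if (length(lambda) != 1 || lambda < 0)
    stop("preference_score: lambda must be >= 0")
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  if (is.null(dim(G))) G <- matrix(G, nrow = 1)
  if (is.null(u)) u <- matrix(0, nrow(Q), ncol(Q))
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  stopifnot(all(dim(Q) == dim(G)), all(dim(Q) == dim(u)), all(u >= 0))
  sq <- softmax_rows(Q)
  P <- beta * sq + (1 - beta) * G - lambda * u
  structure(list(P = P,
                 action = apply(P, 1, which_max_first) - 1L,
                 softmax_q = sq, G = G, u = u,
                 beta = beta, lambda = lambda),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat("<recommendation> beta = ", x$beta, ", lambda = ", x$lambda, "; ",
      nrow(x$P), " state(s)\n", sep = "")
  cat("  actions:", paste(utils::head(x$action, 10), collapse = " "),
      if (length(x$action) > 10) "...", "\n")
  invisible(x)
}

#' Hourly treatment recommendations along a patient trajectory
#'
#' Computes the preference score at every non-terminal hour of one
#' patient's assembled states, logging all components — suitable for
#' recommended-treatment heatmaps across `(beta, lambda)` settings.
#'
#' @param dataset a `transition_dataset`.
#' @param patient_id patient to follow.
#' @param ensemble a `c51_ensemble` (for mixture Q and uncertainty).
#' @param cloner a `behavior_cloner`.
#' @param beta,lambda preference parameters.
#' @return data frame with one row per hour: chosen action, its components,
#'   the clinician's actual action, and per-action scores as a matrix
#'   attribute `P`.
#' @export
recommend_trajectory <- function(dataset, patient_id, ensemble, cloner,
                                 beta = 0.5, lambda = 0) {
  rows <- which(dataset$patient_id == patient_id)
  if (!length(rows)) stop("recommend_trajectory: unknown patient")
  S <- dataset$states[rows, , drop = FALSE]
  eq <- ensemble_q(ensemble, S)
  G <- predict(cloner, S)
  u <- model_uncertainty(ensemble, S)
  rec <- preference_score(eq$qv$Q, G, u, beta = beta, lambda = lambda)
  out <- data.frame(patient_id = patient_id, hour = dataset$hour[rows],
                    action = rec$action,
                    clinician_action = dataset$action[rows],
                    V_ensemble = eq$qv$V,
                    u_chosen = u[cbind(seq_along(rows), rec$action + 1L)],
                    G_chosen = G[cbind(seq_along(rows), rec$action + 1L)])
  attr(out, "P") <- rec$P
  out
}
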