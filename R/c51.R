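#' Project a shifted return distribution onto a fixed atom grid
#'
#' The categorical (C51) projection: each target atom value is clipped to
#' the support and its probability mass split linearly between the two
#' nearest grid atoms. Mass is conserved exactly, and the distribution mean
#' is preserved up to one atom spacing whenever no clipping occurs.
#'
#' @param atoms the fixed, equally spaced support (length N).
#' @param target_z matrix (rows = samples) of shifted atom values
#'   `r + gamma * z`, same number of columns as `target_p`.
#' @param target_p matrix of probabilities, rows summing to 1.
#' @return matrix (rows = samples, N columns) of projected probabilities.
#' @examples
#' c51_project(c(-1, 0, 1), matrix(0.5), matrix(1))  # (0, 0.5, 0.5)
#' @export
c51_project <- function(atoms, target_z, target_p) {
  if (is.null(dim(target_z))) target_z <- matrix(target_z, nrow = 1)
  if (is.null(dim(target_p))) target_p <- matrix(target_p, nrow = 1)
  stopifnot(ncol(target_z) == ncol(target_p), nrow(target_z) == nrow(target_p))
  N <- length(atoms)
  vmin <- atoms[1]; vmax <- atoms[N]
  dz <- (vmax - vmin) / (N - 1)
  n <- nrow(target_z)
  Tz <- pmin(pmax(target_z, vmin), vmax)
  b <- (Tz - vmin) / dz                 # in [0, N-1]
  l <- floor(b); u <- ceiling(b)
  same <- l == u
  wl <- ifelse(same, 1, u - b) * target_p
  wu <- ifelse(same, 0, b - l) * target_p
  out <- numeric(n * N)
  row <- rep.int(seq_len(n), ncol(Tz))
  acc <- function(colidx, w) {
    li <- row + n * as.integer(colidx)  # 0-based column -> linear index
    s <- rowsum(as.vector(w), li)
    ii <- as.integer(rownames(s))
    out[ii] <<- out[ii] + s[, 1]
  }
  acc(l, wl)
  acc(pmin(u, N - 1), wu)
  matrix(out, n, N)
}

## ---- replay weighting -------------------------------------------------

#' Calibrate outcome-weighted experience-replay weights
#'
#' Builds the per-transition multinomial sampling weights used for training:
#' terminal death and terminal survival transitions are upweighted so that a
#' batch of `batch_size` contains on average one of each; near-death
#' transitions (non-survivors within `near_horizon` hours of death) receive
#' an intermediate weight. With `n_d` death terminals the calibration is
#' closed-form: `W = S0 * B / (B - 2)` where `S0` is the total weight of
#' non-terminal transitions, and `w_death = W / (B * n_d)` (survival
#' analogously).
#'
#' @param dataset a `transition_dataset` from [assemble_transitions()], or a
#'   list with `terminal_type`, `outcome`, `time_to_event`.
#' @param batch_size batch size the calibration targets.
#' @param w_base weight of ordinary transitions.
#' @param w_neardeath weight of near-death transitions.
#' @param near_horizon hours before death counting as near-death.
#' @return numeric weight per transition, with the class weights as
#'   attributes.
#' @export
calibrate_replay_weights <- function(dataset, batch_size = 100, w_base = 1,
                                     w_neardeath = 5, near_horizon = 24) {
  stopifnot(batch_size > 2, w_base > 0, w_neardeath > 0)
  tt <- dataset$terminal_type
  near <- dataset$outcome == "nonsurvivor" & tt == "none" &
    dataset$time_to_event <= near_horizon
  n_d <- sum(tt == "death"); n_s <- sum(tt == "survival")
  if (n_d == 0 || n_s == 0)
    stop("calibrate_replay_weights: need at least one terminal of each type")
  w <- rep(w_base, length(tt))
  w[near] <- w_neardeath
  S0 <- sum(w[tt == "none"])
  W <- S0 * batch_size / (batch_size - 2)
  w_d <- W / (batch_size * n_d)
  w_s <- W / (batch_size * n_s)
  w[tt == "death"] <- w_d
  w[tt == "survival"] <- w_s
  attr(w, "class_weights") <- c(w_base = w_base, w_neardeath = w_neardeath,
                                w_death = w_d, w_survival = w_s)
  w
}

#' Draw a weighted replay batch
#'
#' Multinomial draw with replacement over transition indices.
#'
#' @param n_transitions number of transitions.
#' @param weights positive sampling weights (recycled if scalar).
#' @param batch_size records per batch.
#' @return integer vector of indices.
#' @export
weighted_sample <- function(n_transitions, weights = 1, batch_size = 100) {
  if (n_transitions < 1) stop("weighted_sample: empty dataset")
  w <- rep_len(weights, n_transitions)
  if (any(w <= 0)) stop("weighted_sample: weights must be positive")
  sample.int(n_transitions, batch_size, replace = TRUE, prob = w)
}

## ---- network ----------------------------------------------------------

# logits: [n x (9 * N)] action-major blocks; returns probs same shape
c51_probs <- function(logits, n_actions, n_atoms) {
  p <- logits
  for (a in seq_len(n_actions)) {
    cols <- ((a - 1) * n_atoms + 1):(a * n_atoms)
    p[, cols] <- softmax_rows(logits[, cols, drop = FALSE])
  }
  p
}

# distributions for all actions: array [n, n_actions, n_atoms]
c51_dist_all <- function(params, states, n_actions, n_atoms,
                         activation = "relu") {
  logits <- mlp_forward(params, states, activation = activation)$out
  p <- c51_probs(logits, n_actions, n_atoms)
  aperm(array(p, c(nrow(p), n_atoms, n_actions)), c(1, 3, 2))
}

# expected values [n x n_actions] from the flat probability matrix
c51_q_from_probs <- function(p, atoms, n_actions, n_atoms) {
  vapply(seq_len(n_actions), function(a)
    as.vector(p[, ((a - 1) * n_atoms + 1):(a * n_atoms), drop = FALSE] %*% atoms),
    numeric(nrow(p)))
}

#' Train a categorical distributional Q-learning agent
#'
#' Offline (batch) C51: a multilayer perceptron maps the 41-dimensional
#' state to 9 per-action categorical distributions over `n_atoms` equally
#' spaced return atoms. Targets are the projected distributional Bellman
#' backup with double-Q action selection (online-network argmax, target
#' network distribution); terminal targets are the projected point mass at
#' the terminal reward. Batches are drawn by outcome-weighted sampling.
#'
#' @param dataset a `transition_dataset`.
#' @param gamma discount factor.
#' @param v_range support `(Vmin, Vmax)` of the return atoms.
#' @param n_atoms number of atoms (51).
#' @param hidden hidden-layer widths of the value network.
#' @param steps gradient steps.
#' @param batch_size batch size (100).
#' @param lr Adam learning rate.
#' @param target_every hard target-network update period (steps).
#' @param replay_weights per-transition sampling weights (e.g. from
#'   [calibrate_replay_weights()]); `NULL` = uniform.
#' @param activation hidden-unit activation of the value network
#'   (`"relu"` or `"tanh"`).
#' @param split train on `"train"` rows only (`"all"` uses everything).
#' @param seed RNG seed.
#' @param verbose print progress.
#' @return a `c51_agent` with `params`, `atoms`, `loss_trace` and config.
#' @export
fit_c51 <- function(dataset, gamma = 0.99, v_range = c(-16, 16),
                    n_atoms = 51, hidden = c(128, 128), steps = 4000,
                    batch_size = 100, lr = 1e-3, target_every = 500,
                    replay_weights = NULL, split = "train", seed = 1,
                    activation = "relu", verbose = FALSE) {
  stopifnot(gamma > 0, gamma <= 1, v_range[1] < v_range[2], batch_size >= 1)
  S <- dataset$states
  keep <- if (split == "all") rep(TRUE, nrow(S)) else dataset$split == split
  idx_keep <- which(keep)
  S <- S[idx_keep, , drop = FALSE]
  act <- dataset$action[idx_keep] + 1L
  rew <- dataset$reward[idx_keep]
  term <- dataset$terminal_type[idx_keep] != "none"
  nxt_global <- dataset$next_state[idx_keep]
  nxt <- match(nxt_global, idx_keep)    # next-state row within the kept set
  n_actions <- 9L
  atoms <- seq(v_range[1], v_range[2], length.out = n_atoms)
  w <- if (is.null(replay_weights)) rep(1, nrow(S)) else replay_weights[idx_keep]

  with_seed(seed, {
    params <- mlp_init(c(ncol(S), hidden, n_actions * n_atoms), out_scale = 0.01)
    target <- params
    opt <- adam_init(params)
    losses <- numeric(steps)
    for (stp in seq_len(steps)) {
      b <- weighted_sample(nrow(S), w, batch_size)
      sb <- S[b, , drop = FALSE]
      ab <- act[b]; rb <- rew[b]; tb <- term[b]
      m <- matrix(0, batch_size, n_atoms)
      if (any(!tb)) {
        ns <- S[nxt[b[!tb]], , drop = FALSE]
        p_on <- c51_probs(mlp_forward(params, ns, activation = activation)$out,
                          n_actions, n_atoms)
        q_on <- c51_q_from_probs(p_on, atoms, n_actions, n_atoms)
        if (is.null(dim(q_on))) q_on <- matrix(q_on, 1)
        astar <- max.col(q_on, ties.method = "first")
        p_tg <- c51_probs(mlp_forward(target, ns, activation = activation)$out,
                          n_actions, n_atoms)
        nn <- nrow(ns)
        cols_star <- rep((astar - 1) * n_atoms, each = n_atoms) +
          rep(seq_len(n_atoms), nn)
        ptarg <- matrix(p_tg[cbind(rep(seq_len(nn), each = n_atoms), cols_star)],
                        nn, n_atoms, byrow = TRUE)
        Tz <- outer(rb[!tb], rep(1, n_atoms)) + gamma *
          outer(rep(1, sum(!tb)), atoms)
        m[!tb, ] <- c51_project(atoms, Tz, ptarg)
      }
      if (any(tb)) {
        pm <- matrix(0, sum(tb), n_atoms); pm[, 1] <- 1
        m[tb, ] <- c51_project(atoms, matrix(rb[tb], sum(tb), n_atoms), pm)
      }
      fw <- mlp_forward(params, sb, activation = activation)
      logits <- fw$out
      dlog <- matrix(0, batch_size, n_actions * n_atoms)
      loss <- 0
      for (a in seq_len(n_actions)) {
        rows <- which(ab == a)
        if (!length(rows)) next
        cols <- ((a - 1) * n_atoms + 1):(a * n_atoms)
        pa <- softmax_rows(logits[rows, cols, drop = FALSE])
        loss <- loss - sum(m[rows, ] * log(pmax(pa, 1e-12)))
        dlog[rows, cols] <- (pa - m[rows, , drop = FALSE]) / batch_size
      }
      losses[stp] <- loss / batch_size
      if (!is.finite(losses[stp])) stop("fit_c51: non-finite loss at step ", stp)
      bk <- mlp_backward(params, fw, dlog)
      upd <- adam_step(params, bk$grads, opt, lr = lr)
      params <- upd$params; opt <- upd$state
      if (stp %% target_every == 0) target <- params
      if (verbose && stp %% 500 == 0)
        message(sprintf("step %5d  loss %.4f", stp, mean(losses[(stp - 499):stp])))
    }
    structure(list(params = params, atoms = atoms, n_actions = n_actions,
                   n_atoms = n_atoms, gamma = gamma, hidden = hidden,
                   activation = activation,
                   loss_trace = losses, batch_size = batch_size,
                   scaling = dataset$scaling,
                   feature_names = dataset$feature_names,
                   n_train = length(idx_keep), seed = seed),
              class = "c51_agent")
  })
}

#' @export
print.c51_agent <- function(x, ...) {
  cat("<c51_agent> ", x$n_atoms, " atoms on [", x$atoms[1], ", ",
      x$atoms[x$n_atoms], "], gamma = ", x$gamma, "\n", sep = "")
  cat("  trained ", length(x$loss_trace), " steps on ", x$n_train,
      " transitions; final loss ",
      sprintf("%.4f", mean(utils::tail(x$loss_trace, 100))), "\n", sep = "")
  invisible(x)
}

#' Per-action value distributions for a batch of states
#'
#' @param agent a `c51_agent`.
#' @param states numeric matrix of (already scaled) states, one per row.
#' @return array `[n, 9, n_atoms]` of categorical probabilities.
#' @export
c51_distributions <- function(agent, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  c51_dist_all(agent$params, states, agent$n_actions, agent$n_atoms,
               activation = agent$activation %||% "relu")
}

#' Expected values, greedy action and entropies from value distributions
#'
#' Summarizes categorical value distributions: per-action expected value
#' `Q(s,a) = sum_i z_i p_i`, the greedy action (ties broken toward the
#' lowest index), and the Shannon entropy of each distribution in nats.
#'
#' @param dist array `[n, n_actions, n_atoms]` (as from
#'   [c51_distributions()]) or a single `n_actions x n_atoms` matrix.
#' @param atoms the atom support.
#' @return list with `Q` (matrix n x actions), `greedy` (1-based action
#'   index), `entropy` (matrix n x actions), `V` (max Q).
#' @export
q_view <- function(dist, atoms) {
  if (length(dim(dist)) == 2) dist <- array(dist, c(1, dim(dist)))
  n <- dim(dist)[1]; A <- dim(dist)[2]
  Q <- matrix(0, n, A); H <- matrix(0, n, A)
  for (a in seq_len(A)) {
    p <- dist[, a, , drop = TRUE]
    if (n == 1) p <- matrix(p, 1)
    Q[, a] <- p %*% atoms
    H[, a] <- -rowSums(ifelse(p > 0, p * log(p), 0))
  }
  list(Q = Q, greedy = max.col(Q, ties.method = "first"),
       entropy = H, V = apply(Q, 1, max))
}

#' @rdname q_view
#' @param object a `c51_agent`.
#' @param states scaled state matrix.
#' @param ... unused.
#' @export
predict.c51_agent <- function(object, states, ...) {
  q_view(c51_distributions(object, states), object$atoms)
}
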