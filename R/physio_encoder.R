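#' Randomly zero out elements of an observation history
#'
#' The denoising corruption used when training the autoencoders: each element
#' is independently zeroed with probability `prob` (a Bernoulli keep mask).
#' Training draws the probability from the 10--25% range; evaluation can
#' corrupt at any fixed level.
#'
#' @param x numeric vector, matrix or array.
#' @param prob corruption probability in `[0, 1)`.
#' @param seed optional seed for a reproducible mask.
#' @return object of the same shape with a random subset of entries zeroed.
#' @examples
#' corrupt_history(matrix(1, 4, 4), prob = 0.5, seed = 1)
#' @export
corrupt_history <- function(x, prob, seed = NULL) {
  if (!is.numeric(prob) || length(prob) != 1 || prob < 0 || prob >= 1)
    stop("corrupt_history: prob must lie in [0, 1)")
  if (prob == 0) return(x)
  with_seed(seed, {
    keep <- stats::rbinom(length(x), 1L, 1 - prob)
    x * array(keep, dim = dim(x) %||% length(x))
  })
}

## ---- internal: tensorize a cohort for sequence training ----------------

physio_channels <- c("hr", "sbp", "dbp", "map", "temp", "spo2", "rr",
                     "sofa", "liver", "renal", "cns", "cardio")

# forward-fill NAs down each column within a patient block, then column means
ffill_matrix <- function(M) {
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    na <- is.na(v)
    if (any(na)) {
      idx <- cumsum(!na)
      v <- c(NA, v[!na])[idx + 1L]
      v[is.na(v)] <- mean(M[, j], na.rm = TRUE)
      M[, j] <- v
    }
  }
  M
}

# Returns arrays: X [n, Tmax, 12] standardized inputs, A [n, Tmax] action
# index, Y [n, Tmax, 4] reconstruction targets (sbp, dbp, map, hr), D [n, 3]
# standardized demographics, len [n], pid [n]. Scaling moments are taken as
# given (train-split moments) or computed.
physio_tensorize <- function(obs, scaling = NULL) {
  stopifnot(all(c(physio_channels, "action", "age", "gender", "weight",
                  "patient_id", "hour") %in% names(obs)))
  obs <- obs[order(obs$patient_id, obs$hour), ]
  pid <- unique(obs$patient_id)
  n <- length(pid)
  len <- as.integer(table(factor(obs$patient_id, levels = pid)))
  Tmax <- max(len)
  Xall <- as.matrix(obs[physio_channels])
  ## per-patient forward fill of missing entries
  ends <- cumsum(len); starts <- ends - len + 1L
  for (p in which(vapply(seq_len(n), function(p)
    anyNA(Xall[starts[p]:ends[p], ]), logical(1))))
    Xall[starts[p]:ends[p], ] <- ffill_matrix(Xall[starts[p]:ends[p], , drop = FALSE])
  Yall <- Xall[, c("sbp", "dbp", "map", "hr")]
  dem <- as.matrix(obs[match(pid, obs$patient_id), c("age", "gender", "weight")])
  dem[is.na(dem[, "weight"]), "weight"] <- mean(dem[, "weight"], na.rm = TRUE)
  if (is.null(scaling))
    scaling <- list(x_mu = colMeans(Xall), x_sd = scale_sd(Xall),
                    d_mu = colMeans(dem), d_sd = scale_sd(dem))
  Xstd <- sweep(sweep(Xall, 2, scaling$x_mu), 2, scaling$x_sd, "/")
  Dstd <- sweep(sweep(dem, 2, scaling$d_mu), 2, scaling$d_sd, "/")
  X <- array(0, c(n, Tmax, length(physio_channels)))
  Y <- array(0, c(n, Tmax, 4L))
  A <- matrix(1L, n, Tmax)
  for (p in seq_len(n)) {
    rows <- starts[p]:ends[p]
    X[p, seq_len(len[p]), ] <- Xstd[rows, ]
    Y[p, seq_len(len[p]), ] <- Yall[rows, ]
    A[p, seq_len(len[p])] <- as.integer(obs$action[rows]) + 1L
  }
  list(X = X, A = A, Y = Y, D = Dstd, len = len, pid = pid,
       scaling = scaling, Tmax = Tmax)
}

## ---- internal: forward / backward over a patient batch ----------------

# params: pe (MLP demographics -> 4), gru, tr (MLP [z, action, h] -> 4);
# offsets off (softplus-inverse baselines) and per-component scales sc.
physio_forward <- function(params, X, A, Y, len, D, corrupt_prob = 0,
                           keep_cache = TRUE) {
  nb <- dim(X)[1]; Tt <- dim(X)[2]; nh <- ncol(params$gru$Ur)
  off <- params$off; sc <- params$sc
  pe <- mlp_forward(params$pe, D)
  z <- pe$out
  H <- matrix(0, nb, nh)
  caches <- if (keep_cache) vector("list", Tt)
  states <- vector("list", Tt)
  preds <- vector("list", Tt)
  loss <- 0
  nvalid <- sum(len)
  for (t in seq_len(Tt)) {
    mask <- as.numeric(len >= t)
    Xt <- X[, t, , drop = TRUE]
    if (nb == 1L) Xt <- matrix(Xt, 1L)
    if (corrupt_prob > 0)
      Xt <- Xt * matrix(stats::rbinom(length(Xt), 1L, 1 - corrupt_prob), nb)
    g <- gru_cell_forward(params$gru, Xt, H)
    H <- g$H1
    tr_in <- cbind(z, one_hot(A[, t], 9L), H)
    trf <- mlp_forward(params$tr, tr_in)
    z1 <- z + trf$out
    pre <- sweep(z1, 2, sc, "*") + rep(off, each = nb)
    st <- data.frame(R = softplus(pre[, 1]), C = softplus(pre[, 2]),
                     SV = softplus(pre[, 3]), T = softplus(pre[, 4]))
    dec <- wk_decode(st)
    Ot <- cbind(dec$Psys, dec$Pdias, dec$Pmap, 60 / st$T)
    Yt <- Y[, t, , drop = TRUE]
    if (nb == 1L) Yt <- matrix(Yt, 1L)
    err <- Ot - Yt
    loss <- loss + sum(mask * rowSums(err^2))
    if (keep_cache)
      caches[[t]] <- list(gru = g$cache, tr = trf, z_prev = z, pre = pre,
                          st = st, err = err, mask = mask)
    z <- z1
    states[[t]] <- st
    preds[[t]] <- Ot
  }
  list(loss = loss / nvalid, caches = caches, pe = pe, states = states,
       preds = preds, nvalid = nvalid)
}

physio_backward <- function(params, fwd, X, A, len) {
  nb <- dim(X)[1]; Tt <- dim(X)[2]
  off <- params$off; sc <- params$sc
  g_pe <- tree_zeros_like(params$pe)
  g_gru <- tree_zeros_like(params$gru)
  g_tr <- tree_zeros_like(params$tr)
  dz_next <- matrix(0, nb, 4L)
  dH_carry <- matrix(0, nb, ncol(params$gru$Ur))
  for (t in rev(seq_len(Tt))) {
    ca <- fwd$caches[[t]]
    dO <- 2 * ca$err * ca$mask / fwd$nvalid     # [nb x 4]
    J <- wk_decode_grad(ca$st)
    dpar <- vapply(c("R", "C", "SV", "T"), function(p)
      dO[, 1] * J$Psys[[p]] + dO[, 2] * J$Pdias[[p]] + dO[, 3] * J$Pmap[[p]] +
        dO[, 4] * (if (p == "T") -60 / ca$st$T^2 else 0),
      numeric(nb))
    if (nb == 1L) dpar <- matrix(dpar, 1L)
    dz1 <- dpar * sigmoid(ca$pre) * rep(sc, each = nb) + dz_next
    trb <- mlp_backward(params$tr, ca$tr, dz1)
    g_tr <- tree_add(g_tr, trb$grads)
    dz_prev <- dz1 + trb$dX[, 1:4, drop = FALSE]
    dH <- trb$dX[, 14:ncol(trb$dX), drop = FALSE] + dH_carry
    gb <- gru_cell_backward(params$gru, ca$gru, dH)
    g_gru <- tree_add(g_gru, gb$grads)
    dH_carry <- gb$dH
    dz_next <- dz_prev
  }
  peb <- mlp_backward(params$pe, fwd$pe, dz_next)
  g_pe <- tree_add(g_pe, peb$grads)
  list(pe = g_pe, gru = g_gru, tr = g_tr,
       off = numeric(4), sc = numeric(4))    # offsets/scales are fixed
}

## ---- fitting ----------------------------------------------------------

#' Fit the physiology-driven denoising recurrent autoencoder
#'
#' Trains the three-network encoder (patient encoder on demographics, GRU
#' over the corrupted vitals/scores history, transition network combining
#' previous latent state, action and history summary) whose fixed decoder is
#' the Windkessel pressure model [wk_decode()]. The latent cardiovascular
#' state is parameterized as a softplus of baseline-plus-deviation, so
#' positivity holds by construction. The reconstruction target is the
#' four observables (systolic, diastolic, mean pressure, heart rate); the
#' loss is the squared error summed over the four outputs and averaged per
#' time step. Inputs are zeroed element-wise with a corruption probability
#' drawn uniformly from `corruption` each batch.
#'
#' @param cohort an `icu_cohort` (or a data frame in the cohort observation
#'   schema).
#' @param gru_hidden GRU hidden width.
#' @param mlp_hidden width of the patient-encoder and transition perceptrons.
#' @param corruption length-2 range of training corruption probabilities.
#' @param epochs training epochs.
#' @param batch_patients minibatch size in patients.
#' @param lr Adam learning rate.
#' @param clip_norm global gradient-norm clip (stabilizes backprop through
#'   time on long sequences).
#' @param val_frac fraction of patients held out (split by patient).
#' @param baselines named vector of fixed baselines `R0, C0, SV0, F0`
#'   (textbook adult values); the network learns deviations from these.
#' @param dev_scale per-component deviation scales on `(R, C, SV, T)`.
#' @param seed RNG seed for the split, initialization and corruption.
#' @param verbose print per-epoch losses.
#' @return a `physio_encoder` object with elements `params`, `scaling`,
#'   `loss_trace` (per-epoch training loss and validation MSE on
#'   uncorrupted input), `val_pid`, and the configuration used.
#' @seealso [predict.physio_encoder()], [reconstruction_mse()]
#' @export
fit_physio_encoder <- function(cohort, gru_hidden = 64, mlp_hidden = 64,
                               corruption = c(0.10, 0.25), epochs = 20,
                               batch_patients = 128, lr = 2e-3,
                               clip_norm = 5, val_frac = 0.2,
                               baselines = c(R = 1.0, C = 2.0, SV = 70, F = 75),
                               dev_scale = c(R = 0.5, C = 0.5, SV = 20, T = 0.2),
                               seed = 1, verbose = FALSE) {
  obs <- if (inherits(cohort, "icu_cohort")) cohort$obs else cohort
  stopifnot(nrow(obs) > 0, all(corruption >= 0), all(corruption < 1))
  with_seed(seed, {
    tz <- physio_tensorize(obs)
    n <- length(tz$pid)
    n_val <- max(1L, round(val_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    ## refit scaling on the training split only
    tz <- physio_tensorize(obs[obs$patient_id %in% tz$pid[tr_idx], ])
    tzv <- physio_tensorize(obs[!obs$patient_id %in% tz$pid, ], scaling = tz$scaling)

    off <- softplus_inv(c(baselines["R"], baselines["C"], baselines["SV"],
                          60 / baselines["F"]))
    params <- list(
      pe = mlp_init(c(3L, mlp_hidden, mlp_hidden, 4L), out_scale = 0.05),
      gru = gru_init(length(physio_channels), gru_hidden),
      tr = mlp_init(c(4L + 9L + gru_hidden, mlp_hidden, mlp_hidden, 4L),
                    out_scale = 0.05),
      off = unname(off), sc = unname(dev_scale))
    opt <- adam_init(params)
    ntr <- dim(tz$X)[1]
    trace <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_mse = numeric())
    for (ep in seq_len(epochs)) {
      ord <- sample.int(ntr)
      ep_loss <- 0; nb_total <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_patients))) {
        cp <- stats::runif(1, corruption[1], corruption[2])
        fwd <- physio_forward(params, tz$X[b, , , drop = FALSE],
                              tz$A[b, , drop = FALSE],
                              tz$Y[b, , , drop = FALSE], tz$len[b],
                              tz$D[b, , drop = FALSE], corrupt_prob = cp)
        if (!is.finite(fwd$loss))
          stop("fit_physio_encoder: non-finite loss at epoch ", ep,
               " (diverged; lower lr)")
        gr <- physio_backward(params, fwd, tz$X[b, , , drop = FALSE],
                              tz$A[b, , drop = FALSE], tz$len[b])
        gr <- tree_clip_norm(gr, clip_norm)
        stp <- adam_step(params, gr, opt, lr = lr)
        params <- stp$params; opt <- stp$state
        ep_loss <- ep_loss + fwd$loss * sum(tz$len[b]); nb_total <- nb_total + sum(tz$len[b])
      }
      val <- physio_forward(params, tzv$X, tzv$A, tzv$Y, tzv$len, tzv$D,
                            corrupt_prob = 0, keep_cache = FALSE)
      trace <- rbind(trace, data.frame(epoch = ep, train_loss = ep_loss / nb_total,
                                       val_mse = val$loss))
      if (verbose)
        message(sprintf("epoch %3d  train %8.2f  val %8.2f", ep,
                        ep_loss / nb_total, val$loss))
    }
    structure(list(params = params, scaling = tz$scaling,
                   loss_trace = trace, val_pid = tzv$pid,
                   baselines = baselines, dev_scale = dev_scale,
                   corruption = corruption, seed = seed),
              class = "physio_encoder")
  })
}

#' @export
print.physio_encoder <- function(x, ...) {
  lt <- x$loss_trace
  cat("<physio_encoder> GRU(", ncol(x$params$gru$Ur), ") + MLPs; ",
      nrow(lt), " epochs\n", sep = "")
  if (nrow(lt))
    cat(sprintf("  final train loss %.2f, val MSE/step %.2f (uncorrupted)\n",
                lt$train_loss[nrow(lt)], lt$val_mse[nrow(lt)]))
  invisible(x)
}

#' Infer latent cardiovascular states and reconstructions
#'
#' Runs the trained encoder over (optionally corrupted) observation
#' histories and returns one [cardio_state()] per patient-hour together with
#' the decoded reconstruction of `(Psys, Pdias, Pmap, F)`.
#'
#' @param object a fitted `physio_encoder`.
#' @param cohort an `icu_cohort` or observation data frame.
#' @param corruption evaluation-time corruption probability (default 0).
#' @param seed seed for the corruption mask.
#' @param ... unused.
#' @return data frame aligned with the patient-hours: `patient_id`, `hour`,
#'   the inferred `R, C, SV, F, T`, the identifiable combinations
#'   `RC, SV_over_C, SV_times_R, CO`, and reconstructed
#'   `Psys_hat, Pdias_hat, Pmap_hat, F_hat`.
#' @export
predict.physio_encoder <- function(object, cohort, corruption = 0,
                                   seed = NULL, ...) {
  obs <- if (inherits(cohort, "icu_cohort")) cohort$obs else cohort
  obs <- obs[order(obs$patient_id, obs$hour), ]
  tz <- physio_tensorize(obs, scaling = object$scaling)
  fwd <- with_seed(seed,
    physio_forward(object$params, tz$X, tz$A, tz$Y, tz$len, tz$D,
                   corrupt_prob = corruption, keep_cache = FALSE))
  rows <- lapply(seq_along(fwd$states), function(t) {
    keep <- which(tz$len >= t)
    st <- fwd$states[[t]][keep, ]
    cbind(data.frame(patient_id = tz$pid[keep], hour = t), st,
          Psys_hat = fwd$preds[[t]][keep, 1], Pdias_hat = fwd$preds[[t]][keep, 2],
          Pmap_hat = fwd$preds[[t]][keep, 3], F_hat = fwd$preds[[t]][keep, 4])
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$patient_id, res$hour), ]
  rownames(res) <- NULL
  res$F <- 60 / res$T
  res$RC <- res$R * res$C
  res$SV_over_C <- res$SV / res$C
  res$SV_times_R <- res$SV * res$R
  res$CO <- res$SV * res$F
  res
}

#' Reconstruction error at chosen corruption levels
#'
#' Evaluates the per-time-step reconstruction MSE (squared error summed over
#' the four outputs, averaged over patient-hours) at each evaluation-time
#' corruption probability. For a trained model this is non-decreasing in the
#' corruption level.
#'
#' @param object a fitted `physio_encoder`.
#' @param cohort cohort to evaluate on.
#' @param levels corruption probabilities.
#' @param seed seed for the corruption masks.
#' @return data frame with columns `corruption`, `mse_per_step`.
#' @export
reconstruction_mse <- function(object, cohort, levels = c(0, 0.25, 0.5),
                               seed = 1) {
  obs <- if (inherits(cohort, "icu_cohort")) cohort$obs else cohort
  tz <- physio_tensorize(obs[order(obs$patient_id, obs$hour), ],
                         scaling = object$scaling)
  mse <- vapply(seq_along(levels), function(i) with_seed(seed + i,
    physio_forward(object$params, tz$X, tz$A, tz$Y, tz$len, tz$D,
                   corrupt_prob = levels[i], keep_cache = FALSE)$loss),
    numeric(1))
  data.frame(corruption = levels, mse_per_step = mse)
}
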