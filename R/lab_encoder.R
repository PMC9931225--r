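lab_channels <- c("anion_gap", "bicarbonate", "creatinine", "chloride",
                  "glucose", "hematocrit", "hemoglobin", "platelet",
                  "potassium", "sodium", "bun", "wbc")

lab_tensorize <- function(labs, scaling = NULL) {
  stopifnot(all(c("patient_id", "hour", lab_channels) %in% names(labs)))
  labs <- labs[order(labs$patient_id, labs$hour), ]
  pid <- unique(labs$patient_id)
  n <- length(pid)
  len <- as.integer(table(factor(labs$patient_id, levels = pid)))
  Tmax <- max(len)
  Xall <- as.matrix(labs[lab_channels])
  ends <- cumsum(len); starts <- ends - len + 1L
  for (p in which(vapply(seq_len(n), function(p)
    anyNA(Xall[starts[p]:ends[p], ]), logical(1))))
    Xall[starts[p]:ends[p], ] <- ffill_matrix(Xall[starts[p]:ends[p], , drop = FALSE])
  if (is.null(scaling))
    scaling <- list(mu = colMeans(Xall), sd = scale_sd(Xall))
  Xstd <- sweep(sweep(Xall, 2, scaling$mu), 2, scaling$sd, "/")
  X <- array(0, c(n, Tmax, length(lab_channels)))
  for (p in seq_len(n)) X[p, seq_len(len[p]), ] <- Xstd[starts[p]:ends[p], ]
  list(X = X, len = len, pid = pid, scaling = scaling, Tmax = Tmax)
}

# forward through the GRU stack; returns per-step reconstructions, the
# representation (last layer's hidden sequence) and caches for backprop
lab_forward <- function(params, X, len, corrupt_prob = 0, keep_cache = TRUE) {
  nb <- dim(X)[1]; Tt <- dim(X)[2]
  nl <- length(params$grus)
  H <- lapply(params$grus, function(g) matrix(0, nb, ncol(g$Ur)))
  caches <- if (keep_cache) vector("list", Tt)
  rep_seq <- vector("list", Tt)
  loss <- 0
  nvalid <- sum(len)
  for (t in seq_len(Tt)) {
    mask <- as.numeric(len >= t)
    Xt <- X[, t, , drop = TRUE]
    if (nb == 1L) Xt <- matrix(Xt, 1L)
    inp <- Xt
    if (corrupt_prob > 0)
      inp <- inp * matrix(stats::rbinom(length(inp), 1L, 1 - corrupt_prob), nb)
    layer_caches <- vector("list", nl)
    cur <- inp
    for (l in seq_len(nl)) {
      g <- gru_cell_forward(params$grus[[l]], cur, H[[l]])
      H[[l]] <- g$H1
      layer_caches[[l]] <- g$cache
      cur <- g$H1
    }
    rec <- add_bias(cur %*% params$head$W, params$head$b)
    err <- (rec - Xt) * mask
    loss <- loss + sum(err^2)
    if (keep_cache) caches[[t]] <- list(layers = layer_caches, top = cur, err = err)
    rep_seq[[t]] <- cur
  }
  list(loss = loss / nvalid, caches = caches, rep_seq = rep_seq, nvalid = nvalid)
}

lab_backward <- function(params, fwd) {
  nl <- length(params$grus)
  Tt <- length(fwd$caches)
  g_grus <- lapply(params$grus, tree_zeros_like)
  g_head <- tree_zeros_like(params$head)
  dH_carry <- lapply(params$grus, function(g)
    matrix(0, nrow(fwd$caches[[1]]$err), ncol(g$Ur)))
  for (t in rev(seq_len(Tt))) {
    ca <- fwd$caches[[t]]
    dRec <- 2 * ca$err / fwd$nvalid
    g_head$W <- g_head$W + crossprod(ca$top, dRec)
    g_head$b <- g_head$b + colSums(dRec)
    dTop <- tcrossprod(dRec, params$head$W)
    for (l in rev(seq_len(nl))) {
      dH <- dH_carry[[l]] + dTop
      gb <- gru_cell_backward(params$grus[[l]], ca$layers[[l]], dH)
      g_grus[[l]] <- tree_add(g_grus[[l]], gb$grads)
      dH_carry[[l]] <- gb$dH
      dTop <- gb$dX          # gradient into the layer below's hidden output
    }
  }
  list(grus = g_grus, head = g_head)
}

#' Fit the denoising stacked recurrent autoencoder for lab history
#'
#' Labs arrive roughly every 12 hours and are carried forward in between;
#' this autoencoder compresses the 12-channel lab history into a
#' 10-dimensional per-hour representation. Three GRU layers with strictly
#' decreasing widths are stacked; the last (10-unit) hidden sequence is the
#' representation and a linear head reconstructs the full 12-channel input.
#' Training corrupts the input by element-wise zeroing with a probability
#' ramped linearly from 0 to `corruption_max` over the epochs; the
#' reconstruction target is always the uncorrupted window.
#'
#' @param cohort an `icu_cohort` or a lab data frame (`patient_id`, `hour`,
#'   12 lab columns).
#' @param widths GRU widths, strictly decreasing, last one 10.
#' @param corruption_max endpoint of the corruption ramp.
#' @param epochs,batch_patients,lr training controls.
#' @param clip_norm global gradient-norm clip.
#' @param seed RNG seed.
#' @param verbose print per-epoch loss.
#' @return a `lab_encoder` with `params`, `scaling` and `loss_trace`.
#' @export
fit_lab_encoder <- function(cohort, widths = c(64, 32, 10),
                            corruption_max = 0.5, epochs = 15,
                            batch_patients = 128, lr = 3e-3, clip_norm = 5,
                            seed = 1, verbose = FALSE) {
  labs <- if (inherits(cohort, "icu_cohort")) cohort$labs else cohort
  stopifnot(length(widths) >= 2, all(diff(widths) < 0),
            widths[length(widths)] == 10,
            corruption_max >= 0, corruption_max < 1)
  with_seed(seed, {
    tz <- lab_tensorize(labs)
    nin <- length(lab_channels)
    params <- list(
      grus = lapply(seq_along(widths), function(l)
        gru_init(if (l == 1) nin else widths[l - 1], widths[l])),
      head = dense_init(widths[length(widths)], nin))
    opt <- adam_init(params)
    n <- dim(tz$X)[1]
    trace <- data.frame(epoch = integer(), corruption = numeric(),
                        train_loss = numeric())
    for (ep in seq_len(epochs)) {
      cp <- if (epochs == 1) corruption_max else
        corruption_max * (ep - 1) / (epochs - 1)
      ord <- sample.int(n)
      ep_loss <- 0; tot <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_patients))) {
        fwd <- lab_forward(params, tz$X[b, , , drop = FALSE], tz$len[b],
                           corrupt_prob = cp)
        if (!is.finite(fwd$loss))
          stop("fit_lab_encoder: non-finite loss at epoch ", ep)
        gr <- tree_clip_norm(lab_backward(params, fwd), clip_norm)
        stp <- adam_step(params, gr, opt, lr = lr)
        params <- stp$params; opt <- stp$state
        ep_loss <- ep_loss + fwd$loss * sum(tz$len[b]); tot <- tot + sum(tz$len[b])
      }
      trace <- rbind(trace, data.frame(epoch = ep, corruption = cp,
                                       train_loss = ep_loss / tot))
      if (verbose) message(sprintf("epoch %3d  corrupt %.2f  loss %.4f",
                                   ep, cp, ep_loss / tot))
    }
    structure(list(params = params, scaling = tz$scaling, widths = widths,
                   loss_trace = trace, seed = seed),
              class = "lab_encoder")
  })
}

#' @export
print.lab_encoder <- function(x, ...) {
  cat("<lab_encoder> GRU stack ", paste(x$widths, collapse = " -> "),
      "; final loss ",
      sprintf("%.4f", utils::tail(x$loss_trace$train_loss, 1)), "\n", sep = "")
  invisible(x)
}

#' Encode lab histories into the 10-dimensional representation
#'
#' Inference is deterministic: the uncorrupted input is passed through the
#' GRU stack and the last layer's hidden state at each hour is returned.
#'
#' @param object a fitted `lab_encoder`.
#' @param cohort an `icu_cohort` or lab data frame.
#' @param ... unused.
#' @return data frame `patient_id`, `hour`, `l1 ... l10`.
#' @export
predict.lab_encoder <- function(object, cohort, ...) {
  labs <- if (inherits(cohort, "icu_cohort")) cohort$labs else cohort
  labs <- labs[order(labs$patient_id, labs$hour), ]
  tz <- lab_tensorize(labs, scaling = object$scaling)
  fwd <- lab_forward(object$params, tz$X, tz$len, corrupt_prob = 0,
                     keep_cache = FALSE)
  rows <- lapply(seq_along(fwd$rep_seq), function(t) {
    keep <- which(tz$len >= t)
    rp <- fwd$rep_seq[[t]][keep, , drop = FALSE]
    colnames(rp) <- paste0("l", seq_len(ncol(rp)))
    cbind(data.frame(patient_id = tz$pid[keep], hour = t), rp)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$patient_id, res$hour), ]
  rownames(res) <- NULL
  res
}

#' @rdname predict.lab_encoder
#' @param model a fitted `lab_encoder`.
#' @export
encode_labs <- function(model, cohort) predict(model, cohort)
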