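# Minimal neural-network core: dense/GRU layers with hand-written backward
# passes and an Adam optimizer. Parameters and gradients are nested lists of
# numeric arrays with identical structure ("trees"). All forward functions
# take row-major design matrices (one sample per row). Gradient correctness
# is pinned down by finite-difference checks in the test suite.

## ---- tree utilities ---------------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_add <- function(a, b) tree_map2(`+`, a, b)
tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

tree_sq_norm <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_sq_norm, numeric(1))) else sum(a^2)
}

# rescale the whole gradient tree to a maximum global L2 norm; non-finite
# entries (overflowed batches) are zeroed before the norm is taken
tree_clip_norm <- function(g, max_norm) {
  nrm <- sqrt(tree_sq_norm(g))
  if (!is.finite(nrm)) {
    g <- tree_map(function(x) ifelse(is.finite(x), x, 0), g)
    nrm <- sqrt(tree_sq_norm(g))
  }
  if (nrm > max_norm) tree_map(function(x) x * max_norm / nrm, g) else g
}

# column SDs for z-scoring; channels constant in the reference split get
# unit scale instead of a tiny floor (which would explode off-split values)
scale_sd <- function(M) {
  s <- apply(M, 2, stats::sd)
  ifelse(!is.finite(s) | s < 1e-8, 1, s)
}

## ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps), state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  if (weight_decay > 0)
    params <- tree_map(function(p) p * (1 - lr * weight_decay), params)
  list(params = params, state = state)
}

## ---- dense / MLP ------------------------------------------------------

# add a bias row-vector to every row of M
add_bias <- function(M, b) M + rep(b, each = nrow(M))

dense_init <- function(n_in, n_out, scale = 1 / sqrt(n_in)) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out),
       b = numeric(n_out))
}

# sizes: c(n_in, hidden..., n_out); tanh hidden units, linear output.
# out_scale shrinks the final layer's init so untrained outputs start small.
mlp_init <- function(sizes, out_scale = 1) {
  L <- length(sizes) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    sc <- 1 / sqrt(sizes[l])
    if (l == L) sc <- sc * out_scale
    layers[[l]] <- dense_init(sizes[l], sizes[l + 1L], sc)
  }
  layers
}

mlp_forward <- function(layers, X, activation = "tanh") {
  L <- length(layers)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- add_bias(acts[[l]] %*% layers[[l]]$W, layers[[l]]$b)
    acts[[l + 1L]] <- if (l < L) {
      if (activation == "relu") pmax(Z, 0) else tanh(Z)
    } else Z
  }
  list(out = acts[[L + 1L]], acts = acts, activation = activation)
}

mlp_backward <- function(layers, cache, dOut) {
  L <- length(layers)
  relu <- identical(cache$activation, "relu")
  grads <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    A_in <- cache$acts[[l]]
    if (l < L) {
      A_out <- cache$acts[[l + 1L]]
      dZ <- if (relu) dA * (A_out > 0) else dA * (1 - A_out^2)
    } else dZ <- dA                      # linear output
    grads[[l]] <- list(W = crossprod(A_in, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[l]]$W)
  }
  list(grads = grads, dX = dA)
}

## ---- GRU cell ---------------------------------------------------------

gru_init <- function(n_in, n_h) {
  si <- 1 / sqrt(n_in); sh <- 1 / sqrt(n_h)
  list(Wr = matrix(stats::rnorm(n_in * n_h, sd = si), n_in, n_h),
       Ur = matrix(stats::rnorm(n_h * n_h, sd = sh), n_h, n_h),
       br = numeric(n_h),
       Wu = matrix(stats::rnorm(n_in * n_h, sd = si), n_in, n_h),
       Uu = matrix(stats::rnorm(n_h * n_h, sd = sh), n_h, n_h),
       bu = numeric(n_h),
       Wc = matrix(stats::rnorm(n_in * n_h, sd = si), n_in, n_h),
       Uc = matrix(stats::rnorm(n_h * n_h, sd = sh), n_h, n_h),
       bc = numeric(n_h))
}

# one GRU step: X [n x d], H [n x h] -> H1 [n x h]
gru_cell_forward <- function(p, X, H) {
  r <- sigmoid(add_bias(X %*% p$Wr + H %*% p$Ur, p$br))
  u <- sigmoid(add_bias(X %*% p$Wu + H %*% p$Uu, p$bu))
  rH <- r * H
  cc <- tanh(add_bias(X %*% p$Wc + rH %*% p$Uc, p$bc))
  H1 <- u * H + (1 - u) * cc
  list(H1 = H1, cache = list(X = X, H = H, r = r, u = u, cc = cc, rH = rH))
}

gru_cell_backward <- function(p, cache, dH1) {
  X <- cache$X; H <- cache$H; r <- cache$r; u <- cache$u; cc <- cache$cc
  du <- dH1 * (H - cc)
  dcc <- dH1 * (1 - u)
  dH <- dH1 * u
  dAc <- dcc * (1 - cc^2)
  drH <- tcrossprod(dAc, p$Uc)
  dr <- drH * H
  dH <- dH + drH * r
  dAu <- du * u * (1 - u)
  dAr <- dr * r * (1 - r)
  dH <- dH + tcrossprod(dAu, p$Uu) + tcrossprod(dAr, p$Ur)
  dX <- tcrossprod(dAr, p$Wr) + tcrossprod(dAu, p$Wu) + tcrossprod(dAc, p$Wc)
  grads <- list(Wr = crossprod(X, dAr), Ur = crossprod(H, dAr), br = colSums(dAr),
                Wu = crossprod(X, dAu), Uu = crossprod(H, dAu), bu = colSums(dAu),
                Wc = crossprod(X, dAc), Uc = crossprod(cache$rH, dAc), bc = colSums(dAc))
  list(grads = grads, dX = dX, dH = dH)
}

## ---- misc -------------------------------------------------------------

one_hot <- function(idx, n) {
  # idx: 1-based integer vector
  M <- matrix(0, length(idx), n)
  M[cbind(seq_along(idx), idx)] <- 1
  M
}
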