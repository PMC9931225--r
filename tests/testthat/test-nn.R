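# Finite-difference verification of the hand-written backward passes.

`%||%` <- sepsisrl:::`%||%`

num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

test_that("MLP backward matches finite differences", {
  set.seed(1)
  layers <- sepsisrl:::mlp_init(c(4, 5, 3))
  X <- matrix(rnorm(6 * 4), 6)
  Y <- matrix(rnorm(6 * 3), 6)
  lossf <- function(l) {
    out <- sepsisrl:::mlp_forward(l, X)$out
    sum((out - Y)^2)
  }
  fw <- sepsisrl:::mlp_forward(layers, X)
  bk <- sepsisrl:::mlp_backward(layers, fw, 2 * (fw$out - Y))
  for (l in seq_along(layers)) for (nm in c("W", "b")) {
    ana <- bk$grads[[l]][[nm]]
    num <- num_grad(function(v) {
      l2 <- layers; l2[[l]][[nm]] <- array(v, dim = dim(l2[[l]][[nm]]) %||% length(v))
      lossf(l2)
    }, as.vector(layers[[l]][[nm]]))
    expect_equal(as.vector(ana), num, tolerance = 1e-5)
  }
  # input gradient
  numX <- num_grad(function(v) {
    sum((sepsisrl:::mlp_forward(layers, matrix(v, 6))$out - Y)^2)
  }, as.vector(X))
  expect_equal(as.vector(bk$dX), numX, tolerance = 1e-5)
})

test_that("GRU cell backward matches finite differences through two steps", {
  set.seed(2)
  p <- sepsisrl:::gru_init(3, 4)
  X1 <- matrix(rnorm(5 * 3), 5); X2 <- matrix(rnorm(5 * 3), 5)
  H0 <- matrix(rnorm(5 * 4), 5)
  tgt <- matrix(rnorm(5 * 4), 5)
  lossf <- function(pp) {
    s1 <- sepsisrl:::gru_cell_forward(pp, X1, H0)
    s2 <- sepsisrl:::gru_cell_forward(pp, X2, s1$H1)
    sum((s2$H1 - tgt)^2)
  }
  s1 <- sepsisrl:::gru_cell_forward(p, X1, H0)
  s2 <- sepsisrl:::gru_cell_forward(p, X2, s1$H1)
  b2 <- sepsisrl:::gru_cell_backward(p, s2$cache, 2 * (s2$H1 - tgt))
  b1 <- sepsisrl:::gru_cell_backward(p, s1$cache, b2$dH)
  tot <- sepsisrl:::tree_add(b2$grads, b1$grads)
  for (nm in names(p)) {
    num <- num_grad(function(v) {
      p2 <- p; p2[[nm]] <- array(v, dim = dim(p2[[nm]]) %||% length(v))
      lossf(p2)
    }, as.vector(p[[nm]]))
    expect_equal(as.vector(tot[[nm]]), num, tolerance = 1e-5,
                 label = paste("grad", nm))
  }
})

test_that("Windkessel decoder Jacobian matches finite differences", {
  st <- data.frame(R = c(0.8, 1.5), C = c(1.7, 2.4),
                   SV = c(55, 90), T = c(0.6, 1.0))
  J <- sepsisrl:::wk_decode_grad(st)
  eps <- 1e-7
  for (p in c("R", "C", "SV", "T")) for (o in c("Psys", "Pdias", "Pmap")) {
    s1 <- st; s1[[p]] <- s1[[p]] + eps
    s2 <- st; s2[[p]] <- s2[[p]] - eps
    num <- (wk_decode(s1)[[o]] - wk_decode(s2)[[o]]) / (2 * eps)
    expect_equal(J[[o]][[p]], num, tolerance = 1e-4,
                 label = paste("d", o, "/d", p))
  }
})

test_that("full autoencoder backward matches finite differences", {
  set.seed(42)
  nb <- 2; Tt <- 4
  X <- array(rnorm(nb * Tt * 12), c(nb, Tt, 12))
  A <- matrix(sample(1:9, nb * Tt, TRUE), nb, Tt)
  Y <- array(rnorm(nb * Tt * 4, mean = c(110, 70, 85, 75)), c(nb, Tt, 4))
  len <- c(4L, 3L)
  D <- matrix(rnorm(nb * 3), nb, 3)
  params <- list(pe = sepsisrl:::mlp_init(c(3, 5, 4), out_scale = 0.1),
                 gru = sepsisrl:::gru_init(12, 5),
                 tr = sepsisrl:::mlp_init(c(4 + 9 + 5, 5, 4), out_scale = 0.1),
                 off = sepsisrl:::softplus_inv(c(1, 2, 70, 0.8)),
                 sc = c(0.5, 0.5, 20, 0.2))
  lossf <- function(p) sepsisrl:::physio_forward(p, X, A, Y, len, D,
                                                 keep_cache = FALSE)$loss
  fwd <- sepsisrl:::physio_forward(params, X, A, Y, len, D)
  gr <- sepsisrl:::physio_backward(params, fwd, X, A, len)
  set.seed(7)
  for (comp in c("pe", "gru", "tr")) {
    for (k in seq_along(params[[comp]])) {
      leaf_names <- if (is.list(params[[comp]][[k]])) names(params[[comp]][[k]]) else NA
      for (lf in leaf_names) {
        v <- if (is.na(lf[1])) params[[comp]][[k]] else params[[comp]][[k]][[lf]]
        gv <- if (is.na(lf[1])) gr[[comp]][[k]] else gr[[comp]][[k]][[lf]]
        ii <- sample(length(v), min(3, length(v)))
        for (i in ii) {
          pert <- function(sign) {
            p2 <- params
            v2 <- v; v2[i] <- v2[i] + sign * 1e-6
            v2 <- array(v2, dim = dim(v) %||% length(v))
            if (is.na(lf[1])) p2[[comp]][[k]] <- v2
            else p2[[comp]][[k]][[lf]] <- v2
            p2
          }
          num <- (lossf(pert(1)) - lossf(pert(-1))) / 2e-6
          expect_equal(unname(gv[i]), num, tolerance = 1e-3)
        }
      }
    }
  }
})

test_that("lab autoencoder backward matches finite differences", {
  set.seed(5)
  nb <- 2; Tt <- 4
  X <- array(rnorm(nb * Tt * 12), c(nb, Tt, 12))
  len <- c(4L, 2L)
  params <- list(grus = list(sepsisrl:::gru_init(12, 6),
                             sepsisrl:::gru_init(6, 4)),
                 head = sepsisrl:::dense_init(4, 12))
  lossf <- function(p) sepsisrl:::lab_forward(p, X, len,
                                              keep_cache = FALSE)$loss
  fwd <- sepsisrl:::lab_forward(params, X, len)
  gr <- sepsisrl:::lab_backward(params, fwd)
  set.seed(8)
  for (l in seq_along(params$grus)) for (nm in names(params$grus[[l]])) {
    v <- params$grus[[l]][[nm]]
    ii <- sample(length(v), min(3, length(v)))
    for (i in ii) {
      pert <- function(sign) {
        p2 <- params
        v2 <- v; v2[i] <- v2[i] + sign * 1e-6
        p2$grus[[l]][[nm]] <- array(v2, dim = dim(v) %||% length(v))
        p2
      }
      num <- (lossf(pert(1)) - lossf(pert(-1))) / 2e-6
      expect_equal(gr$grus[[l]][[nm]][i], num, tolerance = 1e-4)
    }
  }
  numW <- num_grad(function(v) {
    p2 <- params; p2$head$W <- matrix(v, nrow(params$head$W))
    lossf(p2)
  }, as.vector(params$head$W))
  expect_equal(as.vector(gr$head$W), numW, tolerance = 1e-5)
})

test_that("Adam reduces a quadratic objective", {
  params <- list(w = c(5, -3))
  opt <- sepsisrl:::adam_init(params)
  for (i in 1:500) {
    g <- list(w = 2 * params$w)
    stp <- sepsisrl:::adam_step(params, g, opt, lr = 0.05)
    params <- stp$params; opt <- stp$state
  }
  expect_lt(sum(params$w^2), 1e-4)
})
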