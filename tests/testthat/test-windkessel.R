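test_that("decoder matches the closed-form pressures and the ODE oracle", {
  s <- cardio_state(R = 1, C = 2, SV = 70, T = 0.8)
  v <- wk_decode(s)
  # frozen from high-precision evaluation cross-checked against RK4
  # integration of the impulse-driven Windkessel ODE over 80 cycles
  expect_equal(v$Psys, 106.16357, tolerance = 1e-6)
  expect_equal(v$Pdias, 71.16357, tolerance = 1e-6)
  expect_equal(v$Pmap, 87.5)
  expect_equal(v$F, 75)

  skip_if_not_installed("deSolve")
  # independent numeric route: integrate dP/dt = -P/RC between impulses
  RC <- 2; T <- 0.8; jump <- 35; P <- 0
  for (cyc in 1:80) {
    sol <- deSolve::ode(c(P = P + jump), seq(0, T, by = T / 400),
                        function(t, y, p) list(-y / RC), NULL, method = "rk4")
    P <- unname(sol[nrow(sol), 2])
  }
  sol <- deSolve::ode(c(P = P + jump), seq(0, T, by = T / 2000),
                      function(t, y, p) list(-y / RC), NULL, method = "rk4")
  expect_equal(max(sol[, 2]), v$Psys, tolerance = 1e-6)
  expect_equal(unname(sol[nrow(sol), 2]), v$Pdias, tolerance = 1e-6)
  expect_equal(mean(sol[-nrow(sol), 2]), v$Pmap, tolerance = 1e-3)
})

test_that("pulse pressure is exactly SV/C and limits behave", {
  g <- wk_grid()
  v <- wk_decode(g)
  expect_equal(v$Psys - v$Pdias, g$SV / g$C, tolerance = 1e-12)
  # T/RC -> infinity: full runoff each beat
  s <- cardio_state(R = 0.01, C = 0.5, SV = 70, T = 2, F = 30)
  v2 <- wk_decode(s)
  expect_equal(v2$Psys, 70 / 0.5, tolerance = 1e-8)
  expect_lt(v2$Pdias, 1e-6)
})

test_that("analytic waveform simulator agrees with decode at steady state", {
  g <- wk_grid(3, 3, 3, 3)
  for (i in seq_len(nrow(g))) {
    s <- g[i, ]
    st <- wk_cycle_stats(s)
    v <- wk_decode(s)
    expect_equal(st$peak, v$Psys, tolerance = 1e-6)
    expect_equal(st$trough, v$Pdias, tolerance = 1e-4)
    expect_equal(st$mean, v$Pmap, tolerance = 1e-4)
  }
})

test_that("waveform scales linearly in SV and never decays when R is huge", {
  s1 <- cardio_state(R = 1, C = 2, SV = 70, T = 0.8)
  s2 <- cardio_state(R = 1, C = 2, SV = 140, T = 0.8)
  w1 <- wk_simulate(s1, 30); w2 <- wk_simulate(s2, 30)
  expect_equal(2 * w1$P, w2$P, tolerance = 1e-12)
  s3 <- cardio_state(R = 1e9, C = 2, SV = 70, T = 0.8)
  w3 <- wk_simulate(s3, 3)
  one_cycle <- w3$P[w3$time < s3$T]
  expect_lt(diff(range(one_cycle)), 1e-6 * one_cycle[1])
})

test_that("identifiable combinations invert the decoder on the grid", {
  g <- wk_grid()
  inv <- wk_invert(wk_decode(g))
  expect_equal(inv$RC, g$R * g$C, tolerance = 1e-9)
  expect_equal(inv$SV_over_C, g$SV / g$C, tolerance = 1e-9)
  expect_equal(inv$SV_times_R, g$SV * g$R, tolerance = 1e-9)
  # worked example
  one <- wk_invert(data.frame(Psys = 106.16357, Pdias = 71.16357,
                              Pmap = 87.5, F = 75))
  expect_equal(one$RC, 2, tolerance = 1e-6)
  expect_equal(one$SV_over_C, 35, tolerance = 1e-9)
  expect_equal(one$SV_times_R, 70, tolerance = 1e-9)
})

test_that("the scale family (kSV, kC, R/k) is unidentifiable by construction", {
  s <- cardio_state(R = 1.2, C = 1.8, SV = 65, F = 80)
  for (k in c(0.5, 2, 3.7)) {
    s2 <- cardio_state(R = s$R / k, C = s$C * k, SV = s$SV * k, F = s$F)
    expect_equal(wk_invert(wk_decode(s2))[c("RC", "SV_over_C", "SV_times_R")],
                 wk_invert(wk_decode(s))[c("RC", "SV_over_C", "SV_times_R")],
                 tolerance = 1e-9)
  }
})

test_that("pressures increase monotonically in SV and R", {
  SVs <- seq(40, 100, by = 10)
  v_sv <- wk_decode(cardio_state(R = 1, C = 2, SV = SVs, F = 75))
  expect_true(all(diff(v_sv$Psys) > 0))
  expect_true(all(diff(v_sv$Pmap) > 0))
  Rs <- seq(0.5, 2, by = 0.25)
  v_r <- wk_decode(cardio_state(R = Rs, C = 2, SV = 70, F = 75))
  expect_true(all(diff(v_r$Psys) > 0))
  expect_true(all(diff(v_r$Pmap) > 0))
})

test_that("cardiac output and constructor guard rails", {
  expect_equal(cardiac_output(cardio_state(R = 1, C = 2, SV = 70, F = 75)), 5250)
  s <- cardio_state(R = 1, C = 2, SV = 70, F = 75)
  expect_equal(cardiac_output(s) / s$F, s$SV)
  expect_error(cardio_state(R = 1, C = 2, SV = 0, F = 75), "positive")
  expect_error(cardio_state(R = -1, C = 2, SV = 70, F = 75), "positive")
  expect_error(cardio_state(R = 1, C = 2, SV = 70, F = 75, T = 1), "inconsistent")
  expect_error(wk_invert(data.frame(Psys = 80, Pdias = 90, Pmap = 85, F = 70)),
               "Psys > Pdias")
  expect_error(wk_simulate(cardio_state(R = 1, C = 2, SV = 70, T = 0.8),
                           n_cycles = 5, dt = 1), "dt")
})
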