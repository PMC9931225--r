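#' Cardiovascular latent state for the two-element Windkessel model
#'
#' Bundles the latent parameters of the lumped arterial circulation model:
#' systemic vascular resistance `R` (mmHg·s/mL), arterial capacitance `C`
#' (mL/mmHg), stroke volume `SV` (mL), heart rate `F` (beats/min) and filling
#' time `T` (s). Heart rate and filling time are redundant (`F = 60/T`) but
#' both are carried; the constructor enforces their consistency.
#'
#' @param R systemic vascular resistance, mmHg·s/mL; must be positive.
#' @param C arterial capacitance, mL/mmHg; must be positive.
#' @param SV stroke volume, mL; must be positive.
#' @param F heart rate, beats/min. Supply `F` or `T` (or both, consistently).
#' @param T filling time, s.
#' @return A `cardio_state` data frame with columns `R`, `C`, `SV`, `F`, `T`;
#'   one row per state. All arguments recycle.
#' @examples
#' s <- cardio_state(R = 1, C = 2, SV = 70, F = 75)
#' wk_decode(s)
#' @export
cardio_state <- function(R, C, SV, F = NULL, T = NULL) {
  if (is.null(F) && is.null(T)) stop("supply F (bpm) or T (s)")
  if (is.null(T)) T <- 60 / F
  if (is.null(F)) F <- 60 / T
  n <- max(length(R), length(C), length(SV), length(F), length(T))
  s <- data.frame(R = rep_len(R, n), C = rep_len(C, n), SV = rep_len(SV, n),
                  F = rep_len(F, n), T = rep_len(T, n))
  if (any(!is.finite(as.matrix(s)))) stop("cardio_state: non-finite parameter")
  if (any(s$R <= 0 | s$C <= 0 | s$SV <= 0 | s$T <= 0))
    stop("cardio_state: R, C, SV, T must all be positive")
  if (any(abs(s$F * s$T - 60) > 1e-6 * 60))
    stop("cardio_state: F and T inconsistent (need F*T = 60)")
  class(s) <- c("cardio_state", "data.frame")
  s
}

#' @export
print.cardio_state <- function(x, ...) {
  cat("<cardio_state> ", nrow(x), " state(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Windkessel pressure decoder
#'
#' The fixed decoder of the physiology-driven autoencoder: maps the latent
#' cardiovascular state to the observable systolic, diastolic and mean
#' arterial pressures, with heart rate passed through. With
#' `x = T/(R*C)`, systolic pressure is `SV/C / (1 - exp(-x))`, diastolic is
#' `SV/C * exp(-x) / (1 - exp(-x))` and mean arterial pressure is
#' `SV*R/T = SV*F*R/60`. Pulse pressure is therefore exactly `SV/C`.
#'
#' @param state a [cardio_state()] (or data frame with the same columns).
#' @return data frame with columns `Psys`, `Pdias`, `Pmap` (mmHg), `F` (bpm).
#' @examples
#' wk_decode(cardio_state(R = 1, C = 2, SV = 70, T = 0.8))
#' @export
wk_decode <- function(state) {
  stopifnot(all(c("R", "C", "SV", "T") %in% names(state)))
  vals <- c(state$R, state$C, state$SV, state$T)
  if (any(!is.finite(vals))) stop("wk_decode: non-finite parameter")
  if (any(vals <= 0)) stop("wk_decode: non-positive parameter")
  x <- state$T / (state$R * state$C)
  k <- state$SV / state$C
  # expm1 keeps 1 - exp(-x) accurate for small x; for very large x the
  # limit forms Psys -> SV/C, Pdias -> 0 fall out automatically.
  D <- -expm1(-x)
  E <- exp(-x)
  data.frame(Psys  = k / D,
             Pdias = k * E / D,
             Pmap  = state$SV * state$R / state$T,
             F     = if ("F" %in% names(state)) state$F else 60 / state$T)
}

# Jacobian of wk_decode with respect to (R, C, SV, T), vectorized over rows.
# Returns a list of 4x4 partials as n-vectors: d<out>_d<par>. Used by the
# autoencoder's backward pass; cross-checked against finite differences in
# the test suite.
wk_decode_grad <- function(state) {
  R <- state$R; C <- state$C; SV <- state$SV; T <- state$T
  x <- T / (R * C)
  E <- exp(-x)
  D <- -expm1(-x)
  k <- SV / C
  dx_dR <- -x / R
  dx_dC <- -x / C
  dx_dT <- 1 / (R * C)
  dk_dSV <- 1 / C
  dk_dC <- -SV / C^2
  # Psys = k/D ; dPsys = dk/D - k*E/D^2 * dx
  cs <- -k * E / D^2
  dPsys <- list(R = cs * dx_dR,
                C = dk_dC / D + cs * dx_dC,
                SV = dk_dSV / D,
                T = cs * dx_dT)
  # Pdias = k*E/D ; dPdias = (E/D) dk - k*E/D^2 dx  (uses D + E = 1)
  dPdias <- list(R = cs * dx_dR,
                 C = dk_dC * E / D + cs * dx_dC,
                 SV = dk_dSV * E / D,
                 T = cs * dx_dT)
  dPmap <- list(R = SV / T, C = 0 * R, SV = R / T, T = -SV * R / T^2)
  dF <- list(R = 0 * R, C = 0 * R, SV = 0 * R, T = -60 / T^2)
  list(Psys = dPsys, Pdias = dPdias, Pmap = dPmap, F = dF)
}

#' Simulate the Windkessel pressure waveform
#'
#' Integrates the two-element Windkessel dynamics
#' `dP/dt = -P/(R*C) + Q(t)/C` with impulsive ejection `Q(t) = SV * delta(t)`
#' at each cycle start. Between impulses the decay is exponential, so the
#' waveform is built from the per-cycle closed form `P(t) = P0 * exp(-t/RC)`
#' with an instantaneous jump of `SV/C` at every beat — this avoids
#' discretization artifacts from approximating the delta impulse on a grid.
#'
#' @param state a single-row [cardio_state()].
#' @param n_cycles number of cardiac cycles to simulate (>= 1).
#' @param dt output sampling interval in seconds; must satisfy `dt < T`.
#' @param P0 initial pressure, mmHg (default 0; steady state is reached
#'   geometrically at rate `exp(-T/RC)` per cycle).
#' @param include_cycle_end also emit the sample at the end of each cycle
#'   (just before the next ejection) so the waveform minimum is exact.
#' @return data frame with columns `time` (s) and `P` (mmHg), sampled on a
#'   grid of spacing `dt` within each cycle (impulse instants included just
#'   after the jump).
#' @examples
#' w <- wk_simulate(cardio_state(R = 1, C = 2, SV = 70, T = 0.8), n_cycles = 50)
#' max(w$P[w$time > 49 * 0.8])  # converges to the decoded systolic pressure
#' @export
wk_simulate <- function(state, n_cycles, dt = state$T[1] / 200, P0 = 0,
                        include_cycle_end = FALSE) {
  stopifnot(nrow(state) == 1L, n_cycles >= 1)
  T <- state$T[1]; RC <- state$R[1] * state$C[1]; jump <- state$SV[1] / state$C[1]
  if (dt >= T) stop("wk_simulate: dt must be smaller than the filling time T")
  tt <- seq(0, T - dt / 2, by = dt)
  if (include_cycle_end) tt <- c(tt, T)
  decay <- exp(-tt / RC)
  out_t <- vector("list", n_cycles)
  out_p <- vector("list", n_cycles)
  P <- P0
  for (cyc in seq_len(n_cycles)) {
    P <- P + jump                        # ejection impulse at cycle start
    out_t[[cyc]] <- (cyc - 1) * T + tt
    out_p[[cyc]] <- P * decay
    P <- P * exp(-T / RC)                # value just before the next beat
  }
  data.frame(time = unlist(out_t), P = unlist(out_p))
}

#' Identifiable parameter combinations from observable pressures
#'
#' The decoder is not one-to-one: only combinations of the latent state are
#' identifiable from `(Psys, Pdias, Pmap, F)`. This inverts the decoder onto
#' the maximal identifiable set — the arterial time constant `RC`, pulse
#' pressure `SV/C`, and `SV*R` — leaving one scale degree of freedom on
#' `{R, C, SV}` unresolved.
#'
#' @param v data frame with columns `Psys`, `Pdias`, `Pmap`, `F` (as returned
#'   by [wk_decode()]).
#' @return data frame with columns `RC` (s), `SV_over_C` (mmHg), `SV_times_R`
#'   (mmHg·s) and `CO_over_SV_ratio`-free `T` (s) for reference.
#' @examples
#' s <- cardio_state(R = 1, C = 2, SV = 70, T = 0.8)
#' wk_invert(wk_decode(s))  # recovers RC = 2, SV/C = 35, SV*R = 70
#' @export
wk_invert <- function(v) {
  stopifnot(all(c("Psys", "Pdias", "Pmap", "F") %in% names(v)))
  if (any(v$Pdias <= 0 | v$Psys <= v$Pdias))
    stop("wk_invert: need Psys > Pdias > 0")
  if (any(v$F <= 0)) stop("wk_invert: need F > 0")
  T <- 60 / v$F
  data.frame(RC = -T / log(v$Pdias / v$Psys),
             SV_over_C = v$Psys - v$Pdias,
             SV_times_R = v$Pmap * T,
             T = T)
}

#' Cardiac output
#'
#' @param state a [cardio_state()].
#' @return cardiac output `SV * F` in mL/min, one value per state row.
#' @examples
#' cardiac_output(cardio_state(R = 1, C = 2, SV = 70, F = 75))  # 5250
#' @export
cardiac_output <- function(state) {
  stopifnot(all(c("SV", "F") %in% names(state)))
  if (any(state$SV <= 0)) stop("cardiac_output: SV must be positive")
  state$SV * state$F
}
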