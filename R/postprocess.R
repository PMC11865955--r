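#' Wave-intensity analysis of a pressure/velocity cycle
#'
#' Decomposes pressure and mean-velocity increments into forward (incident)
#' and backward (reflected) components,
#' `dp+- = (dp +- rho c du) / 2` and `du+- = (du +- dp / (rho c)) / 2`,
#' cumulates them into component waveforms starting from the first sample,
#' and forms the time-normalised wave intensities
#' `WI+- = (dp+-/dt) (du+-/dt)`. The identities `dp+ + dp- = dp` and
#' `du+ + du- = du` hold exactly.
#'
#' @param p pressure samples over one cycle (mmHg), uniform grid.
#' @param ubar mean velocity samples (cm/s), same length.
#' @param rho blood density (g/cm^3).
#' @param c_pwv pulse-wave velocity (cm/s) used for the decomposition; by
#'   default supply the local linearised value `sqrt(2 Eh /(3 rho r0))`.
#' @param dt sample spacing (s).
#' @return a list of class `pt_wia` with per-step increments (`dp`, `dpp`,
#'   `dpm`, `du`, `dup`, `dum`), cumulated components (`p_plus`, `p_minus`,
#'   `u_plus`, `u_minus`), wave intensities (`wi_plus`, `wi_minus`),
#'   `c_pwv`, `dt`, and the reflection coefficient `IR`.
#' @export
wia <- function(p, ubar, rho, c_pwv, dt) {
  stopifnot(length(p) == length(ubar), c_pwv > 0, dt > 0)
  p_cgs <- mmhg_to_cgs(p)
  dp <- diff(p_cgs)
  du <- diff(ubar)
  zc <- rho * c_pwv
  dpp <- (dp + zc * du) / 2
  dpm <- (dp - zc * du) / 2
  dup <- (du + dp / zc) / 2
  dum <- (du - dp / zc) / 2
  cum <- function(g0, d) g0 + c(0, cumsum(d))
  out <- list(
    dp = dp, dpp = dpp, dpm = dpm, du = du, dup = dup, dum = dum,
    p_plus = cgs_to_mmhg(cum(p_cgs[1], dpp)),
    p_minus = cgs_to_mmhg(cum(p_cgs[1], dpm)),
    u_plus = cum(ubar[1], dup),
    u_minus = cum(ubar[1], dum),
    wi_plus = (dpp / dt) * (dup / dt),
    wi_minus = (dpm / dt) * (dum / dt),
    c_pwv = c_pwv, dt = dt, gamma0_p = p[1], gamma0_u = ubar[1]
  )
  out$IR <- reflection_coefficient(structure(out, class = "pt_wia"))
  structure(out, class = "pt_wia")
}

# largest total rise of the cumulated component over a maximal run of
# compressive increments (d > 0)
compressive_amplitude <- function(d) {
  if (!length(d) || all(d <= 0)) return(0)
  r <- rle(d > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rises <- vapply(which(r$values), function(k) {
    sum(d[starts[k]:ends[k]])
  }, numeric(1))
  max(rises)
}

#' Wave-reflection coefficient
#'
#' Ratio of the amplitudes of the reflected to the incident compressive
#' pressure waves, `IR = dP- / dP+`. A compressive wave carries positive
#' pressure increments (`dp+- > 0`); the amplitude is the largest total rise
#' of the cumulated component over a maximal compressive run.
#'
#' @param series a `pt_wia`.
#' @return `IR` (>= 0), or `NA` (flagged missing) when no incident
#'   compressive wave is present.
#' @export
reflection_coefficient <- function(series) {
  stopifnot(inherits(series, "pt_wia"))
  dP_plus <- compressive_amplitude(series$dpp)
  dP_minus <- compressive_amplitude(series$dpm)
  if (dP_plus <= 0) return(NA_real_)
  dP_minus / dP_plus
}

#' Wall shear stress in the Stokes boundary layer
#'
#' `tau_w = mu * ubar / delta` with `ubar = q/A`: the tangential viscous
#' stress the fluid exerts on the wall, using the flat-core/boundary-layer
#' velocity profile. The sign follows the flow.
#'
#' @param q flow samples (ml/s).
#' @param A area samples (cm^2), positive.
#' @param mu dynamic viscosity (g/cm/s).
#' @param delta boundary-layer thickness (cm).
#' @return a tibble with columns `ubar` and `tau_w` (g cm^-1 s^-2).
#' @export
wss <- function(q, A, mu, delta) {
  stopifnot(all(A > 0), delta > 0)
  ubar <- q / A
  tibble(ubar = ubar, tau_w = mu * ubar / delta)
}

#' Pulse metrics at a location in a solution
#'
#' Systolic/diastolic/pulse pressure, pulse flow (max - min) and relative
#' area deformation over the final cycle at a stated location.
#'
#' @param sol a `pt_solution`.
#' @param vessel_id vessel id.
#' @param x_frac fractional position along the vessel in `[0, 1]`.
#' @return a one-row tibble: `vessel`, `x_frac`, `p_sys`, `p_dia`,
#'   `pulse_pressure` (mmHg), `q_max`, `q_min`, `pulse_flow` (ml/s),
#'   `area_deformation` ((max A - min A)/min A).
#' @export
summarize_solution <- function(sol, vessel_id, x_frac = 0.5) {
  vs <- sol$vessels[[as.character(vessel_id)]]
  if (is.null(vs)) abort(sprintf("vessel %s not in solution", vessel_id))
  if (x_frac < 0 || x_frac > 1) abort("x_frac must lie in [0, 1]")
  i <- x_index(vs, x_frac)
  p <- vs$p[i, ]; q <- vs$q[i, ]; A <- vs$A[i, ]
  tibble(vessel = vs$id, x_frac = x_frac,
         p_sys = max(p), p_dia = min(p), pulse_pressure = max(p) - min(p),
         q_max = max(q), q_min = min(q), pulse_flow = max(q) - min(q),
         area_deformation = (max(A) - min(A)) / min(A))
}

#' Wave-intensity analysis at a solution location
#'
#' Convenience wrapper running [wia()] on the final-cycle pressure and mean
#' velocity at a vessel location, with the pulse-wave velocity taken as the
#' local linearised value `sqrt(2 Eh / (3 rho r0))`.
#'
#' @inheritParams summarize_solution
#' @return a `pt_wia`.
#' @export
solution_wia <- function(sol, vessel_id, x_frac = 0.5) {
  vs <- sol$vessels[[as.character(vessel_id)]]
  if (is.null(vs)) abort(sprintf("vessel %s not in solution", vessel_id))
  i <- x_index(vs, x_frac)
  rho <- sol$params$blood$rho
  # f = (4/3) Eh/r0, so c0 = sqrt(f / (2 rho)) = sqrt(2 Eh / (3 rho r0))
  c_pwv <- sqrt(vs$f[i] / (2 * rho))
  wia(vs$p[i, ], vs$q[i, ] / vs$A[i, ], rho, c_pwv, sol$dt)
}

#' Wall shear stress at a solution location
#'
#' @inheritParams summarize_solution
#' @return a tibble with `t`, `ubar`, `tau_w`.
#' @export
solution_wss <- function(sol, vessel_id, x_frac = 0.5) {
  vs <- sol$vessels[[as.character(vessel_id)]]
  if (is.null(vs)) abort(sprintf("vessel %s not in solution", vessel_id))
  i <- x_index(vs, x_frac)
  w <- wss(vs$q[i, ], vs$A[i, ], sol$params$blood$mu, sol$delta_cm)
  tibble(t = sol$t, ubar = w$ubar, tau_w = w$tau_w)
}
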