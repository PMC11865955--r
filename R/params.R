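#' Blood and simulation constants
#'
#' @param rho blood density (g/cm^3).
#' @param mu dynamic viscosity (g/cm/s).
#' @param nu kinematic viscosity (cm^2/s); nominally `mu/rho`.
#' @param T cardiac period (s).
#' @param p0_mmhg reference (unstressed) pressure offset (mmHg).
#' @return a list of class `pt_blood`; includes the Stokes boundary-layer
#'   thickness `delta_cm = sqrt(nu * T / (2 * pi))`.
#' @export
blood_params <- function(rho = 1.06, mu = 0.032, nu = 0.030, T = 0.71,
                         p0_mmhg = 0) {
  stopifnot(rho > 0, mu > 0, nu > 0, T > 0)
  structure(list(rho = rho, mu = mu, nu = nu, T = T,
                 delta_cm = sqrt(nu * T / (2 * pi)), p0_mmhg = p0_mmhg),
            class = "pt_blood")
}

#' Full forward-model parameter set
#'
#' Collects everything the forward model needs beyond the network geometry:
#' blood constants, the large-vessel stiffness constants per vessel group
#' (`k1, k2, k3`, groups 1-4), the small-vessel stiffness constants per
#' structured-tree group (`ks1, ks2, ks3`), and the structured-tree geometry
#' constants (`tree_alpha`, `tree_beta`, `lrr`).
#'
#' @param blood a `pt_blood`.
#' @param k1,k2,k3 length-4 numeric vectors (one value per large-vessel
#'   group); scalars are recycled.
#' @param ks1,ks2,ks3 length-4 numeric vectors per small-vessel group.
#' @param tree_alpha,tree_beta,lrr structured-tree constants.
#' @return a list of class `pt_params`.
#' @export
haemo_params <- function(blood = blood_params(),
                         k1 = 2e7, k2 = -25, k3 = 5.6e5,
                         ks1 = 2e7, ks2 = -35, ks3 = 3.8e5,
                         tree_alpha = 0.9, tree_beta = 0.6, lrr = 50) {
  rec4 <- function(x) {
    if (length(x) == 1) rep(x, 4) else {
      stopifnot(length(x) == 4)
      as.numeric(x)
    }
  }
  structure(list(blood = blood,
                 k1 = rec4(k1), k2 = rec4(k2), k3 = rec4(k3),
                 ks1 = rec4(ks1), ks2 = rec4(ks2), ks3 = rec4(ks3),
                 tree_alpha = tree_alpha, tree_beta = tree_beta, lrr = lrr),
            class = "pt_params")
}

#' Nominal cohort parameter values
#'
#' Nominal stiffness and structured-tree constants for the two
#' single-ventricle cohorts (native-aorta DORV and reconstructed-aorta HLHS).
#' Group-level stiffness constants are the cohort nominal values replicated
#' across the four vessel groups.
#'
#' @param cohort `"DORV"` or `"HLHS"`.
#' @param T cardiac period (s); defaults to the cohort mean.
#' @return a `pt_params`.
#' @export
nominal_params <- function(cohort = c("DORV", "HLHS"), T = NULL) {
  cohort <- match.arg(cohort)
  if (cohort == "DORV") {
    if (is.null(T)) T <- 0.710
    haemo_params(blood = blood_params(T = T),
                 k1 = 2e7, k2 = -25, k3 = 5.6e5,
                 ks1 = 2e7, ks2 = -35, ks3 = 3.8e5)
  } else {
    if (is.null(T)) T <- 0.770
    haemo_params(blood = blood_params(T = T),
                 k1 = 2e7, k2 = -35, k3 = 7.3e5,
                 ks1 = 2e7, ks2 = -30, ks3 = 5.4e5)
  }
}

#' Linearised pulse-wave velocity at the unstressed state
#'
#' `c0 = sqrt(2 Eh / (3 rho r0))`, the wave speed of the wall law linearised
#' at `A = A0`.
#'
#' @param Ehr0 wall stiffness Eh/r0 (g/cm/s^2).
#' @param rho blood density (g/cm^3).
#' @return wave speed (cm/s).
#' @export
pulse_wave_velocity <- function(Ehr0, rho = 1.06) sqrt(2 * Ehr0 / (3 * rho))

#' Transmural pressure from the wall law
#'
#' `p = p0 + (4/3) (Eh/r0) (1 - sqrt(A0/A))`, reported in mmHg.
#'
#' @param A current cross-sectional area (cm^2), positive.
#' @param A0 unstressed area (cm^2).
#' @param Ehr0 wall stiffness Eh/r0 (g/cm/s^2).
#' @param p0_mmhg reference pressure (mmHg).
#' @return pressure (mmHg).
#' @export
wall_pressure <- function(A, A0, Ehr0, p0_mmhg = 0) {
  if (any(A <= 0)) abort("solver-state error: non-positive area")
  p_cgs <- (4 / 3) * Ehr0 * (1 - sqrt(A0 / A))
  p0_mmhg + cgs_to_mmhg(p_cgs)
}
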