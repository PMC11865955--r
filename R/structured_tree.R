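#' Structured-tree parameters
#'
#' Parameters of the asymmetric structured tree of small vessels used as an
#' outflow boundary: daughter radii are `tree_alpha * r` and `tree_beta * r`,
#' vessel length is `lrr * r`, and branches terminate once the radius falls
#' below `r_min_cm`. The wall stiffness of the small vessels follows the same
#' exponential law as the large vessels with its own constants `ks1, ks2,
#' ks3`. `tree_alpha` is distinct from the allometric exponent.
#'
#' @param tree_alpha radius ratio of the first daughter (nominal 0.9).
#' @param tree_beta radius ratio of the second daughter (nominal 0.6).
#' @param lrr length-to-radius ratio (nominal 50).
#' @param r_min_cm termination radius (cm).
#' @param ks1,ks2,ks3 small-vessel stiffness constants (g/cm/s^2, 1/cm,
#'   g/cm/s^2).
#' @return a list of class `pt_tree_params`.
#' @export
tree_params <- function(tree_alpha = 0.9, tree_beta = 0.6, lrr = 50,
                        r_min_cm = 0.001, ks1 = 2e7, ks2 = -35,
                        ks3 = 3.8e5) {
  if (!(tree_beta > 0 && tree_beta <= tree_alpha && tree_alpha < 1)) {
    abort("require 0 < tree_beta <= tree_alpha < 1")
  }
  if (lrr <= 0 || r_min_cm <= 0) abort("lrr and r_min_cm must be positive")
  structure(list(tree_alpha = tree_alpha, tree_beta = tree_beta, lrr = lrr,
                 r_min_cm = r_min_cm, ks1 = ks1, ks2 = ks2, ks3 = ks3),
            class = "pt_tree_params")
}

#' Vessel wall stiffness Eh/r0
#'
#' Exponential stiffness law `Eh/r0 = k1 * exp(k2 * r0) + k3` with `k2 < 0`:
#' stiffness increases as the radius decreases. The same form is used for
#' large vessels (constants `k1, k2, k3` per vessel group) and for the small
#' vessels of the structured trees (`ks1, ks2, ks3`).
#'
#' @param r0 unstressed radius (cm), positive.
#' @param k1,k2,k3 stiffness constants.
#' @return Eh/r0 (g cm^-1 s^-2).
#' @export
vessel_stiffness <- function(r0, k1, k2, k3) {
  stopifnot(all(r0 > 0))
  k1 * exp(k2 * r0) + k3
}

#' @rdname vessel_stiffness
#' @param params a `pt_tree_params` supplying `ks1, ks2, ks3`.
#' @export
small_vessel_stiffness <- function(r0, params) {
  vessel_stiffness(r0, params$ks1, params$ks2, params$ks3)
}

#' Womersley viscous factor
#'
#' `F_J = 2 J1(w0) / (w0 J0(w0))` with `w0^2 = i^3 r0^2 omega / nu`, the
#' Bessel-function factor of the pulsatile (Womersley) velocity profile in
#' the linearised small-vessel equations.
#'
#' @param r0 vessel radius (cm).
#' @param omega angular frequency (rad/s), positive.
#' @param nu kinematic viscosity (cm^2/s).
#' @return complex `F_J` values.
#' @export
womersley_fj <- function(r0, omega, nu) {
  .womersley_fj_cpp(as.numeric(r0), as.numeric(omega), nu)
}

#' Input impedance of a single small vessel
#'
#' Frequency-domain input impedance `Z(0, omega)` of one vessel of the
#' structured tree given the impedance `Z_L` at its distal end:
#' `Z(0,w) = (i g^-1 sin(wL/c) + Z_L cos(wL/c)) /
#'           (cos(wL/c) + i g Z_L sin(wL/c))`
#' with `g = sqrt(C A0 (1-F_J)/rho)` and wave speed
#' `c = sqrt(A0 (1-F_J)/(rho C))`, `C = 3 A0 r0 / (2 Eh)`. At `omega = 0` the
#' analytic Poiseuille limit `Z(0,0) = 8 mu L / (pi r0^4) + Z_L` is used.
#'
#' @param Z_L distal impedance (complex).
#' @param omega angular frequency (rad/s), >= 0.
#' @param r0 vessel radius (cm).
#' @param L vessel length (cm).
#' @param Ehr0 wall stiffness Eh/r0 (g cm^-1 s^-2).
#' @param rho blood density (g/cm^3).
#' @param mu dynamic viscosity (g/cm/s).
#' @return complex impedance at the vessel inlet (g cm^-4 s^-1).
#' @export
vessel_input_impedance <- function(Z_L, omega, r0, L, Ehr0, rho = 1.06,
                                   mu = 0.032) {
  if (any(!is.finite(Z_L))) abort("non-finite distal impedance")
  stopifnot(length(omega) == 1, omega >= 0)
  if (omega == 0) return(Z_L + 8 * mu * L / (pi * r0^4))
  A0 <- pi * r0^2
  C <- 3 * A0 / (2 * Ehr0)
  FJ <- womersley_fj(r0, omega, mu / rho)
  g <- sqrt(as.complex(C * A0 * (1 - FJ) / rho))
  cw <- sqrt(as.complex(A0 * (1 - FJ) / (rho * C)))
  kL <- omega * L / cw
  (1i / g * sin(kL) + Z_L * cos(kL)) / (cos(kL) + 1i * g * Z_L * sin(kL))
}

#' Root input-impedance spectrum of a structured tree
#'
#' Generates the asymmetric binary tree from the root radius, propagates
#' impedance from the terminal branches (terminal impedance zero at all
#' frequencies) through each bifurcation (daughters combine in parallel by
#' pressure continuity and mass conservation), and returns the impedance at
#' the tree root at the harmonics `omega_k = 2 pi k / T`, `k = 0..K_f`.
#' Subtrees with equal daughter-ratio counts are shared, so the cost grows
#' with the memoised (alpha-count, beta-count) grid rather than with the
#' exponential number of branches.
#'
#' The zero-impedance termination is applied through a smooth pinch ramp:
#' a daughter whose radius falls in `[0.9 r_min, r_min)` is kept as a
#' terminal stub whose length shrinks smoothly to zero, and below
#' `0.9 r_min` it is a zero-impedance short that grounds its junction. This
#' makes the root impedance a continuous, once-differentiable function of
#' `tree_alpha`, `tree_beta`, `lrr` and `r_min_cm` — without the ramp the
#' tree topology, and with it the impedance, jumps each time a branch
#' crosses the termination radius, which breaks gradient-based calibration.
#'
#' @param r_root root radius (cm), must exceed `params$r_min_cm`.
#' @param params a `pt_tree_params`.
#' @param T cardiac period (s).
#' @param K_f number of positive harmonics retained.
#' @param rho,mu blood density and dynamic viscosity.
#' @param thin frequency thinning factor: harmonics `0..exact_k` are always
#'   computed exactly; above that only every `thin`-th harmonic is computed
#'   and the smooth remainder of the spectrum is filled in by cubic-spline
#'   interpolation of its real and imaginary parts. `thin = 1` disables
#'   interpolation.
#' @param exact_k number of low harmonics always computed exactly.
#' @return a list of class `pt_impedance`: `omega` (length `K_f + 1`,
#'   starting at 0), `Z` (complex), `T`.
#' @export
root_impedance <- function(r_root, params, T, K_f, rho = 1.06, mu = 0.032,
                           thin = 1, exact_k = 32) {
  stopifnot(inherits(params, "pt_tree_params"))
  calc <- function(omega) {
    .root_impedance_cpp(r_root, params$tree_alpha, params$tree_beta,
                        params$lrr, params$r_min_cm, params$ks1,
                        params$ks2, params$ks3, rho, mu, omega)
  }
  omega <- 2 * pi * (0:K_f) / T
  if (thin <= 1 || K_f <= exact_k + 2 * thin) {
    Z <- calc(omega)
  } else {
    kk <- unique(c(0:exact_k, seq(exact_k, K_f, by = thin), K_f))
    Zs <- calc(2 * pi * kk / T)
    k_all <- 0:K_f
    Z <- complex(real = stats::spline(kk, Re(Zs), xout = k_all)$y,
                 imaginary = stats::spline(kk, Im(Zs), xout = k_all)$y)
  }
  structure(list(omega = omega, Z = Z, T = T), class = "pt_impedance")
}

#' Time-domain boundary kernel from an impedance spectrum
#'
#' Extends the spectrum to negative frequencies by conjugate symmetry and
#' inverse-transforms it into a real periodic kernel `z_m` of length `n_t`
#' such that the outlet pressure is the cyclic convolution
#' `p(L, t_m) = p0 + sum_j z_j q(L, t_{m-j})`. The kernel sums to the DC
#' impedance, so a constant flow `q` produces `p = p0 + Z_DC * q`.
#'
#' @param spec a `pt_impedance` with harmonics `0..K_f`.
#' @param n_t number of time samples per period (>= 2 * K_f).
#' @return a list of class `pt_kernel`: `z` (length `n_t`), `dt`, `T`.
#' @export
impedance_to_kernel <- function(spec, n_t) {
  stopifnot(inherits(spec, "pt_impedance"))
  K_f <- length(spec$Z) - 1
  if (n_t < 2 * K_f) abort("n_t must be at least twice the harmonic count")
  S <- complex(real = rep(0, n_t))
  S[1] <- spec$Z[1]
  for (k in seq_len(K_f)) {
    if (2 * k == n_t) {
      S[k + 1] <- complex(real = Re(spec$Z[k + 1]))
    } else {
      S[k + 1] <- spec$Z[k + 1]
      S[n_t - k + 1] <- Conj(spec$Z[k + 1])
    }
  }
  z <- fft(S, inverse = TRUE) / n_t
  if (max(abs(Im(z))) > 1e-8 * max(abs(z))) {
    warn("impedance kernel has a non-negligible imaginary part")
  }
  structure(list(z = Re(z), dt = spec$T / n_t, T = spec$T),
            class = "pt_kernel")
}

#' Recover the impedance spectrum represented by a kernel
#'
#' Forward transform of the time-domain kernel; inverse of
#' [impedance_to_kernel()] up to the retained harmonics.
#'
#' @param kernel a `pt_kernel`.
#' @param K_f number of harmonics to return.
#' @return a `pt_impedance`.
#' @export
kernel_to_impedance <- function(kernel, K_f) {
  S <- fft(kernel$z)
  structure(list(omega = 2 * pi * (0:K_f) / kernel$T, Z = S[1:(K_f + 1)],
                 T = kernel$T), class = "pt_impedance")
}
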