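# shared test utilities: naive structured-tree oracle, tiny networks,
# analytic test residuals

# Naive recursive structured-tree impedance at a single frequency:
# plain series-parallel combination in R (no memoisation), same pinch
# semantics as the solver. Returns the impedance and the segment count.
oracle_tree <- function(r_root, omega, tp, rho = 1.06, mu = 0.032) {
  rmin <- tp$r_min_cm
  rec <- function(r) {
    if (r < 0.9 * rmin) return(list(z = 0 + 0i, n = 0))
    if (r < rmin) {
      t <- (r - 0.9 * rmin) / (0.1 * rmin)
      w <- t * t * (3 - 2 * t)
      z <- vessel_input_impedance(0 + 0i, omega, r, w * tp$lrr * r,
                                  small_vessel_stiffness(r, tp), rho, mu)
      return(list(z = z, n = 1))
    }
    a <- rec(tp$tree_alpha * r)
    b <- rec(tp$tree_beta * r)
    zl <- if (Mod(a$z) == 0 || Mod(b$z) == 0) 0 + 0i else {
      a$z * b$z / (a$z + b$z)
    }
    z <- vessel_input_impedance(zl, omega, r, tp$lrr * r,
                                small_vessel_stiffness(r, tp), rho, mu)
    list(z = z, n = a$n + b$n + 1)
  }
  rec(r_root)
}

single_vessel_net <- function(L = 10, r_in = 0.5, r_out = 0.45,
                              g_large = 1, g_small = 1, r_min = 0.01) {
  build_network(data.frame(id = 1, length_cm = L, r_in_cm = r_in,
                           r_out_cm = r_out, group_large = g_large,
                           group_small = g_small, r_min_cm = r_min))
}

# parent + single child with identical cross-section and stiffness group
chain_net <- function(L1 = 6, L2 = 6, r = 0.5, r_min = 0.01) {
  v <- data.frame(id = 1:2, length_cm = c(L1, L2), r_in_cm = r,
                  r_out_cm = r, group_large = 1, group_small = 1,
                  r_min_cm = r_min)
  build_network(v, data.frame(parent = 1, child = 2))
}

test_inflow <- function(CO = 4, T = 0.71, Tp = 20) make_inflow(CO, T, Tp)

# minimal pt_solution stand-in for location-based summaries
fake_solution <- function(p, q, A, dt = 0.01) {
  n <- length(p)
  vs <- list(id = 1, name = "v", x = c(0, 1, 2), A0 = rep(A[1], 3),
             f = rep(7.5e5, 3),
             p = matrix(rep(p, each = 3), 3, n),
             q = matrix(rep(q, each = 3), 3, n),
             A = matrix(rep(A, each = 3), 3, n))
  structure(list(vessels = list(`1` = vs), t = (0:(n - 1)) * dt,
                 T = n * dt, dt = dt, n_t = n, cycles = 1,
                 converged = TRUE, periodicity = 0,
                 params = nominal_params("DORV"), network = NULL,
                 delta_cm = 0.06),
            class = "pt_solution")
}

# series J0, J1 for complex argument (small |z|), used as an independent
# check of the Womersley factor
series_besselj <- function(nu, z, terms = 60) {
  s <- 0 + 0i
  for (k in 0:terms) {
    s <- s + (-1)^k / (factorial(k) * gamma(k + nu + 1)) * (z / 2)^(2 * k + nu)
  }
  s
}

rosenbrock_resid <- function(th) {
  c(1 - th[["x"]], sqrt(10) * (th[["y"]] - th[["x"]]^2))
}
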