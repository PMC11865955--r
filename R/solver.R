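#' Solver configuration
#'
#' Numerical settings for the network Lax-Wendroff solve. The time step is
#' tied to the spatial grid through the CFL condition
#' `dt <= cfl * dx / max(|u| + c)`; when `n_t` is `NULL` the number of time
#' steps per cycle is chosen automatically (next power of two satisfying the
#' CFL bound at the unstressed wave speeds with a safety margin).
#'
#' @param points_per_cm spatial resolution (grid points per cm).
#' @param min_points minimum grid points per vessel (>= 4).
#' @param cfl CFL number in (0, 1).
#' @param n_t time steps per cardiac cycle (power of two recommended); `NULL`
#'   for automatic selection.
#' @param cycles_max maximum number of cardiac cycles.
#' @param periodicity_tol relative L2 change in mid-vessel pressure between
#'   consecutive cycles required for convergence.
#' @param fixed_cycles run exactly this many cycles (no periodicity test);
#'   `NULL` to iterate to periodicity. A fixed cycle count keeps the forward
#'   model a smooth function of its parameters, which finite-difference
#'   gradients need.
#' @param taper radius taper used to build r0(x).
#' @param kernel_harmonics number of structured-tree impedance harmonics
#'   computed explicitly; above this the spectrum is extended flat at its
#'   last value (the root impedance approaches its high-frequency plateau).
#' @param kernel_thin frequency thinning factor passed to
#'   [root_impedance()] (1 = compute every harmonic).
#' @param visc artificial-dissipation coefficient for the interior scheme
#'   (dimensionless second-difference blend on the deviation from the
#'   unstressed state; 0 disables it). A small value (~0.05) regularises
#'   near-sonic steepening in extreme geometries at the cost of some
#'   numerical damping.
#' @param umax_margin additive wave-speed margin (cm/s) in the automatic time
#'   step, covering advective speeds.
#' @return a list of class `pt_config`.
#' @export
solver_config <- function(points_per_cm = 2, min_points = 5, cfl = 0.5,
                          n_t = NULL, cycles_max = 30,
                          periodicity_tol = 1e-3, fixed_cycles = NULL,
                          taper = c("exponential", "linear"),
                          umax_margin = 200, kernel_harmonics = 512,
                          kernel_thin = 1, visc = 0) {
  stopifnot(cfl > 0, cfl < 1, min_points >= 4)
  structure(list(points_per_cm = points_per_cm, min_points = min_points,
                 cfl = cfl, n_t = n_t, cycles_max = cycles_max,
                 periodicity_tol = periodicity_tol,
                 fixed_cycles = fixed_cycles, taper = match.arg(taper),
                 umax_margin = umax_margin,
                 kernel_harmonics = kernel_harmonics,
                 kernel_thin = kernel_thin, visc = visc),
            class = "pt_config")
}

#' Pin the number of time steps per cycle for a family of solves
#'
#' The automatic time step depends on the wave speeds, hence on the
#' stiffness parameters; inside a calibration loop the grid must not jump
#' between parameter evaluations or the objective becomes discontinuous.
#' This chooses the automatic `n_t` with the stiffness inflated by
#' `stiffness_margin` (covering the calibration bounds) so one value is
#' CFL-safe across the whole sweep.
#'
#' @param net a `pt_network`.
#' @param T cardiac period (s).
#' @param params a `pt_params`.
#' @param config a `pt_config`.
#' @param stiffness_margin multiplicative margin on Eh/r0.
#' @return integer number of time steps per cycle (power of two).
#' @export
choose_nt <- function(net, T, params, config, stiffness_margin = 1.7) {
  grids <- lapply(seq_len(nrow(net$vessels)), function(i) {
    build_vessel_grid(net$vessels[i, ], params, config)
  })
  lam <- max(vapply(grids, function(gr) {
    max(sqrt(gr$f * stiffness_margin / (2 * params$blood$rho)))
  }, numeric(1))) * 1.2 + config$umax_margin
  dx_min <- min(vapply(grids, function(gr) gr$dx, numeric(1)))
  # round up to a multiple of 64 (even, FFT-friendly, no power-of-two jump)
  max(64 * ceiling(T * lam / (config$cfl * dx_min) / 64), 64)
}

# per-vessel discrete geometry for the C++ stepper
build_vessel_grid <- function(vessel, params, config) {
  L <- vessel$length_cm
  nx <- max(config$min_points, ceiling(L * config$points_per_cm) + 1)
  dx <- L / (nx - 1)
  x <- seq(0, L, length.out = nx)
  xh <- x[-nx] + dx / 2
  ri <- vessel$r_in_cm; ro <- vessel$r_out_cm
  if (config$taper == "exponential") {
    r0 <- ri * (ro / ri)^(x / L); r0h <- ri * (ro / ri)^(xh / L)
    dr <- r0 * log(ro / ri) / L; drh <- r0h * log(ro / ri) / L
  } else {
    r0 <- ri + (ro - ri) * x / L; r0h <- ri + (ro - ri) * xh / L
    dr <- rep((ro - ri) / L, nx); drh <- rep((ro - ri) / L, nx - 1)
  }
  g <- vessel$group_large
  if (is.na(g)) g <- 1L
  k1 <- params$k1[g]; k2 <- params$k2[g]; k3 <- params$k3[g]
  stiff <- function(r) (4 / 3) * (k1 * exp(k2 * r) + k3)
  dstiff <- function(r, drdx) (4 / 3) * k1 * k2 * exp(k2 * r) * drdx
  list(nx = as.integer(nx), dx = dx, x = x, r0 = r0,
       A0 = pi * r0^2, f = stiff(r0),
       dA0 = 2 * pi * r0 * dr, df = dstiff(r0, dr),
       A0h = pi * r0h^2, fh = stiff(r0h),
       dA0h = 2 * pi * r0h * drh, dfh = dstiff(r0h, drh),
       kernel_id = -1L)
}

#' Solve pulse-wave propagation on a vessel network
#'
#' Runs the explicit two-step Lax-Wendroff scheme for the nonlinear 1-D
#' mass/momentum system on every vessel of the network, with the prescribed
#' periodic inflow at the root, pressure continuity and mass conservation at
#' junctions, and structured-tree impedance kernels at the terminal vessels.
#' Cycles repeat from the unstressed initial state (`A = A0`, `q = 0`) until
#' the pressure field is periodic (or for a fixed cycle count).
#'
#' @param net a `pt_network`; every terminal vessel needs `r_min_cm` and a
#'   small-vessel group in `group_small`.
#' @param inflow a `pt_waveform` (ml/s) imposed at the root inlet; its period
#'   sets the cardiac cycle length and overrides `params$blood$T`.
#' @param params a `pt_params`.
#' @param config a `pt_config`.
#' @return an object of class `pt_solution`: per-vessel `x` grid, matrices
#'   `p` (mmHg), `q` (ml/s), `A` (cm^2) of size `nx` by `n_t` over the final
#'   cycle, the cycle time grid `t`, and solver diagnostics (`cycles`,
#'   `converged`, `periodicity`). A non-periodic run returns the best cycle
#'   with `converged = FALSE` and a warning.
#' @export
solve_network <- function(net, inflow, params = nominal_params("DORV"),
                          config = solver_config()) {
  stopifnot(inherits(net, "pt_network"), inherits(params, "pt_params"))
  T0 <- wf_period(inflow)
  blood <- params$blood
  delta <- sqrt(blood$nu * T0 / (2 * pi))
  v <- net$vessels
  ids <- v$id
  grids <- lapply(seq_len(nrow(v)), function(i) {
    build_vessel_grid(v[i, ], params, config)
  })
  # automatic time step from the CFL bound at unstressed wave speeds
  n_t <- config$n_t
  if (is.null(n_t)) {
    lam <- max(vapply(grids, function(gr) {
      max(sqrt(gr$f / (2 * blood$rho)))
    }, numeric(1))) * 1.2 + config$umax_margin
    dx_min <- min(vapply(grids, function(gr) gr$dx, numeric(1)))
    n_t <- 2^ceiling(log2(T0 * lam / (config$cfl * dx_min)))
    n_t <- max(n_t, 2 * nrow(inflow), 64)
  }
  dt <- T0 / n_t

  # structured-tree kernels for terminal vessels (or an explicit override:
  # config$terminal_Z_fn(omega, vessel_row) -> complex impedance spectrum,
  # used e.g. for matched-impedance or free-outflow experiments)
  term_idx <- which(v$terminal)
  kernels <- list()
  for (j in seq_along(term_idx)) {
    i <- term_idx[j]
    if (!is.null(config$terminal_Z_fn)) {
      K_f <- n_t / 2
      omega <- 2 * pi * (0:K_f) / T0
      spec <- structure(list(omega = omega,
                             Z = config$terminal_Z_fn(omega, v[i, ]),
                             T = T0), class = "pt_impedance")
      kernels[[j]] <- impedance_to_kernel(spec, n_t)$z
      grids[[i]]$kernel_id <- as.integer(j - 1)
      next
    }
    gs <- v$group_small[i]
    if (is.na(gs)) abort(sprintf(
      "terminal vessel %d needs a small-vessel group", v$id[i]))
    if (is.na(v$r_min_cm[i])) abort(sprintf(
      "terminal vessel %d needs r_min_cm", v$id[i]))
    tp <- tree_params(tree_alpha = params$tree_alpha,
                      tree_beta = params$tree_beta, lrr = params$lrr,
                      r_min_cm = v$r_min_cm[i], ks1 = params$ks1[gs],
                      ks2 = params$ks2[gs], ks3 = params$ks3[gs])
    K_f <- min(n_t / 2, config$kernel_harmonics)
    key <- paste(signif(c(v$r_out_cm[i], unlist(tp), blood$rho, blood$mu,
                          T0, K_f, config$kernel_thin), 15), collapse = "|")
    spec <- .pt_tree_cache[[key]]
    if (is.null(spec)) {
      spec <- root_impedance(v$r_out_cm[i], tp, T0, K_f = K_f,
                             rho = blood$rho, mu = blood$mu,
                             thin = config$kernel_thin)
      if (length(ls(.pt_tree_cache)) > 400) {
        rm(list = ls(.pt_tree_cache), envir = .pt_tree_cache)
      }
      assign(key, spec, envir = .pt_tree_cache)
    }
    if (K_f < n_t / 2) { # flat high-frequency tail
      spec$Z <- c(spec$Z, rep(spec$Z[K_f + 1], n_t / 2 - K_f))
      spec$omega <- 2 * pi * (0:(n_t / 2)) / T0
    }
    kernels[[j]] <- impedance_to_kernel(spec, n_t)$z
    grids[[i]]$kernel_id <- as.integer(j - 1)
  }

  qin <- resample_periodic(inflow, n_t)$flow_ml_s
  jn <- lapply(unique(net$edges$parent), function(p) {
    kids <- net$edges$child[net$edges$parent == p]
    as.integer(c(match(p, ids), match(kids, ids)) - 1L)
  })
  root0 <- as.integer(match(net$root_id, ids) - 1L)
  fixed <- if (is.null(config$fixed_cycles)) -1L
           else as.integer(config$fixed_cycles)

  raw <- .solve_lw_cpp(grids, jn, root0, qin, kernels, blood$rho, blood$nu,
                       delta, dt, as.integer(n_t),
                       as.integer(config$cycles_max), config$periodicity_tol,
                       fixed, config$visc %||% 0)
  if (!raw$converged) {
    warn(sprintf(paste0("solver did not reach periodicity tolerance %.1e ",
                        "within %d cycles (last change %.2e); returning the ",
                        "final cycle"),
                 config$periodicity_tol, config$cycles_max,
                 raw$periodicity))
  }
  # stored column s has cycle phase (s+1) dt; rotate so column j is at j dt
  idx <- c(n_t, seq_len(n_t - 1))
  p0 <- blood$p0_mmhg
  vout <- lapply(seq_len(nrow(v)), function(i) {
    A <- raw$vessels[[i]]$A[, idx, drop = FALSE]
    q <- raw$vessels[[i]]$q[, idx, drop = FALSE]
    gr <- grids[[i]]
    p <- p0 + cgs_to_mmhg(gr$f * (1 - sqrt(gr$A0 / A)))
    list(id = v$id[i], name = v$name[i], x = gr$x, A0 = gr$A0, f = gr$f,
         A = A, q = q, p = p)
  })
  names(vout) <- as.character(v$id)
  structure(list(vessels = vout, t = (0:(n_t - 1)) * dt, T = T0, dt = dt,
                 n_t = n_t, cycles = raw$cycles, converged = raw$converged,
                 periodicity = raw$periodicity, params = params,
                 network = net, delta_cm = delta),
            class = "pt_solution")
}

#' @export
print.pt_solution <- function(x, ...) {
  cat(sprintf(
    "<pt_solution> %d vessels, %d steps/cycle, %d cycle(s), %s (dP %.2e)\n",
    length(x$vessels), x$n_t, x$cycles,
    if (x$converged) "periodic" else "NOT periodic", x$periodicity))
  invisible(x)
}

# nearest interior x-index for a fractional position along a vessel
x_index <- function(sol_vessel, x_frac) {
  nx <- length(sol_vessel$x)
  max(1L, min(nx, round(x_frac * (nx - 1)) + 1L))
}

#' Sample a solution field at a vessel location and arbitrary cycle times
#'
#' Time interpolation is trigonometric (the solution is periodic); the
#' location is the nearest grid node to `x_frac * L`.
#'
#' @param sol a `pt_solution`.
#' @param vessel_id vessel id.
#' @param x_frac fractional position along the vessel in `[0, 1]`.
#' @param times times within the cycle (s); defaults to the solver grid.
#' @param field `"q"`, `"p"` or `"A"`.
#' @return numeric vector of field values at `times`.
#' @export
solution_at <- function(sol, vessel_id, x_frac = 1, times = NULL,
                        field = c("q", "p", "A")) {
  field <- match.arg(field)
  vs <- sol$vessels[[as.character(vessel_id)]]
  if (is.null(vs)) abort(sprintf("vessel %s not in solution", vessel_id))
  i <- x_index(vs, x_frac)
  y <- vs[[field]][i, ]
  if (is.null(times)) return(y)
  w <- flow_waveform(sol$t, y, sol$T)
  waveform_at(w, times)
}

#' Period-averaged mass balance of a solution
#'
#' Compares the period-averaged inflow with the sum of period-averaged
#' outflows over all terminal vessels; for a periodic solution the relative
#' imbalance should be small.
#'
#' @param sol a `pt_solution`.
#' @return a list with `Q_in`, `Q_out` and `imbalance` (relative).
#' @export
mass_balance <- function(sol) {
  net <- sol$network
  root <- as.character(net$root_id)
  Q_in <- mean(sol$vessels[[root]]$q[1, ])
  term <- net$vessels$id[net$vessels$terminal]
  Q_out <- sum(vapply(as.character(term), function(id) {
    qm <- sol$vessels[[id]]$q
    mean(qm[nrow(qm), ])
  }, numeric(1)))
  list(Q_in = Q_in, Q_out = Q_out, imbalance = abs(Q_out - Q_in) / abs(Q_in))
}
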