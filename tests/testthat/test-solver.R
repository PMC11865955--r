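test_that("wall law evaluates, saturates, and rejects bad areas", {
  expect_equal(wall_pressure(2.1, 2.1, 5.6e5, p0_mmhg = 7), 7)
  # A = 4 A0 at the DORV nominal k3: (4/3) * 5.6e5 * 0.5 in CGS
  p <- wall_pressure(4, 1, 5.6e5, p0_mmhg = 0)
  expect_equal(p * 1333.22, (4 / 3) * 5.6e5 * 0.5, tolerance = 1e-12)
  expect_equal(p, 280.0, tolerance = 1e-3)
  # saturation pressure as A -> infinity
  expect_equal(wall_pressure(1e12, 1, 5.6e5) * 1333.22, (4 / 3) * 5.6e5,
               tolerance = 1e-5)
  expect_error(wall_pressure(-1, 1, 5.6e5), "area")
})

test_that("large-vessel stiffness law is the decaying exponential", {
  expect_equal(vessel_stiffness(1.0, 2e7, -25, 5.6e5),
               2e7 * exp(-25) + 5.6e5)
  expect_equal(vessel_stiffness(1.0, 2e7, -25, 5.6e5) / 1e5, 5.600,
               tolerance = 1e-4)
  expect_equal(vessel_stiffness(50, 2e7, -25, 5.6e5), 5.6e5)
  r <- seq(0.05, 1.5, length.out = 40)
  expect_true(all(diff(vessel_stiffness(r, 2e7, -25, 5.6e5)) < 0))
})

test_that("a uniform vessel at rest is an exact discrete equilibrium", {
  net <- single_vessel_net(L = 8, r_in = 0.5, r_out = 0.5)
  T0 <- 0.71
  tt <- seq(0, T0, length.out = 21)[1:20]
  zero <- flow_waveform(tt, rep(0, 20), T0)
  sol <- solve_network(net, zero, nominal_params("DORV"),
                       solver_config(fixed_cycles = 1))
  vs <- sol$vessels[["1"]]
  expect_equal(max(abs(vs$A / vs$A0 - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(vs$q)), 0, tolerance = 1e-9)
})

test_that("interior scheme conserves mass to round-off on a compact pulse", {
  nx <- 201
  x <- seq(0, 40, length.out = nx)
  A0 <- pi * 0.25
  A_init <- A0 * (1 + 0.05 * exp(-(x - 20)^2 / 4))
  out <- pulsetree:::.lw_single_cpp(A_init, rep(0, nx), A0, 7.5e5, 1.06,
                                    0.03, 0.06, 40 / (nx - 1), 1e-4, 120,
                                    FALSE)
  m <- out$mass
  # per-step mass change: the interior flux sums telescope exactly and the
  # quiescent pinned ends contribute no net flux while the pulse is compact
  expect_lt(max(abs(diff(m))) / m[1], 1e-12)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-12)
})

test_that("the two-step scheme converges at second order on a smooth pulse", {
  A0 <- pi * 0.25
  f <- 7.5e5
  run <- function(nx, nsteps) {
    x <- seq(0, 40, length.out = nx)
    A_init <- A0 * (1 + 0.05 * exp(-(x - 20)^2 / 8))
    pulsetree:::.lw_single_cpp(A_init, rep(0, nx), A0, f, 1.06, 0, 0.06,
                               40 / (nx - 1), 0.02 / nsteps, nsteps, FALSE)
  }
  ref <- run(3201, 4096)$A
  err <- sapply(list(c(101, 128), c(201, 256), c(401, 512)), function(g) {
    A <- run(g[1], g[2])$A
    stride <- 3200 / (g[1] - 1)
    sqrt(mean((A - ref[seq(1, 3201, by = stride)])^2))
  })
  order12 <- log2(err[1] / err[2])
  order23 <- log2(err[2] / err[3])
  expect_gte(order12, 1.8)
  expect_gte(order23, 1.8)
})

test_that("a single-child junction between identical vessels is transparent", {
  T0 <- 0.71
  w <- make_inflow(2.5, T0, 20)
  p <- nominal_params("DORV")
  cfg <- solver_config(points_per_cm = 2, periodicity_tol = 1e-4,
                       cycles_max = 40)
  sol2 <- solve_network(chain_net(L1 = 6, L2 = 6, r = 0.5), w, p, cfg)
  sol1 <- solve_network(single_vessel_net(L = 12, r_in = 0.5, r_out = 0.5),
                        w, p, cfg)
  # compare the far-field state: outlet of the chain vs outlet of the
  # single vessel
  q2 <- solution_at(sol2, 2, 1, sol1$t)
  q1 <- solution_at(sol1, 1, 1, sol1$t)
  expect_lt(max(abs(q2 - q1)) / max(abs(q1)), 0.01)
  p2 <- solution_at(sol2, 1, 0, sol1$t, field = "p")
  p1 <- solution_at(sol1, 1, 0, sol1$t, field = "p")
  expect_lt(max(abs(p2 - p1)) / diff(range(p1)), 0.01)
})

test_that("junction and symmetric-daughter flows obey the coupling laws", {
  # symmetric bifurcation: daughters split the parent flow evenly
  v <- data.frame(id = 1:3, length_cm = c(6, 8, 8), r_in_cm = c(0.6, 0.4, 0.4),
                  r_out_cm = c(0.6, 0.4, 0.4), group_large = 1,
                  group_small = c(NA, 1, 1), r_min_cm = c(NA, 0.01, 0.01))
  net <- build_network(v, data.frame(parent = c(1, 1), child = c(2, 3)))
  sol <- solve_network(net, make_inflow(3, 0.71, 20), nominal_params("DORV"),
                       solver_config(periodicity_tol = 1e-4, cycles_max = 40))
  q1 <- sol$vessels[["1"]]$q; q2 <- sol$vessels[["2"]]$q
  q3 <- sol$vessels[["3"]]$q
  expect_equal(q2[1, ], q3[1, ], tolerance = 1e-10)
  # mass conservation at the junction, every step
  expect_lt(max(abs(q1[nrow(q1), ] - q2[1, ] - q3[1, ])), 1e-8)
  # pressure continuity
  p1 <- sol$vessels[["1"]]$p
  p2 <- sol$vessels[["2"]]$p
  expect_lt(max(abs(p1[nrow(p1), ] - p2[1, ])), 1e-8)
})

test_that("terminal boundary reproduces DC, free and closed-end limits", {
  T0 <- 0.71
  net <- single_vessel_net(L = 8, r_in = 0.4, r_out = 0.4)
  p <- nominal_params("DORV")
  # constant inflow against a structured tree: p(L) -> p0 + Z_dc * qbar
  tt <- seq(0, T0, length.out = 21)[1:20]
  const <- flow_waveform(tt, rep(20, 20), T0)
  cfg <- solver_config(periodicity_tol = 1e-7, cycles_max = 80)
  sol <- solve_network(net, const, p, cfg)
  tp <- tree_params(r_min_cm = 0.01, ks1 = p$ks1[1], ks2 = p$ks2[1],
                    ks3 = p$ks3[1])
  zdc <- Re(root_impedance(0.4, tp, T0, 0)$Z[1])
  pL <- solution_at(sol, 1, 1, field = "p")
  expect_equal(mean(pL) * 1333.22, zdc * 20, tolerance = 0.005)
  # zero-impedance kernel: free outflow at the reference pressure
  cfg0 <- solver_config(fixed_cycles = 3)
  cfg0$terminal_Z_fn <- function(omega, vessel) rep(0 + 0i, length(omega))
  sol0 <- solve_network(net, make_inflow(2, T0, 20), p, cfg0)
  expect_lt(max(abs(solution_at(sol0, 1, 1, field = "p"))), 1e-6)
  # huge DC resistance behaves like a closed end: outlet flow dies
  cfgc <- solver_config(fixed_cycles = 30)
  cfgc$terminal_Z_fn <- function(omega, vessel) rep(1e9 + 0i, length(omega))
  solc <- solve_network(net, make_inflow(2, T0, 20), p, cfgc)
  qL <- solution_at(solc, 1, 1)
  expect_lt(max(abs(qL)) / max(sol0$vessels[["1"]]$q[1, ]), 1e-3)
})

test_that("low-amplitude response matches linear impedance theory", {
  T0 <- 0.71
  net <- single_vessel_net(L = 10, r_in = 0.35, r_out = 0.35)
  p <- nominal_params("DORV")
  n <- 64
  tt <- seq(0, T0, length.out = n + 1)[1:n]
  qbar <- 15; eps <- 0.4
  w <- flow_waveform(tt, qbar + eps * sin(2 * pi * tt / T0), T0)
  sol <- solve_network(net, w, p, solver_config(periodicity_tol = 1e-7,
                                                cycles_max = 100))
  # frequency-domain prediction: large vessel as one linearised segment
  # terminated by the structured tree
  omega1 <- 2 * pi / T0
  tp <- tree_params(r_min_cm = 0.01, ks1 = p$ks1[1], ks2 = p$ks2[1],
                    ks3 = p$ks3[1])
  ZL <- root_impedance(0.35, tp, T0, 4)$Z[2]
  Ehr <- vessel_stiffness(0.35, p$k1[1], p$k2[1], p$k3[1])
  Zin <- vessel_input_impedance(ZL, omega1, 0.35, 10, Ehr)
  p0t <- solution_at(sol, 1, 0, field = "p") * 1333.22
  ph <- fft(p0t) / length(p0t)
  amp_model <- 2 * Mod(ph[2])
  amp_theory <- Mod(Zin) * eps
  expect_equal(amp_model, amp_theory, tolerance = 0.05)
})

test_that("canonical run is positive, periodic and mass-conserving", {
  net <- canonical_network("DORV")
  w <- make_inflow(4.0, 0.802, 20)
  sol <- solve_network(net, w, nominal_params("DORV", T = 0.802),
                       solver_config(periodicity_tol = 1e-3))
  expect_true(sol$converged)
  for (vs in sol$vessels) expect_true(all(vs$A > 0))
  mb <- mass_balance(sol)
  expect_lt(mb$imbalance, 0.01)
  # doubling grid resolution moves mid-vessel systolic pressure by < 1%
  sys1 <- summarize_solution(sol, 1, 0.5)$p_sys
  sol2 <- solve_network(net, w, nominal_params("DORV", T = 0.802),
                        solver_config(points_per_cm = 4,
                                      periodicity_tol = 1e-3))
  sys2 <- summarize_solution(sol2, 1, 0.5)$p_sys
  expect_lt(abs(sys2 - sys1) / sys2, 0.01)
})

test_that("pulse-wave speed matches the linearised wall law", {
  # wavefront arrival in a long uniform vessel
  r <- 0.4
  p <- nominal_params("DORV")
  Ehr <- vessel_stiffness(r, p$k1[1], p$k2[1], p$k3[1])
  c0 <- pulse_wave_velocity(Ehr, p$blood$rho)
  L <- 60
  net <- single_vessel_net(L = L, r_in = r, r_out = r)
  T0 <- 0.71
  w <- make_inflow(2, T0, 24)
  sol <- solve_network(net, w, p, solver_config(points_per_cm = 4,
                                                fixed_cycles = 1))
  # arrival = first crossing of 5% of peak flow at inlet/outlet; the first
  # stored column belongs to the end of the start-up cycle, so skip it
  nx <- length(sol$vessels[["1"]]$x)
  tg <- sol$t[-1]
  qi <- sol$vessels[["1"]]$q[1, -1]
  qo <- sol$vessels[["1"]]$q[nx, -1]
  thr <- 0.05 * max(qi)
  t_in <- tg[which(qi > thr)[1]]
  t_out <- tg[which(qo > thr)[1]]
  c_meas <- L / (t_out - t_in)
  expect_equal(c_meas, c0, tolerance = 0.03)
})
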