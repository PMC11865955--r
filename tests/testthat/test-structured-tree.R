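test_that("small-vessel stiffness law evaluates and is monotone", {
  tp0 <- tree_params(ks1 = 0, ks2 = -35, ks3 = 4.2e5)
  expect_equal(small_vessel_stiffness(c(0.01, 0.1, 0.5), tp0),
               rep(4.2e5, 3))
  # nominal constants at r0 = 0.05 cm
  tp <- tree_params(ks1 = 2e7, ks2 = -35, ks3 = 3.8e5)
  expect_equal(small_vessel_stiffness(0.05, tp),
               2e7 * exp(-1.75) + 3.8e5, tolerance = 1e-12)
  expect_equal(small_vessel_stiffness(0.05, tp) / 1e6, 3.855,
               tolerance = 1e-3)
  r <- seq(0.001, 0.5, length.out = 50)
  expect_true(all(diff(small_vessel_stiffness(r, tp)) < 0))
})

test_that("Womersley factor matches a series evaluation at small |w|", {
  nu <- 0.0302
  for (x in c(0.3, 1.2, 3, 5.5)) {
    # choose (r, omega) giving |w0| = x
    r <- 0.05
    omega <- x^2 * nu / r^2
    fj <- womersley_fj(r, omega, nu)
    w <- x * exp(3i * pi / 4)
    fj_ser <- 2 * series_besselj(1, w) / (w * series_besselj(0, w))
    expect_equal(fj, fj_ser, tolerance = 1e-10)
  }
  # low-frequency limit: F_J -> 1
  expect_equal(Mod(womersley_fj(0.01, 1e-6, nu)), 1, tolerance = 1e-6)
})

test_that("single-vessel impedance has the Poiseuille DC limit", {
  mu <- 0.032
  # L = lrr * r0 with lrr = 50
  z0 <- vessel_input_impedance(0 + 0i, 0, r0 = 0.01, L = 0.5,
                               Ehr0 = 1e6, mu = mu)
  expect_equal(Re(z0), 8 * mu * 0.5 / (pi * 0.01^4), tolerance = 1e-12)
  expect_equal(Re(z0) / 1e6, 4.074, tolerance = 1e-3)
  # numeric omega -> 0 limit agrees with the analytic DC branch
  z_eps <- vessel_input_impedance(0 + 0i, 1e-4 * 2 * pi / 0.71, 0.01, 0.5,
                                  1e6, mu = mu)
  expect_lt(Mod(z_eps - z0) / Mod(z0), 1e-6)
  # zero-length vessel is transparent at any frequency
  for (om in c(0, 3, 40)) {
    expect_equal(vessel_input_impedance(123 + 45i, om, 0.05, 0, 1e6),
                 123 + 45i, tolerance = 1e-12)
  }
  expect_error(vessel_input_impedance(NaN + 0i, 1, 0.05, 1, 1e6),
               "finite")
})

test_that("degenerate trees reduce to hand-computed resistances", {
  mu <- 0.032
  # both daughters below the pinch zone: a single Poiseuille segment
  tp <- tree_params(tree_alpha = 0.7, tree_beta = 0.5, lrr = 50,
                    r_min_cm = 0.009)
  z <- root_impedance(0.01, tp, T = 0.7, K_f = 0)
  expect_equal(Re(z$Z[1]), 8 * mu * 50 / (pi * 0.01^3), tolerance = 1e-10)
  # symmetric two-level tree: R_root + R_daughter / 2
  tp2 <- tree_params(tree_alpha = 0.6, tree_beta = 0.6, lrr = 50,
                     r_min_cm = 0.005)
  z2 <- root_impedance(0.01, tp2, T = 0.7, K_f = 0)
  R <- function(r) 8 * mu * 50 / (pi * r^3)
  expect_equal(Re(z2$Z[1]), R(0.01) + R(0.006) / 2, tolerance = 1e-10)
  # an empty tree is rejected
  expect_error(root_impedance(0.001, tp, T = 0.7, K_f = 0), "r_min")
})

test_that("DC impedance equals the brute-force resistor oracle", {
  set.seed(12)
  for (case in 1:6) {
    tp <- tree_params(tree_alpha = runif(1, 0.75, 0.9),
                      tree_beta = runif(1, 0.55, 0.7),
                      lrr = runif(1, 30, 60),
                      r_min_cm = 0.01,
                      ks1 = 2e7, ks2 = -35, ks3 = 3.8e5)
    r_root <- runif(1, 0.03, 0.065)
    or <- oracle_tree(r_root, 0, tp)
    expect_lte(or$n, 200)
    z <- root_impedance(r_root, tp, T = 0.71, K_f = 0)
    expect_equal(Re(z$Z[1]), Re(or$z), tolerance = 1e-8)
  }
})

test_that("memoised spectrum equals naive recursion at pulsatile frequencies", {
  tp <- tree_params(tree_alpha = 0.85, tree_beta = 0.65, lrr = 50,
                    r_min_cm = 0.01)
  spec <- root_impedance(0.08, tp, T = 0.71, K_f = 8)
  for (k in c(1, 4, 8)) {
    zo <- oracle_tree(0.08, spec$omega[k + 1], tp)$z
    expect_lt(Mod(spec$Z[k + 1] - zo) / Mod(zo), 1e-8)
  }
})

test_that("root impedance is passive and grows as r_min shrinks", {
  tp <- function(rmin) tree_params(r_min_cm = rmin)
  spec <- root_impedance(0.3, tp(0.005), T = 0.71, K_f = 64)
  expect_true(all(Re(spec$Z) > 0))
  expect_true(all(is.finite(Mod(spec$Z))))
  expect_true(Im(spec$Z[1]) == 0)
  zdc <- sapply(c(0.02, 0.01, 0.005, 0.002),
                function(rm) Re(root_impedance(0.3, tp(rm), 0.71, 0)$Z[1]))
  expect_true(all(diff(zdc) > 0))
})

test_that("impedance kernels invert the spectrum and keep the DC response", {
  T0 <- 0.71
  # flat real spectrum -> all kernel mass at lag zero
  flat <- structure(list(omega = 2 * pi * (0:32) / T0,
                         Z = rep(1234 + 0i, 33), T = T0),
                    class = "pt_impedance")
  k <- impedance_to_kernel(flat, 64)
  expect_equal(k$z[1], 1234, tolerance = 1e-10)
  expect_equal(max(abs(k$z[-1])), 0, tolerance = 1e-9)
  # any spectrum: convolution with constant flow gives Z_dc * q
  tp <- tree_params(r_min_cm = 0.01)
  spec <- root_impedance(0.2, tp, T0, K_f = 32)
  kz <- impedance_to_kernel(spec, 64)
  expect_equal(sum(kz$z) * 2.5, Re(spec$Z[1]) * 2.5, tolerance = 1e-8)
  # kernel -> spectrum round trip (oversampled so no harmonic sits at the
  # Nyquist mode, which is forced real)
  kz2 <- impedance_to_kernel(spec, 128)
  spec2 <- kernel_to_impedance(kz2, 32)
  expect_equal(spec2$Z, spec$Z, tolerance = 1e-10)
})
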