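test_that("ensemble averaging is pointwise and flags grid mismatches", {
  T0 <- 0.8
  tt <- seq(0, T0, length.out = 11)[1:10]
  w <- flow_waveform(tt, sin(2 * pi * tt / T0), T0)
  ens <- average_ensemble(rep(list(w), 5))
  expect_equal(ens$mean$flow_ml_s, w$flow_ml_s)
  expect_equal(ens$sd, rep(0, 10))

  # symmetric replicates cancel
  reps <- list(w, flow_waveform(tt, -w$flow_ml_s, T0), w,
               flow_waveform(tt, -w$flow_ml_s, T0),
               flow_waveform(tt, 0 * tt, T0))
  expect_equal(average_ensemble(reps)$mean$flow_ml_s, rep(0, 10))

  w2 <- flow_waveform(tt + 0.01, w$flow_ml_s, T0)
  expect_error(average_ensemble(list(w, w2)), "grid")
})

test_that("replicate sd converges to the injected noise level", {
  set.seed(31)
  T0 <- 0.7
  tt <- seq(0, T0, length.out = 6)[1:5]
  sigma <- 0.4
  reps <- lapply(1:10000, function(i) {
    flow_waveform(tt, 10 + rnorm(5, 0, sigma), T0)
  })
  ens <- average_ensemble(reps)
  expect_equal(ens$sd, rep(sigma, 5), tolerance = 0.03)
})

test_that("mass-conservation rescaling has the closed form", {
  T0 <- 0.9
  tt <- seq(0, T0, length.out = 13)[1:12]
  mk <- function(Q) flow_waveform(tt, rep(Q, 12), T0)
  # four equal branches must each shed one sixth
  res <- conserve_mass(mk(100), lapply(c(30, 30, 30, 30), mk))
  expect_equal(res$alpha$alpha, rep(-1 / 6, 4), tolerance = 1e-12)
  expect_equal(sum(res$alpha$Q_scaled), 100, tolerance = 1e-10)
  # already conservative: nothing to do
  res0 <- conserve_mass(mk(90), lapply(c(40, 50), mk))
  expect_equal(res0$alpha$alpha, c(0, 0), tolerance = 1e-14)
  # a single branch is forced onto the inlet
  res1 <- conserve_mass(mk(60), list(mk(50)))
  expect_equal(res1$alpha$alpha, 0.2, tolerance = 1e-12)
  expect_equal(mean_flow(res1$scaled[[1]]), 60, tolerance = 1e-12)
  expect_error(conserve_mass(mk(60), list(mk(0), mk(0))), "degenerate")
})

test_that("rescaling is the minimum-norm feasible scaling", {
  # oracle: eliminate the equality constraint and minimise ||alpha||^2
  # numerically over the remaining free coordinates
  set.seed(42)
  T0 <- 0.75
  tt <- seq(0, T0, length.out = 9)[1:8]
  for (case in 1:100) {
    n <- sample(2:5, 1)
    Q <- runif(n, 5, 60)
    Qin <- sum(Q) * runif(1, 0.7, 1.3)
    branches <- lapply(Q, function(q) {
      flow_waveform(tt, q + 0.3 * q * sin(2 * pi * tt / T0), T0)
    })
    inlet <- flow_waveform(tt, rep(Qin, 8), T0)
    res <- conserve_mass(inlet, branches)
    a <- res$alpha$alpha
    # feasibility to 1e-10 relative
    expect_lt(abs(sum((1 + a) * Q) - Qin) / Qin, 1e-10)
    # numeric minimiser over the free coordinates
    obj <- function(af) {
      an <- (Qin - sum(Q) - sum(af * Q[-n])) / Q[n]
      sum(af^2) + an^2
    }
    opt <- optim(rep(0, n - 1), obj, method = "BFGS",
                 control = list(reltol = 1e-14))
    a_or <- c(opt$par, (Qin - sum(Q) - sum(opt$par * Q[-n])) / Q[n])
    expect_equal(a, a_or, tolerance = 1e-5)
  }
})

test_that("pointwise rescaling and CSV round trip work", {
  T0 <- 0.7
  tt <- seq(0, T0, length.out = 13)[1:12]
  q1 <- 30 + 10 * sin(2 * pi * tt / T0)
  q2 <- 20 + 5 * cos(2 * pi * tt / T0)
  inlet <- flow_waveform(tt, 1.07 * (q1 + q2), T0)
  res <- conserve_mass(inlet, list(flow_waveform(tt, q1, T0),
                                   flow_waveform(tt, q2, T0)),
                       pointwise = TRUE)
  # the least-squares factors reduce the pointwise misfit
  mis0 <- sum((inlet$flow_ml_s - q1 - q2)^2)
  mis1 <- sum((inlet$flow_ml_s - res$scaled[[1]]$flow_ml_s -
                 res$scaled[[2]]$flow_ml_s)^2)
  expect_lt(mis1, mis0)
  # CSV round trip preserves samples and period
  f <- withr::local_tempfile(fileext = ".csv")
  write_waveform(inlet, f)
  w2 <- read_waveform(f)
  expect_equal(w2$flow_ml_s, inlet$flow_ml_s)
  expect_equal(attr(w2, "period"), T0)
})

test_that("trigonometric resampling is exact for band-limited input", {
  T0 <- 0.8
  # constant waveform stays constant
  tt <- seq(0, T0, length.out = 21)[1:20]
  wc <- resample_periodic(flow_waveform(tt, rep(3.3, 20), T0), 200)
  expect_equal(wc$flow_ml_s, rep(3.3, 200), tolerance = 1e-12)
  # a single harmonic is reproduced exactly off-grid
  w <- flow_waveform(tt, sin(2 * pi * tt / T0), T0)
  w2 <- resample_periodic(w, 200)
  expect_equal(w2$flow_ml_s, sin(2 * pi * w2$time_s / T0),
               tolerance = 1e-10)
  # the period average (DC mode) is preserved to machine precision
  set.seed(5)
  tt21 <- seq(0, T0, length.out = 22)[1:21]
  wr <- flow_waveform(tt21, rnorm(21), T0)
  expect_lt(abs(mean_flow(resample_periodic(wr, 210)) - mean_flow(wr)),
            1e-12)
})

test_that("resampling commutes with grid-aligned time shifts", {
  T0 <- 0.6
  n <- 12
  tt <- seq(0, T0, length.out = n + 1)[1:n]
  set.seed(8)
  q <- rnorm(n)
  for (s in c(1, 3, 7)) {
    shifted <- flow_waveform(tt, q[((seq_len(n) - 1 + s) %% n) + 1], T0)
    r1 <- resample_periodic(shifted, 4 * n)$flow_ml_s
    r0 <- resample_periodic(flow_waveform(tt, q, T0), 4 * n)$flow_ml_s
    r0s <- r0[((seq_len(4 * n) - 1 + 4 * s) %% (4 * n)) + 1]
    expect_equal(r1, r0s, tolerance = 1e-10)
  }
})
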