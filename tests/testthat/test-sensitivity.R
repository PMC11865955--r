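# analytic residual used as a cheap stand-in model: three influential
# parameters, one inert, mild nonlinearity and a correlated pair
surrogate_resid <- function(th) {
  x <- log(th)
  c(3 * x[["a"]] + 0.5 * x[["b"]]^2,
    2 * x[["a"]] - x[["b"]],
    1.5 * x[["c"]] + 0.2 * sin(x[["a"]]),
    x[["c"]] - 0.8 * x[["d"]])
}

test_that("local sensitivities are exact for linear maps and rank by norm", {
  B <- matrix(c(1, 0, 2, -1, 0.5, 3), nrow = 2)
  rf <- function(th) as.numeric(B %*% log(th))
  th <- c(p1 = 2, p2 = 1.5, p3 = 0.7)
  s <- local_sensitivity(rf, th, sa_config(psi = 0.01))
  expect_equal(unname(s$S), B, tolerance = 1e-10)
  expect_equal(s$ranking$parameter[1], "p3")   # largest column norm
  # duplicate parameters produce identical columns and norms
  rf2 <- function(th) c(log(th[["x"]]) + log(th[["y"]]))
  s2 <- local_sensitivity(rf2, c(x = 1.3, y = 1.3), sa_config())
  expect_equal(unname(s2$S[, "x"]), unname(s2$S[, "y"]),
               tolerance = 1e-12)
  expect_equal(unname(s2$norms["x"]), unname(s2$norms["y"]),
               tolerance = 1e-12)
})

test_that("centred differences carry second-order truncation error", {
  rf <- function(th) sin(log(th[["x"]]))
  th <- c(x = exp(0.7))
  exact <- cos(0.7)
  err <- sapply(c(0.1, 0.05), function(psi) {
    abs(local_sensitivity(rf, th, sa_config(psi = psi))$S[1, 1] - exact)
  })
  expect_equal(unname(err[1] / err[2]), 4, tolerance = 0.2)
})

test_that("Morris step size and summaries follow the elementary-effect rules", {
  cfg <- sa_config(M = 60, K = 30)
  expect_equal(cfg$delta, 60 / (2 * 59))
  expect_equal(round(cfg$delta, 3), 0.508)
  th <- c(a = 1, b = 2, c = 0.5, d = 1.1)
  # linear residual in unit-cube coordinates: constant elementary effects
  lin <- function(th) c(5 * th[["a"]], -2 * th[["b"]])
  m <- morris_screening(lin, th, config = cfg, seed = 4)
  expect_equal(unname(m$sigma2["a"]), 0, tolerance = 1e-18)
  expect_equal(unname(m$sigma2["b"]), 0, tolerance = 1e-18)
  # mu* reflects the bound-width scaling of each parameter
  b <- sa_bounds(th, cfg)
  expect_equal(unname(m$mu_star["a"]),
               5 * (b$upper[["a"]] - b$lower[["a"]]), tolerance = 1e-10)
  # inert parameters score zero and rank last
  expect_equal(unname(m$mu_star["c"] + m$sigma2["c"]), 0)
  expect_true(all(m$ranking$rank[m$ranking$parameter %in% c("c", "d")] >=
                    3))
})

test_that("Morris screening is reproducible and stable across seeds", {
  th <- c(a = 1.1, b = 0.9, c = 1.2, d = 1.4)
  cfg <- sa_config(K = 25)
  m1 <- morris_screening(surrogate_resid, th, config = cfg, seed = 11)
  m2 <- morris_screening(surrogate_resid, th, config = cfg, seed = 11)
  expect_identical(m1$effects, m2$effects)
  # the top-3 set is stable across seeds and matches the local top-3
  loc <- local_sensitivity(surrogate_resid, th, sa_config())
  top_local <- loc$ranking$parameter[1:3]
  for (s in 1:10) {
    m <- morris_screening(surrogate_resid, th, config = cfg, seed = s)
    expect_setequal(m$ranking$parameter[1:3], top_local)
  }
})

test_that("correlation analysis flags collinearity and ignores s2", {
  # orthogonal, equal-norm columns: identity correlation
  S <- structure(list(S = diag(3) * 2, norms = rep(2, 3),
                      ranking = tibble::tibble(parameter = c("a", "b", "c"),
                                               S_norm = 2, rank = 1:3)),
                 class = "pt_sensitivity")
  colnames(S$S) <- c("a", "b", "c")
  cv <- correlation_analysis(S, sa_config())
  expect_equal(unname(cv$correlation), diag(3), tolerance = 1e-12)
  expect_equal(nrow(cv$pairs), 0)
  # hand-computed 3-parameter case with Gram [[2,1,0],[1,2,0],[0,0,1]]:
  # V = s2 * [[2/3,-1/3,0],[-1/3,2/3,0],[0,0,1]], correlation(a,b) = -1/2
  Sh <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0, 0, 0, 0, 1), nrow = 4)
  colnames(Sh) <- c("a", "b", "c")
  Sv <- structure(list(S = Sh), class = "pt_sensitivity")
  cv2 <- correlation_analysis(Sv, sa_config())
  expect_equal(cv2$correlation["a", "b"], -0.5, tolerance = 1e-10)
  expect_equal(diag(cv2$correlation), c(a = 1, b = 1, c = 1))
  # correlation is invariant to the observation variance
  cv3 <- correlation_analysis(Sv, sa_config(s2 = 37.5))
  expect_equal(cv3$correlation, cv2$correlation, tolerance = 1e-12)
  # proportional columns saturate |v| and get flagged
  Sp <- cbind(a = c(1, 2, 3), b = c(2.0001, 4.0001, 6.0004),
              c = c(0, 1, -1))
  cvp <- correlation_analysis(structure(list(S = Sp),
                                        class = "pt_sensitivity"),
                              sa_config())
  expect_true(any(cvp$pairs$par1 == "a" & cvp$pairs$par2 == "b"))
  expect_gt(abs(cvp$correlation["a", "b"]), 0.9)
})

test_that("subset selection drops weak and correlated parameters", {
  th <- c(a = 1.1, b = 0.9, c = 1.2, d = 1.4)
  loc <- local_sensitivity(surrogate_resid, th, sa_config())
  mor <- morris_screening(surrogate_resid, th, config = sa_config(K = 20),
                          seed = 2)
  cv <- correlation_analysis(loc, sa_config())
  sub <- select_subset(loc, mor, cv)
  # the inert direction 'd' only enters through the pair with 'c'
  expect_true(all(sub$keep %in% c("a", "b", "c", "d")))
  expect_true(length(sub$keep) >= 1)
  # no correlations, all influential: keep everything
  S <- structure(list(S = diag(3), norms = rep(1, 3),
                      ranking = tibble::tibble(parameter = c("a", "b", "c"),
                                               S_norm = 1, rank = 1:3)),
                 class = "pt_sensitivity")
  colnames(S$S) <- c("a", "b", "c")
  names(S$norms) <- c("a", "b", "c")
  mor3 <- structure(list(ranking = tibble::tibble(
    parameter = c("a", "b", "c"), mu_star = 1, sigma2 = 0, score = 1,
    rank = 1:3)), class = "pt_morris")
  cv3 <- correlation_analysis(S, sa_config())
  sub3 <- select_subset(S, mor3, cv3)
  expect_setequal(sub3$keep, c("a", "b", "c"))
  # within a flagged pair the lower-ranked member is fixed
  expect_true(all(sub$log$action == "fixed"))
})
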