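#' Sensitivity-analysis configuration
#'
#' @param psi centred-difference step on log-scaled parameters.
#' @param K number of Morris samples (elementary effects per parameter).
#' @param M number of Morris grid levels (even).
#' @param range_stiffness relative perturbation range for stiffness
#'   parameters (+-10% nominally).
#' @param range_tree relative perturbation range for the structured-tree
#'   constants (+-5% nominally).
#' @param corr_threshold absolute correlation above which a parameter pair is
#'   flagged as correlated.
#' @param s2 constant observation variance used in the covariance matrix.
#' @return a list of class `pt_sa_config`. The Morris step is
#'   `delta = M / (2 (M - 1))` in unit-hypercube coordinates.
#' @export
sa_config <- function(psi = 0.01, K = 100, M = 60, range_stiffness = 0.10,
                      range_tree = 0.05, corr_threshold = 0.9, s2 = 1) {
  stopifnot(psi > 0, psi < 1, M %% 2 == 0, K >= 2)
  structure(list(psi = psi, K = K, M = M, delta = M / (2 * (M - 1)),
                 range_stiffness = range_stiffness, range_tree = range_tree,
                 corr_threshold = corr_threshold, s2 = s2),
            class = "pt_sa_config")
}

#' Local derivative-based sensitivity of a residual vector
#'
#' Centred finite differences of the residual with respect to log-scaled
#' parameters: column n is
#' `(r(exp(ltheta + psi e_n)) - r(exp(ltheta - psi e_n))) / (2 psi)`.
#' Log scaling keeps parameters positive and on a common scale. Parameters
#' are ranked by the 2-norm of their sensitivity column. If the residual
#' cannot be evaluated at a perturbed point, a one-sided difference is used
#' with a warning.
#'
#' @param residual_fn function taking a named numeric parameter vector and
#'   returning a numeric residual vector.
#' @param theta named numeric vector of nominal parameter values (positive).
#' @param config a `pt_sa_config`.
#' @return a list of class `pt_sensitivity`: `S` (residual-length x n_par
#'   matrix of derivatives w.r.t. log-parameters), `norms`, and `ranking` (a
#'   tibble sorted from most to least influential).
#' @export
local_sensitivity <- function(residual_fn, theta, config = sa_config()) {
  stopifnot(all(theta > 0))
  psi <- config$psi
  lt <- log(theta)
  nm <- names(theta)
  cols <- lapply(seq_along(theta), function(n) {
    up <- lt; up[n] <- up[n] + psi
    dn <- lt; dn[n] <- dn[n] - psi
    r_up <- try(residual_fn(setNames(exp(up), nm)), silent = TRUE)
    r_dn <- try(residual_fn(setNames(exp(dn), nm)), silent = TRUE)
    if (inherits(r_up, "try-error") && inherits(r_dn, "try-error")) {
      abort(sprintf("residual evaluation failed on both sides for '%s'",
                    nm[n]))
    }
    if (inherits(r_up, "try-error") || inherits(r_dn, "try-error")) {
      warn(sprintf("one-sided difference used for '%s'", nm[n]))
      r0 <- residual_fn(theta)
      if (inherits(r_up, "try-error")) (r0 - r_dn) / psi
      else (r_up - r0) / psi
    } else {
      (r_up - r_dn) / (2 * psi)
    }
  })
  S <- do.call(cbind, cols)
  colnames(S) <- nm
  norms <- sqrt(colSums(S^2))
  ranking <- tibble(parameter = nm, S_norm = norms) %>%
    arrange(dplyr::desc(.data$S_norm)) %>%
    mutate(rank = dplyr::row_number())
  structure(list(S = S, norms = norms, ranking = ranking, psi = psi),
            class = "pt_sensitivity")
}

#' Perturbation bounds for global screening
#'
#' Stiffness parameters are perturbed +-10% and the structured-tree
#' constants (`tree_alpha`, `tree_beta`, `lrr`) +-5% about their nominal
#' values, keeping the sweep within a physiological range.
#'
#' @param theta named nominal magnitudes.
#' @param config a `pt_sa_config`.
#' @return list with named vectors `lower` and `upper`.
#' @export
sa_bounds <- function(theta, config = sa_config()) {
  is_tree <- grepl("^(tree_alpha|tree_beta|lrr)", names(theta))
  r <- ifelse(is_tree, config$range_tree, config$range_stiffness)
  # bounds must bracket theta regardless of sign
  lower <- theta - r * abs(theta)
  upper <- theta + r * abs(theta)
  list(lower = lower, upper = upper)
}

#' Morris elementary-effects screening
#'
#' Global one-at-a-time screening on an M-level grid in unit-hypercube
#' coordinates with step `delta = M / (2 (M - 1))`. For each of `K`
#' trajectories a random grid point is drawn and each parameter is perturbed
#' once by +-delta; the elementary effect is
#' `d_n = (r(x + delta e_n) - r(x)) / delta`, summarised per parameter by the
#' 2-norm over the residual. `mu_star` is the mean absolute effect norm,
#' `sigma2` the sample variance; parameters are ranked by
#' `mu_star^2 + sigma2` (ties broken by `mu_star`).
#'
#' @param residual_fn function of a named parameter vector returning a
#'   residual vector.
#' @param lower,upper named bounds defining the hypercube (see
#'   [sa_bounds()]); defaults derived from `theta` and `config`.
#' @param theta nominal parameter values (used for default bounds).
#' @param config a `pt_sa_config`.
#' @param seed integer seed; the design is deterministic given the seed.
#' @return a list of class `pt_morris`: `effects` (K x n_par matrix of
#'   effect norms), `mu_star`, `sigma2`, `score`, `ranking`.
#' @export
morris_screening <- function(residual_fn, theta, lower = NULL, upper = NULL,
                             config = sa_config(), seed = 1) {
  nm <- names(theta)
  if (is.null(lower) || is.null(upper)) {
    b <- sa_bounds(theta, config)
    lower <- b$lower; upper <- b$upper
  }
  stopifnot(all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower))
  B <- length(theta)
  M <- config$M; delta <- config$delta; K <- config$K
  to_theta <- function(x) setNames(lower + x * (upper - lower), nm)
  # grid levels {0, 1/(M-1), ..., 1}; base points drawn so that one +-delta
  # step stays inside the unit interval
  levels <- (0:(M - 1)) / (M - 1)
  set.seed(seed)
  D <- matrix(NA_real_, K, B, dimnames = list(NULL, nm))
  k <- 1
  while (k <= K) {
    x0 <- levels[sample.int(M, B, replace = TRUE)]
    dir <- ifelse(x0 + delta <= 1, 1, -1)
    ok <- TRUE
    r0 <- try(residual_fn(to_theta(x0)), silent = TRUE)
    if (inherits(r0, "try-error")) {
      message("residual evaluation failed at a Morris grid point; ",
              "resampling the trajectory")
      next
    }
    for (n in seq_len(B)) {
      x1 <- x0
      x1[n] <- x1[n] + dir[n] * delta
      r1 <- try(residual_fn(to_theta(x1)), silent = TRUE)
      if (inherits(r1, "try-error")) {
        message("residual evaluation failed at a Morris grid point; ",
                "resampling the trajectory")
        ok <- FALSE
        break
      }
      d <- (r1 - r0) / (dir[n] * delta)
      D[k, n] <- sqrt(sum(d^2))
    }
    if (ok) k <- k + 1
  }
  mu_star <- colMeans(abs(D))
  sigma2 <- apply(D, 2, var)
  score <- mu_star^2 + sigma2
  ranking <- tibble(parameter = nm, mu_star = mu_star, sigma2 = sigma2,
                    score = score) %>%
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$mu_star)) %>%
    mutate(rank = dplyr::row_number())
  structure(list(effects = D, mu_star = mu_star, sigma2 = sigma2,
                 score = score, ranking = ranking, delta = delta,
                 seed = seed),
            class = "pt_morris")
}

#' Covariance / correlation identifiability analysis
#'
#' Builds the asymptotic covariance `V = s2 * solve(t(S) %*% S)` from a local
#' sensitivity matrix and the correlation matrix
#' `v_nj = V_nj / sqrt(V_nn V_jj)`; pairs with `|v| >` the threshold are
#' flagged as practically correlated. A singular information matrix is
#' handled with a pseudo-inverse and reported as structural
#' non-identifiability.
#'
#' @param sens a `pt_sensitivity`.
#' @param config a `pt_sa_config`.
#' @return a list of class `pt_covariance`: `V`, `correlation`, `pairs` (a
#'   tibble of flagged pairs), `rank_deficient`.
#' @export
correlation_analysis <- function(sens, config = sa_config()) {
  stopifnot(inherits(sens, "pt_sensitivity"))
  S <- sens$S
  G <- crossprod(S)
  nm <- colnames(S)
  rank_def <- FALSE
  V <- tryCatch(config$s2 * solve(G), error = function(e) NULL)
  if (is.null(V) || !all(is.finite(V)) || kappa(G) > 1e12) {
    rank_def <- TRUE
    V <- config$s2 * MASS::ginv(G)
    dimnames(V) <- list(nm, nm)
  }
  dv <- sqrt(abs(diag(V)))
  corr <- V / outer(dv, dv)
  diag(corr) <- 1
  idx <- which(upper.tri(corr) & abs(corr) > config$corr_threshold,
               arr.ind = TRUE)
  pairs <- tibble(par1 = nm[idx[, 1]], par2 = nm[idx[, 2]],
                  correlation = corr[idx])
  structure(list(V = V, correlation = corr, pairs = pairs,
                 rank_deficient = rank_def,
                 threshold = config$corr_threshold),
            class = "pt_covariance")
}

#' Select an influential, uncorrelated parameter subset
#'
#' Deterministic rule combining the three analyses: (1) parameters whose
#' local sensitivity norm falls below `influence_cutoff` times the maximum
#' norm are dropped; (2) within each flagged correlated pair the
#' lower-ranked member (by the average of local and Morris ranks) is fixed.
#' Every decision is recorded in an audit log.
#'
#' @param sens_local a `pt_sensitivity`.
#' @param sens_morris a `pt_morris`.
#' @param corr a `pt_covariance`.
#' @param influence_cutoff relative influence cutoff (fraction of the top
#'   local sensitivity norm).
#' @return a list of class `pt_subset`: `keep` (parameter names), `fixed`,
#'   `log` (tibble of decisions).
#' @export
select_subset <- function(sens_local, sens_morris, corr,
                          influence_cutoff = 0.01) {
  nm <- sens_local$ranking$parameter
  lrank <- setNames(sens_local$ranking$rank, sens_local$ranking$parameter)
  mrank <- setNames(sens_morris$ranking$rank, sens_morris$ranking$parameter)
  avg_rank <- (lrank[nm] + mrank[nm]) / 2
  keep <- nm
  log <- tibble(parameter = character(), action = character(),
                reason = character())
  cutoff <- influence_cutoff * max(sens_local$norms)
  weak <- nm[sens_local$norms[nm] < cutoff]
  for (w in weak) {
    keep <- setdiff(keep, w)
    log <- bind_rows(log, tibble(parameter = w, action = "fixed",
                                 reason = "below influence cutoff"))
  }
  if (nrow(corr$pairs)) {
    for (i in seq_len(nrow(corr$pairs))) {
      a <- corr$pairs$par1[i]; b <- corr$pairs$par2[i]
      if (!(a %in% keep) || !(b %in% keep)) next
      drop <- if (avg_rank[a] <= avg_rank[b]) b else a
      keep <- setdiff(keep, drop)
      log <- bind_rows(log, tibble(
        parameter = drop, action = "fixed",
        reason = sprintf("correlated with %s (|v| = %.3f)",
                         if (drop == a) b else a,
                         abs(corr$pairs$correlation[i]))))
    }
  }
  if (!length(keep)) abort("subset selection removed every parameter")
  structure(list(keep = keep, fixed = setdiff(nm, keep), log = log),
            class = "pt_subset")
}

#' @method tidy pt_sensitivity
#' @export
tidy.pt_sensitivity <- function(x, ...) x$ranking

#' @method tidy pt_morris
#' @export
tidy.pt_morris <- function(x, ...) x$ranking

#' @method tidy pt_covariance
#' @export
tidy.pt_covariance <- function(x, ...) x$pairs
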