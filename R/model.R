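#' Named parameter vectors for calibration
#'
#' Calibration and sensitivity analysis act on a named positive vector
#' `theta`. Recognised names are the structured-tree constants
#' (`tree_alpha`, `tree_beta`, `lrr`), per-group large-vessel stiffness
#' (`k1_g1`..`k3_g4`), and per-group or global small-vessel stiffness
#' (`ks1_g1`.., `ks2`, `ks3` ...). A name without the `_gN` suffix applies to
#' all four groups. The decaying stiffness exponents `k2`/`ks2` are
#' physically negative; in `theta` they are carried as positive magnitudes
#' (log-scaling requires positivity) and the negative sign is restored when
#' the vector is applied.
#'
#' `apply_theta()` returns a copy of `params` with the entries of `theta`
#' substituted; `theta_nominal()` extracts the nominal magnitudes of the
#' named parameters from a `pt_params`.
#'
#' @param params a `pt_params`.
#' @param theta named numeric vector (positive magnitudes).
#' @return `apply_theta()`: a `pt_params`; `theta_nominal()`: a named
#'   numeric vector.
#' @export
apply_theta <- function(params, theta) {
  stopifnot(inherits(params, "pt_params"), !is.null(names(theta)))
  neg <- c("k2", "ks2")
  for (nm in names(theta)) {
    val <- unname(theta[[nm]])
    if (nm %in% c("tree_alpha", "tree_beta", "lrr")) {
      params[[nm]] <- val
      next
    }
    m <- regmatches(nm, regexec("^(ks?[123])(_g([1-4]))?$", nm))[[1]]
    if (!length(m)) abort(sprintf("unknown parameter name '%s'", nm))
    base <- m[2]
    if (base %in% neg) val <- -val
    if (m[4] == "") params[[base]] <- rep(val, 4)
    else params[[base]][as.integer(m[4])] <- val
  }
  params
}

#' @rdname apply_theta
#' @param names parameter names to extract.
#' @export
theta_nominal <- function(params, names) {
  vapply(names, function(nm) {
    if (nm %in% c("tree_alpha", "tree_beta", "lrr")) {
      return(params[[nm]])
    }
    m <- regmatches(nm, regexec("^(ks?[123])(_g([1-4]))?$", nm))[[1]]
    if (!length(m)) abort(sprintf("unknown parameter name '%s'", nm))
    v <- if (m[4] == "") params[[m[2]]][1]
         else params[[m[2]]][as.integer(m[4])]
    abs(v)
  }, numeric(1))
}

#' Default calibration bounds
#'
#' Stiffness magnitudes are bounded at 50-150% of nominal; the
#' structured-tree constants are restricted to ranges that keep the tree
#' well formed (`tree_beta <= tree_alpha < 1`).
#'
#' @param theta named nominal magnitudes.
#' @return list with named vectors `lower`, `upper`.
#' @export
default_bounds <- function(theta) {
  lower <- 0.5 * theta
  upper <- 1.5 * theta
  for (nm in names(theta)) {
    if (nm == "tree_alpha") { lower[nm] <- 0.70; upper[nm] <- 0.98 }
    if (nm == "tree_beta") { lower[nm] <- 0.35; upper[nm] <- 0.85 }
    if (nm == "lrr") { lower[nm] <- 20; upper[nm] <- 100 }
  }
  list(lower = lower, upper = upper)
}

#' Residuals between a model solution and calibration data
#'
#' Flow residuals per site are `(q_model - q_data) / max(q_data)` at the
#' data time points; the two pressure residuals are the relative systolic
#' and diastolic mismatches at the cuff site.
#'
#' @param model_flows matrix (Tp x n_sites) of model flows at the data time
#'   points.
#' @param data_flows matrix (Tp x n_sites) of measured (site-mean) flows.
#' @param model_sysdia numeric length 2: model systolic and diastolic
#'   pressure at the cuff site (mmHg).
#' @param cuff numeric length 2: measured systolic and diastolic pressure.
#' @return a list of class `pt_residuals`: `rq` (list of per-site residual
#'   vectors), `rp` (length 2), and the concatenated vector `all`.
#' @export
residual_set <- function(model_flows, data_flows, model_sysdia = NULL,
                         cuff = NULL) {
  stopifnot(all(dim(model_flows) == dim(data_flows)))
  qmax <- apply(abs(data_flows), 2, max)
  if (any(qmax == 0)) abort("a calibration site has zero peak flow")
  rq <- lapply(seq_len(ncol(data_flows)), function(i) {
    (model_flows[, i] - data_flows[, i]) / qmax[i]
  })
  rp <- if (!is.null(cuff)) {
    c((model_sysdia[1] - cuff[1]) / cuff[1],
      (model_sysdia[2] - cuff[2]) / cuff[2])
  } else numeric(0)
  structure(list(rq = rq, rp = rp, all = c(unlist(rq), rp)),
            class = "pt_residuals")
}

#' Residual sum of squares
#'
#' Sum of squared flow residuals over all sites and time points plus the two
#' squared relative pressure residuals.
#'
#' @param res a `pt_residuals`.
#' @return scalar RSS.
#' @export
rss <- function(res) {
  stopifnot(inherits(res, "pt_residuals"))
  sum(res$all^2)
}

#' Forward-model factory for a calibration problem
#'
#' Packages a network, inflow, calibration sites and data into closures used
#' by sensitivity analysis and inference:
#' \describe{
#'   \item{`flows(theta)`}{model flows at the data time points, one column
#'     per site.}
#'   \item{`sysdia(theta)`}{systolic/diastolic model pressure at the cuff
#'     site.}
#'   \item{`residual_flow(theta)`}{concatenated flow residual blocks
#'     (the sensitivity quantity of interest).}
#'   \item{`residual_full(theta)`}{flow blocks plus pressure residuals.}
#'   \item{`rss(theta)`}{the scalar objective.}
#' }
#' The forward solve uses a fixed cycle count so the objective is a smooth,
#' deterministic function of `theta` (finite-difference gradients require
#' this); the same solution is reused across the closures via a one-slot
#' cache keyed on `theta`.
#'
#' @param net a `pt_network`.
#' @param inflow a `pt_waveform`.
#' @param params nominal `pt_params` (entries of `theta` override it).
#' @param sites tibble with columns `vessel`, `x_frac` (calibration sites).
#' @param times data time points within the cycle (s).
#' @param data_flows matrix (length(times) x nrow(sites)) of measured flows,
#'   or `NULL` when only forward evaluation is needed.
#' @param cuff measured (sys, dia) pressures (mmHg), or `NULL`.
#' @param cuff_site list/row with `vessel`, `x_frac` of the cuff location.
#' @param config a `pt_config`; `fixed_cycles` defaults to 4 here.
#' @param include_pressure_in_qoi include the pressure residuals in the
#'   sensitivity quantity of interest (default `FALSE`: flows only).
#' @return a list of class `pt_model` with the closures above plus the
#'   stored inputs.
#' @export
forward_model <- function(net, inflow, params, sites, times,
                          data_flows = NULL, cuff = NULL, cuff_site = NULL,
                          config = NULL,
                          include_pressure_in_qoi = FALSE) {
  if (is.null(config)) {
    config <- solver_config(points_per_cm = 1, min_points = 4, cfl = 0.8,
                            fixed_cycles = 4, kernel_harmonics = 64)
  }
  if (is.null(config$fixed_cycles)) config$fixed_cycles <- 4
  if (is.null(config$n_t)) {
    config$n_t <- choose_nt(net, wf_period(inflow), params, config)
  }
  cache <- new.env(parent = emptyenv())
  cache$key <- NULL
  solve_for <- function(theta) {
    key <- paste(names(theta), signif(theta, 15), collapse = ";")
    if (identical(cache$key, key)) return(cache$sol)
    sol <- solve_network(net, inflow, apply_theta(params, theta), config)
    cache$key <- key
    cache$sol <- sol
    sol
  }
  flows <- function(theta) {
    sol <- solve_for(theta)
    vapply(seq_len(nrow(sites)), function(i) {
      solution_at(sol, sites$vessel[i], sites$x_frac[i], times, "q")
    }, numeric(length(times)))
  }
  sysdia <- function(theta) {
    sol <- solve_for(theta)
    p <- solution_at(sol, cuff_site$vessel, cuff_site$x_frac, NULL, "p")
    c(max(p), min(p))
  }
  resid_full <- function(theta) {
    rs <- residual_set(flows(theta), data_flows,
                       if (!is.null(cuff)) sysdia(theta) else NULL, cuff)
    rs$all
  }
  resid_flow <- function(theta) {
    rs <- residual_set(flows(theta), data_flows)
    if (include_pressure_in_qoi && !is.null(cuff)) {
      return(c(rs$all, residual_set(flows(theta), data_flows,
                                    sysdia(theta), cuff)$rp))
    }
    rs$all
  }
  structure(list(
    flows = flows, sysdia = sysdia,
    residual_flow = resid_flow, residual_full = resid_full,
    rss = function(theta) sum(resid_full(theta)^2),
    net = net, inflow = inflow, params = params, sites = sites,
    times = times, data_flows = data_flows, cuff = cuff,
    cuff_site = cuff_site, config = config),
    class = "pt_model")
}

#' Per-site coefficient of determination of model flows
#'
#' `R^2 = 1 - SS_res / SS_tot` of the model flow waveform against the
#' site-mean measured waveform, per calibration site.
#'
#' @param model a `pt_model`.
#' @param theta parameter vector at which to evaluate.
#' @return named numeric vector of R^2 values, one per site.
#' @export
model_r2 <- function(model, theta) {
  qm <- model$flows(theta)
  qd <- model$data_flows
  r2 <- vapply(seq_len(ncol(qd)), function(i) {
    1 - sum((qm[, i] - qd[, i])^2) / sum((qd[, i] - mean(qd[, i]))^2)
  }, numeric(1))
  names(r2) <- if (!is.null(model$sites$site)) model$sites$site
               else paste0("site", seq_len(ncol(qd)))
  r2
}
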