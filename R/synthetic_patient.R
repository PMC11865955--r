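#' Noise model for synthetic patients
#'
#' @param flow_noise multiplicative Gaussian noise s.d. per replicate flow
#'   sample (0.05 = 5%).
#' @param deconservation range of the per-vessel bias factor magnitude by
#'   which branch flows violate mass conservation before rescaling; `c(0,0)`
#'   disables it.
#' @param cuff_sd s.d. (mmHg) of the cuff measurement offset.
#' @param n_replicates flow waveform replicates per site.
#' @param geom_sd s.d. of the multiplicative log-normal geometry jitter.
#' @return a list of class `pt_noise`.
#' @export
noise_config <- function(flow_noise = 0.05, deconservation = c(0.05, 0.15),
                         cuff_sd = 2, n_replicates = 5, geom_sd = 0.05) {
  structure(list(flow_noise = flow_noise, deconservation = deconservation,
                 cuff_sd = cuff_sd, n_replicates = n_replicates,
                 geom_sd = geom_sd),
            class = "pt_noise")
}

#' Parametric cardiac inflow waveform
#'
#' Half-sine systolic ejection over a fraction of the cycle plus a small
#' diastolic baseline, scaled so that the period-averaged flow equals the
#' cardiac output: `CO` l/min corresponds to `CO * 1000 / 60` ml/s.
#'
#' @param CO_l_min cardiac output (l/min), in the observed range 2.8-5.4.
#' @param T cardiac period (s), in the observed range 0.598-0.942.
#' @param Tp number of samples per cycle (19-28 for emulated velocimetry).
#' @param systolic_fraction fraction of the cycle occupied by ejection.
#' @param baseline_frac diastolic baseline as a fraction of peak flow.
#' @return a `pt_waveform` with `Tp` samples.
#' @examples
#' w <- make_inflow(4.0, 0.802, 20)
#' mean_flow(w) # 66.67 ml/s
#' @export
make_inflow <- function(CO_l_min, T, Tp, systolic_fraction = 0.35,
                        baseline_frac = 0.03) {
  stopifnot(CO_l_min > 0, T > 0, Tp >= 4)
  qbar <- CO_l_min * 1000 / 60
  Ts <- systolic_fraction * T
  tt <- seq(0, T, length.out = Tp + 1)[1:Tp]
  shape <- ifelse(tt < Ts, sin(pi * tt / Ts), 0)
  # mean of the continuous profile: peak*(2/pi)*Ts/T + base*(1 - Ts/T)
  q <- shape + baseline_frac * (tt >= Ts)
  w <- flow_waveform(tt, q, T)
  # scale so the discrete (trapezoidal) period average matches the target
  flow_waveform(tt, q * qbar / mean_flow(w), T)
}

# observed cohort ranges for cardiac output and cycle length
cohort_ranges <- function(cohort) {
  if (cohort == "DORV") list(CO = c(3.3, 4.0), T = c(0.598, 0.802))
  else list(CO = c(2.8, 5.4), T = c(0.605, 0.942))
}

jitter_network <- function(cohort, geom_sd) {
  net <- canonical_network(cohort)
  v <- net$vessels
  for (tries in 1:20) {
    fr <- exp(rnorm(nrow(v), 0, geom_sd))
    fl <- exp(rnorm(nrow(v), 0, geom_sd))
    vj <- v
    vj$r_in_cm <- v$r_in_cm * fr
    vj$r_out_cm <- v$r_out_cm * fr
    vj$length_cm <- v$length_cm * fl
    # preserve the cohort signature: the reconstructed HLHS arch is wider
    # than the ascending aorta
    if (cohort == "HLHS" && vj$r_in_cm[2] <= vj$r_in_cm[1]) next
    vj$terminal <- NULL
    return(build_network(vj, net$edges))
  }
  abort("geometry jitter failed to preserve the cohort signature")
}

#' Generate a complete synthetic patient
#'
#' Forward-simulates a ground-truth model on a (geometry-jittered) vessel
#' network and emulates the measured data the calibration pipeline expects:
#' per-site flow waveforms sampled at `Tp` points per cycle with 5 noisy
#' replicates each, per-vessel bias factors that deliberately violate mass
#' conservation (as velocity-encoded imaging does), and a systolic/diastolic
#' cuff pressure pair. Regenerating with the same seed is bit-identical.
#'
#' Two layouts are available: `"full"` uses the canonical 17-vessel network
#' with calibration sites in the descending aorta, innominate, left common
#' carotid and left subclavian arteries and the cuff at the left-brachial
#' midpoint; `"reduced"` is a desk-scale 3-vessel twin (aortic arch II, left
#' subclavian, descending aorta) with two sites per daughter vessel and the
#' cuff at the subclavian midpoint.
#'
#' @param cohort `"DORV"` or `"HLHS"`.
#' @param seed integer seed; all randomness derives from it.
#' @param noise a `pt_noise`.
#' @param layout `"reduced"` or `"full"`.
#' @param Tp samples per cycle; default drawn from 19-28.
#' @param config solver configuration used for the truth run (and intended
#'   for calibration); default: the desk-scale configuration of
#'   [forward_model()].
#' @param p0_mmhg reference pressure (mmHg) of the truth model, representing
#'   the distal pressure head below the structured-tree truncation.
#' @return a list of class `pt_patient`: `network`, `params_true`,
#'   `theta_true` (named magnitudes of the standard inference subset),
#'   `subset` (its names), `inflow`, `sites`, `ensembles`, `cuff`,
#'   `truth_flows`, `times`, `cohort`, `seed`, `noise`, `config`,
#'   `cuff_site`.
#' @export
generate_patient <- function(cohort = c("DORV", "HLHS"), seed = 1,
                             noise = noise_config(),
                             layout = c("reduced", "full"), Tp = NULL,
                             config = NULL, p0_mmhg = 45) {
  cohort <- match.arg(cohort)
  layout <- match.arg(layout)
  set.seed(seed)
  rg <- cohort_ranges(cohort)
  CO <- runif(1, rg$CO[1], rg$CO[2])
  T0 <- runif(1, rg$T[1], rg$T[2])
  if (is.null(Tp)) Tp <- sample(19:28, 1)
  params <- nominal_params(cohort, T = T0)
  params$blood$p0_mmhg <- p0_mmhg

  if (layout == "reduced") {
    subset <- c("tree_alpha", "k3_g1", "k3_g4", "ks2", "ks3_g1", "ks3_g4")
    sites <- tibble(site = c("subclavian mid", "subclavian out",
                             "desc aorta mid", "desc aorta out"),
                    vessel = c(6, 6, 7, 7), x_frac = c(0.5, 1, 0.5, 1),
                    conserving = c(FALSE, TRUE, FALSE, TRUE))
    cuff_site <- list(vessel = 6, x_frac = 0.5)
    if (is.null(config)) {
      config <- solver_config(points_per_cm = 1, min_points = 4, cfl = 0.8,
                              fixed_cycles = 4, kernel_harmonics = 64)
    }
  } else {
    subset <- c("tree_alpha", paste0("k3_g", 1:4), "ks2",
                paste0("ks3_g", 1:4))
    sites <- tibble(site = c("desc aorta", "innominate", "LCC",
                             "L subclavian"),
                    vessel = c(7, 3, 5, 6), x_frac = c(0.5, 0.5, 0.5, 0.5),
                    conserving = c(TRUE, TRUE, TRUE, TRUE))
    cuff_site <- list(vessel = 8, x_frac = 0.5)
    if (is.null(config)) {
      config <- solver_config(fixed_cycles = 8)
    }
  }

  for (attempt in 1:5) {
    net <- jitter_network(cohort, noise$geom_sd)
    if (layout == "reduced") {
      net <- subnetwork(net, c(4, 6, 7), r_min_new = 0.001)
      net$vessels$group_small[net$vessels$id == 6] <- 4L
    }
    inflow <- make_inflow(CO, T0, Tp)
    if (is.null(config$n_t)) {
      config$n_t <- choose_nt(net, T0, params, config)
    }
    sol <- try(solve_network(net, inflow, params, config), silent = TRUE)
    if (!inherits(sol, "try-error")) break
    message("forward solve failed on jittered geometry; re-jittering")
    if (attempt == 5) abort("could not simulate a stable synthetic patient")
  }

  times <- inflow$time_s
  truth_flows <- vapply(seq_len(nrow(sites)), function(i) {
    solution_at(sol, sites$vessel[i], sites$x_frac[i], times, "q")
  }, numeric(Tp))
  colnames(truth_flows) <- sites$site

  # per-vessel de-conservation bias, then replicate noise
  meas_vessels <- unique(sites$vessel)
  eta <- setNames(
    sample(c(-1, 1), length(meas_vessels), replace = TRUE) *
      runif(length(meas_vessels), noise$deconservation[1],
            noise$deconservation[2]),
    meas_vessels)
  ensembles <- lapply(seq_len(nrow(sites)), function(i) {
    qb <- truth_flows[, i] * (1 + eta[[as.character(sites$vessel[i])]])
    reps <- lapply(seq_len(noise$n_replicates), function(r) {
      flow_waveform(times, qb * (1 + rnorm(Tp, 0, noise$flow_noise)), T0)
    })
    average_ensemble(reps)
  })
  names(ensembles) <- sites$site

  pc <- solution_at(sol, cuff_site$vessel, cuff_site$x_frac, NULL, "p")
  cuff <- c(sys = max(pc) + rnorm(1, 0, noise$cuff_sd),
            dia = min(pc) + rnorm(1, 0, noise$cuff_sd))
  if (cuff["dia"] >= cuff["sys"]) cuff["dia"] <- cuff["sys"] - 5

  structure(list(
    network = net, params_true = params,
    theta_true = theta_nominal(params, subset), subset = subset,
    inflow = inflow, sites = sites, ensembles = ensembles, cuff = cuff,
    truth_flows = truth_flows, times = times, cohort = cohort, seed = seed,
    noise = noise, config = config, cuff_site = cuff_site, CO = CO, T = T0,
    eta = eta),
    class = "pt_patient")
}

#' Calibration-ready data and model for a synthetic patient
#'
#' Averages the replicate ensembles, rescales the conserving branch flows
#' against the inlet cardiac output (mass conservation; the per-vessel scale
#' factor is applied to every site of that vessel), and wraps the result in
#' a [forward_model()] whose nominal parameters match the patient's
#' generation constants.
#'
#' @param patient a `pt_patient`.
#' @param config optional `pt_config` override for calibration solves.
#' @return a list: `model` (a `pt_model`), `data_flows` (Tp x n_sites
#'   matrix), `scaling` (the `pt_scaling` from the conservation step).
#' @export
patient_model <- function(patient, config = NULL) {
  stopifnot(inherits(patient, "pt_patient"))
  sites <- patient$sites
  means <- lapply(patient$ensembles, function(e) e$mean)
  cons_i <- which(sites$conserving)
  scaling <- conserve_mass(patient$inflow, means[cons_i])
  fac <- setNames(1 + scaling$alpha$alpha, sites$vessel[cons_i])
  data_flows <- vapply(seq_len(nrow(sites)), function(i) {
    f <- fac[as.character(sites$vessel[i])]
    if (is.na(f)) f <- 1
    means[[i]]$flow_ml_s * f
  }, numeric(length(patient$times)))
  colnames(data_flows) <- sites$site
  model <- forward_model(
    net = patient$network, inflow = patient$inflow,
    params = patient$params_true, sites = sites, times = patient$times,
    data_flows = data_flows, cuff = patient$cuff,
    cuff_site = patient$cuff_site,
    config = if (is.null(config)) patient$config else config)
  list(model = model, data_flows = data_flows, scaling = scaling)
}
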