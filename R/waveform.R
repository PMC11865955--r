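#' Periodic flow waveform
#'
#' A flow waveform is a tibble with columns `time_s` and `flow_ml_s`, sample
#' times strictly increasing in `[0, T)`, carrying the cardiac period as the
#' `period` attribute. The waveform is treated as T-periodic.
#'
#' @param time_s sample times (s), strictly increasing, all in `[0, T)`.
#' @param flow_ml_s flow samples (ml/s), same length.
#' @param period cardiac period T (s), positive.
#' @return a tibble of class `pt_waveform`.
#' @export
flow_waveform <- function(time_s, flow_ml_s, period) {
  if (length(time_s) != length(flow_ml_s)) {
    abort("`time_s` and `flow_ml_s` must have the same length")
  }
  if (!is.numeric(period) || length(period) != 1 || period <= 0) {
    abort("`period` must be a single positive number")
  }
  if (any(diff(time_s) <= 0) || any(time_s < 0) || any(time_s >= period)) {
    abort("`time_s` must be strictly increasing within [0, period)")
  }
  w <- tibble(time_s = as.numeric(time_s), flow_ml_s = as.numeric(flow_ml_s))
  attr(w, "period") <- period
  class(w) <- c("pt_waveform", class(w))
  w
}

wf_period <- function(w) attr(w, "period")

#' Period-averaged flow (cardiac output) of a waveform
#'
#' Trapezoidal mean over one period with periodic closure of the last
#' interval; on a uniform grid this reduces to the arithmetic mean of the
#' samples.
#'
#' @param w a `pt_waveform`.
#' @return mean flow (ml/s).
#' @export
mean_flow <- function(w) {
  T <- wf_period(w)
  t <- c(w$time_s, w$time_s[1] + T)
  q <- c(w$flow_ml_s, w$flow_ml_s[1])
  sum(diff(t) * (head(q, -1) + tail(q, -1)) / 2) / T
}

#' Average a replicate ensemble of flow waveforms
#'
#' Emulates the practice of extracting several nearby waveforms within a
#' straight vessel section and averaging them into one representative
#' waveform with a pointwise standard-deviation envelope.
#'
#' @param replicates list of `pt_waveform` objects on a shared time grid.
#' @return a list of class `pt_ensemble` with elements `mean` (a
#'   `pt_waveform`), `sd` (pointwise standard deviation) and `replicates`.
#' @export
average_ensemble <- function(replicates) {
  if (!length(replicates)) abort("need at least one replicate")
  t0 <- replicates[[1]]$time_s
  T0 <- wf_period(replicates[[1]])
  for (r in replicates) {
    if (!isTRUE(all.equal(r$time_s, t0)) ||
        !isTRUE(all.equal(wf_period(r), T0))) {
      abort("replicates must share the same time grid and period")
    }
  }
  Q <- vapply(replicates, function(r) r$flow_ml_s, numeric(length(t0)))
  m <- rowMeans(Q)
  s <- if (ncol(Q) > 1) apply(Q, 1, sd) else rep(0, length(t0))
  structure(list(mean = flow_waveform(t0, m, T0), sd = s,
                 replicates = replicates),
            class = "pt_ensemble")
}

#' Rescale branch flows to conserve mass against the inlet
#'
#' Velocity-encoded flow measurements are generally not divergence-free, so
#' the branch cardiac outputs do not sum to the inlet cardiac output. The
#' smallest scale factors `alpha_i` (minimum Euclidean norm) are found such
#' that `sum((1 + alpha_i) * Q_i) = Q_inlet`, where `Q` denotes
#' period-averaged flow; the inlet is held fixed. The closed form is
#' `alpha_i = (Q_inlet - sum(Q_j)) * Q_i / sum(Q_j^2)`.
#'
#' Optionally (`pointwise = TRUE`) the constraint is enforced in a pointwise
#' least-squares sense on the summed waveforms instead of on cardiac outputs;
#' the scalar per-branch factors are then the least-squares solution of
#' `sum_i alpha_i q_i(t_j) = q_inlet(t_j) - sum_i q_i(t_j)` ridge-regularised
#' by the same minimum-norm objective.
#'
#' @param inlet inlet `pt_waveform` (held fixed).
#' @param branches list of branch `pt_waveform` objects (n >= 1), all with the
#'   inlet's period.
#' @param pointwise enforce the constraint pointwise rather than on
#'   period-averaged flows; default `FALSE`.
#' @return a list of class `pt_scaling`: `alpha` (tibble with `branch`,
#'   `alpha`, `Q_original`, `Q_scaled`) and `scaled` (list of rescaled
#'   waveforms `(1 + alpha_i) * q_i`).
#' @export
conserve_mass <- function(inlet, branches, pointwise = FALSE) {
  if (!length(branches)) abort("need at least one branch waveform")
  T0 <- wf_period(inlet)
  for (b in branches) {
    if (!isTRUE(all.equal(wf_period(b), T0))) {
      abort("all waveforms must share the inlet period")
    }
  }
  Qin <- mean_flow(inlet)
  Qi <- vapply(branches, mean_flow, numeric(1))
  if (all(Qi == 0)) abort("degenerate constraint: all branch mean flows are 0")
  if (!pointwise) {
    alpha <- (Qin - sum(Qi)) * Qi / sum(Qi^2)
  } else {
    # least-squares on the shared grid: minimise ||alpha||^2 s.t. best fit of
    # sum_i alpha_i q_i(t) = q_in(t) - sum_i q_i(t)
    Qmat <- vapply(branches, function(b) b$flow_ml_s,
                   numeric(nrow(branches[[1]])))
    rhs <- inlet$flow_ml_s - rowSums(Qmat)
    alpha <- qr.solve(Qmat, rhs)
  }
  scaled <- purrr::map2(branches, alpha, function(b, a) {
    flow_waveform(b$time_s, (1 + a) * b$flow_ml_s, T0)
  })
  structure(list(
    alpha = tibble(branch = seq_along(branches), alpha = alpha,
                   Q_original = Qi, Q_scaled = (1 + alpha) * Qi),
    scaled = scaled, Q_inlet = Qin),
    class = "pt_scaling")
}

#' Trigonometric resampling of a periodic waveform
#'
#' Fourier-series (trigonometric) interpolation of a periodically sampled
#' waveform onto a uniform grid of `n_out` points starting at t = 0. On a
#' uniform input grid the interpolant passes through the original samples and
#' the period average (DC mode) is preserved to machine precision. Non-uniform
#' input grids are first moved to a uniform grid by periodic linear
#' interpolation.
#'
#' @param w a `pt_waveform`.
#' @param n_out number of output samples (>= number of input samples).
#' @return a `pt_waveform` on the uniform `n_out`-point grid.
#' @export
resample_periodic <- function(w, n_out) {
  T0 <- wf_period(w)
  n_in <- nrow(w)
  if (n_out < n_in) abort("`n_out` must be at least the input sample count")
  t_u <- seq(0, T0, length.out = n_in + 1)[1:n_in]
  q <- w$flow_ml_s
  if (!isTRUE(all.equal(w$time_s, t_u))) {
    tt <- c(w$time_s - T0, w$time_s, w$time_s + T0)
    qq <- rep(w$flow_ml_s, 3)
    q <- approx(tt, qq, xout = t_u)$y
  }
  Q <- fft(q) / n_in
  # place harmonics into the n_out-length spectrum (conjugate-symmetric)
  S <- complex(real = rep(0, n_out))
  half <- floor(n_in / 2)
  S[1] <- Q[1]
  for (k in seq_len(half)) {
    if (k < n_in - k) {          # a genuine +/- pair
      S[k + 1] <- Q[k + 1]
      S[n_out - k + 1] <- Q[n_in - k + 1]
    } else if (2 * k == n_in) {  # Nyquist mode: split evenly
      S[k + 1] <- Q[k + 1] / 2
      S[n_out - k + 1] <- Q[k + 1] / 2
    }
  }
  y <- Re(fft(S, inverse = TRUE))
  flow_waveform(seq(0, T0, length.out = n_out + 1)[1:n_out], y, T0)
}

#' Read / write a flow waveform as CSV
#'
#' Columns `time_s` and `flow_ml_s` (plus any replicate columns are kept);
#' the cardiac period is stored in a `# period_s:` header comment.
#'
#' @param w a `pt_waveform`.
#' @param path CSV file path.
#' @return `read_waveform()` returns a `pt_waveform`; `write_waveform()`
#'   returns `path` invisibly.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "pt_waveform"))
  writeLines(sprintf("# period_s: %.17g", wf_period(w)), path)
  readr::write_csv(as.data.frame(w), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# period_s:", hdr)) {
    abort("waveform file lacks the '# period_s:' header")
  }
  T0 <- as.numeric(sub("^# period_s:", "", hdr))
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  flow_waveform(d$time_s, d$flow_ml_s, T0)
}

#' Evaluate a waveform at arbitrary times by trigonometric interpolation
#' @keywords internal
waveform_at <- function(w, times) {
  T0 <- wf_period(w)
  n <- nrow(w)
  t_u <- seq(0, T0, length.out = n + 1)[1:n]
  q <- w$flow_ml_s
  if (!isTRUE(all.equal(w$time_s, t_u))) {
    tt <- c(w$time_s - T0, w$time_s, w$time_s + T0)
    q <- approx(tt, rep(w$flow_ml_s, 3), xout = t_u)$y
  }
  Q <- fft(q) / n
  half <- floor((n - 1) / 2)
  y <- rep(Re(Q[1]), length(times))
  if (half > 0) {
    k <- seq_len(half)
    E <- exp(outer(2i * pi * times / T0, k))     # n_times x half
    y <- y + 2 * Re(E %*% Q[k + 1])[, 1]
  }
  if (n %% 2 == 0) {
    k <- n / 2
    y <- y + Re(Q[k + 1]) * cos(2 * pi * k * times / T0)
  }
  y
}
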