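#' Plot a flow waveform
#'
#' @param object a `pt_waveform`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pt_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$flow_ml_s)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "flow (ml/s)")
}

#' Plot pressure and flow of a solved network
#'
#' One panel per vessel showing the final-cycle time course at the chosen
#' fractional location.
#'
#' @param object a `pt_solution`.
#' @param vessels vessel ids to include (default: all).
#' @param x_frac fractional location along each vessel.
#' @param field `"p"`, `"q"` or `"A"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pt_solution <- function(object, vessels = NULL, x_frac = 0.5,
                                 field = c("p", "q", "A"), ...) {
  field <- match.arg(field)
  ids <- if (is.null(vessels)) names(object$vessels) else as.character(vessels)
  df <- purrr::map_dfr(ids, function(id) {
    vs <- object$vessels[[id]]
    tibble(vessel = paste0(vs$id, ": ", vs$name), t = object$t,
           value = solution_at(object, vs$id, x_frac, NULL, field))
  })
  ylab <- switch(field, p = "pressure (mmHg)", q = "flow (ml/s)",
                 A = "area (cm²)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~vessel, scales = "free_y") +
    ggplot2::labs(x = "time in cycle (s)", y = ylab)
}

#' Plot an impedance spectrum
#'
#' Modulus and phase of the structured-tree root impedance against
#' frequency.
#'
#' @param object a `pt_impedance`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pt_impedance <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble(f_hz = object$omega / (2 * pi),
           modulus = Mod(object$Z),
           phase = Arg(object$Z)),
    c("modulus", "phase"), names_to = "part", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_hz, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~part, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)",
                  y = "impedance (g cm⁻⁴ s⁻¹) / rad")
}

#' Plot a wave-intensity decomposition
#'
#' Cumulated forward/backward pressure components and the signed wave
#' intensities over the cycle.
#'
#' @param object a `pt_wia`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pt_wia <- function(object, ...) {
  n <- length(object$p_plus)
  t <- (seq_len(n) - 1) * object$dt
  df <- bind_rows(
    tibble(t = t, value = object$p_plus, series = "p+ (mmHg)"),
    tibble(t = t, value = object$p_minus, series = "p- (mmHg)"),
    tibble(t = t[-1], value = object$wi_plus, series = "WI+"),
    tibble(t = t[-1], value = object$wi_minus, series = "WI-"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time in cycle (s)", y = NULL)
}

#' Plot multistart estimates
#'
#' Per-start estimates for each inferred parameter, scaled by the
#' across-start mean, with the coefficient of variation in the strip label.
#'
#' @param object a `pt_inference`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pt_inference <- function(object, ...) {
  stopifnot(isTRUE(object$identifiable))
  est <- tidyr::pivot_longer(object$estimates, -c("start", "rss"),
                             names_to = "parameter", values_to = "value")
  est <- dplyr::left_join(est, object$cv, by = "parameter") %>%
    mutate(label = sprintf("%s (CV %.3f)", .data$parameter, .data$cv))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$start,
                                    y = .data$value / .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "start", y = "estimate / mean")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
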