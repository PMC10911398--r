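#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a current trace
#'
#' @param object A `current_trace`.
#' @param downsample Keep roughly this many points for display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.current_trace <- function(object, downsample = 20000, ...) {
  n <- nrow(object)
  step <- max(1L, floor(n / downsample))
  dat <- object[seq(1, n, by = step), ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_s, .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "current (pA)")
}

#' Plot a variance-mean baseline fit
#'
#' Shows the binned variance-mean points, the fitted shot-noise line, the
#' quiescent noise variance, and the back-extrapolated corrected baseline.
#'
#' @param object A `vm_fit` from [variance_mean_baseline()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vm_fit <- function(object, ...) {
  bins <- attr(object, "bins")
  ggplot2::ggplot(bins, ggplot2::aes(.data$mean_pA, .data$variance_pA2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = -object$slope,
      colour = "steelblue"
    ) +
    ggplot2::geom_hline(
      yintercept = object$noise_variance,
      linetype = "dashed"
    ) +
    ggplot2::geom_vline(
      xintercept = object$corrected_baseline,
      colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "bin mean current (pA)", y = expression(variance ~ (pA^2)),
      title = "variance-mean baseline correction"
    )
}

#' Plot a comparative energy landscape
#'
#' Energy offsets (mutant minus reference) along the reaction coordinate:
#' pre-primed state, priming transition state, RRP state, fusion transition
#' state. The reference lies at zero by construction; the post-fusion level
#' is unknown and omitted.
#'
#' @param object An `energy_landscape` from [build_landscape()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.energy_landscape <- function(object, ...) {
  prof <- landscape_profile(object)
  prof <- prof[prof$known, ]
  ggplot2::ggplot(prof, ggplot2::aes(.data$position, .data$energy_kbt,
    colour = .data$condition, group = .data$condition
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(
      breaks = 1:4,
      labels = c("pre-primed", "priming TS", "RRP", "fusion TS")
    ) +
    ggplot2::labs(
      x = NULL, y = expression(Delta * E ~ (k[B] * T)),
      title = "energy offsets relative to reference"
    )
}

#' Plot the electrostatic charge-to-rate curves
#'
#' @param object A `charge_model`.
#' @param z Charge grid.
#' @param ... Unused.
#' @return A ggplot (log10 rate vs charge, spontaneous and evoked curves).
#' @export
autoplot.charge_model <- function(object, z = seq(-10, 45, by = 0.25), ...) {
  dat <- charge_curve(object, z)
  ggplot2::ggplot(dat, ggplot2::aes(.data$z, .data$rate, colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "net charge Z", y = "release rate (1/s)",
      title = "electrostatic triggering model"
    )
}

#' Plot a train back-extrapolation fit
#'
#' @param object A `train_fit` from [train_summary()].
#' @param ... Unused.
#' @return A ggplot of cumulative charge vs time with the fitted line.
#' @export
autoplot.train_fit <- function(object, ...) {
  cum <- attr(object, "cumulative")
  fr <- attr(object, "fit_range")
  ggplot2::ggplot(cum, ggplot2::aes(.data$time_s, .data$cumulative_pC)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = cum[fr, ], colour = "steelblue") +
    ggplot2::geom_abline(
      intercept = object$rrp_ev, slope = object$priming_rate_ev,
      colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "time (s)", y = "cumulative evoked charge (pC)",
      title = "back-extrapolation of cumulative evoked charge"
    )
}
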