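#' Saturating electrostatic charge-to-rate model of release triggering
#'
#' The per-vesicle fusion rate increases with the net positive charge Z on
#' the SNARE-complex surface, exponentially at low rates and saturating at a
#' ceiling. The form used is logistic in the rate:
#' \deqn{k(Z) = \frac{K k_0 e^{\beta Z}}{K + k_0 (e^{\beta Z} - 1)}}
#' with \eqn{k_0} = `rate_at_zero` (the rate at Z = 0), ceiling
#' \eqn{K} = `fraction_f * max_rate`, and log-linear sensitivity `slope_beta`
#' (kBT per unit charge) in the sub-saturated regime. Evoked release follows
#' the same curve translated by `evoked_offset` positive charges. The exact
#' parameterization of the published curve is not reprinted; this
#' saturating log-linear form honors its three anchors (rate at Z = 0,
#' ceiling `f * max_rate`, and charge-separation calibration) and the form
#' used is recorded in the object. `fraction_f` is interpreted as a ceiling
#' scaling (the fraction of the maximal rate that is reachable).
#'
#' @param rate_at_zero Spontaneous per-vesicle rate at Z = 0, 1/s.
#' @param max_rate Maximal rate, 1/s; the reachable ceiling is
#'   `fraction_f * max_rate`.
#' @param fraction_f Fraction of `max_rate` forming the ceiling, in (0, 1].
#' @param slope_beta Sub-saturated log-linear sensitivity, kBT per charge.
#'   The default calibrates a 22.47-fold rate ratio to a separation of 5.6
#'   charges (ln(22.47)/5.6 = 0.5557); a calibration, not ground truth.
#' @param evoked_offset Charges added to Z for evoked release (default 35).
#' @return An object of class `charge_model`.
#' @examples
#' m <- charge_model()
#' rate_at_charge(m, 0) # 0.00029
#' @export
charge_model <- function(rate_at_zero = 0.00029, max_rate = 6000,
                         fraction_f = 0.030,
                         slope_beta = log(22.47) / 5.6,
                         evoked_offset = 35) {
  ceiling_rate <- fraction_f * max_rate
  if (!(rate_at_zero > 0 && rate_at_zero < ceiling_rate)) {
    abort("need 0 < rate_at_zero < fraction_f * max_rate")
  }
  if (!(fraction_f > 0 && fraction_f <= 1)) abort("`fraction_f` must be in (0, 1]")
  if (!is.finite(slope_beta) || slope_beta <= 0) abort("`slope_beta` must be > 0")
  if (!is.finite(evoked_offset) || evoked_offset < 0) {
    abort("`evoked_offset` must be >= 0")
  }
  structure(
    list(
      rate_at_zero = rate_at_zero, max_rate = max_rate,
      fraction_f = fraction_f, ceiling_rate = ceiling_rate,
      slope_beta = slope_beta, evoked_offset = evoked_offset,
      form = "logistic-in-rate saturating log-linear"
    ),
    class = "charge_model"
  )
}

#' @export
print.charge_model <- function(x, ...) {
  cat(sprintf(
    "<charge_model> k(0) = %g 1/s, ceiling = %g 1/s (f = %g x %g), beta = %.4f kBT/charge, evoked offset = %g charges\n",
    x$rate_at_zero, x$ceiling_rate, x$fraction_f, x$max_rate,
    x$slope_beta, x$evoked_offset
  ))
  invisible(x)
}

check_mode <- function(mode) {
  if (!mode %in% c("spontaneous", "evoked")) {
    abort('`mode` must be "spontaneous" or "evoked"')
  }
  mode
}

#' Release rate at a given SNARE surface charge
#'
#' Strictly increasing in Z; `rate_at_charge(m, 0)` equals `rate_at_zero`,
#' and the limit at large Z is the ceiling `fraction_f * max_rate`. Evoked
#' mode evaluates the curve at `Z + evoked_offset`. Overflow-safe for large
#' |Z|.
#'
#' @param model A [charge_model()].
#' @param z Net charge (vectorized).
#' @param mode `"spontaneous"` or `"evoked"`.
#' @return Rate, 1/s.
#' @export
rate_at_charge <- function(model, z, mode = "spontaneous") {
  check_mode(mode)
  if (mode == "evoked") z <- z + model$evoked_offset
  K <- model$ceiling_rate
  k0 <- model$rate_at_zero
  # k(Z) = K / (1 + (K/k0 - 1) exp(-beta Z)): no overflow for any finite Z
  K / (1 + (K / k0 - 1) * exp(-model$slope_beta * z))
}

#' Charge corresponding to a given release rate (model inverse)
#'
#' Exact inverse of [rate_at_charge()] on the open range
#' (0, `fraction_f * max_rate`); used to place measured rates on the charge
#' axis by interpolation in the model.
#'
#' @param model A [charge_model()].
#' @param rate Rate, 1/s (vectorized; must lie strictly inside the model
#'   range).
#' @param mode `"spontaneous"` or `"evoked"`.
#' @return Net charge Z.
#' @examples
#' m <- charge_model()
#' charge_at_rate(m, rate_at_charge(m, 7)) # 7
#' @export
charge_at_rate <- function(model, rate, mode = "spontaneous") {
  check_mode(mode)
  K <- model$ceiling_rate
  k0 <- model$rate_at_zero
  if (any(!is.finite(rate)) || any(rate <= 0) || any(rate >= K)) {
    abort(sprintf("`rate` must lie in the open interval (0, %g)", K))
  }
  z <- log(rate * (K - k0) / (k0 * (K - rate))) / model$slope_beta
  if (mode == "evoked") z <- z - model$evoked_offset
  z
}

#' Charge separation between two release rates
#'
#' The difference in model charge between two measured rates,
#' `charge_at_rate(rate_b) - charge_at_rate(rate_a)`.
#'
#' @inheritParams charge_at_rate
#' @param rate_a,rate_b Rates, 1/s, inside the model range.
#' @return Charge difference (positive when `rate_b` is faster).
#' @export
delta_charge <- function(model, rate_a, rate_b, mode = "spontaneous") {
  charge_at_rate(model, rate_b, mode) - charge_at_rate(model, rate_a, mode)
}

#' Rescale a peak release rate by an eEPSC amplitude ratio
#'
#' When deconvolution of one condition is unreliable, its peak release rate
#' can be obtained by downscaling a related condition's rate by the ratio of
#' the two eEPSC amplitudes.
#'
#' @param rate Peak release rate to rescale, 1/s.
#' @param amplitude_ref Amplitude of the condition the rate was measured in,
#'   nA (> 0).
#' @param amplitude_target Amplitude of the target condition, nA (> 0).
#' @return `rate * amplitude_target / amplitude_ref`.
#' @examples
#' downscale_peak_rate(1, 0.2668, 0.0475) # downscaling factor 1/5.617
#' @export
downscale_peak_rate <- function(rate, amplitude_ref, amplitude_target) {
  if (!is.finite(amplitude_ref) || amplitude_ref <= 0 ||
    !is.finite(amplitude_target) || amplitude_target <= 0) {
    abort("amplitudes must be > 0")
  }
  rate * amplitude_target / amplitude_ref
}

#' Tabulate the charge-to-rate curve
#'
#' @param model A [charge_model()].
#' @param z Charge grid (default -10..45).
#' @return A tibble `z`, `mode`, `rate` for both spontaneous and evoked
#'   curves, suitable for export or plotting.
#' @export
charge_curve <- function(model, z = seq(-10, 45, by = 0.25)) {
  dplyr::bind_rows(
    tibble(z = z, mode = "spontaneous", rate = rate_at_charge(model, z, "spontaneous")),
    tibble(z = z, mode = "evoked", rate = rate_at_charge(model, z, "evoked"))
  )
}
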