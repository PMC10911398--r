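#' Hypertonic sucrose application protocol
#'
#' Describes a local perfusion pulse of hypertonic solution. During the
#' application the per-vesicle fusion rate `kf` is multiplied by `n_suc` (the
#' fold-increase produced by sucrose) and the leak current may shift by
#' `baseline_shift`. Solution exchange is modeled as an exponential approach
#' with time constant `exchange_time`; autaptic micro-island perfusion reaches
#' the whole dendritic tree within tens of milliseconds, hence the 0.05 s
#' default.
#'
#' @param onset_time Application start, s.
#' @param duration Application duration, s (> 0).
#' @param n_suc Fold-increase of `kf` during application (>= 1). 0.5 M sucrose
#'   corresponds to `n_suc` > 5000 in wildtype neurons.
#' @param baseline_shift Additive leak-current change during application, pA
#'   (inward shifts are negative).
#' @param exchange_time Solution-exchange time constant, s (>= 0; 0 = step).
#' @return An object of class `sucrose_protocol`.
#' @examples
#' sucrose_protocol(onset_time = 2, duration = 5, n_suc = 5000)
#' @export
sucrose_protocol <- function(onset_time, duration, n_suc,
                             baseline_shift = -20, exchange_time = 0.05) {
  if (!is.finite(n_suc) || n_suc < 1) abort("`n_suc` must be >= 1")
  if (!is.finite(duration) || duration <= 0) abort("`duration` must be > 0")
  if (!is.finite(exchange_time) || exchange_time < 0) {
    abort("`exchange_time` must be >= 0")
  }
  if (!is.finite(onset_time) || onset_time < 0) abort("`onset_time` must be >= 0")
  structure(
    list(
      onset_time = onset_time, duration = duration, n_suc = n_suc,
      baseline_shift = baseline_shift, exchange_time = exchange_time
    ),
    class = "sucrose_protocol"
  )
}

# fold-multiplier of kf at time t (exponential exchange ramp up and down)
protocol_multiplier <- function(protocol, t) {
  if (is.null(protocol)) return(rep(1, length(t)))
  on <- protocol$onset_time
  off <- on + protocol$duration
  tau <- protocol$exchange_time
  m <- rep(1, length(t))
  during <- t >= on & t < off
  after <- t >= off
  if (tau == 0) {
    m[during] <- protocol$n_suc
  } else {
    m[during] <- 1 + (protocol$n_suc - 1) * (1 - exp(-(t[during] - on) / tau))
    m_off <- 1 + (protocol$n_suc - 1) * (1 - exp(-protocol$duration / tau))
    m[after] <- 1 + (m_off - 1) * exp(-(t[after] - off) / tau)
  }
  m
}

# fractional activation in [0,1] of the baseline shift (same exchange kinetics)
protocol_shift_fraction <- function(protocol, t) {
  if (is.null(protocol)) return(rep(0, length(t)))
  on <- protocol$onset_time
  off <- on + protocol$duration
  tau <- protocol$exchange_time
  s <- rep(0, length(t))
  during <- t >= on & t < off
  after <- t >= off
  if (tau == 0) {
    s[during] <- 1
  } else {
    s[during] <- 1 - exp(-(t[during] - on) / tau)
    s_off <- 1 - exp(-protocol$duration / tau)
    s[after] <- s_off * exp(-(t[after] - off) / tau)
  }
  s
}

#' Action-potential train protocol
#'
#' A train of `n_stimuli` action potentials at `frequency` Hz. At each
#' stimulus every primed vesicle fuses independently with probability `p_vr`
#' (the per-AP vesicular release probability); optional facilitation adds
#' `facilitation_increment` to the release probability after each stimulus,
#' decaying exponentially with time constant `facilitation_tau`.
#'
#' @param n_stimuli Number of stimuli (>= 1).
#' @param frequency Stimulation frequency, Hz.
#' @param p_vr Per-AP vesicular release probability in \[0, 1\].
#' @param facilitation_increment Per-AP increment of the release probability.
#' @param facilitation_tau Decay time constant of facilitation, s.
#' @return An object of class `train_protocol`.
#' @examples
#' train_protocol(n_stimuli = 50, frequency = 40, p_vr = 0.2)
#' @export
train_protocol <- function(n_stimuli = 50, frequency = 40, p_vr = 0.2,
                           facilitation_increment = 0, facilitation_tau = 0.1) {
  if (!is.finite(n_stimuli) || n_stimuli < 1) abort("`n_stimuli` must be >= 1")
  if (!is.finite(frequency) || frequency <= 0) abort("`frequency` must be > 0")
  if (!is.finite(p_vr) || p_vr < 0 || p_vr > 1) abort("`p_vr` must be in [0, 1]")
  structure(
    list(
      n_stimuli = as.integer(n_stimuli), frequency = frequency, p_vr = p_vr,
      facilitation_increment = facilitation_increment,
      facilitation_tau = facilitation_tau
    ),
    class = "train_protocol"
  )
}

#' Miniature-current waveform kernel
#'
#' Unitary (single-vesicle) postsynaptic current waveform, modeled as a
#' difference of exponentials with the time integral normalized to
#' `unitary_charge`. The defaults are typical AMPA-receptor mEPSC scales;
#' they are free instrument/biology parameters, configurable and never used
#' as ground truth.
#'
#' @param unitary_charge Charge per fusion event, pC (> 0).
#' @param rise_tau Rise time constant, s.
#' @param decay_tau Decay time constant, s (must exceed `rise_tau`).
#' @param amplitude_cv Trial-to-trial coefficient of variation of event
#'   amplitude (>= 0).
#' @return An object of class `mini_kernel`.
#' @examples
#' mini_kernel()
#' @export
mini_kernel <- function(unitary_charge = 0.05, rise_tau = 0.5e-3,
                        decay_tau = 3e-3, amplitude_cv = 0.3) {
  if (!is.finite(unitary_charge) || unitary_charge <= 0) {
    abort("`unitary_charge` must be > 0")
  }
  if (!(decay_tau > rise_tau && rise_tau > 0)) {
    abort("need decay_tau > rise_tau > 0")
  }
  if (amplitude_cv < 0) abort("`amplitude_cv` must be >= 0")
  structure(
    list(
      unitary_charge = unitary_charge, rise_tau = rise_tau,
      decay_tau = decay_tau, amplitude_cv = amplitude_cv
    ),
    class = "mini_kernel"
  )
}

# discretize kernel at fs; sum(k)/fs == 1 so a unit-charge impulse convolved
# with it integrates to exactly 1 pC
kernel_samples <- function(kernel, sampling_rate) {
  dt <- 1 / sampling_rate
  if (dt > kernel$rise_tau) {
    abort("sampling interval exceeds rise_tau: kernel unresolvable at this rate")
  }
  t <- seq(0, kernel$decay_tau * 10, by = dt)
  k <- exp(-t / kernel$decay_tau) - exp(-t / kernel$rise_tau)
  k / (sum(k) * dt)
}
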