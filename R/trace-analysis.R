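#' Variance-mean correction of the sucrose baseline
#'
#' Hypertonic sucrose changes the leak current, so the raw plateau current
#' confounds synaptic release with a baseline shift. Synaptic release is shot
#' noise, for which the current variance grows linearly with the mean synaptic
#' current. The trace is detrended with a running average, the variance and
#' mean of the current are computed in short bins across the application, a
#' line is fitted to the variance-mean plot, and the corrected baseline is the
#' current at which that line reaches the variance measured in the absence of
#' synaptic activity (a quiescent pre-application stretch).
#'
#' Bin variances are strongly heteroscedastic (their sampling error scales
#' with the variance itself), so the regression is fitted by iteratively
#' reweighted least squares with weights inversely proportional to the
#' squared predicted variance, the appropriate weighting for variance-mean
#' data.
#'
#' If the fitted slope is not significantly positive in the shot-noise
#' direction, the function warns and falls back to the raw pre-application
#' mean current (flagged in the output).
#'
#' @param trace A `current_trace`.
#' @param application_window Numeric length-2, start/end of the application, s.
#' @param bin_width Bin width for variance/mean, s (default 0.050).
#' @param smoothing_window Running-average window used for detrending, s.
#' @param reference_window Quiescent window for the noise-variance reference;
#'   default is the 0.5 s immediately before the application.
#' @return A one-row tibble of class `vm_fit`: `corrected_baseline` (pA),
#'   `slope` (pA, variance per unit mean, sign-corrected to the inward
#'   convention), `intercept` (pA^2), `noise_variance` (pA^2), `fallback`
#'   (logical), `n_bins`. Bin data are attached for plotting.
#' @examples
#' rec <- simulate_pool(rate_triple(200, 0.1, 0.001),
#'   t_end = 4,
#'   protocol = sucrose_protocol(1, 3, 3000), seed = 1
#' )
#' tr <- render_trace(rec, mini_kernel(), seed = 1)
#' variance_mean_baseline(tr, c(1, 4))
#' @export
variance_mean_baseline <- function(trace, application_window,
                                   bin_width = 0.050,
                                   smoothing_window = 0.003,
                                   reference_window = NULL) {
  fs <- trace_fs(trace)
  x <- trace$current_pA
  t <- trace$time_s
  aw <- check_window(application_window, t)
  if (is.null(reference_window)) {
    reference_window <- c(max(t[1], aw[1] - 0.5), aw[1])
  }
  rw <- check_window(reference_window, t)
  if (diff(aw) < 10 * bin_width) {
    abort("application window must contain at least 10 variance-mean bins")
  }

  w <- max(3L, as.integer(round(smoothing_window * fs)))
  detr <- x - running_mean(x, w)

  in_app <- t >= aw[1] & t < aw[2]
  idx <- which(in_app)
  bin <- floor((t[idx] - aw[1]) / bin_width)
  keep <- bin < floor(diff(aw) / bin_width) # drop ragged last bin
  idx <- idx[keep]
  bin <- bin[keep]
  bin_mean <- as.numeric(tapply(x[idx], bin, mean))
  bin_var <- as.numeric(tapply(detr[idx], bin, var))

  ref <- x[t >= rw[1] & t < rw[2]]
  # detrending removes 1/w of the white-noise variance; match the reference
  noise_var <- robust_noise_sd(ref)^2 * (1 - 1 / w)

  # IRLS: weights 1/predicted^2 (constant relative error of variance
  # estimates); a plain OLS pass provides starting values
  fit <- lm(bin_var ~ bin_mean)
  for (i in 1:6) {
    pred <- pmax(coef(fit)[1] + coef(fit)[2] * bin_mean, noise_var / 2)
    fit <- lm(bin_var ~ bin_mean, weights = 1 / pred^2)
  }
  sl <- coef(fit)[2]
  ic <- coef(fit)[1]
  # inward currents are negative: synaptic activity makes the mean more
  # negative, so shot noise gives a NEGATIVE slope vs raw current
  p_one_sided <- tryCatch(
    {
      s <- summary(fit)$coefficients
      stats::pt(s[2, "t value"], df = fit$df.residual) # P(slope < observed)
    },
    error = function(e) 1
  )
  fallback <- !is.finite(sl) || sl >= 0 || p_one_sided > 0.05
  if (fallback) {
    warn("variance-mean slope not significantly positive for shot noise; falling back to raw pre-application baseline")
    baseline <- mean(ref)
  } else {
    baseline <- (noise_var - ic) / sl
  }
  out <- tibble(
    corrected_baseline = as.numeric(baseline),
    slope = as.numeric(-sl), # report as positive pA per unit inward current
    intercept = as.numeric(ic),
    noise_variance = noise_var,
    fallback = fallback,
    n_bins = length(bin_mean)
  )
  class(out) <- c("vm_fit", class(out))
  attr(out, "bins") <- tibble(
    mean_pA = as.numeric(bin_mean),
    variance_pA2 = as.numeric(bin_var)
  )
  out
}

check_window <- function(w, t) {
  if (length(w) != 2 || !all(is.finite(w)) || w[2] <= w[1]) {
    abort("window must be c(start, end) with end > start")
  }
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  if (w[1] < t[1] - 1e-9 || w[2] > tail(t, 1) + dt + 1e-9) {
    abort("window lies outside the trace")
  }
  w
}

# centered running mean, edges padded by partial windows
running_mean <- function(x, w) {
  n <- length(x)
  w <- min(w, n)
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# noise SD from median absolute successive difference; immune to sparse events
robust_noise_sd <- function(x) {
  d <- diff(x)
  median(abs(d)) / (0.6744898 * sqrt(2))
}

#' RRP charge and plateau current from a sucrose response
#'
#' Integrates the baseline-subtracted current over the application window and
#' splits it into the transient readily-releasable-pool component and the
#' steady plateau (sustained priming-driven release). The plateau is the mean
#' baseline-subtracted current over the late part of the application; the RRP
#' charge is the total integral minus the plateau component. Inward currents
#' are negative in the trace; both outputs are reported as positive
#' magnitudes. The baseline error cancels exactly in the RRP charge (it enters
#' the integral and the plateau subtraction with opposite signs).
#'
#' @param trace A `current_trace`.
#' @param application_window Numeric length-2, start/end of application, s.
#' @param corrected_baseline Baseline current, pA (from
#'   [variance_mean_baseline()]).
#' @param plateau_frac Final fraction of the application averaged for the
#'   plateau (default 0.2). Must not reach back into the depletion transient.
#' @param exchange_time Solution-exchange time constant assumed by the
#'   analysis, s; the plateau component is credited only after the exchange
#'   ramp.
#' @param pre_baseline Optional pre-application baseline current, pA. When
#'   given (with a non-zero `exchange_time`), the charge lost to the
#'   leak-current shift ramping in over the exchange (shift x exchange_time,
#'   unaccounted for when subtracting the constant corrected baseline) is
#'   restored.
#' @return One-row tibble: `rrp_charge_pC`, `plateau_pA`, `total_charge_pC`,
#'   `plateau_window_s`.
#' @export
sucrose_rrp_charge <- function(trace, application_window, corrected_baseline,
                               plateau_frac = 0.2, exchange_time = 0,
                               pre_baseline = NULL) {
  fs <- trace_fs(trace)
  t <- trace$time_s
  aw <- check_window(application_window, t)
  if (plateau_frac <= 0 || plateau_frac >= 1) {
    abort("`plateau_frac` must be in (0, 1)")
  }
  in_app <- t >= aw[1] & t < aw[2]
  y <- -(trace$current_pA[in_app] - corrected_baseline) # inward -> positive
  total <- sum(y) / fs
  if (!is.null(pre_baseline) && exchange_time > 0) {
    total <- total - (corrected_baseline - pre_baseline) * exchange_time
  }
  p_start <- aw[2] - plateau_frac * diff(aw)
  in_plat <- t >= p_start & t < aw[2]
  plateau <- mean(-(trace$current_pA[in_plat] - corrected_baseline))
  rrp <- total - plateau * (diff(aw) - exchange_time)
  tibble(
    rrp_charge_pC = rrp,
    plateau_pA = plateau,
    total_charge_pC = total,
    plateau_window_s = diff(aw) * plateau_frac
  )
}

#' Detect miniature events in a quiescent trace
#'
#' Counts inward (negative) miniature currents by Wiener deconvolution with a
#' unitary-event template: the detrended trace is deconvolved back to a
#' near-impulse train, and local maxima of the deconvolved signal exceeding
#' the threshold and separated by at least `min_interval` are counted as
#' events. Deconvolution resolves events that overlap within a waveform
#' width, so counting stays accurate at high event rates; the residual merge
#' loss from the enforced separation is removed by the non-paralyzable
#' dead-time correction `rate/(1 - rate * min_interval)`.
#'
#' @param trace A `current_trace`.
#' @param threshold Detection threshold on the deconvolved output, in
#'   multiples of its noise SD (default 6). Below 3 a warning is issued.
#' @param min_interval Minimum separation between events, s; also the dead
#'   time used in the rate correction.
#' @param window Optional analysis window (length-2, s); default whole trace.
#' @param template A [mini_kernel()] supplying the template waveform shape
#'   (only the time constants matter; amplitude is normalized out).
#' @param detrend_window Running-median detrend width, s.
#' @param regularization Wiener regularization, relative to the template's
#'   peak spectral power. Larger values widen the effective point-spread
#'   function (more noise suppression, less temporal resolution).
#' @return A list of class `mini_detection`: `events` (tibble `time_s`,
#'   `amplitude_pA`, the detrended trace excursion at the event), `mini_rate`
#'   (Hz), `mini_rate_corrected` (Hz), `noise_sd` (raw trace, pA),
#'   `threshold` (deconvolved units), `duration`.
#' @export
detect_minis <- function(trace, threshold = NULL, min_interval = 0.002,
                         window = NULL, template = mini_kernel(),
                         detrend_window = 0.050, regularization = 0.1) {
  fs <- trace_fs(trace)
  t <- trace$time_s
  if (is.null(window)) window <- c(t[1], tail(t, 1) + 1 / fs)
  w <- check_window(window, t)
  sel <- t >= w[1] & t < w[2]
  x <- trace$current_pA[sel]
  duration <- length(x) / fs

  kmed <- as.integer(round(detrend_window * fs))
  if (kmed %% 2 == 0) kmed <- kmed + 1L
  base <- stats::runmed(x, k = max(3L, kmed), endrule = "median")
  y <- -(x - base) # positive deflections = inward events

  k <- kernel_samples(template, fs)
  n <- length(y)
  np <- nextn(n + length(k), c(2, 3, 5))
  K <- fft(c(k, numeric(np - length(k))))
  lam <- max(Mod(K)^2) * regularization
  H <- Conj(K) / (Mod(K)^2 + lam)
  d <- Re(fft(fft(c(y, numeric(np - n))) * H, inverse = TRUE))[seq_len(n)] / np

  sigma_raw <- robust_noise_sd(x)
  sigma_d <- sigma_raw * sqrt(mean(Mod(H)^2))
  nsd <- threshold %||% 6
  if (nsd < 3) warn("detection threshold below 3x noise SD; expect false positives")
  thr <- nsd * sigma_d

  cand <- which(d > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[d[cand] >= d[cand - 1L] & d[cand] > d[cand + 1L]]
  peaks <- integer(0)
  if (length(cand) > 0) {
    o <- cand[order(d[cand], decreasing = TRUE)]
    min_sep <- max(1L, as.integer(round(min_interval * fs)))
    for (j in o) {
      if (length(peaks) == 0 || min(abs(peaks - j)) >= min_sep) {
        peaks <- c(peaks, j)
      }
    }
    peaks <- sort(peaks)
  }
  # amplitude: largest trace excursion within a template rise-to-peak of the
  # deconvolved event position
  amp <- if (length(peaks) > 0) {
    halfw <- as.integer(round(0.002 * fs))
    vapply(peaks, function(j) {
      max(y[max(1L, j - halfw):min(n, j + halfw)])
    }, numeric(1))
  } else {
    numeric(0)
  }
  rate <- length(peaks) / duration
  rate_corr <- rate / max(1e-12, (1 - rate * min_interval))
  out <- list(
    events = tibble(
      time_s = t[sel][peaks],
      amplitude_pA = amp
    ),
    mini_rate = rate,
    mini_rate_corrected = rate_corr,
    noise_sd = sigma_raw,
    threshold = thr,
    duration = duration
  )
  class(out) <- "mini_detection"
  out
}

#' @export
print.mini_detection <- function(x, ...) {
  cat(sprintf(
    "<mini_detection> %d events in %.1f s (rate %.3f Hz, dead-time corrected %.3f Hz)\n",
    nrow(x$events), x$duration, x$mini_rate, x$mini_rate_corrected
  ))
  invisible(x)
}

#' Train back-extrapolation summary
#'
#' Estimates the evoked readily releasable pool (RRP_ev) by back-extrapolating
#' a linear fit to the cumulative evoked charges over the late, steady part of
#' a high-frequency train: the fitted intercept at time zero is the pool drawn
#' down during the train, and the slope is the ongoing priming rate. Also
#' computes the release probability (first response / RRP_ev) and the
#' paired-pulse ratio.
#'
#' @param charges Per-stimulus evoked charges, pC (positive magnitudes).
#' @param frequency Stimulation frequency, Hz.
#' @param fit_range Integer indices of stimuli used for the linear fit;
#'   default the last 20 stimuli (or the last 40\% for short trains).
#' @param first_charge_index Index of the response used for the release
#'   probability.
#' @param ppr_pair Length-2 indices for the paired-pulse ratio.
#' @param amplitudes Optional per-stimulus amplitudes; if supplied, the
#'   paired-pulse ratio uses amplitudes instead of charges.
#' @return One-row tibble of class `train_fit`: `rrp_ev` (pC),
#'   `priming_rate_ev` (pC/s), `p_release_ev`, `paired_pulse_ratio`,
#'   `valid` (FALSE when the intercept is <= 0, i.e. insufficient depletion),
#'   `flag`.
#' @examples
#' ch <- 100 * 0.2 * 0.8^(0:49) + 0.5 # depressing train
#' train_summary(ch, frequency = 40)
#' @export
train_summary <- function(charges, frequency, fit_range = NULL,
                          first_charge_index = 1, ppr_pair = c(1, 2),
                          amplitudes = NULL) {
  n <- length(charges)
  if (n < 2) abort("need at least 2 stimuli")
  if (is.null(fit_range)) {
    k <- if (n >= 50) 20L else max(2L, ceiling(0.4 * n))
    fit_range <- (n - k + 1L):n
  }
  if (length(fit_range) < 2 || any(fit_range < 1) || any(fit_range > n)) {
    abort("`fit_range` must index at least 2 stimuli within the train")
  }
  # time axis at the end of each interstimulus interval: a train without
  # depletion then back-extrapolates to ~0 rather than to the first charge
  times <- seq_len(n) / frequency
  cum <- cumsum(charges)
  fit <- lm(cum[fit_range] ~ times[fit_range])
  rrp_ev <- as.numeric(coef(fit)[1])
  slope <- as.numeric(coef(fit)[2])
  # the intercept must be meaningfully positive relative to the total
  # released charge; ~zero means the train never depleted a standing pool
  valid <- is.finite(rrp_ev) && rrp_ev > 1e-6 * max(cum)
  p_rel <- if (valid) charges[first_charge_index] / rrp_ev else NA_real_
  flag <- if (!valid) {
    "back-extrapolation invalid: non-positive intercept (insufficient depletion)"
  } else if (is.finite(p_rel) && p_rel > 1) {
    "release probability > 1: observables inconsistent"
  } else {
    NA_character_
  }
  ppr_src <- if (is.null(amplitudes)) charges else amplitudes
  ppr <- ppr_src[ppr_pair[2]] / ppr_src[ppr_pair[1]]
  out <- tibble(
    rrp_ev = rrp_ev,
    priming_rate_ev = slope,
    p_release_ev = p_rel,
    paired_pulse_ratio = ppr,
    cumulative_final = cum[n],
    valid = valid,
    flag = flag
  )
  class(out) <- c("train_fit", class(out))
  attr(out, "cumulative") <- tibble(time_s = times, cumulative_pC = cum)
  attr(out, "fit_range") <- fit_range
  out
}

#' Synchronous release fraction of an evoked response
#'
#' Fits the cumulative charge of a single evoked EPSC with a double
#' exponential \eqn{A_f (1 - e^{-t/\tau_f}) + A_s (1 - e^{-t/\tau_s})} and
#' reports the fast-component share of the total charge. Time constants are
#' sorted so the fast one is reported first. If the two-component fit fails to
#' converge, a single-exponential fallback is used and the fraction is 1
#' (flagged).
#'
#' @param trace A `current_trace` containing the evoked response.
#' @param stimulus_time Stimulus onset, s.
#' @param window Integration window after the stimulus, s.
#' @param baseline Baseline current, pA; default the mean over the 50 ms
#'   before the stimulus.
#' @return One-row tibble: `fraction_synchronous`, `fast_tau`, `slow_tau`,
#'   `total_charge_pC`, `fallback`.
#' @export
synchronous_fraction <- function(trace, stimulus_time, window = 0.5,
                                 baseline = NULL) {
  fs <- trace_fs(trace)
  t <- trace$time_s
  if (is.null(baseline)) {
    pre <- trace$current_pA[t >= stimulus_time - 0.05 & t < stimulus_time]
    baseline <- if (length(pre) > 0) mean(pre) else trace$current_pA[1]
  }
  sel <- t >= stimulus_time & t < stimulus_time + window
  ts <- t[sel] - stimulus_time
  q <- cumsum(-(trace$current_pA[sel] - baseline)) / fs
  total <- tail(q, 1)
  dat <- data.frame(ts = ts, q = q)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      q ~ af * (1 - exp(-ts / tf)) + as. * (1 - exp(-ts / tsl)),
      data = dat,
      start = list(af = 0.6 * total, tf = 0.003, as. = 0.4 * total, tsl = 0.05),
      lower = c(0, 1e-5, 0, 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  ok <- !is.null(fit)
  if (ok) {
    p <- coef(fit)
    taus <- c(p[["tf"]], p[["tsl"]])
    amps <- c(p[["af"]], p[["as."]])
    o <- order(taus)
    taus <- taus[o]
    amps <- amps[o]
    # near-degenerate time constants or a vanishing component: effectively
    # single-exponential
    if (taus[2] / taus[1] < 1.5 || any(amps < 0) || sum(amps) <= 0 ||
      min(amps) / sum(amps) < 0.01) {
      ok <- FALSE
    }
  }
  if (!ok) {
    sfit <- tryCatch(
      minpack.lm::nlsLM(q ~ a * (1 - exp(-ts / tau)),
        data = dat,
        start = list(a = total, tau = 0.01), lower = c(0, 1e-5)
      ),
      error = function(e) NULL
    )
    tau1 <- if (is.null(sfit)) NA_real_ else coef(sfit)[["tau"]]
    return(tibble(
      fraction_synchronous = 1, fast_tau = tau1, slow_tau = NA_real_,
      total_charge_pC = total, fallback = TRUE
    ))
  }
  tibble(
    fraction_synchronous = amps[1] / sum(amps),
    fast_tau = taus[1], slow_tau = taus[2],
    total_charge_pC = total, fallback = FALSE
  )
}

#' Release probability from the sucrose-probed pool
#'
#' The fraction of the readily releasable pool released by one action
#' potential, computed as the evoked EPSC charge divided by the sucrose RRP
#' charge measured in the same cell.
#'
#' @param eepsc_charge Evoked EPSC charge, pC (>= 0).
#' @param rrp_charge Sucrose RRP charge, pC (> 0).
#' @return One-row tibble: `p_release`, `flag` (set when the ratio exceeds 1;
#'   never clamped).
#' @examples
#' release_probability_sucrose(10, 100)
#' @export
release_probability_sucrose <- function(eepsc_charge, rrp_charge) {
  if (!is.finite(rrp_charge) || rrp_charge <= 0) {
    abort("`rrp_charge` must be > 0")
  }
  p <- eepsc_charge / rrp_charge
  tibble(
    p_release = p,
    flag = ifelse(p > 1, "release probability > 1: pathological input", NA_character_)
  )
}
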