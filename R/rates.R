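#' Kinetic rate triple of the one-pool model
#'
#' The readily releasable pool (RRP) is described by a single-compartment model
#' filled by priming at rate `k1` (vesicles/s) from an effectively unlimited
#' upstream pool, and drained by per-vesicle depriming (`k_minus1`, 1/s) and
#' per-vesicle spontaneous fusion (`kf`, 1/s):
#' \deqn{dRRP(t)/dt = k_1 - (k_{-1} + k_f) RRP(t)}
#'
#' @param k1 Priming rate, vesicles/s.
#' @param k_minus1 Depriming rate, 1/s (per vesicle).
#' @param kf Spontaneous fusion rate, 1/s (per vesicle).
#' @return An object of class `rate_triple` (a named list).
#' @examples
#' rate_triple(385.6, 0.0903, 0.000844)
#' @export
rate_triple <- function(k1, k_minus1, kf) {
  for (v in list(k1 = k1, k_minus1 = k_minus1, kf = kf)) {
    if (length(v) != 1 || !is.finite(v) || v < 0) {
      abort("all rates must be single finite non-negative numbers")
    }
  }
  structure(list(k1 = k1, k_minus1 = k_minus1, kf = kf), class = "rate_triple")
}

#' @export
print.rate_triple <- function(x, ...) {
  cat(sprintf(
    "<rate_triple> k1 = %g vesicles/s, k-1 = %g 1/s, kf = %g 1/s\n",
    x$k1, x$k_minus1, x$kf
  ))
  invisible(x)
}

as_rate_triple <- function(x) {
  if (inherits(x, "rate_triple")) return(x)
  if (is.numeric(x) && length(x) == 3) {
    nm <- names(x)
    if (!is.null(nm) && all(c("k1", "k_minus1", "kf") %in% nm)) {
      return(rate_triple(x[["k1"]], x[["k_minus1"]], x[["kf"]]))
    }
    return(rate_triple(x[[1]], x[[2]], x[[3]]))
  }
  if (is.list(x) && all(c("k1", "k_minus1", "kf") %in% names(x))) {
    return(rate_triple(x$k1, x$k_minus1, x$kf))
  }
  abort("cannot interpret `rates` as a rate triple (k1, k_minus1, kf)")
}

#' Steady-state RRP size of the one-pool model
#'
#' At steady state the pool settles at `k1 / (k_minus1 + kf)` vesicles.
#'
#' @param k1,k_minus1,kf Rate constants (vectorized); see [rate_triple()].
#' @return Steady-state pool size in vesicles.
#' @examples
#' steady_state_rrp(385.6, 0.0903, 0.000844) # about 4231 vesicles
#' @export
steady_state_rrp <- function(k1, k_minus1, kf) {
  check_rates(k1, k_minus1, kf)
  denom <- k_minus1 + kf
  if (any(denom <= 0 & k1 > 0)) {
    abort("k_minus1 + kf must be > 0 for a steady state with k1 > 0")
  }
  ifelse(k1 == 0, 0, k1 / denom)
}

#' RRP filling time course
#'
#' Closed-form solution of the one-pool ODE, generalized to an arbitrary
#' starting pool `rrp0`:
#' \deqn{RRP(t) = RRP_\infty + (rrp_0 - RRP_\infty) e^{-(k_{-1}+k_f)t}}
#'
#' @inheritParams steady_state_rrp
#' @param t Time, s (vectorized, must be >= 0).
#' @param rrp0 Pool size at t = 0 (vesicles).
#' @return Pool size in vesicles at each `t`.
#' @examples
#' lam <- 0.0903 + 0.000844
#' rrp_time_course(385.6, 0.0903, 0.000844, t = 1 / lam) # RRPinf * (1 - 1/e)
#' @export
rrp_time_course <- function(k1, k_minus1, kf, t, rrp0 = 0) {
  check_rates(k1, k_minus1, kf)
  if (any(!is.finite(t)) || any(t < 0)) abort("`t` must be finite and >= 0")
  n <- max(length(k1), length(k_minus1), length(kf), length(t), length(rrp0))
  k1 <- rep_len(k1, n)
  lam <- rep_len(k_minus1 + kf, n)
  t <- rep_len(t, n)
  rrp0 <- rep_len(rrp0, n)
  out <- numeric(n)
  pos <- lam > 0
  rinf <- k1[pos] / lam[pos]
  out[pos] <- rinf + (rrp0[pos] - rinf) * exp(-lam[pos] * t[pos])
  out[!pos] <- rrp0[!pos] + k1[!pos] * t[!pos] # pure accumulation limit
  out
}

#' Predicted steady-state miniature release rate
#'
#' The spontaneous (miniature EPSC) event rate at steady state is the
#' per-vesicle fusion rate times the steady-state pool:
#' `kf * k1 / (k_minus1 + kf)`.
#'
#' @inheritParams steady_state_rrp
#' @return Expected miniature event rate, events/s.
#' @examples
#' predicted_mini_rate(385.6, 0.0903, 0.000844) # about 3.57 Hz
#' @export
predicted_mini_rate <- function(k1, k_minus1, kf) {
  kf * steady_state_rrp(k1, k_minus1, kf)
}

check_rates <- function(k1, k_minus1, kf) {
  if (any(!is.finite(k1)) || any(!is.finite(k_minus1)) || any(!is.finite(kf)) ||
    any(k1 < 0) || any(k_minus1 < 0) || any(kf < 0)) {
    abort("rates must be finite and non-negative")
  }
  invisible(TRUE)
}

#' Reference rate constants for SNAP25 conditions
#'
#' Published point estimates of the one-pool rate constants for wildtype-rescue
#' and SNAP25 mutant conditions (epileptic-encephalopathy mutations V48F and
#' D166Y) and for the synaptotagmin-1 knockout comparison, used throughout the
#' package as simulation presets. Each mutant was estimated against a wildtype
#' recorded in parallel, so the wildtype values differ between experiment sets;
#' the `set` column pairs each condition with its own reference.
#'
#' @return A tibble with columns `condition`, `set`, `reference` (logical),
#'   `k1` (vesicles/s), `k_minus1` (1/s), and `kf` (1/s).
#' @examples
#' reference_rates()
#' @export
reference_rates <- function() {
  tibble(
    condition = c("WT", "V48F", "WT", "D166Y", "Syt1_WT", "Syt1_KO"),
    set       = c("V48F", "V48F", "D166Y", "D166Y", "Syt1", "Syt1"),
    reference = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    k1        = c(385.6, 79.87, 457.4, 37.68, 1227, 646),
    k_minus1  = c(0.0903, 0.0605, 0.1114, 0.0294, 0.140, 0.114),
    kf        = c(0.000844, 0.0164, 0.000398, 0.03522, 0.000235, 0.00286)
  )
}
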