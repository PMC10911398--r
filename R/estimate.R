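#' Estimate one-pool rate constants from observables (saturating sucrose)
#'
#' Inverts the one-pool model assuming the sucrose stimulus drives the
#' per-vesicle fusion rate far above depriming, so the plateau reports the
#' priming rate directly: `kf = mini_rate / rrp`, `k1 = plateau_rate`,
#' `k_minus1 = k1 / rrp - kf`. The round trip on noiseless forward-model
#' observables is exact.
#'
#' @param rrp_vesicles Steady-state RRP size, vesicles (> 0).
#' @param mini_rate Spontaneous miniature rate, events/s.
#' @param plateau_rate Sucrose plateau release rate, vesicles/s (must be >=
#'   `mini_rate`).
#' @return One-row tibble: `k1`, `k_minus1`, `kf`, `flag` (set when the
#'   implied `k_minus1` is negative; never clipped, since clipping would hide
#'   a model violation).
#' @examples
#' estimate_rates(4230.7, 3.571, 385.6)
#' @export
estimate_rates <- function(rrp_vesicles, mini_rate, plateau_rate) {
  if (!is.finite(rrp_vesicles) || rrp_vesicles <= 0) {
    abort("`rrp_vesicles` must be > 0")
  }
  if (plateau_rate < mini_rate) {
    abort("`plateau_rate` must be >= `mini_rate` (plateau includes all release)")
  }
  kf <- mini_rate / rrp_vesicles
  k1 <- plateau_rate
  km1 <- k1 / rrp_vesicles - kf
  tibble(
    k1 = k1, k_minus1 = km1, kf = kf,
    flag = ifelse(km1 < 0,
      "negative implied k_minus1: observables inconsistent with one-pool model",
      NA_character_
    )
  )
}

#' Estimate rate constants with a finite sucrose fold-increase
#'
#' When sucrose multiplies the fusion rate by a finite factor `n_suc`, the
#' plateau release rate is `kf * n_suc * k1 / (k_minus1 + kf * n_suc)` rather
#' than `k1` itself. This solves the two-equation system
#' \{`rrp = k1 / (k_minus1 + kf)`; plateau as above\} in closed form with
#' `kf = mini_rate / rrp`, and converges to [estimate_rates()] as
#' `n_suc` grows.
#'
#' @inheritParams estimate_rates
#' @param n_suc Fold-increase of `kf` during the application (> 1); `Inf`
#'   reproduces [estimate_rates()].
#' @return One-row tibble: `k1`, `k_minus1`, `kf`, `flag`.
#' @examples
#' estimate_rates_finite_nsuc(4230.7, 3.571, 377.6, n_suc = 5000)
#' @export
estimate_rates_finite_nsuc <- function(rrp_vesicles, mini_rate, plateau_rate,
                                       n_suc) {
  if (!is.finite(rrp_vesicles) || rrp_vesicles <= 0) {
    abort("`rrp_vesicles` must be > 0")
  }
  if (is.infinite(n_suc)) {
    return(estimate_rates(rrp_vesicles, mini_rate, plateau_rate))
  }
  if (!is.finite(n_suc) || n_suc <= 1) abort("`n_suc` must be > 1")
  kf <- mini_rate / rrp_vesicles
  kfs <- kf * n_suc
  denom <- kfs - plateau_rate / rrp_vesicles
  k1 <- plateau_rate * (kfs - kf) / denom
  km1 <- k1 / rrp_vesicles - kf
  bad <- !is.finite(k1) || k1 <= 0 || denom <= 0
  tibble(
    k1 = k1, k_minus1 = km1, kf = kf,
    flag = dplyr::case_when(
      bad ~ "no positive solution for the finite-n_suc system",
      km1 < 0 ~ "negative implied k_minus1: observables inconsistent with one-pool model",
      TRUE ~ NA_character_
    )
  )
}

#' Estimate rates from the measured sucrose transient (depletion-corrected)
#'
#' The integrated sucrose transient does not measure the steady-state pool
#' exactly: it measures `(RRP0 - RRP_ss) * kf'/(k_minus1 + kf')`, where
#' `kf' = kf * n_suc` is the stimulated fusion rate and `RRP_ss` is the small
#' residual pool sustained during the application. This estimator solves the
#' full system self-consistently by fixed-point iteration: starting from the
#' raw transient, it re-estimates the rates with
#' [estimate_rates_finite_nsuc()] and updates the implied initial pool until
#' convergence. On noiseless forward-model observables the recovery is exact.
#'
#' @param transient_vesicles Integrated transient charge expressed in
#'   vesicles (RRP charge / unitary charge).
#' @param mini_rate Spontaneous miniature rate, events/s.
#' @param plateau_rate Plateau release rate, vesicles/s.
#' @param n_suc Fold-increase of `kf` during application (`Inf` allowed).
#' @param tol,max_iter Fixed-point convergence controls.
#' @return One-row tibble: `k1`, `k_minus1`, `kf`, `rrp_vesicles` (the
#'   depletion-corrected initial pool), `flag`.
#' @export
estimate_rates_depletion <- function(transient_vesicles, mini_rate,
                                     plateau_rate, n_suc = Inf,
                                     tol = 1e-10, max_iter = 100) {
  if (!is.finite(transient_vesicles) || transient_vesicles <= 0) {
    abort("`transient_vesicles` must be > 0")
  }
  r0 <- transient_vesicles
  est <- NULL
  for (i in seq_len(max_iter)) {
    est <- estimate_rates_finite_nsuc(r0, mini_rate, plateau_rate, n_suc)
    if (!is.na(est$flag) && grepl("no positive solution", est$flag)) break
    if (is.infinite(n_suc)) {
      r_new <- transient_vesicles
    } else {
      kfs <- est$kf * n_suc
      lam <- est$k_minus1 + kfs
      r_ss <- est$k1 / lam
      r_new <- transient_vesicles * lam / kfs + r_ss
    }
    if (abs(r_new - r0) <= tol * max(1, r0)) {
      r0 <- r_new
      break
    }
    r0 <- r_new
  }
  est <- estimate_rates_finite_nsuc(r0, mini_rate, plateau_rate, n_suc)
  dplyr::mutate(est, rrp_vesicles = r0, .before = "flag")
}

#' Decompose an RRP-size change into rate contributions
#'
#' Expresses the log-ratio of steady-state RRP sizes between a mutant and a
#' reference as additive contributions of the changes in `k1`, `k_minus1`,
#' and `kf`, by swapping one parameter at a time along the sequential path
#' reference -> (k1) -> (k_minus1) -> (kf). The three contributions sum
#' exactly to the total log RRP ratio (the `k_minus1` and `kf` terms are
#' mildly path-dependent because they share the denominator; the order used
#' is reported).
#'
#' @param rates_ref,rates_mut [rate_triple()]s (or length-3 numerics).
#' @return A tibble with one row per term (`k1`, `k_minus1`, `kf`, `total`),
#'   the log-ratio `contribution`, and the equivalent `fold_change`.
#' @examples
#' decompose_rrp_change(c(457.4, 0.1114, 0.000398), c(37.68, 0.0294, 0.03522))
#' @export
decompose_rrp_change <- function(rates_ref, rates_mut) {
  a <- as_rate_triple(rates_ref)
  b <- as_rate_triple(rates_mut)
  r <- function(k1, km1, kf) steady_state_rrp(k1, km1, kf)
  steps <- c(
    log(r(b$k1, a$k_minus1, a$kf) / r(a$k1, a$k_minus1, a$kf)),
    log(r(b$k1, b$k_minus1, a$kf) / r(b$k1, a$k_minus1, a$kf)),
    log(r(b$k1, b$k_minus1, b$kf) / r(b$k1, b$k_minus1, a$kf))
  )
  tibble(
    term = c("k1", "k_minus1", "kf", "total"),
    contribution = c(steps, sum(steps)),
    fold_change = exp(c(steps, sum(steps)))
  )
}
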