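test_that("steady-state pool size follows k1/(k_minus1 + kf)", {
  expect_equal(steady_state_rrp(385.6, 0.0903, 0.000844), 4230.668, tolerance = 1e-6)
  expect_equal(steady_state_rrp(37.68, 0.0294, 0.03522), 583.1012, tolerance = 1e-6)
  expect_equal(steady_state_rrp(0, 0.2, 0.1), 0)
  expect_error(steady_state_rrp(10, 0, 0), "k_minus1")
  expect_error(steady_state_rrp(-1, 0.1, 0.1), "non-negative")
})

test_that("pool filling time course matches the closed form and its limits", {
  lam <- 0.0903 + 0.000844
  expect_equal(rrp_time_course(385.6, 0.0903, 0.000844, t = 0), 0)
  expect_equal(
    rrp_time_course(385.6, 0.0903, 0.000844, t = 1 / lam),
    4230.668 * (1 - exp(-1)),
    tolerance = 1e-6
  )
  expect_equal(
    rrp_time_course(385.6, 0.0903, 0.000844, t = 1e4),
    steady_state_rrp(385.6, 0.0903, 0.000844),
    tolerance = 1e-9
  )
  # arbitrary starting pool relaxes toward the same steady state
  expect_equal(
    rrp_time_course(385.6, 0.0903, 0.000844, t = 1e4, rrp0 = 9000),
    steady_state_rrp(385.6, 0.0903, 0.000844),
    tolerance = 1e-9
  )
  expect_error(rrp_time_course(1, 1, 1, t = -1), ">= 0")
})

test_that("closed-form filling curve agrees with numerical ODE integration", {
  withr::with_seed(42, {
    for (i in 1:10) {
      k1 <- runif(1, 1, 1000)
      km1 <- runif(1, 0.001, 1)
      kf <- runif(1, 1e-4, 0.1)
      rrp0 <- runif(1, 0, 2) * k1 / (km1 + kf)
      tt <- seq(0, 30, length.out = 31)
      num <- deSolve::lsoda(
        y = c(R = rrp0), times = tt,
        func = function(t, y, p) list(k1 - (km1 + kf) * y),
        parms = NULL, rtol = 1e-11, atol = 1e-11
      )[, "R"]
      cls <- rrp_time_course(k1, km1, kf, tt, rrp0 = rrp0)
      expect_lt(max(abs(cls - num) / pmax(abs(num), 1e-6)), 1e-8)
    }
  })
})

test_that("predicted mini rate is kf times the steady-state pool", {
  expect_equal(predicted_mini_rate(385.6, 0.0903, 0.000844), 3.570684, tolerance = 1e-6)
  expect_equal(predicted_mini_rate(37.68, 0.0294, 0.03522), 20.53682, tolerance = 1e-6)
  expect_equal(predicted_mini_rate(385.6, 0.0903, 0), 0)
})

test_that("rate estimation inverts the forward model exactly (saturating sucrose)", {
  r0 <- steady_state_rrp(385.6, 0.0903, 0.000844)
  est <- estimate_rates(r0, predicted_mini_rate(385.6, 0.0903, 0.000844), 385.6)
  expect_equal(est$k1, 385.6)
  expect_equal(est$k_minus1, 0.0903, tolerance = 1e-12)
  expect_equal(est$kf, 0.000844, tolerance = 1e-12)
  expect_true(is.na(est$flag))

  expect_error(estimate_rates(100, 5, 4), "plateau_rate")
  expect_error(estimate_rates(0, 1, 2), "rrp_vesicles")

  # observables inconsistent with the one-pool model: the implied negative
  # depriming rate is flagged, never clipped
  bad <- estimate_rates_finite_nsuc(1000, 50, 40, n_suc = 5000)
  expect_lt(bad$k_minus1, 0)
  expect_match(bad$flag, "negative")
})

test_that("finite-n_suc estimation converges to the saturating closure and inverts its own forward observables", {
  obs <- forward_observables(385.6, 0.0903, 0.000844, n_suc = 5000)
  est <- estimate_rates_finite_nsuc(obs$rrp, obs$mini, obs$plateau, n_suc = 5000)
  expect_equal(est$k1, 385.6, tolerance = 1e-10)
  expect_equal(est$k_minus1, 0.0903, tolerance = 1e-10)

  # the plateau at n_suc = 1e6 is within rounding of k1 itself
  obs_hi <- forward_observables(385.6, 0.0903, 0.000844, n_suc = 1e6)
  est_hi <- estimate_rates_finite_nsuc(obs_hi$rrp, obs_hi$mini, obs_hi$plateau, 1e6)
  est_inf <- estimate_rates(obs_hi$rrp, obs_hi$mini, obs_hi$plateau)
  expect_equal(est_hi$k1, est_inf$k1, tolerance = 2e-4)
  expect_equal(est_hi$k_minus1, est_inf$k_minus1, tolerance = 5e-4)
  expect_identical(
    estimate_rates_finite_nsuc(obs$rrp, obs$mini, obs$plateau, Inf),
    estimate_rates(obs$rrp, obs$mini, obs$plateau)
  )
})

test_that("estimated k1 is continuous and monotone in the assumed n_suc", {
  # fixed noiseless observables measured at n_suc = 5000, re-interpreted
  # under different assumed fold-increases
  obs <- forward_observables(385.6, 0.0903, 0.000844, n_suc = 5000)
  # sweep over assumed fold-increases large enough for a positive solution
  ns <- 10^seq(2.5, 6, length.out = 30)
  k1s <- vapply(
    ns,
    function(n) estimate_rates_finite_nsuc(obs$rrp, obs$mini, obs$plateau, n)$k1,
    numeric(1)
  )
  expect_true(all(diff(k1s) < 0)) # larger assumed n_suc needs less correction
  expect_equal(k1s[length(k1s)], obs$plateau * 1.0000, tolerance = 1e-3)

  # conditions with higher resting kf are less sensitive to the assumed n_suc
  rel_span <- function(k1, km1, kf) {
    o <- forward_observables(k1, km1, kf, 5000)
    v <- vapply(
      c(1000, 1e6),
      function(n) estimate_rates_finite_nsuc(o$rrp, o$mini, o$plateau, n)$k1,
      numeric(1)
    )
    abs(diff(v)) / v[2]
  }
  expect_gt(
    rel_span(385.6, 0.0903, 0.000844), # wildtype-like, low kf
    rel_span(37.68, 0.0294, 0.03522) # mutant-like, high kf
  )
})

test_that("depletion-corrected estimation recovers rates exactly from noiseless observables", {
  for (r in list(c(385.6, 0.0903, 0.000844), c(79.87, 0.0605, 0.0164), c(37.68, 0.0294, 0.03522))) {
    obs <- forward_observables(r[1], r[2], r[3], n_suc = 5000)
    est <- estimate_rates_depletion(obs$transient, obs$mini, obs$plateau, n_suc = 5000)
    expect_equal(est$k1, r[1], tolerance = 1e-8)
    expect_equal(est$k_minus1, r[2], tolerance = 1e-8)
    expect_equal(est$kf, r[3], tolerance = 1e-8)
    expect_equal(est$rrp_vesicles, obs$rrp, tolerance = 1e-8)
  }
})

test_that("RRP-change decomposition sums exactly and isolates single-rate changes", {
  ref <- c(457.4, 0.1114, 0.000398)
  mut <- c(37.68, 0.0294, 0.03522)
  dec <- decompose_rrp_change(ref, mut)
  total <- dec$contribution[dec$term == "total"]
  expect_equal(total, log(583.1012 / 4091.308), tolerance = 1e-6)
  expect_equal(sum(dec$contribution[dec$term != "total"]), total, tolerance = 1e-12)

  same <- decompose_rrp_change(ref, ref)
  expect_true(all(same$contribution == 0))

  only_kf <- decompose_rrp_change(c(100, 0.1, 0.001), c(100, 0.1, 0.004))
  expect_equal(only_kf$contribution[only_kf$term %in% c("k1", "k_minus1")], c(0, 0))
  expect_lt(only_kf$contribution[only_kf$term == "kf"], 0)
})
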