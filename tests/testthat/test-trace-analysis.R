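make_shot_trace <- function(rate, q_pC, t_end, protocol, seed,
                            noise_sd = 3, cv = 0) {
  kern <- mini_kernel(unitary_charge = q_pC, amplitude_cv = cv)
  withr::with_seed(seed, {
    n_ev <- rpois(1, rate * (t_end - protocol$onset_time))
    times <- sort(runif(n_ev, protocol$onset_time, t_end))
    render_trace(fixed_events(times, t_end = t_end, protocol = protocol),
      kern,
      noise_sd = noise_sd
    )
  })
}

test_that("variance-mean back-extrapolation recovers an injected baseline shift", {
  prot <- sucrose_protocol(1, 4, 100, baseline_shift = -20, exchange_time = 0.02)
  for (s in 1:3) {
    tr <- make_shot_trace(
      rate = 400, q_pC = 0.05, t_end = 5, protocol = prot,
      seed = s, cv = 0.3
    )
    vm <- variance_mean_baseline(tr, c(1, 5))
    expect_false(vm$fallback)
    expect_lt(abs(vm$corrected_baseline - (-20)), 2)
  }
})

test_that("an event-free trace falls back to the raw baseline", {
  prot <- sucrose_protocol(1, 4, 100, baseline_shift = 0, exchange_time = 0)
  withr::with_seed(5, {
    tr <- current_trace(rnorm(5 * 20000, mean = -30, sd = 3), 20000)
  })
  expect_warning(vm <- variance_mean_baseline(tr, c(1, 5)), "fall")
  expect_true(vm$fallback)
  expect_lt(abs(vm$corrected_baseline - (-30)), 0.5)
})

test_that("the variance-mean slope scales with the unitary charge", {
  prot <- sucrose_protocol(1, 4, 100, baseline_shift = -10, exchange_time = 0.02)
  slope_at <- function(q, seeds) {
    mean(vapply(seeds, function(s) {
      tr <- make_shot_trace(rate = 400, q_pC = q, t_end = 5, protocol = prot, seed = s)
      variance_mean_baseline(tr, c(1, 5))$slope
    }, numeric(1)))
  }
  s1 <- slope_at(0.05, 1:4)
  s2 <- slope_at(0.10, 11:14)
  expect_lt(abs(s2 / s1 - 2), 0.3)
})

test_that("baseline correction is translation-equivariant", {
  prot <- sucrose_protocol(1, 4, 100, baseline_shift = -20, exchange_time = 0.02)
  tr <- make_shot_trace(rate = 300, q_pC = 0.05, t_end = 5, protocol = prot, seed = 9)
  v0 <- variance_mean_baseline(tr, c(1, 5))
  tr2 <- tr
  tr2$current_pA <- tr2$current_pA + 13.7
  v1 <- variance_mean_baseline(tr2, c(1, 5))
  expect_equal(v1$corrected_baseline, v0$corrected_baseline + 13.7, tolerance = 1e-8)
  expect_equal(v1$slope, v0$slope, tolerance = 1e-8)
})

test_that("sucrose charge integration is linear in unitary charge and null without events", {
  prot <- sucrose_protocol(1, 3, 5000, baseline_shift = 0, exchange_time = 0)
  times <- withr::with_seed(2, sort(runif(400, 1, 2)))
  mk <- function(q) {
    render_trace(fixed_events(times, t_end = 4.5, protocol = prot),
      mini_kernel(unitary_charge = q, amplitude_cv = 0),
      noise_sd = 0
    )
  }
  a <- sucrose_rrp_charge(mk(0.05), c(1, 4), corrected_baseline = 0, plateau_frac = 0.3)
  b <- sucrose_rrp_charge(mk(0.10), c(1, 4), corrected_baseline = 0, plateau_frac = 0.3)
  expect_equal(b$rrp_charge_pC / a$rrp_charge_pC, 2, tolerance = 1e-6)
  expect_equal(a$rrp_charge_pC, 400 * 0.05, tolerance = 0.02)

  withr::with_seed(3, {
    quiet <- current_trace(rnorm(4.5 * 20000, sd = 3), 20000)
  })
  z <- sucrose_rrp_charge(quiet, c(1, 4), corrected_baseline = 0, plateau_frac = 0.3)
  expect_lt(abs(z$rrp_charge_pC), 2)
  expect_lt(abs(z$plateau_pA), 0.5)
  expect_error(
    sucrose_rrp_charge(quiet, c(1, 4), 0, plateau_frac = 1.2),
    "plateau_frac"
  )
})

test_that("mini detection finds well-separated events and scales with rate", {
  kern <- mini_kernel()
  withr::with_seed(21, {
    times <- seq(0.3, 59.7, length.out = 100) + runif(100, -0.05, 0.05)
    tr <- render_trace(fixed_events(times, t_end = 60), kern, noise_sd = 2)
  })
  det <- detect_minis(tr)
  expect_gte(nrow(det$events), 95)
  expect_lt(abs(det$mini_rate_corrected - 100 / 60) / (100 / 60), 0.05)

  withr::with_seed(22, {
    quiet <- current_trace(rnorm(30 * 20000, sd = 3), 20000)
  })
  expect_equal(detect_minis(quiet)$mini_rate, 0)

  rate_of <- function(r, seed) {
    withr::with_seed(seed, {
      tt <- sort(runif(rpois(1, r * 40), 0, 40))
      trr <- render_trace(fixed_events(tt, t_end = 40), kern, noise_sd = 3)
    })
    detect_minis(trr)$mini_rate_corrected
  }
  r1 <- mean(vapply(1:4, function(s) rate_of(4, 30 + s), numeric(1)))
  r2 <- mean(vapply(1:4, function(s) rate_of(8, 40 + s), numeric(1)))
  expect_lt(abs(r2 / r1 - 2), 0.15)
})

test_that("train back-extrapolation recovers a fully depleted deterministic pool", {
  ch <- deterministic_train(rrp0 = 100, p = 0.2, r = 0.5, n = 50)
  fit <- train_summary(ch, frequency = 40)
  expect_true(fit$valid)
  expect_lt(abs(fit$rrp_ev - 100) / 100, 0.05)
  # slope recovers the replenishment per unit time
  expect_equal(fit$priming_rate_ev, 0.5 * 40, tolerance = 0.01)
  expect_equal(fit$p_release_ev, ch[1] / fit$rrp_ev)
  expect_equal(fit$paired_pulse_ratio, ch[2] / ch[1])
})

test_that("trains without depletion or without replenishment are handled", {
  flat <- train_summary(rep(2, 50), frequency = 40)
  expect_false(flat$valid)
  expect_match(flat$flag, "insufficient depletion")

  single <- train_summary(c(5, rep(0, 49)), frequency = 40)
  expect_true(single$valid)
  expect_equal(single$rrp_ev, 5)
  expect_equal(single$p_release_ev, 1)

  amp <- train_summary(c(4, 2, rep(1, 10)),
    frequency = 40,
    amplitudes = c(10, 14, rep(1, 10))
  )
  expect_equal(amp$paired_pulse_ratio, 1.4)
  expect_error(train_summary(c(1), 40), "at least 2")
})

test_that("synchronous/asynchronous decomposition recovers known charge fractions", {
  fs <- 20000
  mk_eepsc <- function(af, tf, as., tsl) {
    t <- seq(0, 0.5 - 1 / fs, by = 1 / fs)
    i_syn <- af / tf * exp(-t / tf) + as. / tsl * exp(-t / tsl)
    current_trace(c(rep(0, fs * 0.1), -i_syn), fs)
  }
  tr <- mk_eepsc(0.8, 0.002, 0.2, 0.05)
  res <- synchronous_fraction(tr, stimulus_time = 0.1, window = 0.4)
  expect_false(res$fallback)
  expect_lt(abs(res$fraction_synchronous - 0.8), 0.02)
  expect_lt(res$fast_tau, res$slow_tau)
  expect_equal(res$fast_tau, 0.002, tolerance = 0.1)

  even <- synchronous_fraction(mk_eepsc(0.5, 0.002, 0.5, 0.05), 0.1, window = 0.4)
  expect_lt(abs(even$fraction_synchronous - 0.5), 0.02)

  single <- synchronous_fraction(mk_eepsc(1, 0.01, 0, 0.0100001), 0.1, window = 0.4)
  expect_true(single$fallback)
  expect_equal(single$fraction_synchronous, 1)
})

test_that("sucrose-normalized release probability behaves as a plain ratio with flags", {
  expect_equal(release_probability_sucrose(10, 100)$p_release, 0.1)
  expect_equal(release_probability_sucrose(0, 100)$p_release, 0)
  over <- release_probability_sucrose(150, 100)
  expect_equal(over$p_release, 1.5)
  expect_match(over$flag, "probability")
  expect_error(release_probability_sucrose(1, 0), "rrp_charge")
})
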