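test_that("stationary pool statistics match the birth-death theory", {
  # the stationary law of the immigration-death chain is Poisson with mean
  # k1/(k_minus1 + kf); starting from it, any later snapshot is a draw from it
  k1 <- 60
  km1 <- 0.5
  kf <- 0.05
  mu <- steady_state_rrp(k1, km1, kf)
  ends <- vapply(1:300, function(s) {
    rec <- simulate_pool(rate_triple(k1, km1, kf),
      t_end = 2,
      initial_pool = "steady", seed = 1000 + s
    )
    tail(rec$pool_path$pool, 1)
  }, numeric(1))
  se <- sd(ends) / sqrt(length(ends))
  expect_lt(abs(mean(ends) - mu), 3 * se)
  # Poisson occupancy: Fano factor (variance/mean) near 1
  fano <- var(ends) / mean(ends)
  expect_lt(abs(fano - 1), 3 * sqrt(2 / length(ends)))
})

test_that("an empty source with an empty pool stays silent", {
  rec <- simulate_pool(rate_triple(0, 0.5, 0.5),
    t_end = 5,
    initial_pool = 0, seed = 1
  )
  expect_length(rec$fusion_times, 0)
  expect_true(all(rec$pool_path$pool == 0))
})

test_that("steady-state fusion-event rate matches kf times the pool, and doubles with kf", {
  per_vesicle_rate <- function(kf, seed) {
    rec <- simulate_pool(rate_triple(100, 0.4, kf),
      t_end = 40,
      initial_pool = "steady", seed = seed
    )
    pp <- rec$pool_path
    occupancy <- sum(pp$pool * diff(c(pp$time_s, rec$t_end)))
    length(rec$fusion_times) / occupancy
  }
  r1 <- vapply(1:8, function(s) per_vesicle_rate(0.02, s), numeric(1))
  r2 <- vapply(1:8, function(s) per_vesicle_rate(0.04, 100 + s), numeric(1))
  expect_lt(abs(mean(r1) - 0.02) / 0.02, 0.1)
  expect_lt(abs(mean(r2) / mean(r1) - 2), 0.25)
})

test_that("event records satisfy their invariants", {
  rec <- simulate_pool(rate_triple(80, 0.3, 0.05),
    t_end = 10,
    protocol = sucrose_protocol(4, 3, 100, exchange_time = 0.02), seed = 7
  )
  expect_true(all(diff(rec$fusion_times) > 0))
  expect_true(all(rec$pool_path$pool >= 0))
  # every fusion time coincides with a pool decrement of exactly 1
  steps <- diff(rec$pool_path$pool)
  expect_true(all(abs(steps) == 1))
  at_fusion <- rec$pool_path$time_s[-1] %in% rec$fusion_times
  expect_true(all(steps[at_fusion] == -1))
})

test_that("sucrose application multiplies the per-vesicle fusion hazard", {
  # closed pool (no priming/depriming): expected fusions over the pulse are
  # N * (1 - exp(-kf * n_suc * T)) for a step application
  n0 <- 4000
  kf <- 1e-4
  n_suc <- 500
  prot <- sucrose_protocol(1, 2, n_suc, exchange_time = 0)
  counts <- vapply(1:10, function(s) {
    rec <- simulate_pool(rate_triple(0, 0, kf),
      t_end = 3, protocol = prot,
      initial_pool = n0, seed = 500 + s
    )
    sum(rec$fusion_times >= 1 & rec$fusion_times < 3)
  }, numeric(1))
  expected <- n0 * exp(-kf * 1) * (1 - exp(-kf * n_suc * 2))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1)
})

test_that("rendered traces conserve charge and reproduce the baseline shift", {
  kern <- mini_kernel(amplitude_cv = 0)
  fs <- 20000

  flat <- render_trace(fixed_events(numeric(0), t_end = 1), kern,
    sampling_rate = fs, noise_sd = 0, baseline = -11, seed = 1
  )
  expect_true(all(flat$current_pA == -11))

  ev <- fixed_events(seq(0.2, 7.8, length.out = 100), t_end = 8)
  tr <- render_trace(ev, kern, sampling_rate = fs, noise_sd = 0, seed = 1)
  q_int <- -sum(tr$current_pA) / fs
  expect_equal(q_int, 100 * kern$unitary_charge, tolerance = 1e-6)

  # leak shift: with no events the in-application level differs from the
  # pre-application level by exactly baseline_shift once exchange settles
  prot <- sucrose_protocol(1, 3, 100, baseline_shift = -20, exchange_time = 0.05)
  tr2 <- render_trace(fixed_events(numeric(0), t_end = 5, protocol = prot),
    kern,
    sampling_rate = fs, noise_sd = 0, seed = 1
  )
  pre <- mean(tr2$current_pA[tr2$time_s < 1])
  late <- mean(tr2$current_pA[tr2$time_s > 2 & tr2$time_s < 4])
  expect_equal(late - pre, -20, tolerance = 1e-3)

  expect_error(
    render_trace(ev, kern, sampling_rate = 1000),
    "rise_tau"
  )
})

test_that("seeded simulation and rendering are deterministic", {
  r <- rate_triple(50, 0.2, 0.01)
  a <- simulate_pool(r, t_end = 5, seed = 11)
  b <- simulate_pool(r, t_end = 5, seed = 11)
  expect_identical(a$fusion_times, b$fusion_times)
  ta <- render_trace(a, mini_kernel(), noise_sd = 2, seed = 3)
  tb <- render_trace(b, mini_kernel(), noise_sd = 2, seed = 3)
  expect_identical(ta$current_pA, tb$current_pA)
})

test_that("train release obeys the limiting cases and geometric depression", {
  # full release on the first stimulus, nothing afterwards
  tr1 <- simulate_train(rate_triple(0, 0.1, 0.001),
    train_protocol(8, 40, p_vr = 1),
    initial_pool = 150, seed = 2
  )
  expect_equal(tr1$released[1], 150)
  expect_true(all(tr1$released[-1] == 0))

  # zero release probability releases nothing
  tr0 <- simulate_train(rate_triple(100, 0.1, 0.001),
    train_protocol(8, 40, p_vr = 0),
    seed = 3
  )
  expect_true(all(tr0$released == 0))

  # negligible replenishment: mean per-stimulus release follows
  # rrp0 * p * (1-p)^(i-1)
  p <- 0.1
  n0 <- 200
  reps <- sapply(1:300, function(s) {
    simulate_train(rate_triple(0, 0, 1e-9),
      train_protocol(5, 40, p_vr = p),
      initial_pool = n0, seed = 4000 + s
    )$released
  })
  expected <- n0 * p * (1 - p)^(0:4)
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(rowMeans(reps) - expected) < 3 * se + 0.05))
})
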