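#' Exact stochastic simulation of the vesicle pool
#'
#' Simulates the one-pool birth-death chain exactly: priming is a Poisson
#' source with intensity `k1`, and every primed vesicle carries independent
#' depriming (`k_minus1`) and fusion (`kf`, multiplied by the sucrose
#' fold-increase while a protocol is active) hazards. The time-varying fusion
#' hazard across the solution-exchange ramp is handled by thinning against a
#' piecewise-constant upper bound, so event statistics are exact, not
#' discretized.
#'
#' @param rates A [rate_triple()] (or a length-3 numeric `c(k1, k_minus1, kf)`).
#' @param t_end Simulation end time, s (> 0).
#' @param protocol A [sucrose_protocol()] or `NULL`.
#' @param initial_pool Starting pool size (count), or `"steady"` to draw from
#'   the stationary Poisson law with mean `k1 / (k_minus1 + kf)`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `event_record`: a list with `fusion_times`
#'   (strictly increasing, s), `pool_path` (tibble of `time_s`, `pool` after
#'   each transition, starting at time 0), `rates`, `protocol`, `seed`,
#'   `t_end`, and `initial_pool`.
#' @examples
#' rec <- simulate_pool(rate_triple(50, 0.1, 0.001), t_end = 10, seed = 1)
#' length(rec$fusion_times)
#' @export
simulate_pool <- function(rates, t_end, protocol = NULL,
                          initial_pool = "steady", seed = NULL) {
  rates <- as_rate_triple(rates)
  if (!is.finite(t_end) || t_end <= 0) abort("`t_end` must be > 0")
  if (!is.null(protocol) && !inherits(protocol, "sucrose_protocol")) {
    abort("`protocol` must be a sucrose_protocol or NULL")
  }
  run <- function() {
    k1 <- rates$k1
    km1 <- rates$k_minus1
    kf <- rates$kf
    if (identical(initial_pool, "steady")) {
      if (km1 + kf <= 0) {
        abort("steady initial pool requires k_minus1 + kf > 0")
      }
      n <- rpois(1, k1 / (km1 + kf))
    } else {
      if (!is.finite(initial_pool) || initial_pool < 0) {
        abort("`initial_pool` must be a non-negative count or \"steady\"")
      }
      n <- as.integer(round(initial_pool))
    }
    has_prot <- !is.null(protocol) && protocol$n_suc > 1
    on <- if (has_prot) protocol$onset_time else Inf
    off <- if (has_prot) on + protocol$duration else Inf
    nsuc <- if (has_prot) protocol$n_suc else 1

    cap <- 1024L
    f_times <- numeric(cap)
    p_times <- numeric(cap)
    p_pool <- integer(cap)
    nf <- 0L
    np <- 0L
    push_path <- function(t, n) {
      np <<- np + 1L
      if (np > length(p_times)) {
        length(p_times) <<- 2L * length(p_times)
        length(p_pool) <<- 2L * length(p_pool)
      }
      p_times[np] <<- t
      p_pool[np] <<- n
    }
    push_path(0, n)

    t <- 0
    while (t < t_end) {
      # upper bound for the per-vesicle fusion multiplier from time t onward,
      # valid until the next protocol breakpoint
      if (t < on) {
        mb <- 1
        brk <- min(on, t_end)
      } else if (t < off) {
        mb <- nsuc
        brk <- min(off, t_end)
      } else {
        mb <- protocol_multiplier(protocol, t) # decaying: bound at current t
        brk <- t_end
      }
      bound <- k1 + n * (km1 + kf * mb)
      if (bound <= 0) { # absorbed: nothing can ever happen again
        t <- brk
        if (t >= t_end) break
        next
      }
      t_prop <- t + rexp(1, bound)
      if (t_prop > brk) {
        t <- brk
        next
      }
      t <- t_prop
      a_fuse <- n * kf * protocol_multiplier(protocol, t)
      a_deprime <- n * km1
      a_total <- k1 + a_deprime + a_fuse
      u <- runif(1) * bound
      if (u > a_total) next # thinning rejection
      if (u <= k1) {
        n <- n + 1L
      } else if (u <= k1 + a_deprime) {
        n <- n - 1L
      } else {
        n <- n - 1L
        nf <- nf + 1L
        if (nf > length(f_times)) length(f_times) <- 2L * length(f_times)
        f_times[nf] <- t
      }
      push_path(t, n)
    }
    structure(
      list(
        fusion_times = f_times[seq_len(nf)],
        pool_path = tibble(time_s = p_times[seq_len(np)], pool = p_pool[seq_len(np)]),
        rates = rates, protocol = protocol, seed = seed,
        t_end = t_end, initial_pool = initial_pool
      ),
      class = "event_record"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.event_record <- function(x, ...) {
  cat(sprintf(
    "<event_record> %d fusion events over %g s (final pool %d)\n",
    length(x$fusion_times), x$t_end, tail(x$pool_path$pool, 1)
  ))
  invisible(x)
}

#' Render an event record as a current trace
#'
#' Converts fusion events into a uniformly sampled membrane current:
#' baseline + protocol leak shift (ramped by the exchange time constant) +
#' one inward (negative) unitary waveform per fusion event, with amplitudes
#' jittered by the kernel's `amplitude_cv` (gamma, mean 1), + Gaussian
#' instrument noise. The noise-free integrated synaptic charge equals
#' (number of events) x `unitary_charge` in expectation.
#'
#' @param events An `event_record` from [simulate_pool()].
#' @param kernel A [mini_kernel()].
#' @param sampling_rate Sampling rate, Hz (default 20 kHz).
#' @param noise_sd Gaussian noise SD, pA.
#' @param baseline Holding (leak) current, pA.
#' @param protocol Protocol used for the baseline shift; defaults to the one
#'   stored in `events`.
#' @param seed Integer seed for amplitude jitter and noise; `NULL` uses the
#'   current RNG state.
#' @return A `current_trace`: tibble with `time_s` and `current_pA`, plus
#'   attributes `sampling_rate`, `protocol`, `units`, and `seed`.
#' @examples
#' rec <- simulate_pool(rate_triple(50, 0.1, 0.02), t_end = 2, seed = 1)
#' tr <- render_trace(rec, mini_kernel(), noise_sd = 0, seed = 1)
#' @export
render_trace <- function(events, kernel, sampling_rate = 20000, noise_sd = 3,
                         baseline = 0, protocol = events$protocol, seed = NULL) {
  if (!inherits(events, "event_record")) abort("`events` must be an event_record")
  if (!inherits(kernel, "mini_kernel")) abort("`kernel` must be a mini_kernel")
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be > 0")
  }
  run <- function() {
    n <- as.integer(round(events$t_end * sampling_rate))
    dt <- 1 / sampling_rate
    time_s <- (seq_len(n) - 1L) * dt
    current <- rep(baseline, n)
    if (!is.null(protocol)) {
      current <- current +
        protocol$baseline_shift * protocol_shift_fraction(protocol, time_s)
    }
    ev <- events$fusion_times
    ev <- ev[ev < events$t_end]
    if (length(ev) > 0) {
      amp <- if (kernel$amplitude_cv > 0) {
        sh <- 1 / kernel$amplitude_cv^2
        rgamma(length(ev), shape = sh, rate = sh)
      } else {
        rep(1, length(ev))
      }
      impulse <- numeric(n)
      idx <- pmin(n, floor(ev * sampling_rate) + 1L)
      # events can share a sample: accumulate
      sums <- tapply(amp * kernel$unitary_charge, idx, sum)
      impulse[as.integer(names(sums))] <- as.numeric(sums)
      k <- kernel_samples(kernel, sampling_rate)
      current <- current - fft_convolve(impulse, k)[seq_len(n)]
    }
    if (noise_sd > 0) current <- current + rnorm(n, sd = noise_sd)
    current_trace(current, sampling_rate,
      protocol = protocol, seed = seed, start_time = 0
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# linear convolution via FFT, padded to a highly composite length
fft_convolve <- function(x, k) {
  n <- length(x) + length(k) - 1L
  np <- nextn(n, c(2, 3, 5))
  xr <- c(x, numeric(np - length(x)))
  kr <- c(k, numeric(np - length(k)))
  Re(fft(fft(xr) * fft(kr), inverse = TRUE))[seq_len(n)] / np
}

#' Construct a current trace
#'
#' @param current_pA Current samples, pA (inward currents negative).
#' @param sampling_rate Sampling rate, Hz.
#' @param protocol Optional protocol annotation.
#' @param seed,start_time Optional provenance annotations.
#' @return A tibble of class `current_trace` with columns `time_s`,
#'   `current_pA`.
#' @export
current_trace <- function(current_pA, sampling_rate, protocol = NULL,
                          seed = NULL, start_time = 0) {
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be > 0")
  }
  out <- tibble(
    time_s = start_time + (seq_along(current_pA) - 1) / sampling_rate,
    current_pA = as.numeric(current_pA)
  )
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "protocol") <- protocol
  attr(out, "seed") <- seed
  attr(out, "units") <- c(time = "s", current = "pA")
  class(out) <- c("current_trace", class(out))
  out
}

trace_fs <- function(trace) {
  fs <- attr(trace, "sampling_rate")
  if (is.null(fs)) fs <- 1 / median(diff(trace$time_s))
  fs
}

#' Simulate an action-potential train
#'
#' At each stimulus every primed vesicle fuses independently with probability
#' `p_vr` (binomial draw); between stimuli the pool evolves under the exact
#' one-pool stochastic dynamics (priming, depriming, spontaneous fusion).
#'
#' @param rates A [rate_triple()].
#' @param train A [train_protocol()].
#' @param kernel A [mini_kernel()]; its `unitary_charge` converts released
#'   vesicle counts to charge.
#' @param initial_pool Starting pool (count or `"steady"`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble of class `train_release` with one row per stimulus:
#'   `stimulus`, `time_s`, `pool_before`, `released`, `charge_pC`.
#' @examples
#' simulate_train(rate_triple(100, 0.1, 0.001),
#'   train_protocol(10, 40, p_vr = 0.2),
#'   seed = 1
#' )
#' @export
simulate_train <- function(rates, train, kernel = mini_kernel(),
                           initial_pool = "steady", seed = NULL) {
  rates <- as_rate_triple(rates)
  if (!inherits(train, "train_protocol")) abort("`train` must be a train_protocol")
  run <- function() {
    if (identical(initial_pool, "steady")) {
      if (rates$k_minus1 + rates$kf <= 0) {
        abort("steady initial pool requires k_minus1 + kf > 0")
      }
      n <- rpois(1, steady_state_rrp(rates$k1, rates$k_minus1, rates$kf))
    } else {
      n <- as.integer(round(initial_pool))
    }
    dt_stim <- 1 / train$frequency
    fac <- 0
    out <- tibble(
      stimulus = seq_len(train$n_stimuli),
      time_s = (seq_len(train$n_stimuli) - 1) * dt_stim,
      pool_before = NA_integer_, released = NA_integer_, charge_pC = NA_real_
    )
    for (i in seq_len(train$n_stimuli)) {
      p <- min(1, train$p_vr + fac)
      rel <- rbinom(1, n, p)
      out$pool_before[i] <- n
      out$released[i] <- rel
      out$charge_pC[i] <- rel * kernel$unitary_charge
      n <- n - rel
      fac <- fac + train$facilitation_increment
      if (i < train$n_stimuli) {
        rec <- simulate_pool(rates,
          t_end = dt_stim, protocol = NULL,
          initial_pool = n, seed = NULL
        )
        n <- tail(rec$pool_path$pool, 1)
        if (is.finite(train$facilitation_tau) && train$facilitation_tau > 0) {
          fac <- fac * exp(-dt_stim / train$facilitation_tau)
        }
      }
    }
    class(out) <- c("train_release", class(out))
    attr(out, "rates") <- rates
    attr(out, "train") <- train
    attr(out, "unitary_charge") <- kernel$unitary_charge
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
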