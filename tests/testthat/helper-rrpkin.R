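# construct an event record directly from known fusion times, for rendering
# and detection tests where the ground truth must be exact
fixed_events <- function(times, t_end, rates = rate_triple(1, 1, 0.1),
                         protocol = NULL) {
  structure(
    list(
      fusion_times = sort(times),
      pool_path = tibble::tibble(time_s = 0, pool = length(times)),
      rates = rates, protocol = protocol, seed = NULL,
      t_end = t_end, initial_pool = length(times)
    ),
    class = "event_record"
  )
}

# noiseless forward-model observables for a rate triple under a finite
# sucrose fold-increase: steady-state pool, resting mini rate, stimulated
# plateau rate, and the transient charge the integral actually measures
forward_observables <- function(k1, km1, kf, n_suc) {
  r0 <- k1 / (km1 + kf)
  kfs <- kf * n_suc
  lam <- km1 + kfs
  r_ss <- k1 / lam
  list(
    rrp = r0,
    mini = kf * r0,
    plateau = kfs * k1 / lam,
    transient = (r0 - r_ss) * kfs / lam
  )
}

# deterministic depressing train: release p*pool per stimulus, replenish r
# per interstimulus interval
deterministic_train <- function(rrp0, p, r, n) {
  pool <- rrp0
  charges <- numeric(n)
  for (i in seq_len(n)) {
    charges[i] <- p * pool
    pool <- pool - charges[i] + r
  }
  charges
}

preset_rates <- function() reference_rates()
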