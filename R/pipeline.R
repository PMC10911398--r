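#' Validate and normalize a run configuration
#'
#' A run configuration names the conditions to simulate (each with a rate
#' triple, a base seed, and a replicate count) together with shared protocol,
#' waveform, and acquisition settings. Accepts a list, or a path to a YAML or
#' JSON file with the same structure. Settings are validated against the
#' module preconditions at load time; every condition must name a seed.
#'
#' @param x A list, or path to a YAML/JSON configuration file.
#' @return A validated configuration list of class `rrp_config`.
#' @examples
#' cfg <- run_config(list(conditions = list(
#'   WT = list(rates = c(385.6, 0.0903, 0.000844), seed = 1, n_cells = 2)
#' )))
#' @export
run_config <- function(x) {
  if (is.character(x)) {
    x <- if (grepl("\\.ya?ml$", x)) {
      yaml::read_yaml(x)
    } else {
      jsonlite::read_json(x, simplifyVector = TRUE)
    }
  }
  if (!is.list(x)) abort("config must be a list or a path to a YAML/JSON file")
  defaults <- list(
    sampling_rate = 20000, noise_sd = 3,
    kernel = list(
      unitary_charge = 0.05, rise_tau = 0.5e-3, decay_tau = 3e-3,
      amplitude_cv = 0.3
    ),
    protocol = list(
      pre_s = 1.5, application_s = 5, post_s = 0.5, n_suc = 5000,
      baseline_shift = -20, exchange_time = 0.05
    ),
    spontaneous_s = 60,
    analysis = list(
      bin_width = 0.050, smoothing_window = 0.003, plateau_frac = 0.5,
      min_interval = 0.002
    )
  )
  cfg <- modifyList(defaults, x[setdiff(names(x), "conditions")])
  conds <- x$conditions
  if (is.null(conds) || length(conds) == 0) {
    abort("config must define at least one condition")
  }
  if (is.null(names(conds)) || any(names(conds) == "")) {
    abort("conditions must be named")
  }
  cfg$conditions <- purrr::imap(conds, function(cn, nm) {
    if (is.null(cn$seed)) abort(sprintf("condition '%s' names no seed", nm))
    if (is.null(cn$rates) || length(unlist(cn$rates)) != 3) {
      abort(sprintf("condition '%s' must give rates = c(k1, k_minus1, kf)", nm))
    }
    rt <- as_rate_triple(unlist(cn$rates))
    list(
      rates = rt,
      seed = as.integer(cn$seed),
      n_cells = as.integer(cn$n_cells %||% 1L),
      n_suc = cn$n_suc %||% cfg$protocol$n_suc
    )
  })
  # validate shared settings against module preconditions
  do.call(mini_kernel, cfg$kernel)
  if (cfg$sampling_rate <= 0 || cfg$noise_sd < 0) {
    abort("invalid acquisition settings")
  }
  structure(cfg, class = "rrp_config")
}

# accept NULL (defaults), a ready rrp_config, or a bare list of overrides
normalize_config <- function(config, rates, seed) {
  if (inherits(config, "rrp_config")) return(config)
  x <- config %||% list()
  if (is.null(x$conditions)) {
    x$conditions <- list(cell = list(
      rates = c(rates$k1, rates$k_minus1, rates$kf), seed = seed
    ))
  }
  run_config(x)
}

cell_protocol <- function(cfg, n_suc) {
  sucrose_protocol(
    onset_time = cfg$protocol$pre_s,
    duration = cfg$protocol$application_s,
    n_suc = n_suc,
    baseline_shift = cfg$protocol$baseline_shift,
    exchange_time = cfg$protocol$exchange_time
  )
}

#' Simulate one synthetic cell (in memory)
#'
#' Generates the pair of recordings the estimation pipeline consumes: a
#' hypertonic-sucrose pulse response and a long spontaneous segment, both
#' from the same rate triple, rendered as noisy current traces.
#'
#' @param rates A [rate_triple()].
#' @param seed Integer seed (one per cell; all randomness in the cell derives
#'   from it).
#' @param config A configuration from [run_config()] (or a bare list of
#'   overrides).
#' @param n_suc Sucrose fold-increase; defaults to the config value.
#' @return A list of class `synthetic_cell`: `sucrose` and `spontaneous`
#'   traces, `protocol`, `rates`, `seed`, `n_suc`, `kernel`.
#' @export
simulate_cell <- function(rates, seed, config = NULL, n_suc = NULL) {
  rates <- as_rate_triple(rates)
  cfg <- normalize_config(config, rates, seed)
  n_suc <- n_suc %||% cfg$protocol$n_suc
  kern <- do.call(mini_kernel, cfg$kernel)
  prot <- cell_protocol(cfg, n_suc)
  t_suc <- cfg$protocol$pre_s + cfg$protocol$application_s + cfg$protocol$post_s
  withr::with_seed(seed, {
    rec_suc <- simulate_pool(rates, t_end = t_suc, protocol = prot)
    tr_suc <- render_trace(rec_suc, kern,
      sampling_rate = cfg$sampling_rate,
      noise_sd = cfg$noise_sd
    )
    rec_sp <- simulate_pool(rates, t_end = cfg$spontaneous_s, protocol = NULL)
    tr_sp <- render_trace(rec_sp, kern,
      sampling_rate = cfg$sampling_rate,
      noise_sd = cfg$noise_sd
    )
  })
  structure(
    list(
      sucrose = tr_suc, spontaneous = tr_sp, protocol = prot,
      rates = rates, seed = seed, n_suc = n_suc, kernel = kern,
      events_sucrose = length(rec_suc$fusion_times),
      events_spontaneous = length(rec_sp$fusion_times)
    ),
    class = "synthetic_cell"
  )
}

#' Analyze one cell: sucrose response + spontaneous segment to rate constants
#'
#' Runs the full estimation chain on a pair of traces: variance-mean baseline
#' correction, plateau and transient-charge extraction, miniature-event
#' detection with dead-time correction, and the depletion-corrected
#' finite-n_suc closure to the rate triple.
#'
#' @param sucrose,spontaneous `current_trace`s (the sucrose trace must carry
#'   its protocol annotation, or supply `application_window`).
#' @param unitary_charge Charge per vesicle, pC, used for the
#'   vesicle/charge conversion.
#' @param n_suc Fold-increase of `kf` assumed during the application.
#' @param application_window Optional length-2 override, s.
#' @param exchange_time Solution-exchange time constant assumed by the
#'   analysis, s.
#' @param plateau_frac Final fraction of the application averaged for the
#'   plateau.
#' @param min_interval Event-detector dead time, s.
#' @param plateau_mode How to convert the sustained plateau into a release
#'   rate: `"current"` divides the baseline-subtracted plateau current by the
#'   unitary charge; `"count"` counts individual fusion events in the plateau
#'   window with the deconvolution detector (insensitive to baseline errors,
#'   but only reliable while events remain countable); `"auto"` (default)
#'   counts when the observed event rate is low enough for the dead-time
#'   correction to stay small (rate x dead time <= 0.1) and falls back to the
#'   current-based estimate for dense release.
#' @return A one-row tibble: baseline fields, `plateau_pA`, `rrp_charge_pC`,
#'   `rrp_vesicles`, `mini_rate`, `k1`, `k_minus1`, `kf`, `plateau_mode`,
#'   `flag`.
#' @export
analyze_cell <- function(sucrose, spontaneous, unitary_charge = 0.05,
                         n_suc = 5000, application_window = NULL,
                         exchange_time = 0.05, plateau_frac = 0.5,
                         min_interval = 0.002,
                         plateau_mode = c("auto", "current", "count")) {
  plateau_mode <- match.arg(plateau_mode)
  prot <- attr(sucrose, "protocol")
  if (is.null(application_window)) {
    if (is.null(prot)) {
      abort("supply `application_window` or a protocol-annotated sucrose trace")
    }
    application_window <- c(prot$onset_time, prot$onset_time + prot$duration)
  }
  vm <- variance_mean_baseline(sucrose, application_window)
  mins <- detect_minis(spontaneous, min_interval = min_interval)
  # pre-application leak level: mean current minus the (inward, negative)
  # standing mini current, so the exchange-ramp charge correction uses the
  # true leak shift
  pre_sel <- sucrose$time_s >= application_window[1] - 0.5 &
    sucrose$time_s < application_window[1]
  pre_baseline <- mean(sucrose$current_pA[pre_sel]) +
    mins$mini_rate_corrected * unitary_charge
  sr <- sucrose_rrp_charge(sucrose, application_window,
    corrected_baseline = vm$corrected_baseline,
    plateau_frac = plateau_frac, exchange_time = exchange_time,
    pre_baseline = pre_baseline
  )
  transient_ves <- sr$rrp_charge_pC / unitary_charge
  plateau_ves <- sr$plateau_pA / unitary_charge
  mode_used <- "current"
  if (plateau_mode != "current") {
    p_win <- c(
      application_window[2] - plateau_frac * diff(application_window),
      application_window[2]
    )
    det_p <- detect_minis(sucrose, window = p_win, min_interval = min_interval)
    if (plateau_mode == "count" ||
      det_p$mini_rate * min_interval <= 0.1) {
      plateau_ves <- det_p$mini_rate_corrected
      mode_used <- "count"
    }
  }
  est <- if (is.finite(transient_ves) && transient_ves > 0 && plateau_ves > 0) {
    estimate_rates_depletion(
      transient_ves, mins$mini_rate_corrected, plateau_ves,
      n_suc = n_suc
    )
  } else {
    tibble(
      k1 = NA_real_, k_minus1 = NA_real_, kf = NA_real_,
      rrp_vesicles = NA_real_,
      flag = "non-positive transient or plateau: cell not analyzable"
    )
  }
  tibble(
    corrected_baseline = vm$corrected_baseline,
    baseline_fallback = vm$fallback,
    plateau_pA = sr$plateau_pA,
    plateau_rate = plateau_ves,
    rrp_charge_pC = sr$rrp_charge_pC,
    rrp_vesicles = est$rrp_vesicles,
    mini_rate = mins$mini_rate,
    mini_rate_corrected = mins$mini_rate_corrected,
    k1 = est$k1, k_minus1 = est$k_minus1, kf = est$kf,
    plateau_mode = mode_used,
    flag = est$flag
  )
}

#' Simulate and analyze replicate cells per condition
#'
#' The full synthetic-recovery loop used for validation: simulate `n_cells`
#' cells per condition (seeds `seed`, `seed + 1`, ...), run [analyze_cell()]
#' on each, and return the per-cell summary table.
#'
#' @param config A [run_config()] configuration (its `conditions` define
#'   rates, seeds, replicate counts, and n_suc).
#' @param progress Print a line per condition.
#' @return A tibble with one row per cell: `condition`, `cell`, `seed`, the
#'   generating rates (`k1_true`, `k_minus1_true`, `kf_true`), and all
#'   [analyze_cell()] columns.
#' @export
recover_rates <- function(config, progress = FALSE) {
  cfg <- if (inherits(config, "rrp_config")) config else run_config(config)
  purrr::imap_dfr(cfg$conditions, function(cn, nm) {
    if (progress) inform(sprintf("condition %s: %d cells", nm, cn$n_cells))
    purrr::map_dfr(seq_len(cn$n_cells), function(i) {
      seed_i <- cn$seed + i - 1L
      cell <- simulate_cell(cn$rates, seed = seed_i, config = cfg, n_suc = cn$n_suc)
      res <- analyze_cell(
        cell$sucrose, cell$spontaneous,
        unitary_charge = cfg$kernel$unitary_charge, n_suc = cn$n_suc,
        exchange_time = cfg$protocol$exchange_time,
        plateau_frac = cfg$analysis$plateau_frac,
        min_interval = cfg$analysis$min_interval
      )
      dplyr::bind_cols(
        tibble(
          condition = nm, cell = i, seed = seed_i,
          k1_true = cn$rates$k1, k_minus1_true = cn$rates$k_minus1,
          kf_true = cn$rates$kf
        ),
        res
      )
    })
  })
}

#' Per-condition rate table from a per-cell summary
#'
#' @param summary A per-cell tibble from [recover_rates()] or
#'   [analyze_cells()].
#' @return A tibble with one row per condition: n, mean and standard error of
#'   `k1`, `k_minus1`, `kf`, mean RRP size, and the number of flagged cells.
#' @export
condition_rates <- function(summary) {
  sem <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x)))
  summary |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      k1_mean = mean(.data$k1, na.rm = TRUE), k1_sem = sem(.data$k1),
      k_minus1_mean = mean(.data$k_minus1, na.rm = TRUE),
      k_minus1_sem = sem(.data$k_minus1),
      kf_mean = mean(.data$kf, na.rm = TRUE), kf_sem = sem(.data$kf),
      rrp_vesicles_mean = mean(.data$rrp_vesicles, na.rm = TRUE),
      n_flagged = sum(!is.na(.data$flag)),
      .groups = "drop"
    )
}

#' Write / read a current trace as delimited text with a JSON sidecar
#'
#' The trace is written as two-column tab-separated text (`time_s`,
#' `current_pA`); acquisition metadata (sampling rate, protocol, seed, units)
#' go to `<prefix>.json`.
#'
#' @param trace A `current_trace`.
#' @param prefix Output path prefix (writes `<prefix>.tsv` and
#'   `<prefix>.json`).
#' @return The prefix, invisibly.
#' @export
write_trace <- function(trace, prefix) {
  readr::write_tsv(as_tibble(trace)[c("time_s", "current_pA")],
    paste0(prefix, ".tsv"),
    progress = FALSE
  )
  prot <- attr(trace, "protocol")
  meta <- list(
    sampling_rate = attr(trace, "sampling_rate"),
    protocol = if (is.null(prot)) NULL else unclass(prot),
    seed = attr(trace, "seed"),
    units = as.list(attr(trace, "units"))
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(prefix)
}

#' @rdname write_trace
#' @export
read_trace <- function(prefix) {
  dat <- readr::read_tsv(paste0(prefix, ".tsv"),
    show_col_types = FALSE,
    progress = FALSE
  )
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  prot <- if (!is.null(meta$protocol)) {
    do.call(sucrose_protocol, meta$protocol[c(
      "onset_time", "duration", "n_suc", "baseline_shift", "exchange_time"
    )])
  } else {
    NULL
  }
  current_trace(dat$current_pA, meta$sampling_rate,
    protocol = prot,
    seed = meta$seed, start_time = dat$time_s[1]
  )
}

#' Simulate a configured study to trace files
#'
#' Writes, for every condition and replicate, the sucrose and spontaneous
#' traces (delimited text + JSON sidecars) and a `manifest.csv` listing every
#' file with its generator parameters. Deterministic given the configured
#' seeds: the same configuration yields byte-identical outputs.
#'
#' @param config A [run_config()] configuration.
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
simulate_cells <- function(config, out_dir) {
  cfg <- if (inherits(config, "rrp_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort("cannot create output directory")
  manifest <- purrr::imap_dfr(cfg$conditions, function(cn, nm) {
    purrr::map_dfr(seq_len(cn$n_cells), function(i) {
      seed_i <- cn$seed + i - 1L
      cell <- simulate_cell(cn$rates, seed = seed_i, config = cfg, n_suc = cn$n_suc)
      pfx_suc <- file.path(out_dir, sprintf("%s_cell%03d_sucrose", nm, i))
      pfx_sp <- file.path(out_dir, sprintf("%s_cell%03d_spontaneous", nm, i))
      write_trace(cell$sucrose, pfx_suc)
      write_trace(cell$spontaneous, pfx_sp)
      tibble(
        condition = nm, cell = i, seed = seed_i,
        kind = c("sucrose", "spontaneous"),
        prefix = c(basename(pfx_suc), basename(pfx_sp)),
        k1 = cn$rates$k1, k_minus1 = cn$rates$k_minus1, kf = cn$rates$kf,
        n_suc = cn$n_suc,
        unitary_charge = cfg$kernel$unitary_charge
      )
    })
  })
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}

#' Analyze a directory of simulated traces
#'
#' Reads `manifest.csv` from `in_dir`, pairs each cell's sucrose and
#' spontaneous traces, and runs [analyze_cell()] on every pair.
#'
#' @param in_dir Directory produced by [simulate_cells()].
#' @param ... Passed to [analyze_cell()].
#' @return A per-cell summary tibble (as in [recover_rates()]).
#' @export
analyze_cells <- function(in_dir, ...) {
  mf_path <- file.path(in_dir, "manifest.csv")
  if (!file.exists(mf_path)) {
    abort(sprintf("no manifest.csv in '%s' (empty or not a simulation directory)", in_dir))
  }
  manifest <- readr::read_csv(mf_path, show_col_types = FALSE, progress = FALSE)
  cells <- dplyr::distinct(manifest, .data$condition, .data$cell)
  purrr::pmap_dfr(cells, function(condition, cell) {
    rows <- manifest[manifest$condition == condition & manifest$cell == cell, ]
    suc <- read_trace(file.path(in_dir, rows$prefix[rows$kind == "sucrose"]))
    sp <- read_trace(file.path(in_dir, rows$prefix[rows$kind == "spontaneous"]))
    res <- analyze_cell(suc, sp,
      unitary_charge = rows$unitary_charge[1],
      n_suc = rows$n_suc[1], ...
    )
    dplyr::bind_cols(
      tibble(
        condition = condition, cell = cell, seed = rows$seed[1],
        k1_true = rows$k1[1], k_minus1_true = rows$k_minus1[1],
        kf_true = rows$kf[1]
      ),
      res
    )
  })
}

#' Energy-landscape table for a rates table
#'
#' Wraps [build_landscape()] for pipeline use: rows with non-positive or
#' non-finite rates are rejected with a message and reported in the
#' `rejected` attribute instead of silently dropped.
#'
#' @param rates A tibble with `condition`, `k1`, `k_minus1`, `kf`.
#' @param reference Reference condition name.
#' @param temperature Absolute temperature, K.
#' @return An `energy_landscape` tibble; rejected rows in
#'   `attr(, "rejected")`.
#' @export
run_landscape <- function(rates, reference, temperature = 298.15) {
  ok <- is.finite(rates$k1) & rates$k1 > 0 &
    is.finite(rates$k_minus1) & rates$k_minus1 > 0 &
    is.finite(rates$kf) & rates$kf > 0
  if (any(!ok)) {
    inform(sprintf(
      "rejecting %d row(s) with non-positive rates: %s",
      sum(!ok), paste(rates$condition[!ok], collapse = ", ")
    ))
  }
  if (!reference %in% rates$condition[ok]) {
    abort(sprintf("reference condition '%s' missing or invalid", reference))
  }
  out <- build_landscape(rates[ok, , drop = FALSE], reference, temperature)
  attr(out, "rejected") <- rates[!ok, , drop = FALSE]
  out
}

#' Charge-equivalent table for a rates table
#'
#' Places each condition's per-vesicle spontaneous fusion rate `kf` on the
#' electrostatic charge axis by interpolation in a [charge_model()].
#'
#' @param rates A tibble with `condition` and `kf`.
#' @param model A [charge_model()].
#' @return A tibble `condition`, `kf`, `z` (charges; NA with a flag when the
#'   rate is outside the model's open range).
#' @export
run_charges <- function(rates, model = charge_model()) {
  z <- purrr::map_dbl(rates$kf, function(k) {
    tryCatch(charge_at_rate(model, k), error = function(e) NA_real_)
  })
  tibble(
    condition = rates$condition, kf = rates$kf, z = z,
    flag = ifelse(is.na(z), "rate outside model range", NA_character_)
  )
}
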