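#' Thermal energy RT in kJ/mol
#'
#' @param temperature Absolute temperature, K (> 0). The default 298.15 K
#'   gives RT = 2.479 kJ/mol, the conventional room-temperature value.
#' @return RT in kJ/mol.
#' @examples
#' rt_kj_per_mol() # 2.479
#' @export
rt_kj_per_mol <- function(temperature = 298.15) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    abort("`temperature` must be > 0 K")
  }
  .R_KJ_PER_MOL_K * temperature
}

#' Convert energies between kBT (per molecule) and kJ/mol
#'
#' 1 kBT per molecule corresponds to RT per mole.
#'
#' @param energy_kbt,energy_kj Energy values.
#' @param temperature Absolute temperature, K.
#' @return Converted energy.
#' @export
kbt_to_kj_mol <- function(energy_kbt, temperature = 298.15) {
  energy_kbt * rt_kj_per_mol(temperature)
}

#' @rdname kbt_to_kj_mol
#' @export
kj_mol_to_kbt <- function(energy_kj, temperature = 298.15) {
  energy_kj / rt_kj_per_mol(temperature)
}

#' Activation-energy difference between two rate constants
#'
#' Under the Arrhenius relation \eqn{k = A e^{-E_a/RT}} with the prefactor A
#' assumed unchanged between conditions, the difference in barrier height is
#' \deqn{\Delta E_a = RT (\ln k_{ref} - \ln k_{mut})}
#' A slower mutant rate therefore maps to a positive (higher) barrier.
#' Antisymmetric under swapping the arguments. Absolute barrier heights would
#' require the unknown prefactor and are never emitted.
#'
#' @param k_ref,k_mut Rate constants (> 0), same units (vectorized).
#' @param temperature Absolute temperature, K.
#' @return A tibble with `delta_e_kbt` (per molecule) and `delta_e_kj_mol`
#'   (per mole).
#' @examples
#' delta_activation_energy(1.31, 0.0583) # about 3.11 kBT
#' @export
delta_activation_energy <- function(k_ref, k_mut, temperature = 298.15) {
  if (any(!is.finite(k_ref)) || any(!is.finite(k_mut)) ||
    any(k_ref <= 0) || any(k_mut <= 0)) {
    abort("rates must be finite and > 0")
  }
  d_kbt <- log(k_ref / k_mut)
  tibble(
    delta_e_kbt = d_kbt,
    delta_e_kj_mol = kbt_to_kj_mol(d_kbt, temperature)
  )
}

#' Comparative energy landscape for priming and fusion
#'
#' Applies the Arrhenius relation sequentially to the priming, depriming, and
#' fusion rates of each condition against a reference, anchoring the
#' pre-primed state at zero energy for all conditions. The resulting offsets
#' (mutant minus reference, in kBT and kJ/mol) locate the priming transition
#' state, the RRP state, and the fusion transition state:
#' \itemize{
#'   \item `d_priming_ts = RT ln(k1_ref / k1_mut)`
#'   \item `d_rrp = d_priming_ts - RT ln(k-1_ref / k-1_mut)`
#'   \item `d_fusion_ts = d_rrp + RT ln(kf_ref / kf_mut)`
#' }
#' Priming may involve collision rates, in which case the Arrhenius prefactor
#' is not guaranteed constant; a note to that effect is attached to the
#' result (attribute `priming_caveat`).
#'
#' @param rates A data frame with columns `condition`, `k1`, `k_minus1`,
#'   `kf` (all rates > 0).
#' @param reference Name of the reference condition (must appear in
#'   `rates$condition`).
#' @param temperature Absolute temperature, K.
#' @return A tibble of class `energy_landscape` with one row per
#'   non-reference condition: offsets at the three states in kBT and kJ/mol,
#'   plus `reference` and `temperature`.
#' @examples
#' tab <- reference_rates() |> dplyr::filter(set == "D166Y")
#' build_landscape(tab, reference = "WT")
#' @export
build_landscape <- function(rates, reference, temperature = 298.15) {
  need <- c("condition", "k1", "k_minus1", "kf")
  if (!all(need %in% names(rates))) {
    abort("`rates` must have columns condition, k1, k_minus1, kf")
  }
  if (!reference %in% rates$condition) {
    abort(sprintf("reference condition '%s' not found in rates table", reference))
  }
  if (any(!is.finite(rates$k1) | rates$k1 <= 0 |
    !is.finite(rates$k_minus1) | rates$k_minus1 <= 0 |
    !is.finite(rates$kf) | rates$kf <= 0)) {
    abort("all rates must be finite and > 0 for energy comparisons")
  }
  ref <- rates[match(reference, rates$condition), ]
  mut <- rates[rates$condition != reference, , drop = FALSE]
  d_prime <- log(ref$k1 / mut$k1)
  d_rrp <- d_prime - log(ref$k_minus1 / mut$k_minus1)
  d_fuse <- d_rrp + log(ref$kf / mut$kf)
  out <- tibble(
    condition = mut$condition,
    reference = reference,
    d_priming_ts_kbt = d_prime,
    d_rrp_kbt = d_rrp,
    d_fusion_ts_kbt = d_fuse,
    d_priming_ts_kj_mol = kbt_to_kj_mol(d_prime, temperature),
    d_rrp_kj_mol = kbt_to_kj_mol(d_rrp, temperature),
    d_fusion_ts_kj_mol = kbt_to_kj_mol(d_fuse, temperature),
    temperature = temperature
  )
  class(out) <- c("energy_landscape", class(out))
  attr(out, "priming_caveat") <- paste(
    "Priming barrier offsets assume an unchanged Arrhenius prefactor;",
    "if priming involves collision rates this assumption may fail."
  )
  out
}

#' Plot-ready state/energy sequence of an energy landscape
#'
#' Orders each condition's energy levels along the reaction coordinate:
#' pre-primed (anchored at 0), priming transition state, RRP state, fusion
#' transition state. Only offsets relative to the reference are known, so the
#' reference is drawn at zero throughout; the post-fusion level is unknown
#' and marked as such rather than fabricated.
#'
#' @param landscape An `energy_landscape` from [build_landscape()].
#' @return A tibble with `condition`, `state` (ordered factor), `position`
#'   (reaction-coordinate index), `energy_kbt`, `known`.
#' @export
landscape_profile <- function(landscape) {
  if (!inherits(landscape, "energy_landscape")) {
    abort("`landscape` must come from build_landscape()")
  }
  states <- c("pre_primed", "priming_ts", "rrp", "fusion_ts", "post_fusion")
  ref <- tibble(
    condition = landscape$reference[1],
    state = factor(states, levels = states),
    position = seq_along(states),
    energy_kbt = c(0, 0, 0, 0, NA_real_),
    known = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  mut <- purrr::pmap_dfr(landscape, function(condition, d_priming_ts_kbt,
                                             d_rrp_kbt, d_fusion_ts_kbt, ...) {
    tibble(
      condition = condition,
      state = factor(states, levels = states),
      position = seq_along(states),
      energy_kbt = c(0, d_priming_ts_kbt, d_rrp_kbt, d_fusion_ts_kbt, NA_real_),
      known = c(TRUE, TRUE, TRUE, TRUE, FALSE)
    )
  })
  dplyr::bind_rows(ref, mut)
}
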