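#' Tidy a variance-mean baseline fit
#'
#' @param x A `vm_fit`.
#' @param ... Unused.
#' @return A one-row tibble of the fit quantities.
#' @export
tidy.vm_fit <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' Tidy an energy landscape into long format
#'
#' @param x An `energy_landscape`.
#' @param ... Unused.
#' @return A tibble with one row per condition and state, energies in both
#'   kBT and kJ/mol.
#' @export
tidy.energy_landscape <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(
      cols = dplyr::ends_with(c("_kbt", "_kj_mol")),
      names_to = c("state", "unit"),
      names_pattern = "d_(.*)_(kbt|kj_mol)",
      values_to = "energy"
    )
}

#' Tidy a train back-extrapolation fit
#'
#' @param x A `train_fit`.
#' @param ... Unused.
#' @return The per-train summary as a plain tibble.
#' @export
tidy.train_fit <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-line summary of a charge model
#'
#' @param x A `charge_model`.
#' @param ... Unused.
#' @return A one-row tibble of the model parameters.
#' @export
glance.charge_model <- function(x, ...) {
  tibble(
    rate_at_zero = x$rate_at_zero, max_rate = x$max_rate,
    fraction_f = x$fraction_f, ceiling_rate = x$ceiling_rate,
    slope_beta = x$slope_beta, evoked_offset = x$evoked_offset,
    form = x$form
  )
}

#' @export
generics::tidy

#' @export
generics::glance
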