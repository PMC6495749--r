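#' Pressure change of a sealed bottle on heating
#'
#' Ideal-gas isochoric scaling: a sealed vessel of fixed volume and fixed
#' gas content filled at `fill_pressure_atm` and `fill_temperature_k`
#' reaches `P2 = P1 * T2 / T1` at the incubation temperature. A 1-atm
#' room-temperature (23 degC, 296.15 K) fill reaches 1.20 atm at 82 degC
#' (355.15 K).
#'
#' @param fill_pressure_atm Fill pressure, atm.
#' @param fill_temperature_k Fill temperature, K (> 0).
#' @param incubation_temperature_k Incubation temperature, K (> 0).
#' @return Pressure at incubation temperature, atm.
#' @export
#'
#' @examples
#' isochoric_pressure(1, 296.15, 355.15) # ~1.20 atm
isochoric_pressure <- function(fill_pressure_atm, fill_temperature_k,
                               incubation_temperature_k) {
  if (any(c(fill_temperature_k, incubation_temperature_k) <= 0)) {
    abort("temperatures must be positive (kelvin).")
  }
  if (any(fill_pressure_atm < 0)) abort("pressure must be non-negative.")
  fill_pressure_atm * incubation_temperature_k / fill_temperature_k
}

#' Moles of gas in a headspace from partial pressure
#'
#' Ideal-gas `n = PV / RT` with `R = 0.082057` l atm mol-1 K-1.
#'
#' @param partial_pressure_atm Partial pressure, atm (>= 0).
#' @param headspace_volume_l Headspace volume, liters (> 0).
#' @param temperature_k Temperature, K (> 0).
#' @return Amount in mol.
#' @export
headspace_amount <- function(partial_pressure_atm, headspace_volume_l,
                             temperature_k) {
  if (any(partial_pressure_atm < 0)) abort("partial pressure must be >= 0.")
  if (any(headspace_volume_l <= 0) || any(temperature_k <= 0)) {
    abort("volume and temperature must be positive.")
  }
  partial_pressure_atm * headspace_volume_l / (GAS_CONSTANT_L_ATM * temperature_k)
}

#' Henry's-law solubility model
#'
#' A reference Henry constant with a van 't Hoff temperature correction:
#' `kH(T) = kh_ref * exp(B * (1/T - 1/T_ref))`. Shipped defaults are
#' literature freshwater constants at 298.15 K; no salinity (Setschenow)
#' correction is applied, so aqueous estimates for seawater-like media
#' carry roughly 10% uncertainty.
#'
#' @param gas One of `"H2"`, `"CH4"`, `"CO2"` to load a shipped default,
#'   or `NULL` when supplying constants directly.
#' @param kh_ref Henry constant at `t_ref_k`, mol l-1 atm-1.
#' @param vant_hoff_b van 't Hoff coefficient, K.
#' @param t_ref_k Reference temperature, K. Default 298.15.
#' @return A list of class `henry_model`.
#' @export
#'
#' @examples
#' henry_model("H2")
henry_model <- function(gas = NULL, kh_ref = NULL, vant_hoff_b = NULL,
                        t_ref_k = 298.15) {
  defaults <- list(
    H2  = list(kh_ref = 7.8e-4, vant_hoff_b = 500),
    CH4 = list(kh_ref = 1.4e-3, vant_hoff_b = 1700),
    CO2 = list(kh_ref = 3.4e-2, vant_hoff_b = 2400)
  )
  if (!is.null(gas)) {
    gas <- match.arg(gas, names(defaults))
    d <- defaults[[gas]]
    kh_ref <- kh_ref %||% d$kh_ref
    vant_hoff_b <- vant_hoff_b %||% d$vant_hoff_b
  }
  if (is.null(kh_ref) || is.null(vant_hoff_b)) {
    abort("supply `gas` or both `kh_ref` and `vant_hoff_b`.")
  }
  if (kh_ref <= 0) abort("`kh_ref` must be positive.")
  structure(
    list(gas = gas, kh_ref = kh_ref, vant_hoff_b = vant_hoff_b,
         t_ref_k = t_ref_k),
    class = "henry_model"
  )
}

#' @export
print.henry_model <- function(x, ...) {
  cat(sprintf("<henry_model> %s: kH = %.3g mol l-1 atm-1 at %.2f K, B = %g K\n",
              x$gas %||% "custom", x$kh_ref, x$t_ref_k, x$vant_hoff_b))
  invisible(x)
}

#' Aqueous concentration from a partial pressure
#'
#' Henry's law with the model's van 't Hoff temperature correction:
#' `c = p * kh_ref * exp(B * (1/T - 1/T_ref))`, reported in micromolar.
#'
#' @param p_atm Partial pressure, atm (>= 0).
#' @param model A [henry_model()].
#' @param temperature_k Temperature, K.
#' @return Aqueous concentration in umol per liter.
#' @export
#'
#' @examples
#' aqueous_from_partial_pressure(1.92, henry_model("H2"), 355.15)
aqueous_from_partial_pressure <- function(p_atm, model, temperature_k) {
  if (any(p_atm < 0)) abort("partial pressure must be >= 0.")
  if (!inherits(model, "henry_model")) abort("`model` must be a henry_model.")
  if (any(temperature_k <= 0)) abort("temperature must be positive.")
  kh <- model$kh_ref *
    exp(model$vant_hoff_b * (1 / temperature_k - 1 / model$t_ref_k))
  p_atm * kh * 1e6
}

#' Gas mixture composition from sparge flow rates
#'
#' In an open sparged reactor at ambient pressure, the mole fraction of
#' each component of the feed gas equals its flow fraction, and its partial
#' pressure is that fraction of `total_pressure_atm` (1 atm by default).
#'
#' @param flows_ml_per_min A data frame with columns `component` and
#'   `flow_ml_per_min`, or a named numeric vector of flows.
#' @param total_pressure_atm Total pressure of the reactor headspace, atm.
#' @return A tibble with `component`, `mole_fraction`,
#'   `partial_pressure_atm`.
#' @export
#'
#' @examples
#' sparge_partial_pressure(c(H2 = 132, CO2 = 20.5))
sparge_partial_pressure <- function(flows_ml_per_min, total_pressure_atm = 1) {
  if (is.data.frame(flows_ml_per_min)) {
    check_columns(flows_ml_per_min, c("component", "flow_ml_per_min"))
    flows <- setNames(flows_ml_per_min$flow_ml_per_min,
                      flows_ml_per_min$component)
  } else {
    flows <- flows_ml_per_min
  }
  if (any(flows < 0)) abort("flows must be >= 0.")
  total <- sum(flows)
  if (total <= 0) abort("total flow must be positive.")
  tibble(
    component = names(flows),
    mole_fraction = unname(flows) / total,
    partial_pressure_atm = unname(flows) / total * total_pressure_atm
  )
}
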