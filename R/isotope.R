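#' Convert between 13C/12C ratios and delta13C values
#'
#' delta13C = (R_sample / R_standard - 1) * 1000 permil, against the VPDB
#' standard ratio R_standard = 0.0112372. The two functions are exact
#' mutual inverses.
#'
#' @param r 13C/12C isotope ratio(s), > 0.
#' @param d delta13C value(s) in permil vs VPDB, > -1000.
#' @return `ratio_to_delta()` returns permil values; `delta_to_ratio()`
#'   returns ratios.
#' @export
#'
#' @examples
#' ratio_to_delta(0.0112372)          # 0 permil
#' delta_to_ratio(50)                 # 0.0112372 * 1.05
ratio_to_delta <- function(r) {
  if (any(r <= 0)) abort("isotope ratios must be positive.")
  (r / R_VPDB - 1) * 1e3
}

#' @rdname ratio_to_delta
#' @export
delta_to_ratio <- function(d) {
  if (any(d <= -1000)) abort("delta13C must exceed -1000 permil.")
  R_VPDB * (1 + d / 1e3)
}

#' Fractionation factor between CO2 and CH4
#'
#' alpha = R_CO2 / R_CH4 = (delta_CO2 + 1000) / (delta_CH4 + 1000) and
#' epsilon = (alpha - 1) * 1000 permil. alpha > 1 whenever the product CH4
#' is isotopically lighter than the substrate CO2.
#'
#' @param d_co2 delta13C of CO2, permil vs VPDB.
#' @param d_ch4 delta13C of CH4, permil vs VPDB.
#' @return A tibble with `alpha` and `epsilon_permil` (vectorized over the
#'   inputs).
#' @export
#'
#' @examples
#' alpha_epsilon(-29.0, -55.9) # epsilon ~ 28.5 permil
alpha_epsilon <- function(d_co2, d_ch4) {
  if (any(d_co2 <= -1000) || any(d_ch4 <= -1000)) {
    abort("delta13C must exceed -1000 permil.")
  }
  alpha <- (d_co2 + 1e3) / (d_ch4 + 1e3)
  tibble(alpha = alpha, epsilon_permil = (alpha - 1) * 1e3)
}

#' Equilibrium CO2(aq)-HCO3- fractionation parameters
#'
#' Temperature-dependent equilibrium carbon-isotope fractionation between
#' dissolved CO2 and bicarbonate, `eps(T) = slope_k / T + intercept` with T
#' in kelvin. The default constants (slope -9866 K permil, intercept
#' +24.12 permil) are the classical equilibrium values for the
#' CO2(aq)-HCO3- pair; at 355.15 K (82 degC) the offset is -3.66 permil.
#'
#' @param slope_k Slope in K permil. Default -9866.
#' @param intercept_permil Intercept in permil. Default 24.12.
#' @return A list of class `mook_params`.
#' @export
mook_params <- function(slope_k = -9866, intercept_permil = 24.12) {
  structure(
    list(slope_k = slope_k, intercept_permil = intercept_permil),
    class = "mook_params"
  )
}

#' Convert delta13C of DIC to delta13C of dissolved CO2
#'
#' Applies the temperature-dependent equilibrium fractionation between
#' CO2(aq) and the DIC pool. Without a pH the DIC is treated as pure
#' bicarbonate (a good approximation near pH 6 at high temperature where
#' carbonate is negligible and CO2(aq) is a trace of the measured pool):
#' `delta_CO2 = delta_DIC + eps(T)`. With a pH supplied, DIC is
#' partitioned between CO2(aq) and HCO3- via the first carbonic-acid
#' dissociation constant and the pairwise fractionation is applied to the
#' bicarbonate fraction only.
#'
#' @param d_dic delta13C of DIC, permil vs VPDB.
#' @param temperature_k Temperature in kelvin; must lie in \[273, 400\].
#' @param ph Optional pH for CO2(aq)/HCO3- partitioning.
#' @param mook A [mook_params()] object.
#' @return delta13C of CO2(aq), permil (vectorized over `d_dic`).
#' @export
#'
#' @examples
#' dic_to_co2(22.6, 355.15)  # ~ +18.9 permil
dic_to_co2 <- function(d_dic, temperature_k, ph = NULL, mook = mook_params()) {
  if (any(temperature_k < 273) || any(temperature_k > 400)) {
    abort("temperature outside the validity range [273, 400] K.")
  }
  eps <- mook$slope_k / temperature_k + mook$intercept_permil
  if (is.null(ph)) {
    frac_bicarb <- 1
  } else {
    ## Harned & Davis first dissociation constant of carbonic acid,
    ## extrapolated; adequate for partitioning at the ~0.1 permil level
    pk1 <- 3404.71 / temperature_k + 0.032786 * temperature_k - 14.8435
    frac_bicarb <- 1 / (1 + 10^(pk1 - ph))
  }
  d_dic + frac_bicarb * eps
}

#' First-order uncertainty of epsilon from delta measurement errors
#'
#' Quadrature propagation through epsilon(delta_CO2, delta_CH4):
#' `sigma_eps^2 = (1000 / (d_CH4 + 1000))^2 sigma_CO2^2 +
#' (1000 * alpha / (d_CH4 + 1000))^2 sigma_CH4^2`.
#'
#' @param d_co2,d_ch4 delta13C values, permil.
#' @param sigma_co2,sigma_ch4 Measurement SDs of the two deltas, permil
#'   (>= 0).
#' @return sigma of epsilon in permil (vectorized).
#' @export
#'
#' @examples
#' propagate_epsilon_uncertainty(-29.0, -55.9, 0.3, 0.3) # ~0.46 permil
propagate_epsilon_uncertainty <- function(d_co2, d_ch4, sigma_co2, sigma_ch4) {
  if (any(sigma_co2 < 0) || any(sigma_ch4 < 0)) abort("sigmas must be >= 0.")
  alpha <- (d_co2 + 1e3) / (d_ch4 + 1e3)
  d_dco2 <- 1e3 / (d_ch4 + 1e3)
  d_dch4 <- -1e3 * alpha / (d_ch4 + 1e3)
  sqrt((d_dco2 * sigma_co2)^2 + (d_dch4 * sigma_ch4)^2)
}
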