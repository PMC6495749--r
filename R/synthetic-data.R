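#' Simulate an exponentially growing batch culture
#'
#' Generates a cell-count time series `x(t) = x0 * exp(k * t)` on the
#' configuration's time grid, with independent multiplicative lognormal
#' counting noise at the configured coefficient of variation. The noise
#' factors have unit mean, so noisy counts are unbiased for the true curve.
#'
#' @param k Specific growth rate in per hour. May be zero or negative
#'   (washout), but must be finite.
#' @param x0 Initial cell concentration in cells per ml; must be positive.
#' @param config A [sim_config()].
#' @param organism_label Free-text organism label carried in the output.
#'
#' @return A tibble with columns `time_h`, `count_per_ml`, `organism_label`,
#'   carrying the seed and generator parameters as attributes.
#' @export
#'
#' @examples
#' cfg <- sim_config(seed = 1, noise_cv_counts = 0)
#' gen_batch_growth(k = log(2), x0 = 1e6, config = cfg)
gen_batch_growth <- function(k, x0, config, organism_label = "methanogen") {
  stopifnot(is.finite(k))
  if (x0 <= 0) abort("`x0` must be positive.")
  t <- config$time_grid_h
  set.seed(config$seed)
  counts <- x0 * exp(k * t) * lognormal_factors(length(t), config$noise_cv_counts)
  out <- tibble(
    time_h = t,
    count_per_ml = counts,
    organism_label = organism_label
  )
  stamp_sim(out, config, list(k = k, x0 = x0, cv = config$noise_cv_counts))
}

#' Simulate a chemostat steady state
#'
#' Constructs a steady-state operating point for a sparged, continuously
#' diluted reactor in which the total CH4 production rate equals
#' `q_true * x * volume * 1000` (cells in the vessel times the per-cell
#' rate). The rate is partitioned between the exiting gas stream and the
#' exiting medium; with zero noise, [chemostat_production_rate()] and
#' [chemostat_yield()] recover `q_true` and `Y = D / q_true` exactly.
#'
#' @param d Dilution rate in per hour; must be positive.
#' @param x Steady-state cell concentration in cells per ml.
#' @param q_true True cell-specific CH4 production rate in mol per cell per
#'   hour (e.g. `496e-15` for 496 fmol per cell per hour).
#' @param gas_flow Gas outflow in liters of gas per hour.
#' @param volume Liquid volume in liters.
#' @param config A [sim_config()]; `noise_cv_counts` is applied as
#'   independent multiplicative lognormal error to the measured cell
#'   concentration and both CH4 concentrations.
#' @param headspace_fraction Fraction of produced CH4 leaving with the gas
#'   stream (the rest leaves dissolved in the medium). Default 0.95; in a
#'   sparged open reactor nearly all CH4 is stripped to the gas phase.
#' @param condition,replicate Labels carried in the output.
#'
#' @return A one-row tibble with the chemostat-state columns
#'   (`dilution_rate_per_h`, `cell_conc_per_ml`, `liquid_volume_l`,
#'   `gas_outflow_l_per_h`, `headspace_ch4_mol_per_l`,
#'   `dissolved_ch4_mol_per_l`) plus `condition` and `replicate`.
#' @export
gen_chemostat_run <- function(d, x, q_true, gas_flow, volume, config,
                              headspace_fraction = 0.95,
                              condition = "chemostat", replicate = 1L) {
  if (d <= 0) abort("`d` (dilution rate) must be positive.")
  if (any(c(x, q_true, gas_flow, volume) <= 0)) {
    abort("`x`, `q_true`, `gas_flow` and `volume` must all be positive.")
  }
  stopifnot(headspace_fraction >= 0, headspace_fraction <= 1)
  rate <- q_true * x * volume * 1e3            # mol CH4 h-1, vessel total
  hs <- headspace_fraction * rate / gas_flow   # mol per l of exiting gas
  dis <- (1 - headspace_fraction) * rate / (d * volume)
  set.seed(config$seed)
  noise <- lognormal_factors(3L, config$noise_cv_counts)
  out <- tibble(
    condition = condition,
    replicate = as.integer(replicate),
    dilution_rate_per_h = d,
    cell_conc_per_ml = x * noise[1],
    liquid_volume_l = volume,
    gas_outflow_l_per_h = gas_flow,
    headspace_ch4_mol_per_l = hs * noise[2],
    dissolved_ch4_mol_per_l = dis * noise[3]
  )
  stamp_sim(out, config, list(
    d = d, x = x, q_true = q_true, gas_flow = gas_flow, volume = volume,
    headspace_fraction = headspace_fraction
  ))
}

#' Simulate interspecies hydrogen transfer in a sealed bottle
#'
#' A fermentative heterotroph grows exponentially, producing H2 (and
#' acetate, optionally formate) in proportion to its integrated cell-hours;
#' a hydrogenotrophic methanogen consumes the transferred H2 at the
#' 4 H2 + CO2 -> CH4 stoichiometry and accrues cells at `y_ch4` cells per
#' mol CH4. The model is quasi-steady: H2 transfer is instantaneous and the
#' standing H2 pool is a small constant fraction of cumulative production,
#' emulating the near-complete H2 removal observed in such cocultures.
#'
#' Per-cell production rates are given in the yield-slope convention
#' `q = k / (ln 2 * Y)`, so zero-noise output round-trips exactly through
#' [batch_yield()] and [metabolite_cell_specific_rate()].
#'
#' @param k_het Heterotroph specific growth rate, per hour.
#' @param h2_per_cell Cell-specific H2 production rate of the heterotroph,
#'   mol per cell per hour (yield-slope convention).
#' @param y_ch4 Methanogen cell yield, cells per mol CH4.
#' @param config A [sim_config()].
#' @param acetate_per_cell,formate_per_cell Cell-specific metabolite
#'   production rates, mol per cell per hour (same convention).
#' @param het0,meth0 Initial cells per bottle for heterotroph and methanogen.
#' @param h2_residual_frac Standing H2 pool as a fraction of cumulative H2
#'   production (default 0.005; the rest is transferred and reduced to CH4).
#'
#' @return A tibble with columns `time_h`, `methanogen_cells_total`,
#'   `heterotroph_cells_total`, `ch4_mol_total`, `h2_mol_total`,
#'   `acetate_mol_total`, `formate_mol_total`.
#' @export
gen_coculture <- function(k_het, h2_per_cell, y_ch4, config,
                          acetate_per_cell = 0, formate_per_cell = 0,
                          het0 = 1e9, meth0 = 1e8,
                          h2_residual_frac = 0.005) {
  if (k_het <= 0) abort("`k_het` must be positive.")
  if (h2_per_cell < 0 || y_ch4 <= 0 || acetate_per_cell < 0 ||
      formate_per_cell < 0) {
    abort("rates must be non-negative and `y_ch4` positive.")
  }
  stopifnot(h2_residual_frac >= 0, h2_residual_frac < 1)
  t <- config$time_grid_h
  het <- het0 * exp(k_het * t)
  ## cumulative product for rate q (yield-slope convention):
  ## P(t) = q * ln2 / k * (het(t) - het0), so slope of cells vs P is k/(q ln2)
  cum_prod <- function(q) q * log(2) / k_het * (het - het0)
  h2_produced <- cum_prod(h2_per_cell)
  h2_pool <- h2_residual_frac * h2_produced
  ch4 <- (h2_produced - h2_pool) / 4
  meth <- meth0 + y_ch4 * ch4
  set.seed(config$seed)
  cv <- config$noise_cv_counts
  out <- tibble(
    time_h = t,
    methanogen_cells_total = meth * lognormal_factors(length(t), cv),
    heterotroph_cells_total = het * lognormal_factors(length(t), cv),
    ch4_mol_total = ch4 * lognormal_factors(length(t), cv),
    h2_mol_total = h2_pool * lognormal_factors(length(t), cv),
    acetate_mol_total = cum_prod(acetate_per_cell) *
      lognormal_factors(length(t), cv),
    formate_mol_total = cum_prod(formate_per_cell) *
      lognormal_factors(length(t), cv)
  )
  stamp_sim(out, config, list(
    k_het = k_het, h2_per_cell = h2_per_cell, y_ch4 = y_ch4,
    acetate_per_cell = acetate_per_cell, formate_per_cell = formate_per_cell,
    het0 = het0, meth0 = meth0, h2_residual_frac = h2_residual_frac
  ))
}

#' Simulate closed-system Rayleigh isotope drawdown
#'
#' Observations of a finite reactant pool consumed with constant
#' fractionation epsilon: at each remaining fraction `f` the residual
#' reactant delta follows the closed-form Rayleigh solution and the
#' accumulated product delta follows isotope mass balance. Gaussian
#' measurement noise of `config$sigma_delta_permil` is added to each delta.
#'
#' @param delta0 Initial reactant delta13C, permil vs VPDB.
#' @param epsilon Fractionation factor epsilon, permil; must be >= 0.
#' @param f_final Final fraction of reactant remaining, in (0, 1].
#' @param n_obs Number of observations, log-spaced in f from 1 to `f_final`.
#' @param config A [sim_config()].
#'
#' @return A tibble with columns `f`, `delta_residual_permil`,
#'   `delta_product_cum_permil` (the product delta is `NA` at `f = 1`,
#'   where no product exists yet).
#' @export
gen_isotope_drawdown <- function(delta0, epsilon, f_final, n_obs, config) {
  if (f_final <= 0 || f_final > 1) abort("`f_final` must be in (0, 1].")
  if (epsilon < 0) abort("`epsilon` must be >= 0.")
  stopifnot(n_obs >= 1)
  f <- exp(seq(0, log(f_final), length.out = n_obs))
  dres <- rayleigh_residual_delta(delta0, epsilon, f)
  dprod <- ifelse(f < 1, (delta0 - f * dres) / (1 - f), NA_real_)
  set.seed(config$seed)
  s <- config$sigma_delta_permil
  out <- tibble(
    f = f,
    delta_residual_permil = dres + rnorm(n_obs, 0, s),
    delta_product_cum_permil = dprod +
      ifelse(is.na(dprod), 0, rnorm(n_obs, 0, s))
  )
  stamp_sim(out, config, list(
    delta0 = delta0, epsilon = epsilon, f_final = f_final, n_obs = n_obs
  ))
}
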