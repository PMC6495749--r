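#' Fit a specific growth rate by log-linear regression
#'
#' Ordinary least squares of `ln(count)` on time over the chosen window;
#' the slope is the specific growth rate `k` (per hour). This is the
#' classical semi-log fit of exponential growth: counts must be strictly
#' positive so the log transform is defined, and non-positive counts are
#' rejected rather than dropped.
#'
#' @param data A data frame with a time column (hours) and a count column
#'   (cells per ml or cells per vessel; `k` is invariant to the scale).
#' @param time,count Column names (tidy-eval) holding times and counts.
#'   Defaults `time_h` and `count_per_ml`.
#' @param window Optional integer index range (e.g. `2:6`) selecting the
#'   points entering the fit; default all points. At least 3 points are
#'   required.
#'
#' @return A `growth_fit` object: a list with elements `k` (per hour),
#'   `ln_intercept`, `stderr_k`, `r_squared`, `window`, `n` and the
#'   underlying `lm` fit. [tidy()] and [glance()] methods are provided.
#' @export
#'
#' @examples
#' d <- tibble::tibble(time_h = 0:5, count_per_ml = 1e6 * exp(0.5 * (0:5)))
#' fit <- fit_growth_rate(d)
#' fit$k
fit_growth_rate <- function(data, time = time_h, count = count_per_ml,
                            window = NULL) {
  t <- dplyr::pull(data, {{ time }})
  x <- dplyr::pull(data, {{ count }})
  if (is.null(window)) window <- seq_along(t)
  if (length(window) < 3L) abort("at least 3 points are required for a growth fit.")
  t <- t[window]
  x <- x[window]
  if (anyNA(t) || anyNA(x)) abort("growth data must not contain missing values.")
  if (any(x <= 0)) abort("all counts must be positive (log transform undefined).")
  if (anyDuplicated(t)) abort("times must be distinct.")
  fit <- lm(log(x) ~ t)
  ## a perfect fit is a designed use case (exact synthetic data); lm's
  ## "essentially perfect fit" warning is noise here
  sm <- suppressWarnings(summary(fit))
  ## r.squared of a flat series is NaN (zero total SS); report 1: the
  ## constant model fits exactly
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 1
  structure(
    list(
      k = unname(coef(fit)[2]),
      ln_intercept = unname(coef(fit)[1]),
      stderr_k = unname(sm$coefficients[2, "Std. Error"]),
      r_squared = r2,
      window = window,
      n = length(window),
      fit = fit,
      data = tibble(time_h = t, count = x)
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> k = %.4g +/- %.2g h-1 (r2 = %.4f, n = %d)\n",
              x$k, x$stderr_k, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_growth_rate
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(
    term = c("ln_intercept", "k"),
    estimate = c(x$ln_intercept, x$k),
    std.error = c(unname(suppressWarnings(
                    summary(x$fit))$coefficients[1, "Std. Error"]),
                  x$stderr_k)
  )
}

#' @rdname fit_growth_rate
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(k = x$k, stderr_k = x$stderr_k, r_squared = x$r_squared, n = x$n)
}

#' Vessel-total CH4 production rate and cell-specific rate in a chemostat
#'
#' The production rate is the sum of CH4 leaving with the gas stream
#' (headspace concentration times gas outflow) and CH4 leaving dissolved in
#' the medium (dissolved concentration times medium outflow `D * V`). The
#' cell-specific rate `q` normalizes by the cells in the vessel.
#'
#' @param state A one-row data frame (or a row per replicate) with columns
#'   `dilution_rate_per_h`, `cell_conc_per_ml`, `liquid_volume_l`,
#'   `gas_outflow_l_per_h`, `headspace_ch4_mol_per_l`,
#'   `dissolved_ch4_mol_per_l`.
#' @param cells_basis `"total"` (default) normalizes the rate by all cells
#'   in the vessel (`X * V * 1000`); `"per_ml"` normalizes by the per-ml
#'   concentration alone, giving a rate per (cells per ml).
#'
#' @return A tibble with one row per input row: `production_rate_mol_per_h`
#'   (vessel total) and `q_fmol_per_cell_h` (femtomol per cell per hour).
#' @export
chemostat_production_rate <- function(state, cells_basis = c("total", "per_ml")) {
  cells_basis <- match.arg(cells_basis)
  need <- c("dilution_rate_per_h", "cell_conc_per_ml", "liquid_volume_l",
            "gas_outflow_l_per_h", "headspace_ch4_mol_per_l",
            "dissolved_ch4_mol_per_l")
  check_columns(state, need)
  if (any(state$cell_conc_per_ml <= 0)) {
    abort("cell concentration must be positive to compute a per-cell rate.")
  }
  rate <- state$headspace_ch4_mol_per_l * state$gas_outflow_l_per_h +
    state$dissolved_ch4_mol_per_l *
      (state$dilution_rate_per_h * state$liquid_volume_l)
  cells <- switch(cells_basis,
    total = state$cell_conc_per_ml * state$liquid_volume_l * 1e3,
    per_ml = state$cell_conc_per_ml
  )
  tibble(
    production_rate_mol_per_h = rate,
    q_fmol_per_cell_h = rate / cells * 1e15
  )
}

#' Chemostat cell yield
#'
#' Cell production rate (dilution rate times cells in the vessel) divided
#' by the CH4 production rate: the steady-state yield `Y` in cells per mol
#' CH4. By construction `Y * q = D` exactly when `q` is expressed in mol
#' per cell per hour.
#'
#' @param state A chemostat-state data frame (see
#'   [chemostat_production_rate()]).
#' @param rate Optional result of [chemostat_production_rate()]; computed
#'   from `state` if omitted.
#'
#' @return A tibble with `yield_cells_per_mol`, `intercept` (0: the
#'   steady-state yield is a pure ratio), `stderr_yield` (`NA`: a single
#'   operating point carries no regression error) and `r_squared` (`NA`).
#' @export
chemostat_yield <- function(state, rate = NULL) {
  if (is.null(rate)) rate <- chemostat_production_rate(state)
  if (any(rate$production_rate_mol_per_h <= 0)) {
    abort("CH4 production rate must be positive to compute a yield.")
  }
  cells_rate <- state$dilution_rate_per_h * state$cell_conc_per_ml *
    state$liquid_volume_l * 1e3
  tibble(
    yield_cells_per_mol = cells_rate / rate$production_rate_mol_per_h,
    intercept = 0,
    stderr_yield = NA_real_,
    r_squared = NA_real_
  )
}

## column name per product channel of a batch bottle series
product_column <- function(product) {
  switch(product,
    CH4 = "ch4_mol_total",
    acetate = "acetate_mol_total",
    formate = "formate_mol_total",
    H2 = "h2_mol_total",
    abort("`product` must be one of CH4, acetate, formate, H2.")
  )
}

#' Batch-bottle cell yield from a cells-vs-product regression
#'
#' Ordinary least squares of cell count against cumulative product amount;
#' the slope is the yield `Y` in cells per mol. The intercept is kept free
#' by default (bottles start with a nonzero inoculum); `through_origin =
#' TRUE` forces the regression through zero.
#'
#' For `product = "CH4"` the methanogen cells are regressed (cells accrue
#' per mol CH4 produced); for the fermentation products (`acetate`,
#' `formate`, `H2`) the heterotroph cells are regressed. Override with
#' `cells`.
#'
#' @param series A batch-bottle data frame with `time_h`, cell columns
#'   (`methanogen_cells_total`, `heterotroph_cells_total`) and product
#'   columns (`ch4_mol_total`, `h2_mol_total`, `acetate_mol_total`,
#'   `formate_mol_total`).
#' @param product One of `"CH4"`, `"acetate"`, `"formate"`, `"H2"`.
#' @param cells Optional column name for the cell counts to regress.
#' @param through_origin Force a zero intercept. Default `FALSE`.
#'
#' @return A `yield_fit` tibble-like object with `yield_cells_per_mol`,
#'   `intercept`, `stderr_yield`, `r_squared`, `n` and `product`.
#' @export
batch_yield <- function(series, product = c("CH4", "acetate", "formate", "H2"),
                        cells = NULL, through_origin = FALSE) {
  product <- match.arg(product)
  pcol <- product_column(product)
  ccol <- cells %||%
    if (product == "CH4") "methanogen_cells_total" else "heterotroph_cells_total"
  check_columns(series, c(pcol, ccol))
  p <- series[[pcol]]
  x <- series[[ccol]]
  if (length(p) < 3L) abort("at least 3 paired points are required.")
  if (all(p == 0)) abort(paste0("all-zero ", product, " column: no yield is defined."))
  fit <- if (through_origin) lm(x ~ p + 0) else lm(x ~ p)
  sm <- suppressWarnings(summary(fit))
  slope_row <- if (through_origin) 1L else 2L
  out <- tibble(
    yield_cells_per_mol = unname(coef(fit)[slope_row]),
    intercept = if (through_origin) 0 else unname(coef(fit)[1]),
    stderr_yield = unname(sm$coefficients[slope_row, "Std. Error"]),
    r_squared = if (is.finite(sm$r.squared)) sm$r.squared else 1,
    n = length(p),
    product = product
  )
  class(out) <- c("yield_fit", class(out))
  attr(out, "fit") <- fit
  out
}

#' @export
print.yield_fit <- function(x, ...) {
  cat(sprintf("<yield_fit> Y_%s = %.4g cells mol-1 (r2 = %.4f, n = %d)\n",
              x$product, x$yield_cells_per_mol, x$r_squared, x$n))
  NextMethod()
}

#' Cell-specific production rate from growth rate and yield
#'
#' The doubling-time-based batch formula `q = k / (ln 2 * Y)`: cells double
#' every `ln 2 / k` hours and each new cell corresponds to `1 / Y` mol of
#' product formed, so the per-cell rate is `k / (ln 2 * Y)` mol per cell per
#' hour. `ln 2` is used at full precision (printed forms of the formula
#' round it to 0.693).
#'
#' @param k Specific growth rate in per hour (a number or a `growth_fit`).
#' @param y Yield in cells per mol (a number, or a yield fit from
#'   [batch_yield()] / [chemostat_yield()]).
#'
#' @return A tibble with `production_rate_mol_per_h` (`NA`: a batch bottle
#'   has no steady vessel-total rate) and `q_fmol_per_cell_h`.
#' @export
batch_cell_specific_rate <- function(k, y) {
  if (inherits(k, "growth_fit")) k <- k$k
  if (is.data.frame(y)) y <- y$yield_cells_per_mol
  if (any(y <= 0)) abort("yield must be positive.")
  tibble(
    production_rate_mol_per_h = NA_real_,
    q_fmol_per_cell_h = k / (log(2) * y) * 1e15
  )
}

#' @rdname batch_cell_specific_rate
#' @param y_metabolite Yield based on a metabolite channel (acetate,
#'   formate or H2), cells per mol.
#' @export
metabolite_cell_specific_rate <- function(k, y_metabolite) {
  batch_cell_specific_rate(k, y_metabolite)
}

check_columns <- function(data, need) {
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(data)
}
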