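test_that("log-linear fit is exact on clean exponentials", {
  d <- tibble::tibble(time_h = 0:5, count_per_ml = 1e6 * exp(0.5 * (0:5)))
  fit <- fit_growth_rate(d)
  expect_equal(fit$k, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$ln_intercept, log(1e6), tolerance = 1e-12)

  flat <- tibble::tibble(time_h = 0:4, count_per_ml = rep(2e6, 5))
  expect_equal(fit_growth_rate(flat)$k, 0, tolerance = 1e-12)
})

test_that("growth fit rejects degenerate inputs instead of dropping them", {
  d <- tibble::tibble(time_h = 0:1, count_per_ml = c(1e6, 2e6))
  expect_error(fit_growth_rate(d), "3 points")
  d2 <- tibble::tibble(time_h = 0:3, count_per_ml = c(1e6, 0, 2e6, 4e6))
  expect_error(fit_growth_rate(d2), "positive")
  d3 <- tibble::tibble(time_h = 0:5, count_per_ml = 1e6 * exp(0.3 * (0:5)))
  expect_error(fit_growth_rate(d3, window = 1:2), "3 points")
})

test_that("growth rate is invariant to count rescaling; window is honored", {
  d <- tibble::tibble(time_h = 0:7,
                      count_per_ml = 1e6 * exp(0.4 * (0:7)) * rep(c(1, 1.1), 4))
  f1 <- fit_growth_rate(d)
  f2 <- fit_growth_rate(dplyr::mutate(d, count_per_ml = count_per_ml * 1e3))
  expect_equal(f1$k, f2$k, tolerance = 1e-12)
  expect_equal(f2$ln_intercept - f1$ln_intercept, log(1e3), tolerance = 1e-12)
  fw <- fit_growth_rate(d, window = 3:7)
  expect_equal(fw$n, 5L)
  expect_false(identical(fw$k, f1$k))
})

test_that("tidy and glance expose the growth fit in broom shape", {
  d <- tibble::tibble(time_h = 0:5, count_per_ml = 1e6 * exp(0.5 * (0:5)))
  fit <- fit_growth_rate(d)
  td <- tidy(fit)
  expect_identical(td$term, c("ln_intercept", "k"))
  expect_equal(td$estimate[2], 0.5, tolerance = 1e-12)
  gl <- glance(fit)
  expect_identical(names(gl), c("k", "stderr_k", "r_squared", "n"))
})

test_that("chemostat rate sums the gas-stream and medium export terms", {
  st <- tibble::tibble(
    condition = "x", replicate = 1L, dilution_rate_per_h = 0.5,
    cell_conc_per_ml = 1e8, liquid_volume_l = 1.5, gas_outflow_l_per_h = 9,
    headspace_ch4_mol_per_l = 0, dissolved_ch4_mol_per_l = 0
  )
  expect_equal(chemostat_production_rate(st)$production_rate_mol_per_h, 0)
  st$headspace_ch4_mol_per_l <- 1e-6
  expect_equal(chemostat_production_rate(st)$production_rate_mol_per_h,
               9e-6, tolerance = 1e-12)
  st$dissolved_ch4_mol_per_l <- 2e-6
  expect_equal(chemostat_production_rate(st)$production_rate_mol_per_h,
               9e-6 + 2e-6 * 0.5 * 1.5, tolerance = 1e-12)
  ## per-ml normalization differs from vessel-total by V * 1000
  q_tot <- chemostat_production_rate(st)$q_fmol_per_cell_h
  q_ml <- chemostat_production_rate(st, cells_basis = "per_ml")$q_fmol_per_cell_h
  expect_equal(q_ml / q_tot, 1.5 * 1e3, tolerance = 1e-12)
})

test_that("chemostat yield obeys Y * q = D across random operating points", {
  set.seed(11)
  for (i in 1:20) {
    st <- tibble::tibble(
      condition = "x", replicate = 1L,
      dilution_rate_per_h = runif(1, 0.05, 1),
      cell_conc_per_ml = 10^runif(1, 7, 9),
      liquid_volume_l = runif(1, 0.5, 2),
      gas_outflow_l_per_h = runif(1, 1, 20),
      headspace_ch4_mol_per_l = 10^runif(1, -7, -5),
      dissolved_ch4_mol_per_l = 10^runif(1, -8, -6)
    )
    rate <- chemostat_production_rate(st)
    y <- chemostat_yield(st, rate)
    expect_equal(y$yield_cells_per_mol * rate$q_fmol_per_cell_h * 1e-15,
                 st$dilution_rate_per_h, tolerance = 1e-12)
  }
  ## worked magnitude: D = 0.5 h-1, X*V = 1e12 cells, rate 0.24 mol h-1
  st <- tibble::tibble(
    condition = "x", replicate = 1L, dilution_rate_per_h = 0.5,
    cell_conc_per_ml = 1e12 / 1.5e3, liquid_volume_l = 1.5,
    gas_outflow_l_per_h = 9, headspace_ch4_mol_per_l = 0.24 / 9,
    dissolved_ch4_mol_per_l = 0
  )
  y <- chemostat_yield(st)
  expect_equal(y$yield_cells_per_mol, 0.5 * 1e12 / 0.24, tolerance = 1e-9)
  expect_equal(y$yield_cells_per_mol / 1e12, 2.1, tolerance = 0.01)
})

test_that("chemostat yield refuses a zero production rate", {
  st <- tibble::tibble(
    condition = "x", replicate = 1L, dilution_rate_per_h = 0.5,
    cell_conc_per_ml = 1e8, liquid_volume_l = 1.5, gas_outflow_l_per_h = 9,
    headspace_ch4_mol_per_l = 0, dissolved_ch4_mol_per_l = 0
  )
  expect_error(chemostat_yield(st), "positive")
})

test_that("batch yield is the cells-vs-product slope, order-invariant", {
  ch4 <- seq(0, 5e-4, length.out = 6)
  s <- tibble::tibble(
    time_h = 0:5,
    methanogen_cells_total = 5e12 * ch4,
    heterotroph_cells_total = 0, ch4_mol_total = ch4, h2_mol_total = 0,
    acetate_mol_total = 0, formate_mol_total = 0
  )
  y <- batch_yield(s, "CH4")
  expect_equal(y$yield_cells_per_mol, 5e12, tolerance = 1e-9)
  expect_equal(y$r_squared, 1, tolerance = 1e-12)
  perm <- s[sample(nrow(s)), ]
  expect_equal(batch_yield(perm, "CH4")$yield_cells_per_mol, 5e12,
               tolerance = 1e-9)
  ## nonzero inoculum goes to the intercept, not the slope
  s2 <- dplyr::mutate(s, methanogen_cells_total = methanogen_cells_total + 1e8)
  y2 <- batch_yield(s2, "CH4")
  expect_equal(y2$yield_cells_per_mol, 5e12, tolerance = 1e-9)
  expect_equal(y2$intercept, 1e8, tolerance = 1e-3)
  expect_error(batch_yield(dplyr::mutate(s, ch4_mol_total = 0), "CH4"),
               "all-zero")
})

test_that("cell-specific rate formula q = k/(ln2 Y) and its identity", {
  expect_equal(batch_cell_specific_rate(log(2), 1e12)$q_fmol_per_cell_h,
               1000, tolerance = 1e-12)
  expect_equal(batch_cell_specific_rate(0, 5e12)$q_fmol_per_cell_h, 0)
  expect_error(batch_cell_specific_rate(0.5, -1e12), "positive")
  ## identity: q * ln2 * Y = k exactly
  for (k in c(0.05, 0.63, 1.04)) {
    for (y in c(1.5e12, 9.1e12)) {
      q <- batch_cell_specific_rate(k, y)$q_fmol_per_cell_h * 1e-15
      expect_equal(q * log(2) * y, k, tolerance = 1e-12)
    }
  }
  ## magnitude at coculture values: k = 0.12, Y = 9.1e12 -> ~19 fmol
  expect_equal(
    batch_cell_specific_rate(0.12, 9.1e12)$q_fmol_per_cell_h,
    19.0, tolerance = 0.01
  )
})

test_that("metabolite channel round-trips the generator's per-cell rate", {
  cfg <- sim_config(seed = 9, noise_cv_counts = 0,
                    time_grid_h = seq(0, 20, length.out = 10))
  g <- gen_coculture(k_het = 0.22, h2_per_cell = 10e-15, y_ch4 = 9.1e12,
                     acetate_per_cell = 1.05e-12, config = cfg)
  y_ac <- batch_yield(g, "acetate")
  k <- fit_growth_rate(g, count = "heterotroph_cells_total")$k
  q <- metabolite_cell_specific_rate(k, y_ac)$q_fmol_per_cell_h
  expect_equal(q * 1e-15, 1.05e-12, tolerance = 1e-9)
  ## zero production channel
  expect_error(batch_yield(g, "formate"), "all-zero")
})
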