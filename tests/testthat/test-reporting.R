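test_that("every writer's output is accepted by its reader", {
  tmp <- withr::local_tempdir()
  cfg <- sim_config(seed = 1, noise_cv_counts = 0)
  g <- gen_batch_growth(1.04, 1e6, cfg)
  p <- file.path(tmp, "counts.tsv")
  write_measurement_tsv(g, p)
  expect_equal(as.data.frame(read_cell_counts(p)), as.data.frame(g),
               tolerance = 1e-12, ignore_attr = TRUE)
  st <- gen_chemostat_run(0.744, 2e8, 496e-15, 9, 1.5, cfg)
  p <- file.path(tmp, "states.tsv")
  write_measurement_tsv(st, p)
  expect_equal(as.data.frame(read_chemostat_states(p)), as.data.frame(st),
               tolerance = 1e-12, ignore_attr = TRUE)
  cc <- gen_coculture(0.16, 1e-13, 9.1e12, cfg)
  p <- file.path(tmp, "bottle.tsv")
  write_measurement_tsv(cc, p)
  expect_equal(as.data.frame(read_batch_series(p)), as.data.frame(cc),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("isotope reader validates its vocabulary", {
  tmp <- withr::local_tempdir()
  iso <- tibble::tibble(
    condition = "c1", analyte = c("DIC", "CH4"), timepoint = c("Tf", "Tf"),
    delta_permil = c(22.6, -32.9), sigma_permil = 0.3
  )
  p <- file.path(tmp, "iso.tsv")
  write_measurement_tsv(iso, p)
  expect_equal(read_isotopes(p)$delta_permil, iso$delta_permil)
  bad <- dplyr::mutate(iso, analyte = c("DIC", "N2O"))
  write_measurement_tsv(bad, p)
  expect_error(read_isotopes(p), "analyte")
})

test_that("metadata sidecars record seed and parameters", {
  tmp <- withr::local_tempdir()
  cfg <- sim_config(seed = 99, noise_cv_counts = 0)
  g <- gen_batch_growth(0.5, 1e6, cfg)
  p <- file.path(tmp, "counts.tsv.meta")
  write_sim_metadata(g, p)
  lines <- readLines(p)
  expect_true("seed=99" %in% lines)
  expect_true(any(grepl("^k=0.5", lines)))
})

test_that("zero-noise simulated study round-trips through run_condition", {
  tmp <- withr::local_tempdir()
  config <- simulate_study(tmp, seed = 5, noise_cv_counts = 0,
                           sigma_delta_permil = 0)
  out <- run_condition(config)
  expect_identical(nrow(out), 4L)
  high <- out[out$condition_label == "high_H2", ]
  ## identical zero-noise replicates: exact point estimates, zero SE
  expect_equal(high$q_fmol_per_cell_h, 496, tolerance = 1e-9)
  expect_equal(high$y_cells_per_mol, 1.5e12, tolerance = 1e-3)
  expect_equal(high$q_se, 0, tolerance = 1e-9)
  expect_equal(high$k_per_h, 1.04, tolerance = 1e-9)
  low <- out[out$condition_label == "low_H2", ]
  expect_equal(low$q_fmol_per_cell_h, 139, tolerance = 1e-9)
  expect_equal(low$y_cells_per_mol, 2.1e12, tolerance = 1e-3)
  ## coculture yields recover the generator's cells-per-mol slope
  malt <- out[out$condition_label == "coculture_maltose", ]
  expect_equal(malt$y_cells_per_mol, 9.1e12, tolerance = 1e-6)
  form <- out[out$condition_label == "coculture_formate", ]
  expect_equal(form$y_cells_per_mol, 13.5e12, tolerance = 1e-6)
  expect_identical(malt$replicate_count, 2L)
})

test_that("simulation and analysis are deterministic for a fixed seed", {
  t1 <- withr::local_tempdir()
  t2 <- withr::local_tempdir()
  c1 <- simulate_study(t1, seed = 7)
  c2 <- simulate_study(t2, seed = 7)
  for (f in dir(t1, pattern = "tsv$")) {
    expect_identical(readLines(file.path(t1, f)), readLines(file.path(t2, f)),
                     label = f)
  }
  o1 <- run_condition(c1)
  o2 <- run_condition(c2)
  expect_identical(dplyr::select(o1, -1), dplyr::select(o2, -1))
  ## a different seed changes the data but not the schema
  t3 <- withr::local_tempdir()
  simulate_study(t3, seed = 8)
  f1 <- readr::read_tsv(file.path(t1, "high_H2_states.tsv"),
                        show_col_types = FALSE)
  f3 <- readr::read_tsv(file.path(t3, "high_H2_states.tsv"),
                        show_col_types = FALSE)
  expect_identical(names(f1), names(f3))
  expect_false(identical(f1$cell_conc_per_ml, f3$cell_conc_per_ml))
})

test_that("isotope tables flow into condition summaries", {
  tmp <- withr::local_tempdir()
  config <- simulate_study(tmp, seed = 3, noise_cv_counts = 0)
  iso <- tibble::tibble(
    condition = "high_H2",
    analyte = c("CO2", "CO2", "CH4"),
    timepoint = c("To", "Tf", "Tf"),
    delta_permil = c(-35.1, -29.0, -55.9),
    sigma_permil = 0.3
  )
  ipath <- file.path(tmp, "iso.tsv")
  write_measurement_tsv(iso, ipath)
  config$conditions[[1]]$isotopes <- ipath
  out <- run_condition(config, out_dir = file.path(tmp, "out"))
  high <- out[out$condition_label == "high_H2", ]
  expect_equal(high$epsilon_permil, 28.5, tolerance = 0.05)
  expect_true(file.exists(file.path(tmp, "out", "condition_summary.tsv")))
  log <- readLines(file.path(tmp, "out", "run_log.txt"))
  expect_true(any(grepl("^config_hash=", log)))
  expect_true(any(grepl("^package_version=", log)))
  ## DIC measurements are Mook-converted before epsilon
  iso_dic <- dplyr::mutate(iso,
    analyte = c("DIC", "DIC", "CH4"),
    delta_permil = c(-35.1 + 3.6595, -29.0 + 3.6595, -55.9)
  )
  write_measurement_tsv(iso_dic, ipath)
  out2 <- run_condition(config)
  expect_equal(out2$epsilon_permil[out2$condition_label == "high_H2"],
               28.5, tolerance = 0.05)
})

test_that("formatted summaries follow the reporting conventions", {
  s <- tibble::tibble(
    condition_label = "high_H2", replicate_count = 3L,
    k_per_h = 1.0412, k_se = 0.118, q_fmol_per_cell_h = 496.23, q_se = 21.4,
    y_cells_per_mol = 1.53e12, y_se = 0.11e12,
    delta_co2_to = -35.1, delta_co2_tf = -29.0, delta_ch4_tf = -55.9,
    epsilon_permil = 28.512
  )
  f <- format_condition_summary(s)
  expect_identical(f$k_per_h, "1.04 ± 0.12")
  expect_identical(f$q_fmol_per_cell_h, "496.2 ± 21.4")
  expect_identical(f$y_1e12_cells_per_mol, "1.5 ± 0.1")
  expect_identical(f$epsilon_permil, "28.5")
})

test_that("condition plots and fit plots build", {
  tmp <- withr::local_tempdir()
  config <- simulate_study(tmp, seed = 2, noise_cv_counts = 0)
  out <- run_condition(config)
  p <- plot_condition_summary(out)
  expect_s3_class(p, "ggplot")
  fit <- fit_growth_rate(gen_batch_growth(1.04, 1e6, sim_config(1)))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(rayleigh_forward(-26.1, 22.1, 0.3, 100)), "ggplot")
})
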