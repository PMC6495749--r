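#' Generate a full synthetic study
#'
#' Writes the measurement tables of a complete study layout to `out_dir`:
#' chemostat steady states under two H2 regimes (three replicates each,
#' with a batch growth series per replicate) and two coculture conditions
#' (interspecies H2 transfer on maltose and on formate). Parameter
#' defaults are the study conditions the estimators are meant for:
#' high-H2 chemostat q = 496 fmol cell-1 h-1 with yield 1.5e12 cells
#' mol-1, low-H2 q = 139 with 2.1e12 (dilution rate D = Y * q at steady
#' state), coculture heterotroph growth 0.22 / 0.16 h-1 with methanogen
#' yields 9.1e12 / 13.5e12 cells mol-1.
#'
#' Every table gets a plain-text `key=value` metadata sidecar recording
#' the seed and generator parameters.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; each generated table uses a distinct seed
#'   derived from it.
#' @param noise_cv_counts,sigma_delta_permil Noise levels passed to
#'   [sim_config()]. Set `noise_cv_counts = 0` for exact round trips.
#' @param n_replicates Chemostat replicates per condition. Default 3.
#' @return Invisibly, a `run_condition()`-ready config list describing
#'   the written files.
#' @export
simulate_study <- function(out_dir, seed,
                           noise_cv_counts = 0.05,
                           sigma_delta_permil = 0.3,
                           n_replicates = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  next_seed <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      (seed * 1000L + i) %% .Machine$integer.max
    }
  })
  cfg <- function(...) sim_config(
    seed = next_seed(), noise_cv_counts = noise_cv_counts,
    sigma_delta_permil = sigma_delta_permil, ...
  )
  chemostat_specs <- list(
    high_H2 = list(q = 496e-15, y = 1.5e12, x = 2e8, k_batch = 1.04),
    low_H2  = list(q = 139e-15, y = 2.1e12, x = 1e8, k_batch = 0.63)
  )
  coculture_specs <- list(
    coculture_maltose = list(k_het = 0.22, h2 = 10e-15, y_ch4 = 9.1e12,
                             acetate = 1.05e-12),
    coculture_formate = list(k_het = 0.16, h2 = 130.9e-15, y_ch4 = 13.5e12,
                             acetate = 0)
  )
  conditions <- list()
  for (lab in names(chemostat_specs)) {
    sp <- chemostat_specs[[lab]]
    states <- purrr::map(seq_len(n_replicates), function(i) {
      gen_chemostat_run(
        d = sp$q * sp$y, x = sp$x, q_true = sp$q,
        gas_flow = 9, volume = 1.5, config = cfg(),
        condition = lab, replicate = i
      )
    })
    states_tbl <- dplyr::bind_rows(states)
    spath <- file.path(out_dir, paste0(lab, "_states.tsv"))
    write_measurement_tsv(states_tbl, spath)
    write_sim_metadata(states[[1]], paste0(spath, ".meta"))
    counts <- purrr::map_chr(seq_len(n_replicates), function(i) {
      g <- gen_batch_growth(k = sp$k_batch, x0 = 1e6, config = cfg())
      p <- file.path(out_dir, sprintf("%s_counts_rep%d.tsv", lab, i))
      write_measurement_tsv(g, p)
      write_sim_metadata(g, paste0(p, ".meta"))
      p
    })
    conditions[[lab]] <- list(label = lab, vessel = "chemostat",
                              states = spath, counts = as.list(counts))
  }
  for (lab in names(coculture_specs)) {
    sp <- coculture_specs[[lab]]
    series <- purrr::map_chr(1:2, function(i) {
      g <- gen_coculture(
        k_het = sp$k_het, h2_per_cell = sp$h2, y_ch4 = sp$y_ch4,
        acetate_per_cell = sp$acetate,
        config = cfg(time_grid_h = seq(0, 20, length.out = 10))
      )
      p <- file.path(out_dir, sprintf("%s_rep%d.tsv", lab, i))
      write_measurement_tsv(g, p)
      write_sim_metadata(g, paste0(p, ".meta"))
      p
    })
    conditions[[lab]] <- list(label = lab, vessel = "coculture",
                              series = as.list(series))
  }
  config <- list(
    seed = seed,
    options = list(temperature_k = 355.15),
    conditions = unname(conditions)
  )
  yaml::write_yaml(config, file.path(out_dir, "study.yml"))
  invisible(config)
}

## mean and standard error across replicate estimates
mean_se <- function(x) {
  x <- x[is.finite(x)]
  list(mean = if (length(x)) mean(x) else NA_real_,
       se = if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_)
}

summarize_isotopes <- function(iso, temperature_k) {
  pick <- function(analyte, timepoint) {
    v <- iso$delta_permil[iso$analyte == analyte & iso$timepoint == timepoint]
    if (length(v)) mean(v) else NA_real_
  }
  co2_to <- pick("CO2", "To")
  co2_tf <- pick("CO2", "Tf")
  ## DIC measurements are converted to CO2(aq) at culture temperature
  if (is.na(co2_to)) {
    d <- pick("DIC", "To")
    if (!is.na(d)) co2_to <- dic_to_co2(d, temperature_k)
  }
  if (is.na(co2_tf)) {
    d <- pick("DIC", "Tf")
    if (!is.na(d)) co2_tf <- dic_to_co2(d, temperature_k)
  }
  ch4_tf <- pick("CH4", "Tf")
  eps <- if (!is.na(co2_tf) && !is.na(ch4_tf)) {
    alpha_epsilon(co2_tf, ch4_tf)$epsilon_permil
  } else NA_real_
  list(delta_co2_to = co2_to, delta_co2_tf = co2_tf,
       delta_ch4_tf = ch4_tf, epsilon_permil = eps)
}

run_chemostat_condition <- function(spec) {
  states <- read_chemostat_states(spec$states)
  per_rep <- states |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_map(function(row, key) {
      rate <- chemostat_production_rate(row)
      y <- chemostat_yield(row, rate)
      tibble(q = rate$q_fmol_per_cell_h, y = y$yield_cells_per_mol)
    }) |>
    dplyr::bind_rows()
  ks <- if (!is.null(spec$counts)) {
    purrr::map_dbl(spec$counts, function(p) fit_growth_rate(read_cell_counts(p))$k)
  } else numeric(0)
  list(k = mean_se(ks), q = mean_se(per_rep$q), y = mean_se(per_rep$y),
       n = nrow(per_rep))
}

run_bottle_condition <- function(spec) {
  per_rep <- purrr::map(spec$series, function(p) {
    s <- read_batch_series(p)
    ## the summary's k, Y and q all describe the methanogen; heterotroph
    ## rates are available through fit_growth_rate()/batch_yield() directly
    k <- fit_growth_rate(s, count = "methanogen_cells_total")$k
    y <- batch_yield(s, product = spec$product %||% "CH4")
    q <- batch_cell_specific_rate(k, y)
    tibble(k = k, y = y$yield_cells_per_mol, q = q$q_fmol_per_cell_h)
  }) |>
    dplyr::bind_rows()
  list(k = mean_se(per_rep$k), q = mean_se(per_rep$q),
       y = mean_se(per_rep$y), n = nrow(per_rep))
}

#' Run the estimator chain for every condition of a study
#'
#' Reads the measurement tables named in a study config (a YAML file or
#' the list [simulate_study()] returns), dispatches per vessel type
#' (`chemostat`: steady-state q and Y per replicate plus growth fits;
#' `bottle` / `coculture`: growth fit, cells-vs-product yield, and
#' `q = k / (ln 2 * Y)` per replicate), aggregates replicates as
#' mean +/- standard error, and attaches isotope summaries
#' (DIC-to-CO2(aq) conversion and epsilon from the final deltas) when an
#' isotope table is present.
#'
#' @param config Path to a YAML config or an equivalent list. Each entry
#'   of `conditions` has `label`, `vessel` (`chemostat`, `bottle` or
#'   `coculture`), file paths (`states` + optional `counts` for
#'   chemostats, `series` for bottles), and optional `isotopes`.
#' @param out_dir Optional directory: writes `condition_summary.tsv` and
#'   a plain-text run log (package version, config hash, seed).
#' @return A tibble with one row per condition: `condition_label`,
#'   `replicate_count`, `k_per_h`, `k_se`, `q_fmol_per_cell_h`, `q_se`,
#'   `y_cells_per_mol`, `y_se`, `delta_co2_to`, `delta_co2_tf`,
#'   `delta_ch4_tf`, `epsilon_permil`.
#' @export
run_condition <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  temperature_k <- config$options$temperature_k %||% 355.15
  rows <- purrr::map(config$conditions, function(spec) {
    vessel <- spec$vessel %||% abort("each condition needs a `vessel`.")
    est <- switch(vessel,
      chemostat = run_chemostat_condition(spec),
      bottle = ,
      coculture = run_bottle_condition(spec),
      abort(paste0("unknown vessel type: ", vessel))
    )
    iso <- if (!is.null(spec$isotopes)) {
      summarize_isotopes(read_isotopes(spec$isotopes), temperature_k)
    } else {
      list(delta_co2_to = NA_real_, delta_co2_tf = NA_real_,
           delta_ch4_tf = NA_real_, epsilon_permil = NA_real_)
    }
    tibble(
      condition_label = spec$label,
      replicate_count = est$n,
      k_per_h = est$k$mean, k_se = est$k$se,
      q_fmol_per_cell_h = est$q$mean, q_se = est$q$se,
      y_cells_per_mol = est$y$mean, y_se = est$y$se,
      delta_co2_to = iso$delta_co2_to,
      delta_co2_tf = iso$delta_co2_tf,
      delta_ch4_tf = iso$delta_ch4_tf,
      epsilon_permil = iso$epsilon_permil
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out, file.path(out_dir, "condition_summary.tsv"),
                     progress = FALSE)
    log_lines <- c(
      paste0("package_version=", as.character(utils::packageVersion("methanofrac"))),
      paste0("config_hash=", rlang::hash(config)),
      paste0("seed=", config$seed %||% "NA"),
      paste0("temperature_k=", temperature_k),
      paste0("n_conditions=", nrow(out))
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  out
}

#' Format a condition summary for reporting
#'
#' Rounds to the reporting conventions of the field: growth rates to
#' 0.01 h-1, cell-specific rates to 0.1 fmol cell-1 h-1, epsilon to
#' 0.1 permil, yields in units of 1e12 cells per mol to one decimal.
#' Machine-readable outputs keep full precision; use this only for
#' human-facing tables.
#'
#' @param summary A tibble from [run_condition()].
#' @return A tibble of formatted character columns.
#' @export
format_condition_summary <- function(summary) {
  fmt <- function(m, s, digits) {
    ifelse(is.na(m), "",
           ifelse(is.na(s), sprintf("%.*f", digits, m),
                  sprintf("%.*f ± %.*f", digits, m, digits, s)))
  }
  tibble(
    condition = summary$condition_label,
    n = summary$replicate_count,
    k_per_h = fmt(summary$k_per_h, summary$k_se, 2),
    q_fmol_per_cell_h = fmt(summary$q_fmol_per_cell_h, summary$q_se, 1),
    y_1e12_cells_per_mol = fmt(summary$y_cells_per_mol / 1e12,
                               summary$y_se / 1e12, 1),
    epsilon_permil = ifelse(is.na(summary$epsilon_permil), "",
                            sprintf("%.1f", summary$epsilon_permil))
  )
}
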