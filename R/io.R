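## TSV readers/writers with a fixed header vocabulary. Every writer's
## output is accepted by the corresponding reader (schema round trip).

cell_count_cols <- c("time_h", "count_per_ml", "organism_label")
chemostat_cols <- c("condition", "replicate", "dilution_rate_per_h",
                    "cell_conc_per_ml", "liquid_volume_l",
                    "gas_outflow_l_per_h", "headspace_ch4_mol_per_l",
                    "dissolved_ch4_mol_per_l")
batch_cols <- c("time_h", "methanogen_cells_total", "heterotroph_cells_total",
                "ch4_mol_total", "h2_mol_total", "acetate_mol_total",
                "formate_mol_total")
isotope_cols <- c("condition", "analyte", "timepoint", "delta_permil",
                  "sigma_permil")

read_schema <- function(path, need) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, need)
  x
}

#' Read and write the package's tabular schemas
#'
#' Thin TSV wrappers with header validation. `read_cell_counts()` expects
#' `time_h, count_per_ml, organism_label`; `read_chemostat_states()` the
#' chemostat operating-point columns; `read_batch_series()` the sealed
#' bottle totals; `read_isotopes()` long-format isotope measurements
#' (`condition, analyte, timepoint, delta_permil, sigma_permil` with
#' analyte in DIC/CO2/CH4 and timepoint in To/Tf).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_cell_counts <- function(path) read_schema(path, cell_count_cols)

#' @rdname read_cell_counts
#' @export
read_chemostat_states <- function(path) read_schema(path, chemostat_cols)

#' @rdname read_cell_counts
#' @export
read_batch_series <- function(path) read_schema(path, batch_cols)

#' @rdname read_cell_counts
#' @export
read_isotopes <- function(path) {
  x <- read_schema(path, isotope_cols)
  bad <- setdiff(unique(x$analyte), c("DIC", "CO2", "CH4"))
  if (length(bad)) abort(paste0("unknown analyte(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(x$timepoint), c("To", "Tf"))
  if (length(bad)) abort(paste0("unknown timepoint(s): ", paste(bad, collapse = ", ")))
  x
}

#' @rdname read_cell_counts
#' @param x A tibble with the matching schema.
#' @export
write_measurement_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
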