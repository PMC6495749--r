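#' Simulation configuration
#'
#' Bundles the random seed, noise levels and sampling grid shared by all
#' synthetic-data generators. Every generator draws from one seeded RNG
#' stream per call and records the configuration in the attributes of its
#' output, so a run is reproducible from the output alone.
#'
#' @param seed Integer seed for the generator's RNG stream.
#' @param noise_cv_counts Coefficient of variation of the multiplicative
#'   lognormal noise applied to cell counts (dimensionless; microscopy
#'   counting error is proportional to the count). Default 0.05.
#' @param sigma_delta_permil Standard deviation of the additive Gaussian
#'   noise on delta13C values, in permil. Default 0.3, the typical
#'   injection-to-injection SD of an IRMS measurement.
#' @param time_grid_h Strictly increasing sequence of sampling times in
#'   hours. Default `seq(0, 4, length.out = 8)`.
#'
#' @return A list of class `sim_config`.
#' @export
#'
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$noise_cv_counts
sim_config <- function(seed,
                       noise_cv_counts = 0.05,
                       sigma_delta_permil = 0.3,
                       time_grid_h = seq(0, 4, length.out = 8)) {
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  if (noise_cv_counts < 0) abort("`noise_cv_counts` must be >= 0.")
  if (sigma_delta_permil < 0) abort("`sigma_delta_permil` must be >= 0.")
  check_time_grid(time_grid_h)
  structure(
    list(
      seed = seed,
      noise_cv_counts = noise_cv_counts,
      sigma_delta_permil = sigma_delta_permil,
      time_grid_h = as.numeric(time_grid_h)
    ),
    class = "sim_config"
  )
}

check_time_grid <- function(t) {
  if (length(t) < 1L || anyNA(t) || any(diff(t) <= 0)) {
    abort("`time_grid_h` must be a strictly increasing sequence of hours.")
  }
  invisible(t)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed =", x$seed,
      "| count CV =", x$noise_cv_counts,
      "| delta SD =", x$sigma_delta_permil, "permil",
      "|", length(x$time_grid_h), "time points\n")
  invisible(x)
}

## Multiplicative lognormal factors with unit mean and the requested CV.
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## Stamp generator metadata on an output tibble.
stamp_sim <- function(x, config, params) {
  attr(x, "sim_seed") <- config$seed
  attr(x, "sim_params") <- params
  x
}

#' Write the metadata sidecar for a generated table
#'
#' Records the seed and generator parameters as plain-text `key=value`
#' lines next to a written TSV, so any generated file can be regenerated.
#'
#' @param x A tibble produced by one of the `gen_*()` generators.
#' @param path Path of the sidecar file to write.
#' @return `path`, invisibly.
#' @export
write_sim_metadata <- function(x, path) {
  params <- attr(x, "sim_params") %||% list()
  lines <- c(
    paste0("seed=", attr(x, "sim_seed")),
    vapply(names(params), function(nm) {
      paste0(nm, "=", paste(format(params[[nm]], digits = 15), collapse = ","))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
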