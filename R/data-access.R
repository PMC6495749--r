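#' Path to a bundled example data file
#'
#' The package ships the published carbon-isotope summary table of
#' chemostat and bottle experiments (`isotope_table.tsv`: per-condition
#' initial aqueous H2, delta13C of CO2 at To/Tf, delta13C of CH4 at Tf,
#' and the printed epsilon) as a worked-example input.
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
#'
#' @examples
#' readr::read_tsv(methanofrac_example("isotope_table.tsv"),
#'                 show_col_types = FALSE)
methanofrac_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "methanofrac")))
  }
  path <- system.file("extdata", file, package = "methanofrac")
  if (path == "") abort(paste0("no bundled file called ", file))
  path
}
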