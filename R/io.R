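#' Read and write the package's CSV dialects
#'
#' Thin, validated wrappers around base CSV I/O for the three instrument
#' formats: titration curves (`ph,absorbance`), competition series
#' (`pzn,ellipticity`) and ITC injection tables (`volume_ul,heat_ucal`).
#' All files are UTF-8 with a header row and decimal points.
#'
#' @param path File path.
#' @param peptide_id,wavelength Metadata passed to the constructors.
#' @return The corresponding container object ([ph_titration_curve],
#'   [competition_series], or a data frame of injections).
#' @name zf_csv
NULL

#' @rdname zf_csv
#' @export
read_titration_csv <- function(path, peptide_id = "", wavelength = 218) {
  d <- read.csv(path)
  if (!all(c("ph", "absorbance") %in% names(d))) {
    zf_error("zf_invalid_input", "expected columns ph,absorbance")
  }
  ph_titration_curve(d$ph, d$absorbance, peptide_id = peptide_id,
                     wavelength = wavelength)
}

#' @rdname zf_csv
#' @param curve A [ph_titration_curve] to write.
#' @export
write_titration_csv <- function(curve, path) {
  write.csv(curve$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname zf_csv
#' @export
read_competition_csv <- function(path, peptide_id = "", wavelength = 220) {
  d <- read.csv(path)
  if (!all(c("pzn", "ellipticity") %in% names(d))) {
    zf_error("zf_invalid_input", "expected columns pzn,ellipticity")
  }
  competition_series(d$pzn, d$ellipticity, peptide_id = peptide_id,
                     wavelength = wavelength)
}

#' @rdname zf_csv
#' @param series A [competition_series] to write.
#' @export
write_competition_csv <- function(series, path) {
  write.csv(series$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname zf_csv
#' @export
read_injections_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("volume_ul", "heat_ucal") %in% names(d))) {
    zf_error("zf_invalid_input", "expected columns volume_ul,heat_ucal")
  }
  d
}

#' Assemble an ITC experiment from an injection table and metadata
#'
#' @param injections Data frame from [read_injections_csv()].
#' @param cell_volume Cell volume, mL.
#' @param cell_concentration Peptide concentration, M.
#' @param syringe_concentration Titrant concentration, M.
#' @param temperature Temperature, K.
#' @param buffer_name Buffer identifier.
#' @return An [itc_experiment].
#' @export
itc_from_injections <- function(injections, cell_volume,
                                cell_concentration, syringe_concentration,
                                temperature = 298.15,
                                buffer_name = "HEPES") {
  itc_experiment(cell_volume, cell_concentration, syringe_concentration,
                 injections$volume_ul, heats = injections$heat_ucal,
                 temperature = temperature, buffer_name = buffer_name)
}
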