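#' Read and write compound descriptor tables
#'
#' CSV dialect: UTF-8, '.' decimal separator, comment lines starting with
#' `#`. The canonical column set is `name, mw, pka, logp, logs, psa, alpha,
#' e_homo, e_lumo, ie_obs` (`ie_obs` may be empty); tables carrying only a
#' subset of descriptor columns (plus optional `omega`, `delta_n`) are
#' accepted and validated against the invariants of [validate_compounds()].
#'
#' @param path CSV file path.
#' @return `read_compounds()` returns the validated data.frame;
#'   `write_compounds()` returns `path` invisibly.
#' @examples
#' read_compounds(corrqsar_example("high_efficiency_drugs.csv"))
#' @export
read_compounds <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                        stringsAsFactors = FALSE)
  validate_compounds(df)
  df
}

#' @rdname read_compounds
#' @param records compound data.frame to write.
#' @export
write_compounds <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read electrochemical parameter tables
#'
#' `read_eis()` expects the impedance table dialect (`conc, rs, n_cpe, cdl,
#' rct, cf, n2, rmol, rtotal, ie`; resistances Ohm cm^2, capacitances
#' uF/cm^2); `read_polarization()` the Tafel table (`conc, ecorr, icorr, ba,
#' bc, ie`; `bc` stored as magnitude). Both use a `conc = 0` row for the
#' uninhibited blank.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @examples
#' read_eis(corrqsar_example("eis_lidocaine.csv"))
#' @export
read_eis <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("conc", "rs", "n_cpe", "cdl", "rct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("EIS table lacks column(s): %s", paste(miss, collapse = ", "),
          class = "corrqsar_invalid_table")
  res <- df[, intersect(c("rs", "rct", "rmol", "rtotal"), names(df))]
  if (any(res < 0, na.rm = TRUE))
    stopf("negative resistance in EIS table", class = "corrqsar_invalid_table")
  both <- !is.na(df$rtotal) & !is.na(df$rmol)
  if (any(abs(df$rtotal[both] - (df$rct[both] + df$rmol[both])) > 0.01))
    stopf("rtotal != rct + rmol beyond 0.01 Ohm cm^2",
          class = "corrqsar_invalid_table")
  df
}

#' @rdname read_eis
#' @export
read_polarization <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("conc", "icorr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("polarization table lacks column(s): %s",
          paste(miss, collapse = ", "), class = "corrqsar_invalid_table")
  if (any(df$icorr <= 0, na.rm = TRUE))
    stopf("icorr must be > 0", class = "corrqsar_invalid_table")
  df
}

#' Path to a bundled example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' corrqsar_example()
#' @export
corrqsar_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "corrqsar")))
  path <- system.file("extdata", file, package = "corrqsar")
  if (path == "")
    stopf("no bundled file named %s", file, class = "corrqsar_invalid_input")
  path
}

#' Molar mass of lidocaine
#'
#' 234.34 g/mol; used to convert ppm (mg/L) concentrations of the
#' experimentally verified inhibitor into mol/L for Langmuir thermodynamics.
#'
#' @return Molar mass in g/mol.
#' @examples
#' ppm_to_molar(50, lidocaine_molar_mass())
#' @export
lidocaine_molar_mass <- function() 234.34

#' Convert ppm (mg/L) to molar concentration
#'
#' @param ppm concentration in mg/L.
#' @param molar_mass molar mass, g/mol.
#' @return Concentration in mol/L.
#' @examples
#' ppm_to_molar(c(20, 50, 100), lidocaine_molar_mass())
#' @export
ppm_to_molar <- function(ppm, molar_mass) {
  stopifnot(is.numeric(ppm), is.numeric(molar_mass), molar_mass > 0)
  ppm / 1000 / molar_mass
}
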