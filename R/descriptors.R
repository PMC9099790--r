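#' Metal reference for electron-transfer calculations
#'
#' Bulk electronegativity and hardness of the metal surface used in the
#' fraction-of-electrons-transferred formula. The default is the conventional
#' bulk-iron pair used throughout the steel corrosion-inhibition literature:
#' \eqn{\chi_{Fe} = 7.0} eV and \eqn{\eta_{Fe} = 0} eV (a perfect electron
#' sink).
#'
#' @param chi_metal absolute electronegativity of the metal, eV. Must be > 0.
#' @param eta_metal global hardness of the metal, eV. Must be >= 0.
#' @return A list of class `metal_reference` with elements `chi_metal` and
#'   `eta_metal`.
#' @examples
#' metal_reference()           # bulk iron
#' metal_reference(4.98, 3.2)  # e.g. an isolated-atom parameterization
#' @export
metal_reference <- function(chi_metal = 7.0, eta_metal = 0.0) {
  stopifnot(is.numeric(chi_metal), is.numeric(eta_metal),
            length(chi_metal) == 1L, length(eta_metal) == 1L)
  if (!is.finite(chi_metal) || chi_metal <= 0)
    stopf("chi_metal must be a finite positive energy (eV), got %s",
          format(chi_metal), class = "corrqsar_invalid_metal")
  if (!is.finite(eta_metal) || eta_metal < 0)
    stopf("eta_metal must be finite and >= 0 (eV), got %s",
          format(eta_metal), class = "corrqsar_invalid_metal")
  structure(list(chi_metal = chi_metal, eta_metal = eta_metal),
            class = "metal_reference")
}

#' @export
print.metal_reference <- function(x, ...) {
  cat(sprintf("Metal reference: chi = %.3f eV, eta = %.3f eV\n",
              x$chi_metal, x$eta_metal))
  invisible(x)
}

#' Ionization energy and electron affinity from frontier orbitals
#'
#' Koopmans' theorem approximation: the vertical ionization energy is the
#' negative of the HOMO energy and the vertical electron affinity the negative
#' of the LUMO energy, \eqn{I = -E_{HOMO}}, \eqn{A = -E_{LUMO}}.
#'
#' @param e_homo HOMO energy, eV (vectorized).
#' @param e_lumo LUMO energy, eV.
#' @return A data.frame with columns `ionization` and `affinity` (eV).
#' @examples
#' koopmans(-5.31, -3.43)  # cephaloridine
#' @export
koopmans <- function(e_homo, e_lumo) {
  stopifnot(is.numeric(e_homo), is.numeric(e_lumo),
            length(e_homo) == length(e_lumo))
  bad <- which(e_homo > e_lumo)
  if (length(bad))
    stopf("e_homo > e_lumo at position(s) %s: an occupied orbital cannot lie above an unoccupied one",
          paste(bad, collapse = ", "), class = "corrqsar_invalid_ordering")
  data.frame(ionization = -e_homo, affinity = -e_lumo)
}

#' Global HSAB reactivity indices
#'
#' Electronegativity, hardness, and chemical potential in the finite-difference
#' conceptual-DFT approximation: \eqn{\chi = (I + A)/2},
#' \eqn{\eta = (I - A)/2}, \eqn{\mu = -\chi}.
#'
#' @param ionization vertical ionization energy I, eV (vectorized).
#' @param affinity vertical electron affinity A, eV.
#' @return A data.frame with columns `chi`, `eta`, `mu` (eV).
#' @examples
#' global_reactivity(5.31, 3.43)
#' @export
global_reactivity <- function(ionization, affinity) {
  stopifnot(is.numeric(ionization), is.numeric(affinity),
            length(ionization) == length(affinity))
  bad <- which(ionization < affinity)
  if (length(bad))
    stopf("ionization < affinity at position(s) %s: hardness would be negative",
          paste(bad, collapse = ", "), class = "corrqsar_negative_hardness")
  chi <- (ionization + affinity) / 2
  data.frame(chi = chi, eta = (ionization - affinity) / 2, mu = -chi)
}

#' Global electrophilicity index
#'
#' In the standard conceptual-DFT definition the electrophilicity is
#' \eqn{\omega = \mu^2 / (2\eta)}: the stabilization a species gains on
#' acquiring electrons from a perfect donor. The reference descriptor tables
#' this package reproduces, however, print \eqn{\omega} values that obey the
#' empirical relation \eqn{\omega = \chi/4} instead of the standard formula
#' (e.g. an electrophilicity of 0.77 eV where \eqn{\mu^2/2\eta} gives 3.79 eV).
#' Both conventions are exposed: `mode = "standard"` is the textbook index,
#' `mode = "table_compatible"` reproduces the published tables and must be
#' used when feeding the frozen published predictor (its x9 coefficient was
#' fitted against table-convention values).
#'
#' @param chi absolute electronegativity, eV (vectorized).
#' @param eta global hardness, eV.
#' @param mode `"standard"` for \eqn{\chi^2/(2\eta)} (using \eqn{\mu = -\chi}),
#'   `"table_compatible"` for \eqn{\chi/4}.
#' @return Electrophilicity, eV.
#' @examples
#' electrophilicity(3.0, 1.5)                             # 3.0
#' electrophilicity(3.085, 1.255, "table_compatible")     # 0.771...
#' @export
electrophilicity <- function(chi, eta, mode = c("standard", "table_compatible")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(chi), is.numeric(eta), length(chi) == length(eta))
  if (mode == "standard") {
    if (any(eta == 0))
      stopf("eta = 0: standard electrophilicity chi^2/(2*eta) divides by zero",
            class = "corrqsar_division_by_zero")
    chi^2 / (2 * eta)
  } else {
    if (any(chi < 0))
      stopf("table-compatible electrophilicity requires chi >= 0",
            class = "corrqsar_invalid_input")
    chi / 4
  }
}

#' Fraction of electrons transferred to the metal surface
#'
#' \eqn{\Delta N = (\chi_{Metal} - \chi_{Inh}) / [2(\eta_{Metal} +
#' \eta_{Inh})]}: the equalization-of-electronegativity estimate of charge
#' donated by the inhibitor molecule to the metal. Larger values indicate a
#' stronger donor and, empirically, higher inhibition efficiency.
#'
#' @param chi_inh inhibitor electronegativity, eV (vectorized).
#' @param eta_inh inhibitor hardness, eV.
#' @param metal a [metal_reference()].
#' @return Dimensionless fraction of electrons transferred.
#' @examples
#' fraction_electrons_transferred(4.37, 0.94)  # cephaloridine vs bulk iron
#' @export
fraction_electrons_transferred <- function(chi_inh, eta_inh,
                                           metal = metal_reference()) {
  stopifnot(inherits(metal, "metal_reference"),
            is.numeric(chi_inh), is.numeric(eta_inh),
            length(chi_inh) == length(eta_inh))
  denom <- 2 * (metal$eta_metal + eta_inh)
  if (any(denom == 0))
    stopf("both metal and inhibitor hardness are zero: Delta N undefined",
          class = "corrqsar_division_by_zero")
  (metal$chi_metal - chi_inh) / denom
}

#' Full HSAB descriptor set for a compound table
#'
#' Composes [koopmans()], [global_reactivity()], [electrophilicity()] and
#' [fraction_electrons_transferred()] over the `e_homo`/`e_lumo` columns of a
#' compound table.
#'
#' @param records a data.frame with numeric columns `e_homo` and `e_lumo`
#'   (eV); other columns are ignored.
#' @param metal a [metal_reference()].
#' @param omega_mode electrophilicity convention, see [electrophilicity()].
#' @return A data.frame with one row per record and columns `ionization`,
#'   `affinity`, `chi`, `eta`, `mu`, `omega`, `delta_n`.
#' @examples
#' compute_descriptors(data.frame(e_homo = -4.92, e_lumo = -2.53),
#'                     omega_mode = "table_compatible")
#' @export
compute_descriptors <- function(records, metal = metal_reference(),
                                omega_mode = c("standard", "table_compatible")) {
  omega_mode <- match.arg(omega_mode)
  stopifnot(is.data.frame(records),
            all(c("e_homo", "e_lumo") %in% names(records)))
  ia <- koopmans(records$e_homo, records$e_lumo)
  gr <- global_reactivity(ia$ionization, ia$affinity)
  out <- cbind(ia, gr)
  out$omega <- electrophilicity(gr$chi, gr$eta, omega_mode)
  out$delta_n <- fraction_electrons_transferred(gr$chi, gr$eta, metal)
  out
}

#' Validate a compound descriptor table
#'
#' Checks the structural invariants of a compound table: positive molecular
#' weight, HOMO below LUMO, and observed inhibition efficiencies (when
#' present) inside \[0, 100\].
#'
#' @param records a data.frame; must contain `name`, `e_homo`, `e_lumo`;
#'   `mw` and `ie_obs` are checked when present.
#' @return `records`, invisibly, if valid; otherwise an error naming the
#'   offending compounds.
#' @export
validate_compounds <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("name", "e_homo", "e_lumo")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("compound table lacks column(s): %s", paste(miss, collapse = ", "),
          class = "corrqsar_invalid_table")
  who <- function(i) paste(records$name[i], collapse = ", ")
  if ("mw" %in% names(records)) {
    i <- which(!is.na(records$mw) & records$mw <= 0)
    if (length(i)) stopf("non-positive molecular weight for: %s", who(i),
                         class = "corrqsar_invalid_table")
  }
  i <- which(records$e_homo > records$e_lumo)
  if (length(i)) stopf("e_homo > e_lumo for: %s", who(i),
                       class = "corrqsar_invalid_table")
  if ("ie_obs" %in% names(records)) {
    i <- which(!is.na(records$ie_obs) &
                 (records$ie_obs < 0 | records$ie_obs > 100))
    if (length(i)) stopf("ie_obs outside [0, 100] for: %s", who(i),
                         class = "corrqsar_invalid_table")
  }
  invisible(records)
}
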