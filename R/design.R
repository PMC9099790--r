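#' Descriptor labels of the candidate dictionary
#'
#' The ten candidate regressors, in their canonical order: x1 = molecular
#' weight (Da), x2 = pKa, x3 = logP, x4 = logS, x5 = polar surface area
#' (\ifelse{html}{\out{&#8491;}}{A}^2), x6 = polarizability
#' (\ifelse{html}{\out{&#8491;}}{A}^3), x7 = E_HOMO (eV), x8 = E_LUMO (eV),
#' x9 = electrophilicity omega (eV), x10 = fraction of electrons transferred
#' Delta N.
#'
#' @return Named character vector mapping labels `x1`...`x10` to compound
#'   table column names.
#' @examples
#' descriptor_labels()
#' @export
descriptor_labels <- function() {
  c(x1 = "mw", x2 = "pka", x3 = "logp", x4 = "logs", x5 = "psa",
    x6 = "alpha", x7 = "e_homo", x8 = "e_lumo", x9 = "omega", x10 = "delta_n")
}

#' Build the candidate design matrix for sparse model identification
#'
#' Arranges compound descriptors into the N x M candidate dictionary used by
#' [frols_select()], with the observed inhibition efficiencies as response.
#' Derived HSAB columns (`x9` = omega, `x10` = Delta N) are taken from the
#' table when present (so printed table values are honoured) and otherwise
#' computed from the orbital energies via [compute_descriptors()].
#'
#' Records missing an observed efficiency are rejected with a diagnostic
#' naming the compound. Zero-variance columns are retained with a warning:
#' the selection stage may still pick them (a constant column acts as an
#' intercept surrogate).
#'
#' @param records compound table (data.frame) with an `ie_obs` column and the
#'   descriptor columns required by `labels`.
#' @param labels character vector of dictionary labels (`x1`...`x10`),
#'   default all ten.
#' @param metal [metal_reference()] for derived Delta N.
#' @param omega_mode electrophilicity convention for a derived omega column.
#' @param intercept add a constant column (labelled `x0`)? Default `FALSE`:
#'   the reference model family has no intercept.
#' @param standardize z-score the descriptor columns? Default `FALSE`: the
#'   reference coefficients are in raw descriptor units.
#' @return An object of class `qsar_design`: list with `X` (N x M numeric
#'   matrix, columns named by label), `y` (length-N response, IE%), `labels`.
#' @examples
#' tab <- data.frame(name = c("a", "b", "c"), pka = c(2, 5, 8),
#'                   e_homo = c(-5.5, -5.0, -4.5), e_lumo = c(-3, -2.5, -2),
#'                   ie_obs = c(90, 92, 95))
#' build_design_matrix(tab, c("x2", "x7"))
#' @export
build_design_matrix <- function(records, labels = names(descriptor_labels()),
                                metal = metal_reference(),
                                omega_mode = c("table_compatible", "standard"),
                                intercept = FALSE, standardize = FALSE) {
  omega_mode <- match.arg(omega_mode)
  stopifnot(is.data.frame(records), length(labels) >= 1L)
  map <- descriptor_labels()
  unknown <- setdiff(labels, names(map))
  if (length(unknown))
    stopf("unknown descriptor label(s): %s", paste(unknown, collapse = ", "),
          class = "corrqsar_unknown_label")
  if (!"ie_obs" %in% names(records))
    stopf("compound table has no ie_obs column", class = "corrqsar_missing_response")
  nm <- if ("name" %in% names(records)) records$name else seq_len(nrow(records))
  drop <- which(is.na(records$ie_obs))
  if (length(drop)) {
    warning(sprintf("rejecting %d record(s) without observed IE%%: %s",
                    length(drop), paste(nm[drop], collapse = ", ")),
            call. = FALSE)
    records <- records[-drop, , drop = FALSE]
  }
  if (!nrow(records))
    stopf("no records with observed IE%% remain", class = "corrqsar_missing_response")

  cols <- map[labels]
  derived <- setdiff(cols, names(records))
  if (length(derived)) {
    if (!all(derived %in% c("omega", "delta_n")))
      stopf("compound table lacks descriptor column(s): %s",
            paste(setdiff(derived, c("omega", "delta_n")), collapse = ", "),
            class = "corrqsar_invalid_table")
    hs <- compute_descriptors(records, metal, omega_mode)
    for (d in derived) records[[d]] <- hs[[d]]
  }
  X <- as.matrix(records[, cols, drop = FALSE])
  colnames(X) <- labels
  storage.mode(X) <- "double"
  if (any(!is.finite(X)))
    stopf("non-finite descriptor values in columns: %s",
          paste(labels[apply(!is.finite(X), 2, any)], collapse = ", "),
          class = "corrqsar_invalid_table")
  zn <- which(colSums(X^2) == 0)
  if (length(zn))
    stopf("zero-norm column(s): %s", paste(labels[zn], collapse = ", "),
          class = "corrqsar_invalid_table")
  zv <- which(apply(X, 2, stats::var) == 0)
  if (length(zv))
    warning(sprintf("zero-variance column(s) retained: %s",
                    paste(labels[zv], collapse = ", ")), call. = FALSE)
  if (standardize)
    X <- scale(X)[, , drop = FALSE]
  if (intercept) {
    X <- cbind(x0 = 1, X)
    labels <- c("x0", labels)
  }
  structure(list(X = X, y = as.numeric(records$ie_obs), labels = labels),
            class = "qsar_design")
}

#' @export
print.qsar_design <- function(x, ...) {
  cat(sprintf("QSAR candidate dictionary: %d compounds x %d terms (%s)\n",
              nrow(x$X), ncol(x$X), paste(x$labels, collapse = ", ")))
  invisible(x)
}
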