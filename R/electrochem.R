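#' Polarization resistance from charge-transfer and film resistances
#'
#' \eqn{R_p = R_{ct} + R_F}: in the two-time-constant equivalent circuit the
#' total resistance opposing the corrosion reaction is the series sum of the
#' charge-transfer resistance and the inhibitor-film resistance.
#'
#' @param rct charge-transfer resistance, Ohm cm^2 (vectorized).
#' @param rf film (molecular layer) resistance, Ohm cm^2; 0 for a bare
#'   surface.
#' @return Polarization resistance, Ohm cm^2.
#' @examples
#' polarization_resistance(1493.00, 151.70)  # 1644.70
#' @export
polarization_resistance <- function(rct, rf = 0) {
  stopifnot(is.numeric(rct), is.numeric(rf))
  if (any(rct < 0) || any(rf < 0))
    stopf("resistances must be >= 0", class = "corrqsar_invalid_input")
  rct + rf
}

#' Inhibition efficiency from impedance measurements
#'
#' \eqn{IE\% = 100\,[(R_{p,blank}^{-1} - R_{p,inh}^{-1}) / R_{p,blank}^{-1}]
#' = 100\,(1 - R_{p,blank}/R_{p,inh})}: the fractional drop in the corrosion
#' rate proxy \eqn{R_p^{-1}} relative to the uninhibited blank.
#'
#' @param rp_blank polarization resistance of the blank, Ohm cm^2 (> 0).
#' @param rp_inh polarization resistance with inhibitor, Ohm cm^2 (> 0,
#'   vectorized).
#' @return IE%, percent.
#' @examples
#' eis_efficiency(127, 1644.70)  # 92.3 at 1 d.p.
#' @export
eis_efficiency <- function(rp_blank, rp_inh) {
  stopifnot(is.numeric(rp_blank), is.numeric(rp_inh))
  if (any(rp_blank <= 0) || any(rp_inh <= 0))
    stopf("polarization resistances must be > 0",
          class = "corrqsar_division_by_zero")
  100 * (1 - rp_blank / rp_inh)
}

#' Inhibition efficiency from polarization (Tafel) measurements
#'
#' \eqn{IE\% = [1 - i_{corr}/i_{corr,blank}] \times 100}: the fractional
#' reduction in corrosion current density relative to the blank.
#'
#' @param icorr_blank blank corrosion current density, uA/cm^2 (> 0).
#' @param icorr corrosion current density with inhibitor, uA/cm^2
#'   (vectorized).
#' @return IE%, percent.
#' @examples
#' tafel_efficiency(67.4, 7.4)  # 89.0 at 1 d.p.
#' @export
tafel_efficiency <- function(icorr_blank, icorr) {
  stopifnot(is.numeric(icorr_blank), is.numeric(icorr))
  if (any(icorr_blank <= 0))
    stopf("blank corrosion current must be > 0",
          class = "corrqsar_division_by_zero")
  (1 - icorr / icorr_blank) * 100
}

#' Impedance of a constant phase element
#'
#' \eqn{Z_{CPE} = Y_0^{-1} (j\omega)^{-n}}. Limiting cases: n = 0 a pure
#' resistance 1/Y0, n = 1 a pure capacitance \eqn{1/(j\omega C)}, n = 0.5 a
#' Warburg element (phase exactly -45 degrees), n = -1 an inductance.
#'
#' @param y0 CPE constant (> 0; units S s^n / cm^2).
#' @param n CPE exponent in \[-1, 1\].
#' @param ang_freq angular frequency, rad/s (> 0, vectorized).
#' @return Complex impedance.
#' @examples
#' cpe_impedance(1e-4, 0.5, 100)  # phase -45 degrees
#' @export
cpe_impedance <- function(y0, n, ang_freq) {
  stopifnot(is.numeric(y0), is.numeric(n), is.numeric(ang_freq))
  if (any(y0 <= 0) || any(ang_freq <= 0))
    stopf("y0 and ang_freq must be > 0", class = "corrqsar_invalid_input")
  if (any(abs(n) > 1))
    stopf("CPE exponent n must lie in [-1, 1]", class = "corrqsar_invalid_input")
  (1 / y0) * (1i * ang_freq)^(-n)
}

#' Double-layer capacitance from CPE parameters
#'
#' \eqn{C_{dl} = Y_0^{1/n} (R_s^{-1} + R_{ct}^{-1})^{(n-1)/n}}: the
#' Brug-type conversion of the double-layer CPE constant into an effective
#' capacitance, using the solution and charge-transfer resistances seen by
#' the element. For n = 1 the CPE is an ideal capacitor and the result is Y0.
#'
#' @param y0 CPE constant (> 0).
#' @param n CPE exponent in (0, 1].
#' @param rs solution resistance, Ohm cm^2 (> 0).
#' @param rct charge-transfer resistance, Ohm cm^2 (> 0).
#' @return Effective double-layer capacitance (same area normalization as
#'   the inputs; F/cm^2 when Y0 is in S s^n/cm^2).
#' @examples
#' double_layer_capacitance(1e-4, 0.5, 10, 90)  # 9e-8
#' @export
double_layer_capacitance <- function(y0, n, rs, rct) {
  stopifnot(is.numeric(y0), is.numeric(n), is.numeric(rs), is.numeric(rct))
  if (any(n <= 0) || any(n > 1))
    stopf("CPE exponent n must lie in (0, 1]", class = "corrqsar_invalid_input")
  if (any(y0 <= 0) || any(rs <= 0) || any(rct <= 0))
    stopf("y0, rs and rct must be > 0", class = "corrqsar_invalid_input")
  y0^(1 / n) * (1 / rs + 1 / rct)^((n - 1) / n)
}

#' Film capacitance from CPE parameters
#'
#' \eqn{C_F = Y_0 (\omega')^{n-1}} where \eqn{\omega'} is the angular
#' frequency at which the real part of the impedance is maximal.
#'
#' @param y0 CPE constant (> 0).
#' @param n CPE exponent.
#' @param ang_freq_at_max_zreal angular frequency of maximal Z_real, rad/s
#'   (> 0).
#' @return Film capacitance.
#' @examples
#' film_capacitance(2, 0.5, 4)  # 1
#' @export
film_capacitance <- function(y0, n, ang_freq_at_max_zreal) {
  stopifnot(is.numeric(y0), is.numeric(n), is.numeric(ang_freq_at_max_zreal))
  if (any(y0 <= 0) || any(ang_freq_at_max_zreal <= 0))
    stopf("y0 and the angular frequency must be > 0",
          class = "corrqsar_invalid_input")
  y0 * ang_freq_at_max_zreal^(n - 1)
}

#' Surface coverage from inhibition efficiency
#'
#' \eqn{\theta = IE\% / 100}: the fraction of surface sites occupied by
#' adsorbed inhibitor, identified with the fractional rate reduction.
#'
#' @param ie inhibition efficiency, percent (vectorized).
#' @return Coverage fraction.
#' @examples
#' coverage(92.3)  # 0.923
#' @export
coverage <- function(ie) {
  stopifnot(is.numeric(ie))
  ie / 100
}

#' Langmuir adsorption isotherm fit with free-energy classification
#'
#' Fits the linearized Langmuir isotherm \eqn{C/\theta = k_{ads}^{-1} + C} by
#' ordinary least squares of \eqn{C/\theta} on \eqn{C}. A slope near 1 and a
#' high \eqn{R^2} indicate monolayer (Langmuir) adsorption. The adsorption
#' equilibrium constant is \eqn{k_{ads} = 1/\mathrm{intercept}} and the
#' standard adsorption free energy
#' \deqn{\Delta G^0_{ads} = -RT \ln(55.5\,k_{ads})}
#' (kJ/mol), where 55.5 mol/L is the molar concentration of water that
#' references the adsorption equilibrium to solvent displacement. The
#' mechanism is then classified by [classify_adsorption()].
#'
#' Slope and \eqn{R^2} are invariant under a uniform rescaling of the
#' concentration units; the intercept (hence \eqn{k_{ads}} and
#' \eqn{\Delta G}) is not, so concentrations must be in mol/L for the
#' thermodynamic outputs to be meaningful.
#'
#' @param conc concentrations, mol/L (>= 3 points, all > 0).
#' @param theta coverages in (0, 1\], same length.
#' @param temperature absolute temperature, K (default 293.15, ambient).
#' @return Object of class `langmuir_fit`: list with `slope`, `intercept`
#'   (mol/L), `r2`, `k_ads` (L/mol), `dg_ads` (kJ/mol), `mechanism`,
#'   `temperature`, `n_points`. A non-positive intercept leaves `k_ads`,
#'   `dg_ads` and `mechanism` as `NA` with a warning.
#' @examples
#' conc <- c(20, 50, 100) / 1000 / 234.34   # ppm lidocaine to mol/L
#' langmuir_fit(conc, c(0.830, 0.923, 0.925))
#' @export
langmuir_fit <- function(conc, theta, temperature = 293.15) {
  stopifnot(is.numeric(conc), is.numeric(theta),
            length(conc) == length(theta), is.numeric(temperature),
            temperature > 0)
  if (length(conc) < 3L)
    stopf("Langmuir fit needs at least 3 points", class = "corrqsar_invalid_input")
  if (any(conc <= 0))
    stopf("concentrations must be > 0", class = "corrqsar_invalid_input")
  if (any(theta <= 0 | theta > 1))
    stopf("coverages must lie in (0, 1]", class = "corrqsar_invalid_input")
  fit <- stats::lm(I(conc / theta) ~ conc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # squared Pearson correlation of fitted vs observed C/theta; identical to
  # the coefficient of determination for a simple OLS fit with intercept
  r2 <- stats::cor(conc / theta, stats::fitted(fit))^2
  if (intercept > 0) {
    k_ads <- 1 / intercept
    R <- 8.314462618  # J / (mol K)
    dg_ads <- -R * temperature * log(55.5 * k_ads) / 1000
    mech <- classify_adsorption(dg_ads)
  } else {
    warning("non-positive Langmuir intercept: k_ads and dG_ads undefined",
            call. = FALSE)
    k_ads <- dg_ads <- NA_real_
    mech <- NA_character_
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 k_ads = k_ads, dg_ads = dg_ads, mechanism = mech,
                 temperature = temperature, n_points = length(conc)),
            class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("Langmuir isotherm fit (%d points, T = %.2f K)\n",
              x$n_points, x$temperature))
  cat(sprintf("  C/theta = %.4f C + %.3g   (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r2))
  if (is.finite(x$k_ads))
    cat(sprintf("  k_ads = %.4g L/mol, dG0_ads = %.2f kJ/mol (%s)\n",
                x$k_ads, x$dg_ads, x$mechanism))
  invisible(x)
}

#' Classify the adsorption mechanism from the free energy
#'
#' By convention in corrosion science the magnitude of
#' \eqn{\Delta G^0_{ads}} separates electrostatic physisorption
#' (|dG| < 20 kJ/mol) from covalent chemisorption (|dG| > 40 kJ/mol), with a
#' combined mechanism in between. Band boundaries (20 and 40 exactly) are
#' assigned to the combined class.
#'
#' @param dg_ads standard adsorption free energy, kJ/mol (vectorized,
#'   finite).
#' @return Character vector: `"physisorption"`, `"combined"` or
#'   `"chemisorption"`.
#' @examples
#' classify_adsorption(-38.39)  # combined
#' @export
classify_adsorption <- function(dg_ads) {
  stopifnot(is.numeric(dg_ads), all(is.finite(dg_ads)))
  a <- abs(dg_ads)
  ifelse(a < 20, "physisorption", ifelse(a > 40, "chemisorption", "combined"))
}
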