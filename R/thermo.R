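#' Thermodynamic context for chemiosmotic calculations
#'
#' Bundles the gas constant, absolute temperature and Faraday's constant used
#' by all proton-motive-force (PMF) calculations. The default temperature is
#' 310.15 K (37 degrees C, the growth temperature); plate-reader measurements
#' at 30 degrees C can be represented with `thermo_context(303.15)`.
#'
#' @param temperature_K Absolute temperature in Kelvin. Must be positive.
#' @param R Gas constant in J mol^-1 K^-1.
#' @param faraday Faraday's constant in C mol^-1.
#'
#' @return An object of class `thermo_context` with fields `R`, `T` and `F`.
#' @examples
#' th <- thermo_context()
#' zeta_factor(th) # about 61.5 mV per pH unit at 37 C
#' @export
thermo_context <- function(temperature_K = 310.15, R = 8.314, faraday = 96485) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    stop("`temperature_K` must be a single positive, finite number", call. = FALSE)
  }
  structure(list(R = R, T = temperature_K, F = faraday), class = "thermo_context")
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> T = %.2f K, R = %.3f J/mol/K, F = %.0f C/mol (Z = %.2f mV/pH)\n",
              x$T, x$R, x$F, zeta_factor(x)))
  invisible(x)
}

as_thermo <- function(thermo) {
  if (inherits(thermo, "thermo_context")) return(thermo)
  if (is.numeric(thermo) && length(thermo) == 1L) return(thermo_context(thermo))
  stop("`thermo` must be a thermo_context or a temperature in Kelvin", call. = FALSE)
}

#' Nernst slope in mV per pH unit
#'
#' The factor Z = ln(10) R T / F converting one pH unit of transmembrane
#' gradient into its electrochemical equivalent in millivolts. Z is strictly
#' positive and linear in temperature (about 61.5 mV at 310.15 K).
#'
#' @param thermo A [thermo_context()] (or a temperature in K).
#' @return Z in mV per pH unit.
#' @export
zeta_factor <- function(thermo = thermo_context()) {
  thermo <- as_thermo(thermo)
  log(10) * thermo$R * thermo$T / thermo$F * 1000
}

check_ph <- function(pH, what = "pH") {
  if (!is.numeric(pH) || any(!is.finite(pH)) || any(pH < 0) || any(pH > 14)) {
    stop(sprintf("`%s` must be finite and within [0, 14]", what), call. = FALSE)
  }
  invisible(pH)
}

#' Electrochemical force of the transmembrane pH gradient
#'
#' Returns the Delta-pH-associated term of the proton motive force,
#' -Z (pH_i - pH_e) in mV, with Z = ln(10) R T / F. Under the sign
#' convention used throughout (inside minus outside), an alkaline-inside
#' cell (pH_i > pH_e) contributes a negative, inward-driving force; an
#' acidified interior inverts the sign.
#'
#' @param pH_i Intracellular pH.
#' @param pH_e Extracellular pH.
#' @param thermo A [thermo_context()].
#' @return Force in mV.
#' @examples
#' ph_gradient_force(7.6, 7.0) # about -36.9 mV
#' ph_gradient_force(5.5, 7.0) # about +92.3 mV, inverted gradient
#' @export
ph_gradient_force <- function(pH_i, pH_e, thermo = thermo_context()) {
  check_ph(pH_i, "pH_i")
  check_ph(pH_e, "pH_e")
  -zeta_factor(thermo) * (pH_i - pH_e)
}

#' Nernst potential of an ion gradient
#'
#' Equilibrium potential (R T / (z F)) ln(ions_e / ions_i), in mV, for an ion
#' of charge `z` with intracellular and extracellular abundances `ions_i` and
#' `ions_e` (any common concentration unit; only the ratio matters).
#'
#' @param ions_i,ions_e Intracellular and extracellular abundances, > 0.
#' @param z Molar ion charge; a nonzero integer.
#' @param thermo A [thermo_context()].
#' @return Potential in mV.
#' @examples
#' nernst_potential(100, 10, z = 1) # about -61.5 mV at 37 C
#' @export
nernst_potential <- function(ions_i, ions_e, z, thermo = thermo_context()) {
  if (!is.numeric(ions_i) || !is.numeric(ions_e) ||
      any(!is.finite(ions_i)) || any(!is.finite(ions_e)) ||
      any(ions_i <= 0) || any(ions_e <= 0)) {
    stop("ion abundances must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(z) || any(z != round(z)) || any(z == 0)) {
    stop("`z` must be a nonzero integer", call. = FALSE)
  }
  thermo <- as_thermo(thermo)
  (thermo$R * thermo$T / (z * thermo$F)) * log(ions_e / ions_i) * 1000
}

#' Total proton motive force
#'
#' The Mitchell composition Delta-p = Delta-psi - Z Delta-pH, i.e. the
#' membrane potential plus the pH-gradient force from
#' [ph_gradient_force()]. Negative values drive protons into the cell.
#'
#' @param delta_psi Membrane potential in mV, inside minus outside.
#' @param pH_i,pH_e Intracellular and extracellular pH.
#' @param thermo A [thermo_context()].
#' @return PMF in mV.
#' @examples
#' pmf_total(-123.1, 7.6, 7.0) # about -160 mV, the normal state
#' @export
pmf_total <- function(delta_psi, pH_i, pH_e, thermo = thermo_context()) {
  if (!is.numeric(delta_psi) || any(!is.finite(delta_psi))) {
    stop("`delta_psi` must be finite", call. = FALSE)
  }
  delta_psi + ph_gradient_force(pH_i, pH_e, thermo)
}

#' Define a weak acid species
#'
#' @param name Species label, e.g. `"C8"` for octanoic acid.
#' @param pKa Acid dissociation constant, strictly inside (0, 14).
#' @param permeant_protonated Logical; `TRUE` for carboxylic acids whose
#'   neutral protonated form crosses the membrane and releases its proton
#'   inside the cell (the C8 case), `FALSE` for membrane-impermeant acids.
#' @return An object of class `acid_species`.
#' @examples
#' octanoic_acid()
#' @export
acid_species <- function(name, pKa, permeant_protonated = TRUE) {
  if (!is.numeric(pKa) || length(pKa) != 1L || !is.finite(pKa) ||
      pKa <= 0 || pKa >= 14) {
    stop("`pKa` must lie strictly inside (0, 14)", call. = FALSE)
  }
  structure(list(name = as.character(name), pKa = pKa,
                 permeant_protonated = isTRUE(permeant_protonated)),
            class = "acid_species")
}

#' @rdname acid_species
#' @export
octanoic_acid <- function() acid_species("C8", pKa = 4.89, permeant_protonated = TRUE)

#' Protonated fraction of a weak acid (Henderson-Hasselbalch)
#'
#' Fraction of the acid in its neutral, protonated form at a given pH:
#' 1 / (1 + 10^(pH - pKa)). For octanoic acid (pKa 4.89) at media pH 7.0
#' this is about 0.8%, i.e. the anion dominates in the bulk.
#'
#' @param pH Ambient pH (vectorised).
#' @param acid An [acid_species()].
#' @return Fraction in (0, 1).
#' @export
protonated_fraction <- function(pH, acid) {
  check_ph(pH)
  stopifnot(inherits(acid, "acid_species"))
  1 / (1 + 10^(pH - acid$pKa))
}

#' pH of equimolar speciation
#'
#' Numerically inverts [protonated_fraction()] to find the pH at which the
#' protonated and unprotonated forms are equimolar. By construction this is
#' the pKa; the inversion (rather than an echo of the stored constant) keeps
#' the operation honest about the speciation model it inverts.
#'
#' @param acid An [acid_species()].
#' @return The pH at which the protonated fraction equals one half.
#' @examples
#' equimolar_pH(octanoic_acid()) # 4.89
#' @export
equimolar_pH <- function(acid) {
  stopifnot(inherits(acid, "acid_species"))
  stats::uniroot(function(p) protonated_fraction(p, acid) - 0.5,
                 interval = c(1e-6, 14 - 1e-6), tol = 1e-12)$root
}
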