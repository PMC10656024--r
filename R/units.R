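# Unit system: time in weeks, concentrations in molar, volumes in litres.
# Literature binding kinetics are printed per second; transport clearances
# per week. Everything is converted to the weekly basis on entry.

#' Unit conversion constants
#'
#' `seconds_per_week()` is the factor applied to per-second binding kinetics
#' to express them on the model's weekly time base. `igg_molecular_weight()`
#' is the molecular weight used for all IgG mass/molar conversions
#' (150 kDa, the standard value for monomeric IgG of any subclass).
#'
#' @return A single number.
#' @export
seconds_per_week <- function() 604800

#' @rdname seconds_per_week
#' @export
igg_molecular_weight <- function() 150000  # g/mol

#' Convert IgG concentrations between mg/ml and molar
#'
#' Mass concentrations (mg/ml, i.e. g/L) are converted to molar using a
#' 150 kDa molecular weight; `igg_molar_to_mass()` is the exact inverse.
#'
#' @param mg_ml,molar Numeric vector of concentrations.
#' @return Numeric vector of converted concentrations.
#' @examples
#' igg_mass_to_molar(1)          # 6.67e-6 M
#' igg_molar_to_mass(igg_mass_to_molar(0.33))
#' @export
igg_mass_to_molar <- function(mg_ml) {
  if (any(mg_ml < 0, na.rm = TRUE)) {
    stop("IgG mass concentration must be non-negative", call. = FALSE)
  }
  mg_ml / igg_molecular_weight()
}

#' @rdname igg_mass_to_molar
#' @export
igg_molar_to_mass <- function(molar) {
  if (any(molar < 0, na.rm = TRUE)) {
    stop("IgG molar concentration must be non-negative", call. = FALSE)
  }
  molar * igg_molecular_weight()
}

#' Derive binding rate constants from an equilibrium dissociation constant
#'
#' Surface plasmon resonance studies report the equilibrium dissociation
#' constant K_D and a (subclass-independent) dissociation rate; the
#' association rate follows from k_on = k_off / K_D. Rates are returned on
#' the weekly time base used internally, alongside the per-second k_on for
#' comparison with published tables.
#'
#' @param K_D Dissociation constant (molar).
#' @param k_off_per_s Dissociation rate (1/s); default 0.15/s.
#' @return A tibble with columns `K_D`, `k_on_per_M_s`, `k_on_per_M_wk`,
#'   `k_off_per_wk`.
#' @examples
#' derive_kinetic_rates(1.25e-8)  # k_on = 1.2e7 /M/s
#' @export
derive_kinetic_rates <- function(K_D, k_off_per_s = 0.15) {
  if (any(K_D <= 0) || any(k_off_per_s <= 0)) {
    stop("K_D and k_off must be strictly positive", call. = FALSE)
  }
  tibble(
    K_D = K_D,
    k_on_per_M_s = k_off_per_s / K_D,
    k_on_per_M_wk = k_off_per_s / K_D * seconds_per_week(),
    k_off_per_wk = k_off_per_s * seconds_per_week()
  )
}

#' Fetal IgG clearance implied by a half-life
#'
#' Converts an intrinsic fetal IgG half-life into the volumetric clearance
#' (L/week) used by the fetal compartment, where the concentration decays at
#' rate (clearance / V_F). The placental parameter table carries a fetal
#' decay clearance of 0.02 L/week, while the immunization model assumes a
#' 31-day fetal half-life; both are representable here and the vaccinated
#' simulations use the 31-day value for the vaccine-induced species by
#' default.
#'
#' @param halflife_days Half-life in days.
#' @param V_F Fetal blood volume (L).
#' @return Clearance in L/week.
#' @examples
#' fetal_decay_clearance(31, 0.2625)  # ~0.041 L/week
#' @export
fetal_decay_clearance <- function(halflife_days, V_F) {
  if (halflife_days <= 0 || V_F <= 0) {
    stop("half-life and volume must be positive", call. = FALSE)
  }
  log(2) / (halflife_days / 7) * V_F
}
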