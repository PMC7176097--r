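# Stoichiometric and physical constants shared across modules.
# Molar masses: C taken as 12 g/mol in the O2 and GWP mass ratios (12/32,
# 44/12, 16/12); the ideal-gas CH4 readout uses 12.011 g/mol.

O2_MOLAR_MASS <- 32 # g/mol
C_MOLAR_MASS <- 12.011 # g/mol, ideal-gas conversion
GAS_CONSTANT_L_ATM <- 0.0820574 # L atm mol-1 K-1

#' Convert an oxygen mass rate to a carbon mass rate
#'
#' Applies the 1 mol O2 : 1 mol C stoichiometry of oxygenic photosynthesis
#' and aerobic respiration, i.e. multiplies by 12/32. Photosynthetic and
#' respiratory quotients other than 1 are applied by the caller (see
#' [oxygen_rates()]): carbon fixed = O2 released / PQ, carbon respired =
#' O2 consumed x RQ.
#'
#' @param x Numeric O2 mass rate(s), any shape (mg O2 per litre, per m2, ...).
#' @return The same-shaped rate in carbon mass units (mg C ...).
#' @examples
#' o2_to_carbon(32) # 12 mg C
#' o2_to_carbon(0.3) # 0.1125
#' @export
o2_to_carbon <- function(x) {
  x * (12 / 32)
}

#' Global-warming-potential constants
#'
#' Mass-based CO2-equivalent accounting over a 100-year horizon: one unit mass
#' of CH4 gas counts as `ch4_co2_factor` (default 28, IPCC AR5) unit masses of
#' CO2. Carbon fluxes are converted to gas masses with the molar ratios
#' CO2/C = 44/12 and CH4/C = 16/12.
#'
#' @param ch4_co2_factor CO2-equivalent multiplier for a unit mass of CH4.
#' @return A list with `ch4_co2_factor`, `co2_per_c` (44/12) and
#'   `ch4_per_c` (16/12).
#' @export
gwp_constants <- function(ch4_co2_factor = 28) {
  stopifnot(is.numeric(ch4_co2_factor), ch4_co2_factor > 0)
  list(
    ch4_co2_factor = ch4_co2_factor,
    co2_per_c = 44 / 12,
    ch4_per_c = 16 / 12
  )
}

#' Vegetation carbon coefficients
#'
#' Mass fraction of carbon in harvested above-ground dry weight, by plant
#' type: 0.45 for helophytes (emergent reeds, mainly *Phragmites australis*)
#' and 0.255 for halophytes (*Salicornia* spp., an average over reported
#' tissue C contents).
#'
#' @param helophyte,halophyte C mass fractions in (0, 1).
#' @return Named list with elements `helophyte` and `halophyte`.
#' @export
carbon_coefficients <- function(helophyte = 0.45, halophyte = 0.255) {
  stopifnot(
    helophyte > 0, helophyte < 1,
    halophyte > 0, halophyte < 1
  )
  list(helophyte = helophyte, halophyte = halophyte)
}
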