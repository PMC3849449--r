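# Fluid, species, and reaction parameter containers with the unit
# conversions between laboratory units (uM, um^2, Darcy, m^2/s) and the
# internal system (mole fraction, cm^2, cm^2/min).

#' Blood (carrier fluid) properties
#'
#' @param molar_density Molar density rho, mmol/cm^3 (default 55.4, water).
#' @param viscosity Dynamic viscosity, mPa s (default 3.5, whole blood).
#' @param fluid_compressibility Fluid compressibility, kPa^-1
#'   (default 5e-7, water).
#' @param structural_compressibility Tissue structural compressibility,
#'   kPa^-1 (default 1.8e-5, soft tissue).
#' @return An object of class `fluid_properties`; the effective
#'   compressibility used in transient flow is
#'   `effective_compressibility = fluid + structural`.
#' @export
fluid_properties <- function(molar_density = 55.4,
                             viscosity = 3.5,
                             fluid_compressibility = 5e-7,
                             structural_compressibility = 1.8e-5) {
  for (nm in c("molar_density", "viscosity", "fluid_compressibility",
               "structural_compressibility")) {
    v <- get(nm)
    .check_scalar(v, nm)
    if (v <= 0) .stopf("'%s' must be > 0", nm)
  }
  structure(list(
    molar_density = molar_density,
    viscosity = viscosity,
    fluid_compressibility = fluid_compressibility,
    structural_compressibility = structural_compressibility,
    effective_compressibility = fluid_compressibility +
      structural_compressibility
  ), class = "fluid_properties")
}

#' Transported species definition
#'
#' Effective diffusion coefficients are the Table-style "effective" values:
#' they already fold in tortuosity, so no additional porosity factor is
#' applied when assembling diffusive exchange.
#'
#' @param name Species identifier, e.g. `"PAC"` or `"PACOH"`.
#' @param molecular_weight g/mol (854 for paclitaxel).
#' @param diffusion_sinusoid Effective diffusivity in sinusoid cells,
#'   cm^2/min (default 2.5e-4).
#' @param diffusion_tissue Effective diffusivity in tissue cells, cm^2/min
#'   (default 2.5e-5, one order of magnitude below the sinusoid value).
#' @return An object of class `species_def`.
#' @export
species_def <- function(name,
                        molecular_weight = 854,
                        diffusion_sinusoid = 2.5e-4,
                        diffusion_tissue = 2.5e-5) {
  if (!is.character(name) || length(name) != 1L) .stopf("name must be a string")
  if (diffusion_sinusoid < 0 || diffusion_tissue < 0)
    .stopf("diffusion coefficients must be >= 0")
  structure(list(name = name,
                 molecular_weight = molecular_weight,
                 diffusion_sinusoid = diffusion_sinusoid,
                 diffusion_tissue = diffusion_tissue),
            class = "species_def")
}

#' Default drug/metabolite species pair
#'
#' Paclitaxel (PAC) and its Phase-I metabolite 6-hydroxypaclitaxel (PACOH);
#' the metabolite inherits the drug's diffusion coefficients (the two
#' molecules are of very similar size).
#'
#' @param pac,pacoh Optional [species_def()] overrides.
#' @return A named list of two `species_def` objects.
#' @export
species_set <- function(pac = species_def("PAC"),
                        pacoh = species_def("PACOH")) {
  list(PAC = pac, PACOH = pacoh)
}

#' Michaelis-Menten elimination parameters
#'
#' The saturable rate used inside tissue cells is
#' `v_max_eff * x / (K_m + x)` with
#' `v_max_eff = v_max * rate_multiplier / scale_factor`; the scale factor
#' maps the microsome-derived bulk rate onto the model tissue cells so that
#' the linear-regime half-life equals `scale_factor * ln 2 / (v_max/K_m)`.
#'
#' @param v_max Maximum rate, mole-fraction/min (default 1.08e-9).
#' @param K_m Half-saturation constant, mole fraction (default 1.8e-7).
#' @param scale_factor Tissue-to-bulk volume scale factor SF
#'   (default 0.76e-6).
#' @param rate_multiplier Dimensionless sensitivity multiplier on `v_max`
#'   (default 1; sensitivity presets use 1e-2 and 1e-3).
#' @return An object of class `reaction_spec`.
#' @seealso [effective_rate()], [michaelis_menten_rate()]
#' @export
reaction_spec <- function(v_max = 1.08e-9,
                          K_m = 1.8e-7,
                          scale_factor = 0.76e-6,
                          rate_multiplier = 1) {
  for (nm in c("v_max", "K_m", "scale_factor", "rate_multiplier")) {
    v <- get(nm)
    .check_scalar(v, nm)
    if (v <= 0) .stopf("'%s' must be > 0", nm)
  }
  structure(list(v_max = v_max, K_m = K_m, scale_factor = scale_factor,
                 rate_multiplier = rate_multiplier),
            class = "reaction_spec")
}

#' Convert molar concentration to mole fraction
#'
#' `x = C / rho` for a dilute solute in a carrier of molar density `rho`:
#' 10 uM in blood (rho = 55.4 mmol/cm^3 = 55.4 mol/L) is 1.8e-7 mole
#' fraction. Works elementwise, and equally for rate units
#' (uM/min -> mole-fraction/min).
#'
#' @param concentration Concentration in uM (umol/L), >= 0.
#' @param fluid A [fluid_properties()].
#' @return Mole fraction (dimensionless).
#' @seealso [fraction_to_molar()]
#' @export
molar_to_fraction <- function(concentration, fluid = fluid_properties()) {
  if (any(concentration < 0)) .stopf("concentration must be >= 0")
  # rho in mmol/cm^3 equals mol/L; uM = 1e-6 mol/L
  concentration * 1e-6 / fluid$molar_density
}

#' Convert mole fraction back to molar concentration (uM)
#'
#' Inverse of [molar_to_fraction()]; the round trip is an identity to
#' machine precision.
#'
#' @param fraction Mole fraction, >= 0.
#' @param fluid A [fluid_properties()].
#' @return Concentration in uM.
#' @export
fraction_to_molar <- function(fraction, fluid = fluid_properties()) {
  if (any(fraction < 0)) .stopf("fraction must be >= 0")
  fraction * fluid$molar_density / 1e-6
}

#' Molecular-weight rescaling of a reference diffusivity
#'
#' Stokes-Einstein-style scaling: the diffusivity of a solute is estimated
#' from a reference solute by the cube root (default exponent 0.33) of the
#' molecular-weight ratio,
#' `D_target = D_ref * (MW_ref / MW_target)^exponent`. With the glucose
#' reference `7.1e-10 m^2/s` and paclitaxel (854 g/mol) this gives
#' `4.2e-10 m^2/s`.
#'
#' @param reference_D Reference diffusivity (any unit; result in the same).
#' @param reference_MW,target_MW Molecular weights, g/mol.
#' @param exponent Scaling exponent (default 0.33).
#' @return Rescaled diffusivity.
#' @export
rescale_diffusion <- function(reference_D, reference_MW, target_MW,
                              exponent = 0.33) {
  for (nm in c("reference_D", "reference_MW", "target_MW")) {
    v <- get(nm)
    .check_scalar(v, nm)
    if (v <= 0) .stopf("'%s' must be > 0", nm)
  }
  reference_D * (reference_MW / target_MW)^exponent
}

#' Effective first-order elimination rate and half-life
#'
#' In the linear regime (`x << K_m`) the Michaelis-Menten law reduces to a
#' first-order decay at `k = v_max / K_m`; applied to the model tissue
#' cells through the scale factor and multiplier this gives a half-life
#' `half_life = scale_factor * ln 2 / (k * rate_multiplier)` and
#' `k_eff = ln 2 / half_life`.
#'
#' @param reaction A [reaction_spec()].
#' @return List with `k_eff` (min^-1) and `half_life` (min).
#' @examples
#' effective_rate(reaction_spec())$half_life # ~8.8e-5 min
#' @export
effective_rate <- function(reaction) {
  if (!inherits(reaction, "reaction_spec")) .stopf("not a reaction_spec")
  k <- reaction$v_max / reaction$K_m
  half_life <- reaction$scale_factor * log(2) / (k * reaction$rate_multiplier)
  list(k_eff = log(2) / half_life, half_life = half_life)
}
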