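# Process-timescale analysis: pressure relaxation, local diffusion,
# reaction half-life, and convective breakthrough estimates. These order
# the regimes the transport scenarios explore.

#' Pressure diffusivity of a compressible porous medium
#'
#' `D_pres = K / (phi * mu * C_eff)`: the diffusivity with which pressure
#' disturbances relax through a medium of permeability `K`, porosity
#' `phi`, fluid viscosity `mu` and effective compressibility `C_eff`.
#'
#' @param K Permeability, cm^2.
#' @param porosity Porosity (0, 1].
#' @param viscosity Viscosity, mPa s.
#' @param C_eff Effective compressibility, kPa^-1.
#' @return Pressure diffusivity, cm^2/min.
#' @examples
#' pressure_diffusivity(1.125e-8, pi / 4, 3.5, 1.85e-5) # ~1.3e4 cm^2/min
#' @export
pressure_diffusivity <- function(K, porosity, viscosity, C_eff) {
  for (nm in c("K", "porosity", "viscosity", "C_eff")) {
    v <- get(nm)
    .check_scalar(v, nm)
    if (v <= 0) .stopf("'%s' must be > 0", nm)
  }
  K / (porosity * .mu_internal(viscosity) * C_eff)
}

#' Characteristic diffusion time over a distance
#'
#' `T = d^2 / D`: the time for a diffusive process of diffusivity `D` to
#' act over distance `d`.
#'
#' @param distance Characteristic distance, cm.
#' @param diffusivity Diffusivity, cm^2/min.
#' @return Time, min.
#' @export
characteristic_time <- function(distance, diffusivity) {
  .check_scalar(distance, "distance")
  .check_scalar(diffusivity, "diffusivity")
  if (distance <= 0) .stopf("distance must be > 0")
  if (diffusivity <= 0) .stopf("diffusivity must be > 0")
  distance^2 / diffusivity
}

#' Convective breakthrough time estimates
#'
#' Pore volume divided by volumetric rate, under the two limiting
#' accessibility assumptions: only the sinusoid network is sampled, or the
#' whole lobule (sinusoid + tissue) pore space is sampled. Observed
#' breakthrough curves should lie between the two.
#'
#' @param pore_volumes A [pore_volumes()] list (fields `sinusoid`, `total`).
#' @param inlet_rate Steady volumetric inflow, cm^3/min (> 0).
#' @return List with `sinusoid` and `total` breakthrough times, min.
#' @export
breakthrough_estimates <- function(pore_volumes, inlet_rate) {
  .check_scalar(inlet_rate, "inlet_rate")
  if (inlet_rate <= 0) .stopf("inlet_rate must be > 0")
  list(sinusoid = pore_volumes$sinusoid / inlet_rate,
       total = pore_volumes$total / inlet_rate)
}

#' Build the process-timescale report
#'
#' Assembles pressure, diffusion, reaction, and breakthrough timescales
#' for a configured lobule into one table. The pressure relaxation entry is
#' the analytic `d^2 / D_pres` estimate; when a
#' [solve_transient_pressure()] result is supplied, its measured 99%%
#' inflow-establishment time is reported alongside (the two differ by the
#' geometry factors the analytic estimate ignores).
#'
#' @param lattice A `lobule_lattice`.
#' @param fluid A [fluid_properties()].
#' @param species A [species_set()].
#' @param reaction A [reaction_spec()].
#' @param flow A solved [solve_steady_pressure()] for the same lattice.
#' @param pressure_distance Characteristic distance for pressure
#'   relaxation, cm (default 0.15, the full lobule size).
#' @param diffusion_distance Characteristic distance for local
#'   concentration smoothing, cm (default 1e-3, ~ one hepatocyte radius).
#' @param transient Optional [solve_transient_pressure()] result.
#' @return An object of class `timescale_report` (a list of named numeric
#'   entries; see [as.data.frame.timescale_report()]).
#' @export
build_timescale_report <- function(lattice, fluid, species, reaction, flow,
                                   pressure_distance = 0.15,
                                   diffusion_distance = 1e-3,
                                   transient = NULL) {
  spec <- lattice$spec
  D_pres <- pressure_diffusivity(spec$sinusoid_permeability,
                                 spec$sinusoid_porosity,
                                 fluid$viscosity,
                                 fluid$effective_compressibility)
  T_pres <- characteristic_time(pressure_distance, D_pres)
  T_diff_sin <- characteristic_time(diffusion_distance,
                                    species$PAC$diffusion_sinusoid)
  T_diff_tis <- characteristic_time(diffusion_distance,
                                    species$PAC$diffusion_tissue)
  T_reac <- effective_rate(reaction)$half_life
  pv <- pore_volumes(lattice)
  bt <- breakthrough_estimates(pv, flow$inlet_rate)
  rep <- list(
    pressure_diffusivity = D_pres,
    pressure_relaxation = T_pres,
    pressure_relaxation_simulated = if (!is.null(transient)) transient$t99
                                    else NA_real_,
    diffusion_time_sinusoid = T_diff_sin,
    diffusion_time_tissue = T_diff_tis,
    reaction_half_life = T_reac,
    breakthrough_sinusoid = bt$sinusoid,
    breakthrough_total = bt$total,
    characteristic_distance_pressure = pressure_distance,
    characteristic_distance_diffusion = diffusion_distance,
    inlet_rate = flow$inlet_rate
  )
  structure(rep, class = "timescale_report")
}

#' Tabulate a timescale report
#'
#' @param x A `timescale_report`.
#' @param row.names,optional,... Ignored (standard generic arguments).
#' @return A two-column data.frame (`process`, `time_min`); diffusivity,
#'   distance, and rate entries are listed under their own units.
#' @export
as.data.frame.timescale_report <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(
    process = c("pressure_diffusivity_cm2_per_min",
                "pressure_relaxation_min",
                "pressure_relaxation_simulated_min",
                "diffusion_time_sinusoid_min",
                "diffusion_time_tissue_min",
                "reaction_half_life_min",
                "breakthrough_sinusoid_min",
                "breakthrough_total_min",
                "characteristic_distance_pressure_cm",
                "characteristic_distance_diffusion_cm",
                "inlet_rate_cm3_per_min"),
    value = c(x$pressure_diffusivity, x$pressure_relaxation,
              x$pressure_relaxation_simulated,
              x$diffusion_time_sinusoid, x$diffusion_time_tissue,
              x$reaction_half_life, x$breakthrough_sinusoid,
              x$breakthrough_total, x$characteristic_distance_pressure,
              x$characteristic_distance_diffusion, x$inlet_rate)
  )
}

#' @export
print.timescale_report <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Lobule process timescales\n")
  for (r in seq_len(nrow(df)))
    cat(sprintf("  %-38s %12.4e\n", df$process[r], df$value[r]))
  invisible(x)
}
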