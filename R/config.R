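# Configuration loading, validation, and scenario orchestration. One
# schema (YAML or JSON) whose defaults reproduce the base case exactly;
# presets override individual scenario switches. The tool is fully
# deterministic: there is no random number generation anywhere.

#' Default run configuration
#'
#' The fully expanded configuration list whose values are the base-case
#' lobule: 51 x 51 lattice, blood fluid properties, paclitaxel/metabolite
#' species, Michaelis-Menten elimination parameters, corner wells at
#' 103 / 101.8 kPa, and the non-reactive diffusion-on scenario.
#'
#' @return A nested named list with blocks `lattice`, `fluid`, `species`,
#'   `reaction`, `wells`, `scenario`, `output`. Field names carry units.
#' @export
default_config <- function() {
  list(
    lattice = list(
      n_side = 51L,
      sinusoid_width_cm = 0.0006,
      boundary_sinusoid_width_cm = 0.0003,
      tissue_width_cm = 0.0024,
      depth_cm = 0.0003,
      sinusoid_porosity = pi / 4,
      sinusoid_permeability_cm2 = tube_permeability(3) * lobule_units$um2_cm2,
      tissue_porosity = 0.2382,
      tissue_permeability_cm2 = 7.45e-2 * lobule_units$darcy_cm2,
      hepatocyte_diameter_cm = 0.0024
    ),
    fluid = list(
      molar_density_mmol_per_cm3 = 55.4,
      viscosity_mPa_s = 3.5,
      fluid_compressibility_per_kPa = 5e-7,
      structural_compressibility_per_kPa = 1.8e-5
    ),
    species = list(
      pac = list(molecular_weight_g_mol = 854,
                 diffusion_sinusoid_cm2_per_min = 2.5e-4,
                 diffusion_tissue_cm2_per_min = 2.5e-5),
      pacoh = list(molecular_weight_g_mol = 870,
                   diffusion_sinusoid_cm2_per_min = 2.5e-4,
                   diffusion_tissue_cm2_per_min = 2.5e-5)
    ),
    reaction = list(
      vmax_molfrac_per_min = 1.08e-9,
      km_molfrac = 1.8e-7,
      scale_factor = 0.76e-6,
      rate_multiplier = 1
    ),
    wells = list(
      injector_cell = c(1L, 1L),
      injector_pressure_kPa = 103,
      producer_cell = c(51L, 51L),
      producer_pressure_kPa = 101.8
    ),
    scenario = list(
      diffusion_enabled = TRUE,
      reaction_enabled = FALSE,
      injected_pac_molfrac = 1.8e-8,
      end_time_min = 1.0,
      snapshot_times_min = c(0.01, 0.14, 0.50),
      transport_dt_min = 1e-3
    ),
    output = list(
      directory = "lobuleflow_out",
      write_vtk = TRUE,
      write_csv = TRUE
    )
  )
}

# recursive merge of user values onto defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    .stopf("unknown configuration key(s): %s",
           paste(paste(c(path, ""), collapse = "."),
                 unknown, sep = "", collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]],
                                      c(path, nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  la <- cfg$lattice
  chk(la$n_side >= 3 && la$n_side %% 2 == 1,
      "lattice.n_side must be an odd integer >= 3")
  for (nm in c("sinusoid_width_cm", "boundary_sinusoid_width_cm",
               "tissue_width_cm", "depth_cm"))
    chk(la[[nm]] > 0, sprintf("lattice.%s must be > 0", nm))
  chk(la$sinusoid_porosity > 0 && la$sinusoid_porosity <= 1,
      "lattice.sinusoid_porosity must lie in (0, 1]")
  chk(la$tissue_porosity > 0 && la$tissue_porosity <= 1,
      "lattice.tissue_porosity must lie in (0, 1]")
  chk(la$sinusoid_permeability_cm2 >= 0 && la$tissue_permeability_cm2 >= 0,
      "lattice permeabilities must be >= 0")
  chk(cfg$wells$injector_pressure_kPa > cfg$wells$producer_pressure_kPa,
      "wells.injector_pressure_kPa must exceed wells.producer_pressure_kPa")
  for (wnm in c("injector_cell", "producer_cell")) {
    wc <- cfg$wells[[wnm]]
    chk(length(wc) == 2 && all(wc >= 1) && all(wc <= la$n_side),
        sprintf("wells.%s must be a pair of indices within the lattice", wnm))
  }
  sc <- cfg$scenario
  chk(sc$end_time_min > 0, "scenario.end_time_min must be > 0")
  chk(sc$injected_pac_molfrac >= 0 && sc$injected_pac_molfrac <= 1,
      "scenario.injected_pac_molfrac must be a mole fraction")
  # snapshot times beyond end_time_min are clipped downstream, so a short
  # run composes with the default snapshot list
  chk(all(sc$snapshot_times_min >= 0),
      "scenario.snapshot_times_min must be >= 0")
  chk(sc$transport_dt_min > 0, "scenario.transport_dt_min must be > 0")
  chk(cfg$reaction$rate_multiplier > 0,
      "reaction.rate_multiplier must be > 0")
  if (length(problems))
    .stopf("invalid configuration:\n  %s", paste(problems, collapse = "\n  "))
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, overlays it on the full
#' defaults ([default_config()]), rejects unknown keys by name, and
#' validates every block. An empty file (or `NULL` path) yields the
#' base-case defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL`.
#' @return A validated, fully defaulted configuration list of class
#'   `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) .stopf("configuration file not found: %s", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  cfg <- .merge_config(default_config(), user)
  cfg <- .validate_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

#' Instantiate model objects from a configuration
#'
#' @param cfg A [load_config()] / [default_config()] configuration.
#' @return List with `lattice`, `fluid`, `species`, `reaction`, `wells`,
#'   `scenario` model objects.
#' @export
config_objects <- function(cfg) {
  la <- cfg$lattice
  spec <- lattice_spec(
    n_side = la$n_side,
    sinusoid_width = la$sinusoid_width_cm,
    boundary_sinusoid_width = la$boundary_sinusoid_width_cm,
    tissue_width = la$tissue_width_cm,
    depth = la$depth_cm,
    sinusoid_porosity = la$sinusoid_porosity,
    sinusoid_permeability = la$sinusoid_permeability_cm2,
    tissue_porosity = la$tissue_porosity,
    tissue_permeability = la$tissue_permeability_cm2,
    hepatocyte_diameter = la$hepatocyte_diameter_cm,
    inlet_cell = cfg$wells$injector_cell,
    outlet_cell = cfg$wells$producer_cell
  )
  fl <- cfg$fluid
  fluid <- fluid_properties(
    molar_density = fl$molar_density_mmol_per_cm3,
    viscosity = fl$viscosity_mPa_s,
    fluid_compressibility = fl$fluid_compressibility_per_kPa,
    structural_compressibility = fl$structural_compressibility_per_kPa
  )
  sp <- cfg$species
  species <- species_set(
    pac = species_def("PAC",
                      molecular_weight = sp$pac$molecular_weight_g_mol,
                      diffusion_sinusoid = sp$pac$diffusion_sinusoid_cm2_per_min,
                      diffusion_tissue = sp$pac$diffusion_tissue_cm2_per_min),
    pacoh = species_def("PACOH",
                        molecular_weight = sp$pacoh$molecular_weight_g_mol,
                        diffusion_sinusoid = sp$pacoh$diffusion_sinusoid_cm2_per_min,
                        diffusion_tissue = sp$pacoh$diffusion_tissue_cm2_per_min)
  )
  re <- cfg$reaction
  reaction <- reaction_spec(
    v_max = re$vmax_molfrac_per_min,
    K_m = re$km_molfrac,
    scale_factor = re$scale_factor,
    rate_multiplier = re$rate_multiplier
  )
  we <- cfg$wells
  wells <- boundary_wells(
    injector_cell = we$injector_cell,
    injector_pressure = we$injector_pressure_kPa,
    producer_cell = we$producer_cell,
    producer_pressure = we$producer_pressure_kPa,
    injector_composition = c(PAC = cfg$scenario$injected_pac_molfrac,
                             PACOH = 0)
  )
  sc <- cfg$scenario
  scenario <- scenario_config(
    diffusion_enabled = sc$diffusion_enabled,
    reaction_enabled = sc$reaction_enabled,
    rate_multiplier = re$rate_multiplier,
    injected_pac = sc$injected_pac_molfrac,
    end_time = sc$end_time_min,
    snapshot_times = sc$snapshot_times_min,
    dt = sc$transport_dt_min
  )
  list(lattice = build_lattice(spec), fluid = fluid, species = species,
       reaction = reaction, wells = wells, scenario = scenario)
}

#' Named scenario presets
#'
#' Configuration overrides for the studied scenarios: the non-reactive
#' tracer with and without diffusion, the base-case reactive runs, the
#' 100x and 1000x reduced-metabolism sensitivities, and the injected
#' concentration sweep (run without diffusion; three injection levels
#' spanning the linear to saturated Michaelis-Menten regimes).
#'
#' @return Named list of configuration override lists; sweep presets carry
#'   an `injection_levels` attribute.
#' @export
scenario_presets <- function() {
  presets <- list(
    base_nonreactive = list(scenario = list(diffusion_enabled = TRUE,
                                            reaction_enabled = FALSE)),
    base_nonreactive_nodiff = list(scenario = list(diffusion_enabled = FALSE,
                                                   reaction_enabled = FALSE)),
    base_reactive = list(scenario = list(diffusion_enabled = TRUE,
                                         reaction_enabled = TRUE)),
    base_reactive_nodiff = list(scenario = list(diffusion_enabled = FALSE,
                                                reaction_enabled = TRUE)),
    reactive_100x_reduced = list(scenario = list(diffusion_enabled = TRUE,
                                                 reaction_enabled = TRUE),
                                 reaction = list(rate_multiplier = 1e-2)),
    reactive_1000x_reduced = list(scenario = list(diffusion_enabled = TRUE,
                                                  reaction_enabled = TRUE),
                                  reaction = list(rate_multiplier = 1e-3)),
    concentration_sweep = list(scenario = list(diffusion_enabled = FALSE,
                                               reaction_enabled = TRUE))
  )
  attr(presets$concentration_sweep, "injection_levels") <-
    c(1.8e-8, 1.8e-7, 1.8e-6)
  presets
}

#' Run a named scenario preset
#'
#' Resolves the preset overrides (plus any user overrides) onto the
#' defaults, runs the steady flow solve, the transport scenario, and the
#' timescale report, and writes all outputs. The concentration-sweep
#' preset runs its three injection levels into subdirectories. Repeated
#' runs of the same preset produce identical outputs.
#'
#' @param name Preset name (see [scenario_presets()]).
#' @param overrides Optional configuration override list (same schema).
#' @param out_dir Output directory.
#' @param config Optional base configuration (default [default_config()]).
#' @return The summary list (or list of summaries for the sweep),
#'   invisibly; outputs are written under `out_dir`.
#' @export
run_preset <- function(name, overrides = list(),
                       out_dir = file.path(tempdir(), name),
                       config = default_config()) {
  presets <- scenario_presets()
  if (!name %in% names(presets))
    .stopf("unknown preset '%s'; available: %s", name,
           paste(names(presets), collapse = ", "))
  cfg <- .merge_config(config, presets[[name]])
  cfg <- .merge_config(cfg, overrides)
  cfg <- .validate_config(cfg)

  levels <- attr(presets[[name]], "injection_levels")
  if (!is.null(levels)) {
    summaries <- lapply(levels, function(lv) {
      cfg_lv <- cfg
      cfg_lv$scenario$injected_pac_molfrac <- lv
      sub <- file.path(out_dir, sprintf("inj%.2e", lv))
      .run_resolved(cfg_lv, sub)
    })
    names(summaries) <- sprintf("inj%.2e", levels)
    return(invisible(summaries))
  }
  invisible(.run_resolved(cfg, out_dir))
}

.run_resolved <- function(cfg, out_dir) {
  obj <- config_objects(cfg)
  flow <- solve_steady_pressure(obj$lattice, obj$fluid, obj$wells)
  result <- run_scenario(obj$lattice, obj$fluid, obj$wells, obj$species,
                         obj$reaction, obj$scenario, flow = flow)
  report <- build_timescale_report(obj$lattice, obj$fluid, obj$species,
                                   obj$reaction, flow)
  write_outputs(result, report, out_dir, config = cfg, pressure = flow)
}
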