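# File output: legacy-ASCII VTK rectilinear grids, CSV tables, JSON
# summaries. All output is plain text and deterministic.

#' Write cell data on the lattice as a legacy-ASCII VTK rectilinear grid
#'
#' Emits a `DATASET RECTILINEAR_GRID` file with the lattice's cell-edge
#' coordinates and one `CELL_DATA` scalar array per element of
#' `cell_data`. Arrays are written in VTK cell order (x varying fastest),
#' which matches the column-major storage of the n x n property matrices.
#'
#' @param path Output file path.
#' @param lattice A `lobule_lattice`.
#' @param cell_data Named list of n x n numeric matrices.
#' @param title Dataset title line.
#' @return `path`, invisibly.
#' @export
write_vtk_rectilinear <- function(path, lattice, cell_data,
                                  title = "lobuleflow field") {
  n <- lattice$n
  edges <- c(0, cumsum(lattice$widths))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) paste(formatC(x, format = "g", digits = 9), collapse = " ")
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 2", n + 1L, n + 1L),
               sprintf("X_COORDINATES %d double", n + 1L), fmt(edges),
               sprintf("Y_COORDINATES %d double", n + 1L), fmt(edges),
               "Z_COORDINATES 2 double", fmt(c(0, lattice$depth)),
               sprintf("CELL_DATA %d", n * n)), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(formatC(as.vector(cell_data[[nm]]), format = "g", digits = 9),
               con)
  }
  invisible(path)
}

#' Export the lattice as VTK and CSV
#'
#' Writes `lattice.vtk` (cell arrays `porosity`, `permeability_cm2`,
#' `cell_type` with 0 = sinusoid, 1 = tissue) and `lattice.csv` (the
#' [as.data.frame.lobule_lattice()] table) into a directory.
#'
#' @param lattice A `lobule_lattice`.
#' @param directory Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
export_lattice <- function(lattice, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_vtk_rectilinear(file.path(directory, "lattice.vtk"), lattice,
                        list(porosity = lattice$porosity,
                             permeability_cm2 = lattice$permeability,
                             cell_type = lattice$is_tissue * 1),
                        title = "lobule lattice properties")
  utils::write.csv(as.data.frame(lattice),
                   file.path(directory, "lattice.csv"), row.names = FALSE)
  invisible(directory)
}

# thin an effluent table to at most max_rows evenly spaced rows
.thin_rows <- function(df, max_rows = 2000L) {
  if (nrow(df) <= max_rows) return(df)
  df[unique(round(seq(1L, nrow(df), length.out = max_rows))), , drop = FALSE]
}

#' Write all outputs of a completed scenario run
#'
#' Writes the effluent CSV (thinned to at most 2000 rows), per-snapshot
#' VTK fields (`x_PAC`, `x_PACOH` plus their log10), the timescale report
#' (CSV and JSON), a machine-readable `summary.json`, and the fully
#' resolved configuration used for the run.
#'
#' @param result A [run_scenario()] result.
#' @param report A [build_timescale_report()] for the same configuration.
#' @param directory Output directory (created if missing).
#' @param config Optional resolved configuration list to record.
#' @param pressure Optional [solve_steady_pressure()] solution to export.
#' @return The summary list, invisibly.
#' @export
write_outputs <- function(result, report, directory, config = NULL,
                          pressure = NULL) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  lattice <- result$system$lattice
  utils::write.csv(.thin_rows(result$effluent),
                   file.path(directory, "effluent.csv"), row.names = FALSE)
  for (nm in names(result$snapshots)) {
    sn <- result$snapshots[[nm]]
    log10_safe <- function(m) log10(pmax(m, 1e-300))
    write_vtk_rectilinear(
      file.path(directory, paste0("fields_", nm, ".vtk")), lattice,
      list(x_PAC = sn$PAC, x_PACOH = sn$PACOH,
           log10_x_PAC = log10_safe(sn$PAC),
           log10_x_PACOH = log10_safe(sn$PACOH)),
      title = paste("species fields", nm))
  }
  if (!is.null(pressure)) {
    vel <- darcy_velocity(pressure, lattice)
    write_vtk_rectilinear(
      file.path(directory, "pressure.vtk"), lattice,
      list(pressure_kPa = pressure$pressure,
           speed_cm_per_min = vel$speed,
           log10_speed = log10(pmax(vel$speed, 1e-300))),
      title = "steady pressure and velocity")
  }
  utils::write.csv(as.data.frame(report),
                   file.path(directory, "timescales.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(report),
                       file.path(directory, "timescales.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  ef <- result$effluent
  final <- ef[nrow(ef), ]
  summary <- list(
    inlet_rate_cm3_per_min = result$system$q_in,
    outlet_rate_cm3_per_min = result$system$q_out,
    half_rise_time_min = result$half_rise_time,
    injected_pac_molfrac = result$system$scenario$injected_pac,
    final_effluent_pac_molfrac = final$pac_molfrac,
    final_effluent_pacoh_molfrac = final$pacoh_molfrac,
    mass_balance_closure = result$mass_balance,
    end_time_min = result$system$scenario$end_time,
    n_steps = nrow(ef)
  )
  jsonlite::write_json(summary, file.path(directory, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(config))
    jsonlite::write_json(config, file.path(directory, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(summary)
}
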