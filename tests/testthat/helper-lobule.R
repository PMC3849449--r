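# Shared fixtures and independent oracles for the test suite. The base
# objects (default 51x51 lattice and its steady flow solve) are computed
# once per session and reused.

.fixtures <- new.env(parent = emptyenv())

base_objects <- function() {
  if (is.null(.fixtures$base)) {
    lat <- build_lattice(lattice_spec())
    fl <- fluid_properties()
    we <- boundary_wells()
    .fixtures$base <- list(
      lattice = lat, fluid = fl, wells = we,
      species = species_set(), reaction = reaction_spec(),
      flow = solve_steady_pressure(lat, fl, we)
    )
  }
  .fixtures$base
}

# a small odd lattice with the default property values, for fast runs
small_objects <- function(n = 11L) {
  lat <- build_lattice(lattice_spec(n_side = n))
  fl <- fluid_properties()
  we <- boundary_wells(producer_cell = c(n, n))
  list(lattice = lat, fluid = fl, wells = we,
       species = species_set(), reaction = reaction_spec(),
       flow = solve_steady_pressure(lat, fl, we))
}

# voxel-counting oracle: volume fraction of a cylinder of radius a along z
# inside a cube of edge 2a, on an m^3 grid of voxel centres
voxel_cylinder_porosity <- function(m = 200L) {
  g <- (seq_len(m) - 0.5) / m * 2 - 1   # centres in [-1, 1], radius 1
  inside <- outer(g^2, g^2, `+`) <= 1
  mean(inside)                           # uniform along the cylinder axis
}

# voxel-counting oracle: complement of a sphere of radius R inscribed in a
# cube of edge L = 2R (slice-wise to keep memory flat)
voxel_sphere_porosity <- function(m = 200L) {
  g <- (seq_len(m) - 0.5) / m * 2 - 1
  inside <- 0
  for (z in g) {
    r2 <- 1 - z^2
    if (r2 > 0) inside <- inside + sum(outer(g^2, g^2, `+`) <= r2)
  }
  1 - inside / m^3
}

# minimal legacy-ASCII VTK rectilinear reader: header fields and named
# CELL_DATA scalar arrays (structural round-trip check for the writer)
parse_vtk_rectilinear <- function(path) {
  lines <- readLines(path)
  stopifnot(grepl("vtk DataFile", lines[1]),
            lines[3] == "ASCII",
            lines[4] == "DATASET RECTILINEAR_GRID")
  dims <- as.integer(strsplit(lines[5], " ")[[1]][-1])
  n_cells_line <- grep("^CELL_DATA", lines, value = TRUE)
  n_cells <- as.integer(sub("CELL_DATA ", "", n_cells_line))
  starts <- grep("^SCALARS", lines)
  arrays <- list()
  for (s in starts) {
    nm <- strsplit(lines[s], " ")[[1]][2]
    vals <- as.numeric(lines[(s + 2):(s + 1 + n_cells)])
    arrays[[nm]] <- vals
  }
  list(dims = dims, n_cells = n_cells, arrays = arrays)
}
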