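# Quarter-lobule lattice geometry: alternating sinusoid channels and
# hepatocyte (tissue) cells on a regular n x n grid, with half-width
# bounding sinusoids shared with the neighbouring symmetry elements.

#' Porosity of a cylindrical vessel inscribed in a cubic grid cell
#'
#' A sinusoid grid cell represents a tubular vessel of diameter `2a` inside a
#' cube of edge `2a`; the fluid-accessible volume fraction is the cylinder to
#' cube volume ratio, `pi a^2 (2a) / (2a)^3 = pi/4`, independent of the
#' radius.
#'
#' @param vessel_radius Vessel radius (any length unit, > 0).
#' @return Dimensionless porosity, `pi/4 = 0.7854`.
#' @examples
#' cylinder_in_cube_porosity(3e-4) # 3 um in cm
#' @export
cylinder_in_cube_porosity <- function(vessel_radius) {
  .check_scalar(vessel_radius, "vessel_radius")
  if (vessel_radius <= 0) .stopf("vessel_radius must be > 0")
  pi / 4
}

#' Permeability of a cylindrical tube
#'
#' Poiseuille flow in a tube of radius `a` is equivalent to Darcy flow with
#' permeability `K = a^2 / 8`.
#'
#' @param vessel_radius Vessel radius (length unit `u`, >= 0).
#' @return Permeability in `u^2`.
#' @examples
#' tube_permeability(3)    # 3 um -> 1.125 um^2
#' @export
tube_permeability <- function(vessel_radius) {
  .check_scalar(vessel_radius, "vessel_radius")
  if (vessel_radius < 0) .stopf("vessel_radius must be >= 0")
  vessel_radius^2 / 8
}

#' Ideal porosity of a sphere packed in a cubic cell
#'
#' A hepatocyte is idealised as a sphere of radius `R` inscribed in a cubic
#' grid cell of edge `L`; the pore fraction is `1 - (4 pi / 3) (R/L)^3`.
#'
#' @param radius_to_cell_ratio `R/L` in `[0, 0.5]` (0.5 = inscribed sphere).
#' @return Dimensionless porosity in `[1 - pi/6, 1]`.
#' @examples
#' ideal_sphere_packing_porosity(0.5) # 0.4764
#' @export
ideal_sphere_packing_porosity <- function(radius_to_cell_ratio) {
  .check_scalar(radius_to_cell_ratio, "radius_to_cell_ratio")
  if (radius_to_cell_ratio < 0 || radius_to_cell_ratio > 0.5)
    .stopf("radius_to_cell_ratio must lie in [0, 0.5]")
  1 - (4 * pi / 3) * radius_to_cell_ratio^3
}

#' Carman-Kozeny permeability of a granular packing
#'
#' `K = D_p^2 phi^3 / (180 (1 - phi)^2)` for flow around particles of
#' diameter `D_p` at porosity `phi`; used to estimate the tissue-cell
#' permeability from the hepatocyte diameter.
#'
#' @param particle_diameter Particle diameter (length unit `u`, > 0).
#' @param porosity Porosity in (0, 1).
#' @return Permeability in `u^2`.
#' @examples
#' carman_kozeny_permeability(24, 0.4764) # um -> 1.262 um^2
#' @export
carman_kozeny_permeability <- function(particle_diameter, porosity) {
  .check_scalar(particle_diameter, "particle_diameter")
  .check_scalar(porosity, "porosity")
  if (particle_diameter <= 0) .stopf("particle_diameter must be > 0")
  if (porosity <= 0 || porosity >= 1) .stopf("porosity must lie in (0, 1)")
  particle_diameter^2 * porosity^3 / (180 * (1 - porosity)^2)
}

#' Specification of the quarter-lobule lattice
#'
#' Collects the geometric and petrophysical parameters of the regular
#' lattice. Defaults reproduce the base-case lobule: a 51 x 51 grid with
#' 0.0006 cm sinusoid channels (half width, 0.0003 cm, on the two bounding
#' rows/columns shared with adjacent symmetry elements) interlacing
#' 0.0024 cm hepatocyte cells, for a side length of 0.0750 cm.
#'
#' @param n_side Odd integer >= 3; cells per side (default 51).
#' @param sinusoid_width Interior sinusoid channel width, cm.
#' @param boundary_sinusoid_width Width of the two bounding half-sinusoids, cm.
#' @param tissue_width Hepatocyte cell width, cm.
#' @param depth Grid depth (third dimension), cm.
#' @param sinusoid_porosity Porosity of sinusoid cells (default `pi/4`).
#' @param sinusoid_permeability Permeability of sinusoid cells, cm^2
#'   (default `a^2/8` with `a = 3` um, i.e. 1.125 um^2).
#' @param tissue_porosity Porosity of tissue cells (base case 0.2382).
#' @param tissue_permeability Permeability of tissue cells, cm^2
#'   (base case 7.45e-2 Darcy).
#' @param hepatocyte_diameter Hepatocyte diameter, cm.
#' @param inlet_cell,outlet_cell 1-based `(i, j)` grid indices of the
#'   injector and producer corner cells.
#' @return An object of class `lattice_spec`.
#' @seealso [build_lattice()]
#' @export
lattice_spec <- function(n_side = 51L,
                         sinusoid_width = 0.0006,
                         boundary_sinusoid_width = 0.0003,
                         tissue_width = 0.0024,
                         depth = 0.0003,
                         sinusoid_porosity = pi / 4,
                         sinusoid_permeability = tube_permeability(3) * lobule_units$um2_cm2,
                         tissue_porosity = 0.2382,
                         tissue_permeability = 7.45e-2 * lobule_units$darcy_cm2,
                         hepatocyte_diameter = 0.0024,
                         inlet_cell = c(1L, 1L),
                         outlet_cell = c(n_side, n_side)) {
  n_side <- as.integer(n_side)
  if (length(n_side) != 1L || is.na(n_side) || n_side < 3L || n_side %% 2L == 0L)
    .stopf("n_side must be an odd integer >= 3 (got %s)", n_side)
  for (nm in c("sinusoid_width", "boundary_sinusoid_width", "tissue_width",
               "depth", "hepatocyte_diameter")) {
    v <- get(nm)
    .check_scalar(v, nm)
    if (v <= 0) .stopf("'%s' must be > 0", nm)
  }
  for (nm in c("sinusoid_porosity", "tissue_porosity")) {
    v <- get(nm)
    .check_scalar(v, nm)
    if (v <= 0 || v > 1) .stopf("'%s' must lie in (0, 1]", nm)
  }
  for (nm in c("sinusoid_permeability", "tissue_permeability")) {
    v <- get(nm)
    .check_scalar(v, nm)
    if (v < 0) .stopf("'%s' must be >= 0", nm)
  }
  spec <- structure(list(
    n_side = n_side,
    sinusoid_width = sinusoid_width,
    boundary_sinusoid_width = boundary_sinusoid_width,
    tissue_width = tissue_width,
    depth = depth,
    sinusoid_porosity = sinusoid_porosity,
    sinusoid_permeability = sinusoid_permeability,
    tissue_porosity = tissue_porosity,
    tissue_permeability = tissue_permeability,
    hepatocyte_diameter = hepatocyte_diameter,
    inlet_cell = as.integer(inlet_cell),
    outlet_cell = as.integer(outlet_cell)
  ), class = "lattice_spec")
  spec
}

# width of grid position k (1-based) in an n-position alternating pattern
.position_widths <- function(spec) {
  n <- spec$n_side
  w <- ifelse(seq_len(n) %% 2L == 1L, spec$sinusoid_width, spec$tissue_width)
  w[c(1L, n)] <- spec$boundary_sinusoid_width
  w
}

#' Build the quarter-lobule lattice
#'
#' Realises a [lattice_spec()] as per-cell geometry and properties. Cell
#' `(i, j)` (1-based) is a tissue (hepatocyte) cell iff both `i` and `j`
#' are even; any cell on an odd row or column lies on a sinusoid channel
#' (channel crossings take sinusoid properties). Widths along each axis
#' follow the pattern half-sinusoid, tissue, sinusoid, tissue, ...,
#' sinusoid, tissue, half-sinusoid.
#'
#' @param spec A [lattice_spec()].
#' @return An object of class `lobule_lattice` with fields `n`, `widths`
#'   (per-position cm), `depth`, `side_length`, matrices `is_tissue`,
#'   `porosity`, `permeability` (cm^2), `flow_area_fraction` (the fraction
#'   of a cell face open to flow: the porosity for vessel-bearing sinusoid
#'   cells, 1 for tissue cells whose Carman-Kozeny permeability is already
#'   superficial), `bulk_volume`, `pore_volume` (cm^3), cell-centre
#'   coordinate vectors `centers` (cm), and the well indices.
#' @examples
#' lat <- build_lattice(lattice_spec())
#' lat$side_length        # 0.075 cm
#' pore_volumes(lat)$total
#' @export
build_lattice <- function(spec) {
  if (!inherits(spec, "lattice_spec")) .stopf("spec must be a lattice_spec")
  n <- spec$n_side
  w <- .position_widths(spec)
  odd <- seq_len(n) %% 2L == 1L
  is_tissue <- outer(!odd, !odd, `&`)       # tissue iff both indices even
  porosity <- ifelse(is_tissue, spec$tissue_porosity, spec$sinusoid_porosity)
  permeability <- ifelse(is_tissue, spec$tissue_permeability,
                         spec$sinusoid_permeability)
  # flow-area fraction of a cell face: a sinusoid cell carries a vessel of
  # cross-section pi a^2 = phi (2a)^2 and its tube permeability a^2/8 acts
  # over that lumen only; the tissue Carman-Kozeny permeability is already
  # superficial (defined per total bed area), so its fraction is 1.
  flow_area_fraction <- ifelse(is_tissue, 1, porosity)
  bulk_volume <- outer(w, w) * spec$depth
  pore_volume <- bulk_volume * porosity
  centers <- cumsum(w) - w / 2
  structure(list(
    n = n,
    spec = spec,
    widths = w,
    depth = spec$depth,
    side_length = sum(w),
    is_tissue = is_tissue,
    porosity = porosity,
    permeability = permeability,
    flow_area_fraction = flow_area_fraction,
    bulk_volume = bulk_volume,
    pore_volume = pore_volume,
    centers = centers,
    inlet_cell = spec$inlet_cell,
    outlet_cell = spec$outlet_cell
  ), class = "lobule_lattice")
}

#' @export
print.lobule_lattice <- function(x, ...) {
  cat(sprintf("lobule_lattice: %d x %d cells, side %.4f cm, depth %.4f cm\n",
              x$n, x$n, x$side_length, x$depth))
  pv <- pore_volumes(x)
  cat(sprintf("  sinusoid cells: %d, tissue cells: %d\n",
              sum(!x$is_tissue), sum(x$is_tissue)))
  cat(sprintf("  pore volume: sinusoid %.3e, tissue %.3e, total %.3e cm^3\n",
              pv$sinusoid, pv$tissue, pv$total))
  invisible(x)
}

#' Pore volumes of the lattice by cell type
#'
#' Sums `bulk_volume * porosity` over sinusoid cells, tissue cells, and all
#' cells. The sinusoid total is the volume accessible to purely convective
#' tracer transport; the grand total is the volume sampled when diffusion
#' equilibrates channels with tissue.
#'
#' @param lattice A `lobule_lattice`.
#' @return List with numeric fields `sinusoid`, `tissue`, `total` (cm^3).
#' @export
pore_volumes <- function(lattice) {
  if (!inherits(lattice, "lobule_lattice")) .stopf("not a lobule_lattice")
  s <- sum(lattice$pore_volume[!lattice$is_tissue])
  t <- sum(lattice$pore_volume[lattice$is_tissue])
  list(sinusoid = s, tissue = t, total = s + t)
}

#' Tabulate per-cell lattice properties
#'
#' @param x A `lobule_lattice`.
#' @param row.names,optional,... Ignored (standard generic arguments).
#' @return A data.frame with one row per cell and columns `i`, `j`,
#'   `x_center_cm`, `y_center_cm`, `dx_cm`, `dy_cm`, `type`, `porosity`,
#'   `permeability_cm2`, `bulk_volume_cm3`, `pore_volume_cm3`.
#' @export
as.data.frame.lobule_lattice <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  n <- x$n
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  data.frame(
    i = ij$i,
    j = ij$j,
    x_center_cm = x$centers[ij$i],
    y_center_cm = x$centers[ij$j],
    dx_cm = x$widths[ij$i],
    dy_cm = x$widths[ij$j],
    type = ifelse(as.vector(x$is_tissue), "tissue", "sinusoid"),
    porosity = as.vector(x$porosity),
    permeability_cm2 = as.vector(x$permeability),
    bulk_volume_cm3 = as.vector(x$bulk_volume),
    pore_volume_cm3 = as.vector(x$pore_volume)
  )
}
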