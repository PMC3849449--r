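# Single-phase Darcy pressure flow on the heterogeneous lattice:
# two-point flux approximation with distance-weighted harmonic permeability
# averaging, fixed-pressure injector/producer corner cells, sparse direct
# solves (Matrix), and a backward-Euler compressible transient.

#' Injector/producer boundary conditions
#'
#' The terminal portal venule (injector) and terminal hepatic venule
#' (producer) are modelled as fixed-pressure cells at opposite corners of
#' the lattice.
#'
#' @param injector_cell 1-based `(i, j)` index of the injector (default (1,1)).
#' @param injector_pressure Injector pressure, kPa (default 103).
#' @param producer_cell 1-based `(i, j)` index of the producer.
#' @param producer_pressure Producer pressure, kPa (default 101.8).
#' @param injector_composition Named numeric vector of injected species mole
#'   fractions (remainder is carrier water); default PAC at 1.8e-8, PACOH 0.
#' @return An object of class `boundary_wells`.
#' @export
boundary_wells <- function(injector_cell = c(1L, 1L),
                           injector_pressure = 103,
                           producer_cell = c(51L, 51L),
                           producer_pressure = 101.8,
                           injector_composition = c(PAC = 1.8e-8, PACOH = 0)) {
  .check_scalar(injector_pressure, "injector_pressure")
  .check_scalar(producer_pressure, "producer_pressure")
  if (injector_pressure <= producer_pressure)
    .stopf("injector_pressure must exceed producer_pressure")
  if (any(injector_composition < 0) || sum(injector_composition) > 1)
    .stopf("injector_composition must be non-negative mole fractions summing to <= 1")
  structure(list(
    injector_cell = as.integer(injector_cell),
    injector_pressure = injector_pressure,
    producer_cell = as.integer(producer_cell),
    producer_pressure = producer_pressure,
    injector_composition = injector_composition
  ), class = "boundary_wells")
}

#' Transmissibility of the face between two adjacent cells
#'
#' Two-point flux approximation with distance-weighted harmonic averaging
#' of the face flow conductivity `phi * K`:
#' `T = A / (mu * (dx_a / (2 phi_a K_a) + dx_b / (2 phi_b K_b)))` where
#' `A` is the shared face area (transverse width times depth) and `phi`
#' is each cell's flow-area fraction. For a sinusoid cell the vessel lumen
#' `pi a^2 = phi (2a)^2` is the only conducting cross-section and the
#' tube permeability `a^2/8` acts over that lumen, so `phi` is the cell
#' porosity; for a tissue cell the Carman-Kozeny permeability is already
#' superficial (defined per total bed area) and `phi = 1`. The volumetric
#' flux through the face is `T * (p_a - p_b)` in cm^3/min. Symmetric in
#' the two cells; zero if either permeability vanishes (sealed face).
#'
#' @param cell_a,cell_b Lists with fields `dx` (cell width along the flow
#'   direction, cm), `width` (transverse width, cm), `depth` (cm), `K`
#'   (permeability, cm^2), and `phi` (flow-area fraction). The two cells
#'   must agree on `width` and `depth`.
#' @param viscosity Fluid viscosity, mPa s.
#' @return Transmissibility in cm^3/(min kPa).
#' @export
face_transmissibility <- function(cell_a, cell_b, viscosity) {
  for (cl in list(cell_a, cell_b)) {
    if (!all(c("dx", "width", "depth", "K", "phi") %in% names(cl)))
      .stopf("cells need fields dx, width, depth, K, phi")
    if (cl$dx <= 0 || cl$width <= 0 || cl$depth <= 0)
      .stopf("cell widths must be > 0")
    if (cl$phi <= 0 || cl$phi > 1) .stopf("porosity must lie in (0, 1]")
  }
  if (cell_a$width != cell_b$width || cell_a$depth != cell_b$depth)
    .stopf("cells are not adjacent: shared face dimensions differ")
  if (cell_a$K == 0 || cell_b$K == 0) return(0)
  area <- cell_a$width * cell_a$depth
  resist <- cell_a$dx / (2 * cell_a$phi * cell_a$K) +
    cell_b$dx / (2 * cell_b$phi * cell_b$K)
  area / (.mu_internal(viscosity) * resist)
}

# All interior faces of the lattice as parallel vectors:
# a, b: linear cell indices (column-major, id = i + (j-1) n); T: cm^3/(min kPa)
.lattice_faces <- function(lattice, viscosity) {
  n <- lattice$n
  w <- lattice$widths
  K <- lattice$permeability * lattice$flow_area_fraction  # face conductivity
  mu <- .mu_internal(viscosity)
  idx <- function(i, j) i + (j - 1L) * n

  # x-direction faces: (i, j) -- (i+1, j)
  i <- rep(seq_len(n - 1L), times = n)
  j <- rep(seq_len(n), each = n - 1L)
  ax <- idx(i, j); bx <- idx(i + 1L, j)
  area_x <- w[j] * lattice$depth
  Tx <- area_x / (mu * (w[i] / (2 * K[cbind(i, j)]) +
                        w[i + 1L] / (2 * K[cbind(i + 1L, j)])))

  # y-direction faces: (i, j) -- (i, j+1)
  i2 <- rep(seq_len(n), times = n - 1L)
  j2 <- rep(seq_len(n - 1L), each = n)
  ay <- idx(i2, j2); by <- idx(i2, j2 + 1L)
  area_y <- w[i2] * lattice$depth
  Ty <- area_y / (mu * (w[j2] / (2 * K[cbind(i2, j2)]) +
                        w[j2 + 1L] / (2 * K[cbind(i2, j2 + 1L)])))

  list(a = c(ax, ay), b = c(bx, by), T = c(Tx, Ty),
       dir = rep(c("x", "y"), c(length(Tx), length(Ty))))
}

# Symmetric TPFA Laplacian L such that (L p)_k = sum_faces T (p_k - p_nb)
.laplacian <- function(faces, n_cells) {
  Matrix::sparseMatrix(
    i = c(faces$a, faces$b, faces$a, faces$b),
    j = c(faces$a, faces$b, faces$b, faces$a),
    x = c(faces$T, faces$T, -faces$T, -faces$T),
    dims = c(n_cells, n_cells)
  )
}

.well_ids <- function(lattice) {
  n <- lattice$n
  c(inlet = lattice$inlet_cell[1] + (lattice$inlet_cell[2] - 1L) * n,
    outlet = lattice$outlet_cell[1] + (lattice$outlet_cell[2] - 1L) * n)
}

# impose Dirichlet rows: identity row, rhs = value
.apply_dirichlet <- function(A, b, ids, values) {
  A[ids, ] <- 0
  A[cbind(ids, ids)] <- 1
  b[ids] <- values
  list(A = A, b = b)
}

.well_rate <- function(p, faces, id) {
  at_a <- faces$a == id
  at_b <- faces$b == id
  sum(faces$T[at_a] * (p[id] - p[faces$b[at_a]])) +
    sum(faces$T[at_b] * (p[id] - p[faces$a[at_b]]))
}

#' Solve the steady Darcy pressure field
#'
#' Assembles the TPFA transmissibility Laplacian for the lattice, imposes
#' the fixed injector/producer pressures, and solves the sparse linear
#' system. At steady state every interior cell has zero net volumetric
#' flux, inlet and outlet rates balance, and the discrete maximum principle
#' bounds all pressures by the two well pressures.
#'
#' @param lattice A `lobule_lattice`.
#' @param fluid A [fluid_properties()].
#' @param wells A [boundary_wells()].
#' @return An object of class `pressure_solution`: `pressure` (n x n matrix,
#'   kPa), `faces` (face list with volumetric flux `q` in cm^3/min, positive
#'   from `a` to `b`), `inlet_rate`, `outlet_rate` (cm^3/min), `residual`
#'   (relative linear-system residual).
#' @export
solve_steady_pressure <- function(lattice, fluid, wells) {
  if (all(lattice$permeability == 0)) .stopf("all permeabilities are zero: singular system")
  n <- lattice$n
  nc <- n * n
  faces <- .lattice_faces(lattice, fluid$viscosity)
  L <- .laplacian(faces, nc)
  ids <- .well_ids(lattice)
  wid <- c(wells$injector_cell[1] + (wells$injector_cell[2] - 1L) * n,
           wells$producer_cell[1] + (wells$producer_cell[2] - 1L) * n)
  if (wid[1] == wid[2]) .stopf("injector and producer must be distinct cells")
  sys <- .apply_dirichlet(L, numeric(nc), wid,
                          c(wells$injector_pressure, wells$producer_pressure))
  p <- as.numeric(Matrix::solve(sys$A, sys$b))
  res <- sqrt(sum((as.numeric(sys$A %*% p) - sys$b)^2)) /
    sqrt(sum(sys$b^2))
  q <- faces$T * (p[faces$a] - p[faces$b])
  inlet_rate <- .well_rate(p, faces, wid[1])
  outlet_rate <- -.well_rate(p, faces, wid[2])
  structure(list(
    pressure = matrix(p, n, n),
    faces = c(faces, list(q = q)),
    inlet_rate = inlet_rate,
    outlet_rate = outlet_rate,
    injector_id = wid[1],
    producer_id = wid[2],
    residual = res,
    wells = wells
  ), class = "pressure_solution")
}

#' @export
print.pressure_solution <- function(x, ...) {
  cat(sprintf("pressure_solution: %d x %d cells\n", nrow(x$pressure), ncol(x$pressure)))
  cat(sprintf("  inlet rate %.4e cm^3/min, outlet rate %.4e cm^3/min\n",
              x$inlet_rate, x$outlet_rate))
  cat(sprintf("  pressure range [%.4f, %.4f] kPa, residual %.2e\n",
              min(x$pressure), max(x$pressure), x$residual))
  invisible(x)
}

#' Solve the transient compressible pressure equation
#'
#' Backward-Euler integration of `V_pore C_eff dp/dt = -(L p)` with the
#' well cells pinned at their fixed pressures, starting from a uniform (or
#' supplied) initial field. Time steps ramp geometrically from a very small
#' initial step so that the fast (~1e-5 min) relaxation is resolved while
#' the integration still reaches steady state cheaply. The scheme is
#' unconditionally stable.
#'
#' @param lattice A `lobule_lattice`.
#' @param fluid A [fluid_properties()]; the storage coefficient per cell is
#'   `pore_volume * effective_compressibility`.
#' @param wells A [boundary_wells()].
#' @param initial_pressure Initial pressure, kPa: a scalar (uniform) or an
#'   n x n matrix. Default: producer pressure everywhere.
#' @param duration Total simulated time, min.
#' @param dt0 Initial time step, min (default 1e-8).
#' @param growth Geometric step growth factor (default 1.2).
#' @param snapshot_times Optional times (min) at which to store the full
#'   pressure field.
#' @return An object of class `pressure_transient`: `times`,
#'   `inlet_rate_history`, `outlet_rate_history`, `snapshots` (named list of
#'   n x n matrices), `steady` (the matching [solve_steady_pressure()]
#'   solution), and `t99` — the first time at which the inlet rate is
#'   within 1% of the steady value (log-interpolated between steps).
#' @export
solve_transient_pressure <- function(lattice, fluid, wells,
                                     initial_pressure = NULL,
                                     duration = 2e-4,
                                     dt0 = 1e-8,
                                     growth = 1.2,
                                     snapshot_times = numeric(0)) {
  if (duration <= 0) .stopf("duration must be > 0")
  if (dt0 <= 0) .stopf("initial time step must be > 0")
  if (fluid$effective_compressibility <= 0) .stopf("effective compressibility must be > 0")
  n <- lattice$n
  nc <- n * n
  faces <- .lattice_faces(lattice, fluid$viscosity)
  L <- .laplacian(faces, nc)
  wid <- c(wells$injector_cell[1] + (wells$injector_cell[2] - 1L) * n,
           wells$producer_cell[1] + (wells$producer_cell[2] - 1L) * n)
  pvals <- c(wells$injector_pressure, wells$producer_pressure)
  storage <- as.vector(lattice$pore_volume) * fluid$effective_compressibility

  if (is.null(initial_pressure)) initial_pressure <- wells$producer_pressure
  p <- if (length(initial_pressure) == 1L) rep(initial_pressure, nc)
       else as.vector(initial_pressure)
  p[wid] <- pvals

  steady <- solve_steady_pressure(lattice, fluid, wells)
  q_ss <- steady$inlet_rate

  times <- numeric(0); qin <- numeric(0); qout <- numeric(0)
  snaps <- list()
  snap_pending <- sort(snapshot_times)
  t <- 0; dt <- dt0
  while (t < duration) {
    dt_step <- min(dt, duration - t)
    S <- L + Matrix::Diagonal(nc, storage / dt_step)
    b <- storage / dt_step * p
    sys <- .apply_dirichlet(S, b, wid, pvals)
    p <- as.numeric(Matrix::solve(sys$A, sys$b))
    t <- t + dt_step
    times <- c(times, t)
    qin <- c(qin, .well_rate(p, faces, wid[1]))
    qout <- c(qout, -.well_rate(p, faces, wid[2]))
    while (length(snap_pending) && t >= snap_pending[1]) {
      snaps[[sprintf("t%.6g", snap_pending[1])]] <- matrix(p, n, n)
      snap_pending <- snap_pending[-1]
    }
    dt <- dt * growth
  }

  # first time the inlet rate is within 1% of steady (log-linear interp)
  gap <- abs(qin - q_ss) / abs(q_ss)
  t99 <- NA_real_
  k <- which(gap <= 0.01)
  if (length(k)) {
    k1 <- k[1]
    if (k1 == 1L) t99 <- times[1] else {
      g0 <- log(gap[k1 - 1L]); g1 <- log(gap[k1])
      f <- (log(0.01) - g0) / (g1 - g0)
      t99 <- times[k1 - 1L] + f * (times[k1] - times[k1 - 1L])
    }
  }

  structure(list(
    times = times,
    inlet_rate_history = qin,
    outlet_rate_history = qout,
    snapshots = snaps,
    steady = steady,
    t99 = t99
  ), class = "pressure_transient")
}

#' Cell-centred Darcy and interstitial velocities
#'
#' Averages the face volumetric fluxes of a solved pressure field to cell
#' centres and divides by the flow cross-section to obtain the Darcy flux
#' velocity, and additionally by porosity for the interstitial (pore) speed
#' that governs tracer transit; the latter is what a velocity-magnitude map
#' of the lattice displays.
#'
#' @param solution A [solve_steady_pressure()] result.
#' @param lattice The same `lobule_lattice`.
#' @return List of n x n matrices: `vx`, `vy` (interstitial components,
#'   cm/min), `speed` (interstitial magnitude), `darcy_vx`, `darcy_vy`,
#'   `darcy_speed` (superficial Darcy flux components and magnitude).
#' @export
darcy_velocity <- function(solution, lattice) {
  n <- lattice$n
  w <- lattice$widths
  depth <- lattice$depth
  faces <- solution$faces
  nx <- (n - 1L) * n  # x-faces come first in the face list

  # face flux -> per-cell average of adjacent faces, per direction
  qx <- matrix(0, n, n); cx <- matrix(0, n, n)
  fq <- faces$q[seq_len(nx)]
  ia <- faces$a[seq_len(nx)]; ib <- faces$b[seq_len(nx)]
  qx_acc <- numeric(n * n); ct_acc <- numeric(n * n)
  add <- function(acc, idx, val) { acc[idx] <- acc[idx] + val; acc }
  # areas transverse to x at a cell: w[j] * depth
  jj <- ((ia - 1L) %/% n) + 1L
  ax <- w[jj] * depth
  qx_acc <- add(qx_acc, ia, fq / ax); ct_acc <- add(ct_acc, ia, 1)
  qx_acc <- add(qx_acc, ib, fq / ax); ct_acc <- add(ct_acc, ib, 1)
  vx_d <- matrix(ifelse(ct_acc > 0, qx_acc / pmax(ct_acc, 1), 0), n, n)

  fqy <- faces$q[-seq_len(nx)]
  ya <- faces$a[-seq_len(nx)]; yb <- faces$b[-seq_len(nx)]
  ii <- ((ya - 1L) %% n) + 1L
  ay <- w[ii] * depth
  qy_acc <- numeric(n * n); cy_acc <- numeric(n * n)
  qy_acc <- add(qy_acc, ya, fqy / ay); cy_acc <- add(cy_acc, ya, 1)
  qy_acc <- add(qy_acc, yb, fqy / ay); cy_acc <- add(cy_acc, yb, 1)
  vy_d <- matrix(ifelse(cy_acc > 0, qy_acc / pmax(cy_acc, 1), 0), n, n)

  phi <- lattice$porosity
  vx <- vx_d / phi; vy <- vy_d / phi
  list(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2),
       darcy_vx = vx_d, darcy_vy = vy_d,
       darcy_speed = sqrt(vx_d^2 + vy_d^2))
}
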