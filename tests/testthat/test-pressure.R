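test_that("face transmissibility matches hand-evaluated harmonic formulas", {
  mu <- 3.5
  mu_int <- mu * 1e-6 / 60  # mPa s -> kPa min
  sin_cell <- list(dx = 0.0006, width = 0.0024, depth = 0.0003,
                   K = 1.125e-8, phi = pi / 4)
  tis_cell <- list(dx = 0.0024, width = 0.0024, depth = 0.0003,
                   K = 7.45e-2 * 9.869e-9, phi = 1)

  # homogeneous limit: T = A phi K / (mu dx)
  expect_equal(face_transmissibility(sin_cell, sin_cell, mu),
               (0.0024 * 0.0003) * (pi / 4) * 1.125e-8 / (mu_int * 0.0006))

  # sinusoid-tissue face: independent scalar arithmetic
  a_face <- 0.0024 * 0.0003
  r <- 0.0006 / (2 * (pi / 4) * 1.125e-8) +
       0.0024 / (2 * 1 * 7.45e-2 * 9.869e-9)
  expect_equal(face_transmissibility(sin_cell, tis_cell, mu),
               a_face / (mu_int * r))
  # symmetry in the two cells
  expect_equal(face_transmissibility(tis_cell, sin_cell, mu),
               face_transmissibility(sin_cell, tis_cell, mu))

  # sealed face
  sealed <- sin_cell; sealed$K <- 0
  expect_equal(face_transmissibility(sealed, tis_cell, mu), 0)

  # mismatched shared-face dimensions
  bad <- sin_cell; bad$width <- 0.001
  expect_error(face_transmissibility(bad, tis_cell, mu), "adjacent")
})

test_that("steady Darcy solve conserves mass and obeys the maximum principle", {
  b <- base_objects()
  sol <- b$flow

  expect_lt(sol$residual, 1e-10)
  expect_lt(abs(sol$inlet_rate - sol$outlet_rate) / sol$inlet_rate, 1e-8)
  expect_true(all(sol$pressure >= 101.8 - 1e-9))
  expect_true(all(sol$pressure <= 103 + 1e-9))
  expect_equal(sol$pressure[1, 1], 103)
  expect_equal(sol$pressure[51, 51], 101.8)
  # geometric + boundary symmetry: the field is transpose-symmetric
  expect_equal(sol$pressure, t(sol$pressure), tolerance = 1e-10)

  # interior cells have zero net volumetric flux
  nc <- 51 * 51
  net <- numeric(nc)
  f <- sol$faces
  for (k in seq_along(f$q)) {
    net[f$a[k]] <- net[f$a[k]] - f$q[k]
    net[f$b[k]] <- net[f$b[k]] + f$q[k]
  }
  interior <- setdiff(seq_len(nc), c(sol$injector_id, sol$producer_id))
  expect_lt(max(abs(net[interior])) / sol$inlet_rate, 1e-8)
})

test_that("steady inlet rate is linear in permeability", {
  s <- small_objects(11L)
  spec2 <- lattice_spec(n_side = 11L,
                        sinusoid_permeability = 2 * 1.125e-8,
                        tissue_permeability = 2 * 7.45e-2 * 9.869e-9)
  lat2 <- build_lattice(spec2)
  we <- boundary_wells(producer_cell = c(11L, 11L))
  sol2 <- solve_steady_pressure(lat2, s$fluid, we)
  expect_equal(sol2$inlet_rate, 2 * s$flow$inlet_rate, tolerance = 1e-10)
})

test_that("sparse solve agrees with an independent dense assembly", {
  n <- 5L
  lat <- build_lattice(lattice_spec(n_side = n))
  fl <- fluid_properties()
  we <- boundary_wells(producer_cell = c(n, n))
  sol <- solve_steady_pressure(lat, fl, we)

  # dense assembly from the exported scalar transmissibility, no shared code
  nc <- n * n
  idx <- function(i, j) i + (j - 1L) * n
  cell <- function(i, j, dx, width) list(
    dx = dx, width = width, depth = lat$depth,
    K = lat$permeability[i, j], phi = lat$flow_area_fraction[i, j])
  A <- matrix(0, nc, nc)
  for (j in seq_len(n)) for (i in seq_len(n - 1L)) {
    Tf <- face_transmissibility(
      cell(i, j, lat$widths[i], lat$widths[j]),
      cell(i + 1L, j, lat$widths[i + 1L], lat$widths[j]), fl$viscosity)
    a <- idx(i, j); bb <- idx(i + 1L, j)
    A[a, a] <- A[a, a] + Tf; A[bb, bb] <- A[bb, bb] + Tf
    A[a, bb] <- A[a, bb] - Tf; A[bb, a] <- A[bb, a] - Tf
  }
  for (j in seq_len(n - 1L)) for (i in seq_len(n)) {
    Tf <- face_transmissibility(
      cell(i, j, lat$widths[j], lat$widths[i]),
      cell(i, j + 1L, lat$widths[j + 1L], lat$widths[i]), fl$viscosity)
    a <- idx(i, j); bb <- idx(i, j + 1L)
    A[a, a] <- A[a, a] + Tf; A[bb, bb] <- A[bb, bb] + Tf
    A[a, bb] <- A[a, bb] - Tf; A[bb, a] <- A[bb, a] - Tf
  }
  rhs <- numeric(nc)
  wid <- c(idx(1L, 1L), idx(n, n))
  A[wid, ] <- 0; A[cbind(wid, wid)] <- 1; rhs[wid] <- c(103, 101.8)
  p_ref <- solve(A, rhs)
  expect_equal(as.vector(sol$pressure), p_ref, tolerance = 1e-10)
})

test_that("2x2 grid refinement changes the inlet rate by under 2 percent", {
  s <- small_objects(11L)
  lat <- s$lattice
  n2 <- 2L * lat$n
  dup <- rep(seq_len(lat$n), each = 2L)
  lat2 <- lat
  lat2$n <- n2
  lat2$widths <- rep(lat$widths / 2, each = 2L)
  for (fld in c("is_tissue", "porosity", "permeability",
                "flow_area_fraction"))
    lat2[[fld]] <- lat[[fld]][dup, dup]
  lat2$bulk_volume <- outer(lat2$widths, lat2$widths) * lat2$depth
  lat2$pore_volume <- lat2$bulk_volume * lat2$porosity

  faces <- lobuleflow:::.lattice_faces(lat2, s$fluid$viscosity)
  L <- lobuleflow:::.laplacian(faces, n2 * n2)
  idx <- function(i, j) i + (j - 1L) * n2
  # wells occupy the same geometric regions: the 2x2 blocks refining the
  # original corner cells
  inj <- c(idx(1L, 1L), idx(2L, 1L), idx(1L, 2L), idx(2L, 2L))
  prd <- c(idx(n2 - 1L, n2 - 1L), idx(n2, n2 - 1L),
           idx(n2 - 1L, n2), idx(n2, n2))
  sys <- lobuleflow:::.apply_dirichlet(L, numeric(n2 * n2), c(inj, prd),
                                       c(rep(103, 4), rep(101.8, 4)))
  p <- as.numeric(Matrix::solve(sys$A, sys$b))
  rate2 <- sum(vapply(inj, function(id)
    lobuleflow:::.well_rate(p, faces, id), numeric(1)))
  # faces internal to the injector block carry no net contribution (both
  # endpoints at 103), so the sum is the block outflow
  expect_equal(rate2, s$flow$inlet_rate, tolerance = 0.02)
})

test_that("transient pressure relaxes to the steady solution", {
  b <- base_objects()
  tr <- solve_transient_pressure(b$lattice, b$fluid, b$wells,
                                 duration = 2e-4)
  q_ss <- b$flow$inlet_rate
  expect_lt(abs(tail(tr$inlet_rate_history, 1) - q_ss) / q_ss, 1e-3)
  expect_false(is.na(tr$t99))
  expect_gt(tr$t99, 0)
  expect_lt(tr$t99, 1e-4)
  # started from the steady field the solve is a fixed point
  tr0 <- solve_transient_pressure(b$lattice, b$fluid, b$wells,
                                  initial_pressure = b$flow$pressure,
                                  duration = 1e-5)
  expect_lt(max(abs(tr0$inlet_rate_history - q_ss)) / q_ss, 1e-6)
})

test_that("doubling the compressibility doubles the relaxation constant", {
  s <- small_objects(11L)
  fit_tau <- function(fluid) {
    tr <- solve_transient_pressure(s$lattice, fluid, s$wells,
                                   duration = 2e-4, growth = 1.1)
    q_ss <- solve_steady_pressure(s$lattice, fluid, s$wells)$inlet_rate
    gap <- abs(tr$inlet_rate_history - q_ss) / q_ss
    keep <- gap > 1e-7 & gap < 1e-2
    -1 / coef(lm(log(gap[keep]) ~ tr$times[keep]))[[2]]
  }
  tau1 <- fit_tau(fluid_properties())
  tau2 <- fit_tau(fluid_properties(structural_compressibility = 3.65e-5))
  # C_eff 1.85e-5 -> 3.70e-5 doubles the storage term
  expect_equal(tau2 / tau1, 2, tolerance = 0.15)
})

test_that("velocity fields reflect the sinusoid/tissue flow contrast", {
  b <- base_objects()
  vel <- darcy_velocity(b$flow, b$lattice)

  # zero flux implies zero velocity everywhere
  still <- b$flow
  still$faces$q[] <- 0
  vel0 <- darcy_velocity(still, b$lattice)
  expect_equal(max(abs(vel0$speed)), 0)

  # transposition swaps the two components
  expect_equal(vel$vx, t(vel$vy), tolerance = 1e-8)
  expect_equal(vel$speed, t(vel$speed), tolerance = 1e-8)

  # channels carry distinctly faster flow than tissue, and the speed map
  # spans orders of magnitude across the lattice (hence the log colour
  # scale on velocity plots)
  med_sin <- median(vel$darcy_speed[!b$lattice$is_tissue])
  med_tis <- median(vel$darcy_speed[b$lattice$is_tissue])
  expect_gt(med_sin / med_tis, 5)
  rng <- quantile(vel$speed[vel$speed > 0], c(0.01, 0.99))
  expect_gt(log10(rng[[2]] / rng[[1]]), 2)
})

test_that("degenerate pressure problems raise errors", {
  lat <- build_lattice(lattice_spec(n_side = 5L,
                                    sinusoid_permeability = 0,
                                    tissue_permeability = 0))
  expect_error(solve_steady_pressure(lat, fluid_properties(),
                                     boundary_wells(producer_cell = c(5L, 5L))),
               "singular")
  expect_error(boundary_wells(injector_pressure = 100,
                              producer_pressure = 101), "exceed")
})
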