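test_that("pressure diffusivity matches an all-SI unit-conversion oracle", {
  K <- 1.125e-8          # cm^2
  phi <- pi / 4
  mu <- 3.5              # mPa s
  C <- 1.85e-5           # kPa^-1
  D <- pressure_diffusivity(K, phi, mu, C)

  # independent route: SI throughout (m, s, Pa), convert once at the end
  D_si <- (K * 1e-4) / (phi * (mu * 1e-3) * (C * 1e-3))  # m^2/s
  expect_equal(D, D_si * 1e4 * 60, tolerance = 1e-12)

  # the printed order-of-magnitude value
  expect_equal(D, 1.5e4, tolerance = 0.2)

  # proportional in K, inverse in the others
  expect_equal(pressure_diffusivity(2 * K, phi, mu, C), 2 * D)
  expect_equal(pressure_diffusivity(K, phi, 2 * mu, C), D / 2)
  expect_error(pressure_diffusivity(K, 0, mu, C), "> 0")
})

test_that("characteristic times reproduce the printed diffusion rows", {
  D_pres <- pressure_diffusivity(1.125e-8, pi / 4, 3.5, 1.85e-5)
  expect_equal(characteristic_time(0.15, D_pres), 1.5e-6, tolerance = 0.2)
  expect_equal(characteristic_time(1e-3, 2.5e-4), 4.0e-3)
  expect_equal(characteristic_time(1e-3, 2.5e-5), 4.0e-2)
  expect_error(characteristic_time(1e-3, 0), "> 0")
})

test_that("breakthrough estimates are pore volume over rate", {
  pv <- list(sinusoid = 4.77e-7, total = 7.344e-7)
  bt <- breakthrough_estimates(pv, 2.44e-6)
  expect_equal(bt$sinusoid, 4.77e-7 / 2.44e-6)
  expect_equal(bt$total, 7.344e-7 / 2.44e-6)
  expect_equal(bt$sinusoid, 0.20, tolerance = 0.03)
  expect_equal(bt$total, 0.30, tolerance = 0.01)
  bt2 <- breakthrough_estimates(pv, 2 * 2.44e-6)
  expect_equal(bt2$sinusoid, bt$sinusoid / 2)
  expect_equal(bt2$total, bt$total / 2)
  expect_error(breakthrough_estimates(pv, 0), "> 0")
})

test_that("timescale report assembles and orders the process constants", {
  b <- base_objects()
  rep <- build_timescale_report(b$lattice, b$fluid, b$species, b$reaction,
                                b$flow)

  # every entry equals an independent single-expression evaluation
  mu_int <- 3.5e-6 / 60
  expect_equal(rep$pressure_diffusivity,
               1.125e-8 / ((pi / 4) * mu_int * 1.85e-5), tolerance = 1e-10)
  expect_equal(rep$pressure_relaxation,
               0.15^2 / rep$pressure_diffusivity, tolerance = 1e-10)
  expect_equal(rep$diffusion_time_sinusoid, 1e-6 / 2.5e-4, tolerance = 1e-10)
  expect_equal(rep$diffusion_time_tissue, 1e-6 / 2.5e-5, tolerance = 1e-10)
  expect_equal(rep$reaction_half_life,
               0.76e-6 * log(2) / 6e-3, tolerance = 1e-10)
  expect_equal(rep$breakthrough_sinusoid,
               pore_volumes(b$lattice)$sinusoid / b$flow$inlet_rate,
               tolerance = 1e-10)

  # default ordering: pressure << reaction << diffusion << breakthrough
  expect_true(rep$pressure_relaxation < rep$reaction_half_life)
  expect_true(rep$reaction_half_life < rep$diffusion_time_sinusoid)
  expect_true(rep$diffusion_time_sinusoid < rep$diffusion_time_tissue)
  expect_true(rep$diffusion_time_tissue < rep$breakthrough_sinusoid)
  expect_true(rep$breakthrough_sinusoid < rep$breakthrough_total)

  # at a 1000-fold reduced rate the reaction is commensurate with transit
  rep3 <- build_timescale_report(b$lattice, b$fluid, b$species,
                                 reaction_spec(rate_multiplier = 1e-3),
                                 b$flow)
  ratio <- rep3$reaction_half_life / rep3$breakthrough_sinusoid
  expect_gt(ratio, 0.1)
  expect_lt(ratio, 10)

  # tabular export mirrors the entries
  df <- as.data.frame(rep)
  expect_equal(df$value[df$process == "reaction_half_life_min"],
               rep$reaction_half_life)
})

test_that("report entries follow the analytic scaling under perturbation", {
  b <- base_objects()
  base_rep <- build_timescale_report(b$lattice, b$fluid, b$species,
                                     b$reaction, b$flow)
  # viscosity +10%: D_pres / 1.1, T_pres * 1.1
  fl2 <- fluid_properties(viscosity = 3.5 * 1.1)
  rep2 <- build_timescale_report(b$lattice, fl2, b$species, b$reaction,
                                 b$flow)
  expect_equal(rep2$pressure_diffusivity,
               base_rep$pressure_diffusivity / 1.1, tolerance = 1e-10)
  expect_equal(rep2$pressure_relaxation,
               base_rep$pressure_relaxation * 1.1, tolerance = 1e-10)
  # distance +10%: T = d^2/D scales by 1.21
  rep3 <- build_timescale_report(b$lattice, b$fluid, b$species, b$reaction,
                                 b$flow, pressure_distance = 0.15 * 1.1)
  expect_equal(rep3$pressure_relaxation,
               base_rep$pressure_relaxation * 1.21, tolerance = 1e-10)
  # rate multiplier 10x: half-life / 10
  rep4 <- build_timescale_report(b$lattice, b$fluid, b$species,
                                 reaction_spec(rate_multiplier = 10), b$flow)
  expect_equal(rep4$reaction_half_life,
               base_rep$reaction_half_life / 10, tolerance = 1e-10)
})
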