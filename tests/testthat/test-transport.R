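test_that("Michaelis-Menten rate has the half-saturation and linear limits", {
  re <- reaction_spec()
  v_eff <- re$v_max / re$scale_factor

  expect_equal(michaelis_menten_rate(re$K_m, re), v_eff / 2)

  # linear limit: rate/x -> k_eff well below K_m
  x <- re$K_m * 1e-6
  expect_equal(michaelis_menten_rate(x, re) / x,
               effective_rate(re)$k_eff, tolerance = 1e-5)

  # independent scalar arithmetic at the injected drug level
  x0 <- 1.8e-8
  expect_equal(michaelis_menten_rate(x0, re),
               (1.08e-9 / 0.76e-6) * x0 / (1.8e-7 + x0), tolerance = 1e-12)

  # multiplier scales the numerator only
  expect_equal(michaelis_menten_rate(x0, re, rate_multiplier = 1e-2),
               michaelis_menten_rate(x0, re) * 1e-2)
  expect_error(michaelis_menten_rate(-1e-9, re), ">= 0")
})

test_that("implicit reaction substep is exact against a fine-step reference", {
  # one stiff implicit step vs many small steps of the same update
  x0 <- 1.8e-8
  v_eff <- 1.08e-9 / 0.76e-6
  K_m <- 1.8e-7
  coarse <- lobuleflow:::.react_implicit(x0, 1e-3, v_eff, K_m)
  xf <- x0
  for (i in 1:4000) xf <- lobuleflow:::.react_implicit(xf, 1e-3 / 4000, v_eff, K_m)
  # both must lie below x0 and agree to first order in dt
  expect_lt(coarse, x0)
  expect_lt(abs(coarse - xf) / x0, 0.2)
  # near-linear regime decay constant ~ v_eff/K_m
  expect_equal(xf / x0, exp(-v_eff / K_m * 1e-3 * (1 + x0 / K_m)^-1),
               tolerance = 0.05)
})

test_that("advancing preserves a uniform composition and closes mass balance", {
  s <- small_objects(11L)
  x0 <- 1.8e-8
  we <- boundary_wells(producer_cell = c(11L, 11L),
                       injector_composition = c(PAC = x0, PACOH = 0))
  sc <- scenario_config(injected_pac = x0, end_time = 0.1)
  sys <- transport_system(s$lattice, s$fluid, we, s$species, s$reaction,
                          sc, flow = s$flow)

  # uniform composition equal to the injected one is a fixed point of
  # advection + diffusion (no reaction)
  st <- initial_state(sys)
  st$moles$PAC <- sys$rho * sys$vpore * x0
  st2 <- advance(st, 5 * sc$dt, sys)
  x2 <- st2$moles$PAC / (sys$rho * sys$vpore)
  expect_equal(x2, rep(x0, length(x2)), tolerance = 1e-10)

  # macro step subdivides to the configured dt: same result as explicit loop
  sta <- advance(initial_state(sys), 5 * sc$dt, sys)
  stb <- initial_state(sys)
  for (k in 1:5) stb <- advance(stb, sc$dt, sys)
  expect_equal(sta$moles$PAC, stb$moles$PAC, tolerance = 1e-12)
  expect_equal(sta$time, stb$time)

  # single-step accounting closes to roundoff
  st1 <- advance(initial_state(sys), sc$dt, sys)
  mb <- mass_balance(st1, sys)
  expect_lt(abs(mb$pac), 1e-10)
  expect_lt(abs(mb$pair), 1e-10)
  expect_error(advance(st1, -1, sys), "> 0")
})

test_that("non-reactive effluent rises monotonically toward the injected level", {
  s <- small_objects(11L)
  res <- run_scenario(s$lattice, s$fluid, s$wells, s$species, s$reaction,
                      scenario_config(end_time = 0.2), flow = s$flow)
  ef <- res$effluent$pac_molfrac
  expect_true(all(diff(ef) > -1e-20))
  expect_true(all(ef <= 1.8e-8 * (1 + 1e-9)))
  expect_true(all(res$effluent$pacoh_molfrac == 0))
  expect_lt(abs(res$mass_balance$pair), 1e-8)
  expect_false(is.na(res$half_rise_time))
})

test_that("reaction is confined to tissue cells and conserves the pair", {
  s <- small_objects(11L)
  res <- run_scenario(s$lattice, s$fluid, s$wells, s$species, s$reaction,
                      scenario_config(reaction_enabled = TRUE,
                                      end_time = 0.1,
                                      snapshot_times = 0.02),
                      flow = s$flow)
  expect_gt(res$state$reacted, 0)
  expect_lt(abs(res$mass_balance$pac), 1e-8)
  expect_lt(abs(res$mass_balance$pacoh), 1e-8)
  expect_lt(abs(res$mass_balance$pair), 1e-8)

  # at an early snapshot the metabolite peaks in tissue, not channels
  sn <- res$snapshots[[1]]
  tis <- s$lattice$is_tissue
  expect_gt(max(sn$PACOH[tis]), max(sn$PACOH[!tis]))

  # a run with reaction disabled produces no metabolite at all
  res0 <- run_scenario(s$lattice, s$fluid, s$wells, s$species, s$reaction,
                       scenario_config(end_time = 0.05), flow = s$flow)
  expect_equal(sum(res0$state$moles$PACOH), 0)
})

test_that("steady effluent drug level decreases with the reaction rate", {
  s <- small_objects(11L)
  finals <- vapply(c(1e-3, 1e-2, 1), function(m) {
    r <- run_scenario(s$lattice, s$fluid, s$wells, s$species, s$reaction,
                      scenario_config(reaction_enabled = TRUE,
                                      rate_multiplier = m,
                                      end_time = 0.15),
                      flow = s$flow)
    tail(r$effluent$pac_molfrac, 1)
  }, numeric(1))
  expect_true(all(diff(finals) < 0))  # multiplier up, surviving drug down
})

test_that("scenario configuration is validated before any compute", {
  expect_error(scenario_config(end_time = 0), "> 0")
  expect_error(scenario_config(dt = 0), "> 0")
  expect_error(scenario_config(injected_pac = 2), "mole fraction")
  expect_error(scenario_config(rate_multiplier = 0), "> 0")
  sc <- scenario_config(snapshot_times = c(0.5, 0.01, 2), end_time = 1)
  expect_equal(sc$snapshot_times, c(0.01, 0.5))  # sorted, clipped to range
})
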