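# Fast solver contracts; the physics validation suite (Poiseuille,
# oscillatory channel, Casson channel, porous channel) lives in
# test-acceptance.R.

test_that("rest is a fixed point under zero pressure drop", {
  m <- channel_mask(1, 8, dx = 0.2)
  st <- init_flow_state(m)
  drv <- pressure_drive(1, function(t) rep(0, length(t)), 1)
  out <- flow_step(st, m, newtonian_props(0.0035), no_coil(), drv)
  expect_identical(max(abs(out$state$u)), 0)
  expect_identical(max(abs(out$state$v)), 0)
  expect_identical(max(abs(out$state$p)), 0)
})

test_that("simulation is deterministic and satisfies the projection contract", {
  m <- build_idealized_geometry(aneurysm_params(36.6, 1.9, porosity = 0.85),
                                dx = 0.4, lu_widths = 2, ld_widths = 2)
  props <- derive_casson_parameters(0.45)
  coil <- coil_model(0.85, 0.25e-3)
  drv <- pressure_drive(0.2, function(t) 40 + 10 * sin(2 * pi * t / 0.2), 2)
  cfg <- solver_config()
  s1 <- simulate_flow(m, props, coil, drv, cfg, sample_times = c(0.15, 0.3))
  s2 <- simulate_flow(m, props, coil, drv, cfg, sample_times = c(0.15, 0.3))
  expect_identical(s1$final_state$u, s2$final_state$u)
  expect_identical(s1$final_state$p, s2$final_state$p)
  expect_identical(s1$peak_state$t, s2$peak_state$t)

  # requested sample instants are hit exactly; exports are readable text
  expect_length(s1$states, 2)
  expect_equal(vapply(s1$states, `[[`, 0, "t"), c(0.15, 0.3),
               tolerance = 1e-9)
  vtk <- tempfile(fileext = ".vtk")
  write_state_vtk(s1$peak_state, m, props, vtk)
  expect_true(any(grepl("VECTORS velocity", readLines(vtk))))
  expect_error(simulate_flow(m, props, coil, drv, cfg, sample_times = 99),
               class = "aneuflow_domain_error")

  # post-projection divergence below 10 * poisson_tol * (u_char / dx)
  st <- s1$final_state
  nx <- m$grid$nx; ny <- m$grid$ny
  dx_m <- m$grid$dx * 1e-3
  div <- (st$u[2:(nx + 1), ] - st$u[1:nx, ] +
            st$v[, 2:(ny + 1)] - st$v[, 1:ny]) / dx_m
  act <- m$cell_label == 1L | m$cell_label == 3L
  u_char <- max(abs(st$u), abs(st$v), cfg$u_floor)
  expect_lt(max(abs(div[act])), 10 * cfg$poisson_tol * u_char / dx_m)
  # outer (continuity) residual criterion of the study
  expect_lt(s1$diagnostics$final_residual, cfg$outer_residual_tol)
})

test_that("the uncoiled limit reproduces the plain Newtonian run", {
  m <- build_idealized_geometry(aneurysm_params(36.6, 1.9, porosity = 0.9),
                                dx = 0.4, lu_widths = 2, ld_widths = 2)
  props <- newtonian_props(0.004)
  drv <- pressure_drive(0.2, function(t) rep(30, length(t)), 1)
  plain <- simulate_flow(m, props, no_coil(), drv)
  # porosity -> 1: permeability diverges, the sink vanishes
  open_coil <- coil_model(1 - 1e-9, 0.25e-3)
  limit <- simulate_flow(m, props, open_coil, drv)
  expect_equal(limit$final_state$u, plain$final_state$u, tolerance = 1e-12)
  expect_equal(limit$final_state$p, plain$final_state$p, tolerance = 1e-10)
})

test_that("inlet and outlet fluxes agree for quasi-steady flow", {
  m <- channel_mask(1, 10, dx = 0.1)
  props <- newtonian_props(0.0035)
  drv <- constant_drive(21, t_total = 1, n_cycles = 5)
  sim <- simulate_flow(m, props, no_coil(), drv)
  st <- sim$final_state
  dx_m <- m$grid$dx * 1e-3
  nx <- m$grid$nx
  qin <- sum(st$u[1, ]) * dx_m
  qout <- sum(st$u[nx + 1, ]) * dx_m
  expect_lt(abs(qin - qout) / abs(qin), 0.01)
})

test_that("solver configuration is validated", {
  expect_error(solver_config(advection_scheme = "quick"),
               class = "aneuflow_config_error")
  expect_error(solver_config(dt_cfl_safety = 0.9),
               class = "aneuflow_config_error")
  expect_error(solver_config(poisson_tol = 1e-3),
               class = "aneuflow_config_error")
})

test_that("sac-averaged velocity is grid-converged on a reduced case", {
  props <- derive_casson_parameters(0.45)
  w <- waveform(n_cycles = 1, period = 0.4)
  drv <- as_pressure_drive(w, 40)
  v <- vapply(c(0.4, 0.2), function(dx) {
    m <- build_idealized_geometry(aneurysm_params(36.6, 1.9), dx = dx,
                                  lu_widths = 2.5, ld_widths = 2,
                                  coiled = FALSE)
    sim <- simulate_flow(m, props, coil_model(NA, enabled = FALSE), drv)
    sac_mean_velocity(sim$peak_state, m)
  }, 0)
  expect_lt(abs(v[1] - v[2]) / v[2], 0.05)
})
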