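#' Numerical configuration of the flow solver
#'
#' The solver advances the incompressible momentum equations with explicit
#' first-order upwind advection and explicit variable-viscosity diffusion,
#' an implicit (pointwise) Darcy sink, and a pressure projection onto the
#' discretely divergence-free space. The time step is
#' `dt = dt_cfl_safety / (|u|_max/dx + 4 nu_max/dx^2)` (combined
#' advective-viscous limit). In explicit projection stepping the momentum
#' equations are satisfied exactly; the governing-equation residual reported
#' is the normalized continuity residual after projection, required to stay
#' below `outer_residual_tol` (default 1e-4).
#'
#' @param dt_cfl_safety time-step safety factor in `(0, 0.5]`.
#' @param poisson_tol relative residual tolerance of the inner
#'   pressure-Poisson conjugate-gradient solve.
#' @param outer_residual_tol outer (continuity) residual criterion.
#' @param max_poisson_iters CG iteration cap per step.
#' @param advection_scheme `"upwind1"` (implemented) or `"quick"`
#'   (reserved; requesting it errors).
#' @param mu_cap stability ceiling on the effective viscosity, Pa.s. The
#'   regularized Casson law is unbounded as shear vanishes; the cap (binding
#'   only below about 0.3 1/s at default blood parameters) keeps the explicit
#'   diffusion limit practical.
#' @param u_floor velocity floor for the CFL estimate and residual
#'   normalization, m/s.
#' @param max_steps hard cap on time steps.
#' @param flux_every record the inlet-flux series every this many steps.
#' @param seed integer; unused by the deterministic solver, reserved.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(dt_cfl_safety = 0.4, poisson_tol = 1e-6,
                          outer_residual_tol = 1e-4,
                          max_poisson_iters = 20000,
                          advection_scheme = c("upwind1", "quick"),
                          mu_cap = 0.04, u_floor = 0.05,
                          max_steps = 5e6, flux_every = 1, seed = NULL) {
  advection_scheme <- match.arg(advection_scheme)
  if (advection_scheme == "quick")
    stop_aneuflow("advection_scheme 'quick' is reserved but not implemented",
                  "aneuflow_config_error")
  if (dt_cfl_safety <= 0 || dt_cfl_safety > 0.5)
    stop_aneuflow("dt_cfl_safety must be in (0, 0.5]", "aneuflow_config_error")
  if (poisson_tol >= outer_residual_tol)
    stop_aneuflow("poisson_tol must be < outer_residual_tol", "aneuflow_config_error")
  structure(list(dt_cfl_safety = dt_cfl_safety, poisson_tol = poisson_tol,
                 outer_residual_tol = outer_residual_tol,
                 max_poisson_iters = as.integer(max_poisson_iters),
                 advection_scheme = advection_scheme,
                 mu_cap = mu_cap, u_floor = u_floor,
                 max_steps = as.integer(max_steps),
                 flux_every = as.integer(flux_every), seed = seed),
            class = "solver_config")
}

#' Flow state at one time instant
#'
#' Staggered velocity components (`u` on x-faces, `(nx+1) x ny`; `v` on
#' y-faces, `nx x (ny+1)`) and cell-centered gauge pressure (`nx x ny`).
#'
#' @param mask a `geometry_mask`.
#' @param t time, s.
#' @return an object of class `flow_state` at rest.
#' @export
init_flow_state <- function(mask, t = 0) {
  nx <- mask$grid$nx; ny <- mask$grid$ny
  structure(list(u = matrix(0, nx + 1, ny), v = matrix(0, nx, ny + 1),
                 p = matrix(0, nx, ny), t = t, cycle_index = 0L),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("flow_state at t = %.5f s (cycle %d): max |u| = %.4g m/s, p in [%.4g, %.4g] Pa\n",
              x$t, x$cycle_index, max(abs(x$u), abs(x$v)),
              min(x$p), max(x$p)))
  invisible(x)
}

as_flow_state <- function(raw, period) {
  structure(list(u = raw$u, v = raw$v, p = raw$p, t = raw$t,
                 cycle_index = as.integer(floor(raw$t / period + 1e-9))),
            class = "flow_state")
}

solver_args <- function(mask, props, coil, drive, cfg) {
  dx_m <- mm_to_m(mask$grid$dx)
  tab <- drive_table(drive)
  mu_cap <- max(cfg$mu_cap, 1.0001 * props$casson_viscosity)
  list(cell = mask$cell_label, dx = dx_m,
       rho = props$density, tau_y = props$yield_stress,
       mu_c = props$casson_viscosity, m = props$regularization_m,
       mu_cap = mu_cap,
       coil_on = isTRUE(coil$enabled), K = coil$permeability,
       drive_t = tab[, 1], drive_p = tab[, 2], period = drive$period)
}

#' Advance the flow by a single time step
#'
#' One fractional step: shear-rate and effective-viscosity evaluation,
#' explicit advection + diffusion with the implicit Darcy factor, pressure
#' Poisson solve with the drive's inlet pressure and 0-gauge outlet, and
#' projection to a discretely divergence-free field.
#'
#' @param state a `flow_state`.
#' @param mask a `geometry_mask`.
#' @param props a [blood_properties()].
#' @param coil a [coil_model()].
#' @param drive a [pressure_drive()].
#' @param cfg a [solver_config()].
#' @return list with the advanced `state` and step `diagnostics`.
#' @export
flow_step <- function(state, mask, props, coil, drive, cfg = solver_config()) {
  a <- solver_args(mask, props, coil, drive, cfg)
  raw <- cpp_flow_run(a$cell, a$dx, state$u, state$v, state$p,
                      state$t, Inf, 1L,
                      a$rho, a$tau_y, a$mu_c, a$m, a$mu_cap,
                      a$coil_on, a$K, a$drive_t, a$drive_p, a$period,
                      numeric(0), numeric(0), numeric(0),
                      Inf, -Inf,
                      cfg$dt_cfl_safety, cfg$poisson_tol,
                      cfg$max_poisson_iters, cfg$u_floor,
                      drive$period / 400, cfg$flux_every)
  list(state = as_flow_state(raw, drive$period), diagnostics = raw$diag)
}

#' Simulate pulsatile flow over the drive's cycles
#'
#' Runs `drive$n_cycles` periods from rest (`t = 0` on the cardiac cycle)
#' and returns: states at `sample_times`, the state at peak systole of the
#' final cycle (the instant of maximum inlet flux there, since flow lags the
#' pressure waveform), `n_osi` uniformly spaced velocity snapshots of the
#' final cycle for OSI quadrature, the inlet-flux time series, and solver
#' diagnostics. Fully deterministic given identical inputs.
#'
#' @inheritParams flow_step
#' @param sample_times times (s) at which full states are recorded.
#' @param n_osi number of uniformly spaced final-cycle velocity snapshots
#'   (>= 20 for OSI).
#' @return an object of class `flow_result`.
#' @export
simulate_flow <- function(mask, props, coil, drive, cfg = solver_config(),
                          sample_times = NULL, n_osi = 24) {
  stopifnot(n_osi >= 20)
  a <- solver_args(mask, props, coil, drive, cfg)
  T <- drive$period; nc <- drive$n_cycles
  t_end <- nc * T
  if (!is.null(sample_times) &&
      (any(sample_times < 0) || any(sample_times > t_end)))
    stop_aneuflow("sample_times must lie in [0, n_cycles * T]",
                  "aneuflow_domain_error")
  osi_times <- (nc - 1) * T + seq_len(n_osi) / n_osi * T
  cyc_times <- seq_len(nc) * T
  st0 <- init_flow_state(mask)
  raw <- cpp_flow_run(a$cell, a$dx, st0$u, st0$v, st0$p,
                      0, t_end, cfg$max_steps,
                      a$rho, a$tau_y, a$mu_c, a$m, a$mu_cap,
                      a$coil_on, a$K, a$drive_t, a$drive_p, a$period,
                      sample_times %||% numeric(0), osi_times, cyc_times,
                      (nc - 1) * T, nc * T,
                      cfg$dt_cfl_safety, cfg$poisson_tol,
                      cfg$max_poisson_iters, cfg$u_floor,
                      T / 400, cfg$flux_every)
  diag <- raw$diag
  diag$steps <- raw$steps
  diag$converged <- is.finite(diag$final_residual) &&
    diag$final_residual < cfg$outer_residual_tol
  peak <- as_flow_state(raw$peak, T)
  structure(list(
    states = lapply(raw$states, as_flow_state, period = T),
    peak_state = peak,
    peak_flux = raw$peak$flux,
    final_state = as_flow_state(raw, T),
    osi_snapshots = raw$osi,
    flux = raw$flux,
    diagnostics = diag,
    period = T, n_cycles = nc
  ), class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow_result: %d cycle(s) of T = %.4g s, %d steps\n",
              x$n_cycles, x$period, as.integer(x$diagnostics$steps)))
  cat(sprintf("  peak systole (max inlet flux) at t = %.4f s, flux %.4g m^2/s\n",
              x$peak_state$t, x$peak_flux))
  cat(sprintf("  final continuity residual %.3g (converged: %s), cycle-to-cycle delta %.3g\n",
              x$diagnostics$final_residual, x$diagnostics$converged,
              x$diagnostics$cycle_delta))
  invisible(x)
}

#' Cell-centered velocity components and speed
#'
#' Interpolates the staggered face velocities to cell centers.
#'
#' @param state a `flow_state`.
#' @return list of `nx x ny` matrices `uc`, `vc`, `speed` (m/s).
#' @export
cell_velocity <- function(state) {
  u <- state$u; v <- state$v
  nx <- nrow(u) - 1; ny <- ncol(u)
  uc <- (u[1:nx, , drop = FALSE] + u[2:(nx + 1), , drop = FALSE]) / 2
  vc <- (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1), drop = FALSE]) / 2
  list(uc = uc, vc = vc, speed = sqrt(uc^2 + vc^2))
}

#' Export a flow state as a legacy VTK structured-points file
#'
#' Cell-centered velocity, pressure, effective viscosity and cell label.
#'
#' @param state a `flow_state`.
#' @param mask a `geometry_mask`.
#' @param props a [blood_properties()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_state_vtk <- function(state, mask, props, path) {
  g <- mask$grid
  cv <- cell_velocity(state)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aneuflow flow state", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", g$nx, g$ny),
               sprintf("ORIGIN %g %g 0", g$origin[1] + g$dx / 2,
                       g$origin[2] + g$dx / 2),
               sprintf("SPACING %g %g 1", g$dx, g$dx),
               sprintf("POINT_DATA %d", g$nx * g$ny),
               "VECTORS velocity float"), con)
  writeLines(paste(sprintf("%g %g 0", as.vector(cv$uc), as.vector(cv$vc)),
                   collapse = "\n"), con)
  writeLines(c("SCALARS pressure float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(state$p), collapse = " "), con)
  writeLines(c("SCALARS cell_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(mask$cell_label), collapse = " "), con)
  invisible(path)
}
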