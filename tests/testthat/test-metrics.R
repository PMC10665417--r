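mk_state <- function(mask, u = 0, v = 0, p = 0) {
  st <- init_flow_state(mask)
  st$u[] <- u; st$v[] <- v; st$p[] <- p
  st
}

test_that("sac-wall mean pressure averages the wall-adjacent sac cells", {
  m <- build_idealized_geometry(aneurysm_params(36.6, 1.9), dx = 0.2)
  st <- mk_state(m, p = 123.4)
  expect_equal(sac_wall_mean_pressure(st, m), 123.4)
  # linear field p = alpha * x: symmetric sac -> value at the centroid x
  g <- m$grid
  xc <- m$sac$center[1]
  xs <- g$origin[1] + (seq_len(g$nx) - 0.5) * g$dx
  st$p <- matrix(xs, g$nx, g$ny) * 2.5
  expect_lt(abs(sac_wall_mean_pressure(st, m) - 2.5 * xc),
            2.5 * 2 * g$dx)
})

test_that("sac velocity statistics follow counting constructions", {
  m <- build_idealized_geometry(aneurysm_params(36.6, 1.9), dx = 0.2)
  st <- mk_state(m)
  expect_equal(sac_mean_velocity(st, m), 0)
  st$u[] <- 0.07
  expect_equal(sac_mean_velocity(st, m), 0.07, tolerance = 1e-12)
  expect_equal(sac_max_velocity(st, m), 0.07, tolerance = 1e-12)

  # half the sac moving at 0.2: mean 0.1 up to one-cell rounding at the split
  g <- m$grid
  xc <- m$sac$center[1]
  xf <- g$origin[1] + (seq_len(g$nx + 1) - 1) * g$dx  # u-face x positions
  st2 <- mk_state(m)
  st2$u[xf < xc, ] <- 0.2
  sel <- m$region_label == 3L & m$cell_label %in% c(1L, 3L)
  spd <- cell_velocity(st2)$speed
  expected <- mean(spd[sel])  # counting oracle on the constructed field
  expect_equal(sac_mean_velocity(st2, m), expected)
  n_bnd <- sum(sel & abs(matrix(xf[-1] - g$dx / 2, g$nx, g$ny) - xc) < g$dx)
  expect_lt(abs(sac_mean_velocity(st2, m) - 0.1), 0.2 * n_bnd / sum(sel) + 0.01)
})

test_that("exceedance fraction counts sac cells above threshold", {
  m <- build_idealized_geometry(aneurysm_params(36.6, 1.9), dx = 0.2)
  st <- mk_state(m)
  expect_equal(exceedance_fraction(st, m), 0)
  st$u[] <- 0.5
  expect_equal(exceedance_fraction(st, m), 1)
  # exactly one sac cell above threshold
  sel <- which(m$region_label == 3L & m$cell_label %in% c(1L, 3L),
               arr.ind = TRUE)
  N <- nrow(sel)
  st1 <- mk_state(m)
  ij <- sel[which.max(sel[, 2]), ]  # dome cell, neighbours are wall/sac
  st1$u[ij[1], ij[2]] <- 0.3; st1$u[ij[1] + 1, ij[2]] <- 0.3
  expect_equal(exceedance_fraction(st1, m, threshold = 0.15), 1 / N)
  expect_error(exceedance_fraction(st, m, threshold = -1),
               class = "aneuflow_domain_error")
})

test_that("wall shear stress matches the Poiseuille wall value", {
  m <- channel_mask(1, 8, dx = 0.1)
  g <- m$grid
  a <- 1e-3; mu <- 0.0035; G <- 2000  # Pa/m
  props <- newtonian_props(mu)
  # fill the channel with the analytic parabola (y measured from bottom wall)
  st <- init_flow_state(m)
  y0 <- m$channel$y0 * 1e-3
  yc <- (g$origin[2] + (seq_len(g$ny) - 0.5) * g$dx) * 1e-3
  uprof <- poiseuille_profile(pmin(pmax(yc - y0, 0), 2 * a), G, a, mu)
  st$u <- matrix(rep(uprof, each = g$nx + 1), g$nx + 1, g$ny)
  wss <- wall_shear_stress(st, m, props)
  chan <- wss$side %in% c("N", "S") & wss$region == 1L
  expect_true(any(chan))
  expect_lt(max(abs(abs(wss$tau[chan]) - G * a)) / (G * a), 0.05)
  # zero flow -> zero WSS; reversal flips the sign
  expect_true(all(wall_shear_stress(init_flow_state(m), m, props)$tau == 0))
  str <- st; str$u <- -st$u
  expect_equal(wall_shear_stress(str, m, props)$tau, -wss$tau,
               tolerance = 1e-12)
})

test_that("OSI reproduces its closed-form cases and bounds", {
  times <- seq(0, 1, length.out = 41)
  mkser <- function(f) lapply(times, function(t)
    data.frame(i = 1:3, j = 1, side = "N", region = 1L, tau = f(t)))
  # constant positive shear: no reversal
  osi_c <- oscillatory_shear_index(mkser(function(t) c(1, 2, 3)), times)
  expect_equal(osi_c$osi, c(0, 0, 0))
  # zero-mean sinusoid: full reversal
  osi_s <- oscillatory_shear_index(
    mkser(function(t) rep(sin(2 * pi * t), 3)), times)
  expect_equal(osi_s$osi, rep(0.5, 3), tolerance = 1e-6)
  # offset sinusoid that never reverses
  osi_o <- oscillatory_shear_index(
    mkser(function(t) rep(1 + 0.5 * sin(2 * pi * t), 3)), times)
  expect_equal(osi_o$osi, rep(0, 3), tolerance = 1e-9)
  # all-zero shear: 0 by convention
  expect_equal(oscillatory_shear_index(mkser(function(t) rep(0, 3)),
                                       times)$osi, rep(0, 3))
  # bounds for arbitrary series
  set.seed(42)
  for (k in 1:5) {
    amp <- runif(3, 0, 2); off <- runif(3, -1, 1); ph <- runif(3, 0, 2 * pi)
    osi_r <- oscillatory_shear_index(
      mkser(function(t) off + amp * sin(2 * pi * t + ph)), times)
    expect_true(all(osi_r$osi >= 0 & osi_r$osi <= 0.5))
  }
  expect_error(oscillatory_shear_index(mkser(function(t) 1:3)[1:10],
                                       times[1:10]),
               class = "aneuflow_domain_error")
})

test_that("streamlines follow uniform and rotational test fields", {
  m <- channel_mask(5, 30, dx = 0.25)  # wide channel
  st <- mk_state(m, u = 0.2)
  sl <- streamlines(st, m, cbind(2, m$channel$y0 + 5), max_steps = 200)[[1]]
  expect_gt(nrow(sl), 50)
  expect_lt(diff(range(sl$y)), 1e-9)
  expect_equal(unique(round(sl$speed, 12)), 0.2)

  # solid-body rotation about the channel center: circles close on themselves
  g <- m$grid
  xc <- g$origin[1] + g$nx * g$dx / 2
  yc <- (m$channel$y0 + m$channel$y1) / 2
  om <- 50  # 1/s
  xu <- g$origin[1] + (seq_len(g$nx + 1) - 1) * g$dx
  ycen <- g$origin[2] + (seq_len(g$ny) - 0.5) * g$dx
  st2 <- init_flow_state(m)
  st2$u <- outer(xu, ycen, function(x, y) -om * (y - yc) * 1e-3)
  xcen <- g$origin[1] + (seq_len(g$nx) - 0.5) * g$dx
  yv <- g$origin[2] + (seq_len(g$ny + 1) - 1) * g$dx
  st2$v <- outer(xcen, yv, function(x, y) om * (x - xc) * 1e-3)
  r0 <- 3
  sl2 <- streamlines(st2, m, cbind(xc + r0, yc), step = 0.2,
                     max_steps = 2500)[[1]]
  rr <- sqrt((sl2$x - xc)^2 + (sl2$y - yc)^2)
  expect_lt(max(abs(rr - r0)) / r0, 0.02)

  expect_error(streamlines(st, m, cbind(2, g$origin[2] + 0.3)),
               class = "aneuflow_seed_error")
})

test_that("summary scalars are invariant under mirroring the geometry", {
  props <- derive_casson_parameters(0.45)
  coil <- coil_model(0.85, 0.25e-3)
  drv <- as_pressure_drive(waveform(n_cycles = 1, period = 0.4), 40)
  p <- aneurysm_params(36.6, 1.9, porosity = 0.85)
  s <- lapply(c("top", "bottom"), function(side) {
    m <- build_idealized_geometry(p, dx = 0.35, lu_widths = 2.5,
                                  ld_widths = 2, side = side)
    hemodynamic_summary(simulate_flow(m, props, coil, drv), m, props)
  })
  for (f in c("mean_sac_wall_pressure", "mean_sac_velocity",
              "max_sac_velocity", "mean_sac_wall_wss", "max_osi",
              "exceedance_fraction"))
    expect_equal(s[[1]][[f]], s[[2]][[f]], tolerance = 1e-4,
                 label = f)
})
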