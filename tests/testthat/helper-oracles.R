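# Analytic oracles and programmatic fixtures shared across the suite.

# ---- channel-flow closed forms -------------------------------------------

# steady plane Poiseuille: u(y) = G/(2 mu) * y * (2a - y), y from wall
poiseuille_profile <- function(y, G, a, mu) G / (2 * mu) * y * (2 * a - y)

# oscillatory plane-channel flow driven by G0*cos(omega t):
# complex amplitude across the half-width coordinate yc in [-a, a]
oscillatory_channel_amplitude <- function(yc, G0, rho, nu, omega, a) {
  k <- sqrt(1i * omega / nu)
  Mod(G0 / (rho * omega) * (1 - cosh(k * yc) / cosh(k * a)))
}

# steady Casson plane channel under gradient G (wall shear tau_w = G a):
# yielded for |yc| > yp = tau_y / G; analytic velocity with y measured
# from the centerline
casson_channel_profile <- function(yc, G, a, tau_y, mu_c) {
  yp <- tau_y / G
  u_at <- function(yy) {
    y <- max(abs(yy), yp)
    (G * (a^2 - y^2) / 2 - (4 / 3) * sqrt(tau_y * G) *
        (a^1.5 - y^1.5) + tau_y * (a - y)) / mu_c
  }
  vapply(yc, u_at, 0)
}

# per-width flux of the Casson channel by fine quadrature of the profile
casson_channel_flux <- function(G, a, tau_y, mu_c, n = 20000) {
  y <- seq(-a, a, length.out = n)
  u <- casson_channel_profile(y, G, a, tau_y, mu_c)
  sum((u[-1] + u[-n]) / 2) * (2 * a / (n - 1))
}

# ---- mask constructions ---------------------------------------------------

# straight channel of half-width a_mm, length L_mm
channel_mask <- function(a_mm, L_mm, dx) {
  p <- suppressWarnings(aneuflow::aneurysm_params(0, a_mm))
  W <- 2 * a_mm
  aneuflow::build_idealized_geometry(p, dx = dx,
                                     lu_widths = L_mm / (2 * W),
                                     ld_widths = L_mm / (2 * W))
}

# channel with the fluid interior converted to a porous (COIL) plug
porous_channel_mask <- function(a_mm, L_mm, dx) {
  m <- channel_mask(a_mm, L_mm, dx)
  fl <- m$cell_label == 1L
  m$cell_label[fl] <- 3L
  m$region_label[fl] <- 3L
  aneuflow::validate_geometry_mask(m)
  m
}

newtonian_props <- function(mu, rho = 1050) {
  aneuflow::blood_properties(density = rho, plasma_viscosity = mu,
                             casson_viscosity = mu, yield_stress = 0)
}

no_coil <- function() aneuflow::coil_model(NA, enabled = FALSE)

constant_drive <- function(dp, t_total, n_cycles = 10) {
  aneuflow::pressure_drive(t_total / n_cycles,
                           function(t) rep(dp, length(t)), n_cycles)
}

# ---- STL fixtures ---------------------------------------------------------

# open cylinder along z: radius r, from z = 0 to z = L
stl_cylinder <- function(r, L, n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  tri <- matrix(NA_real_, 0, 9)
  for (k in seq_len(n)) {
    p1 <- c(r * cos(th[k]), r * sin(th[k]), 0)
    p2 <- c(r * cos(th[k + 1]), r * sin(th[k + 1]), 0)
    p3 <- c(r * cos(th[k]), r * sin(th[k]), L)
    p4 <- c(r * cos(th[k + 1]), r * sin(th[k + 1]), L)
    tri <- rbind(tri, c(p1, p2, p3), c(p2, p4, p3))
  }
  tri
}

# closed lat-long sphere of radius r centered at the origin
stl_sphere <- function(r, nlat = 32, nlon = 48) {
  phi <- seq(0, pi, length.out = nlat + 1)
  th <- seq(0, 2 * pi, length.out = nlon + 1)
  pt <- function(ph, t) r * c(sin(ph) * cos(t), sin(ph) * sin(t), cos(ph))
  tri <- matrix(NA_real_, 0, 9)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    p1 <- pt(phi[i], th[j]); p2 <- pt(phi[i + 1], th[j])
    p3 <- pt(phi[i], th[j + 1]); p4 <- pt(phi[i + 1], th[j + 1])
    if (i > 1) tri <- rbind(tri, c(p1, p2, p3))
    if (i < nlat) tri <- rbind(tri, c(p2, p4, p3))
  }
  tri
}

# binary little-endian STL writer (fixture only)
write_stl_binary <- function(triangles, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(triangles)), con, size = 4, endian = "little")
  for (k in seq_len(nrow(triangles))) {
    writeBin(numeric(3), con, size = 4, endian = "little")  # normal
    writeBin(as.numeric(triangles[k, ]), con, size = 4, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
  invisible(path)
}

# reduced-resolution campaign settings used by direction checks: a short
# domain and dx = 0.3 mm keep a 9-run CCD inside the test budget
reduced_campaign_config <- function(factors, ...) {
  aneuflow::campaign_config(factors = factors, dx = 0.3,
                            lu_widths = 4, ld_widths = 3, ...)
}
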