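# Per-run hemodynamic responses: sac-wall pressure, sac-averaged velocity,
# exceedance fraction, wall shear stress, OSI, streamlines.

active_cells <- function(mask) {
  mask$cell_label == CELL_FLUID | mask$cell_label == CELL_COIL
}

sac_cells <- function(mask) {
  active_cells(mask) & mask$region_label == REGION_SAC
}

#' Mean sac-wall pressure
#'
#' Arithmetic mean of cell gauge pressure over the FLUID/COIL cells of the
#' SAC region that are 4-adjacent to a WALL cell — the discrete sac wall.
#' Intended for states sampled at peak systole.
#'
#' @param state a `flow_state`.
#' @param mask a `geometry_mask`.
#' @return mean pressure, Pa gauge (relative to the outlet).
#' @export
sac_wall_mean_pressure <- function(state, mask) {
  sel <- sac_cells(mask) & wall_adjacent4(mask)
  if (!any(sel))
    stop_aneuflow("no sac-wall cells in mask (straight channel?)",
                  "aneuflow_geometry_error")
  mean(state$p[sel])
}

wall_adjacent4 <- function(mask) {
  cell <- mask$cell_label
  nx <- nrow(cell); ny <- ncol(cell)
  wall <- cell == CELL_WALL
  adj <- matrix(FALSE, nx, ny)
  adj[1:(nx - 1), ] <- adj[1:(nx - 1), ] | wall[2:nx, ]
  adj[2:nx, ] <- adj[2:nx, ] | wall[1:(nx - 1), ]
  adj[, 1:(ny - 1)] <- adj[, 1:(ny - 1)] | wall[, 2:ny]
  adj[, 2:ny] <- adj[, 2:ny] | wall[, 1:(ny - 1)]
  adj
}

#' Sac-averaged velocity magnitude
#'
#' Mean of the cell-centered speed over all SAC cells (COIL included).
#'
#' @inheritParams sac_wall_mean_pressure
#' @return mean speed, m/s.
#' @export
sac_mean_velocity <- function(state, mask) {
  sel <- sac_cells(mask)
  if (!any(sel))
    stop_aneuflow("mask has no SAC cells", "aneuflow_geometry_error")
  mean(cell_velocity(state)$speed[sel])
}

#' Maximum sac velocity magnitude
#'
#' @inheritParams sac_wall_mean_pressure
#' @return maximum cell-centered speed over SAC cells, m/s.
#' @export
sac_max_velocity <- function(state, mask) {
  sel <- sac_cells(mask)
  if (!any(sel))
    stop_aneuflow("mask has no SAC cells", "aneuflow_geometry_error")
  max(cell_velocity(state)$speed[sel])
}

#' Velocity-exceedance fraction inside the sac
#'
#' Fraction of SAC cells whose speed exceeds a threshold — the 2D analogue
#' of comparing velocity iso-surfaces (default threshold 0.15 m/s).
#'
#' @inheritParams sac_wall_mean_pressure
#' @param threshold speed threshold, m/s (> 0).
#' @return fraction in `[0, 1]`.
#' @export
exceedance_fraction <- function(state, mask, threshold = 0.15) {
  if (threshold <= 0)
    stop_aneuflow("threshold must be > 0", "aneuflow_domain_error")
  sel <- sac_cells(mask)
  if (!any(sel))
    stop_aneuflow("mask has no SAC cells", "aneuflow_geometry_error")
  mean(cell_velocity(state)$speed[sel] > threshold)
}

#' Wall shear stress field
#'
#' One-sided first-order wall shear stress for every active cell face
#' touching a WALL cell: `tau_w = mu_eff * u_t / (dx/2)`, with the
#' tangential cell-centered velocity `u_t`, the wall-normal distance
#' `dx/2` from cell center to the wall face, and the effective viscosity
#' evaluated at the local wall shear rate `|u_t| / (dx/2)`. The sign of
#' `tau_w` follows the sign of `u_t`, so flow reversal flips it.
#'
#' @inheritParams sac_wall_mean_pressure
#' @param props a [blood_properties()].
#' @return data.frame with columns `i`, `j` (cell), `side` (`"N"`, `"S"`,
#'   `"E"`, `"W"`: where the wall lies), `region`, `tau` (Pa, signed).
#' @export
wall_shear_stress <- function(state, mask, props) {
  cell <- mask$cell_label
  nx <- nrow(cell); ny <- ncol(cell)
  act <- active_cells(mask)
  wall <- cell == CELL_WALL
  cv <- cell_velocity(state)
  h <- mm_to_m(mask$grid$dx) / 2
  out <- list()
  side_defs <- list(
    N = list(di = 0, dj = 1, tang = cv$uc),
    S = list(di = 0, dj = -1, tang = cv$uc),
    E = list(di = 1, dj = 0, tang = cv$vc),
    W = list(di = -1, dj = 0, tang = cv$vc))
  for (s in names(side_defs)) {
    d <- side_defs[[s]]
    ii <- seq_len(nx); jj <- seq_len(ny)
    ok <- matrix(FALSE, nx, ny)
    is <- ii[ii + d$di >= 1 & ii + d$di <= nx]
    js <- jj[jj + d$dj >= 1 & jj + d$dj <= ny]
    ok[is, js] <- act[is, js] & wall[is + d$di, js + d$dj]
    if (!any(ok)) next
    idx <- which(ok, arr.ind = TRUE)
    ut <- d$tang[ok]
    gdot <- abs(ut) / h
    tau <- effective_viscosity(gdot, props) * ut / h
    out[[s]] <- data.frame(i = idx[, 1], j = idx[, 2], side = s,
                           region = mask$region_label[ok], tau = tau)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 * (1 - |int tau dt| / int |tau| dt)` by trapezoidal quadrature
#' over one cycle: 0 where shear never reverses, approaching 0.5 for
#' zero-mean reversal. Locations with identically zero shear get OSI 0 by
#' convention.
#'
#' @param wss_series list of wall fields (as returned by
#'   [wall_shear_stress()], identical row layout) time-ordered over exactly
#'   one period; at least 20 samples.
#' @param times sample times, s, same length as `wss_series`.
#' @return the first field's `i`, `j`, `side`, `region` columns plus `osi`.
#' @export
oscillatory_shear_index <- function(wss_series, times) {
  if (length(wss_series) < 20)
    stop_aneuflow("OSI needs >= 20 samples spanning one period",
                  "aneuflow_domain_error")
  if (length(times) != length(wss_series))
    stop_aneuflow("times must match wss_series", "aneuflow_domain_error")
  tau <- sapply(wss_series, `[[`, "tau")  # nloc x nt
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = 1)
  dt <- diff(times)
  trapz <- function(x) as.vector((x[, -ncol(x), drop = FALSE] +
                                    x[, -1, drop = FALSE]) %*% dt / 2)
  num <- abs(trapz(tau))
  den <- trapz(abs(tau))
  osi <- ifelse(den <= 0, 0, 0.5 * (1 - num / den))
  osi <- pmin(pmax(osi, 0), 0.5)
  out <- wss_series[[1]][c("i", "j", "side", "region")]
  out$osi <- osi
  out
}

# Bilinear interpolation of the staggered field at physical point (x, y) mm.
interp_velocity <- function(state, mask, x, y) {
  g <- mask$grid
  dx <- g$dx
  # u faces at (i*dx, (j-0.5)*dx), i = 0..nx
  xi <- (x - g$origin[1]) / dx
  yj <- (y - g$origin[2]) / dx
  bil <- function(M, fx, fy) {
    i0 <- floor(fx); j0 <- floor(fy)
    i0 <- min(max(i0, 0), nrow(M) - 2); j0 <- min(max(j0, 0), ncol(M) - 2)
    ax <- fx - i0; ay <- fy - j0
    M[i0 + 1, j0 + 1] * (1 - ax) * (1 - ay) + M[i0 + 2, j0 + 1] * ax * (1 - ay) +
      M[i0 + 1, j0 + 2] * (1 - ax) * ay + M[i0 + 2, j0 + 2] * ax * ay
  }
  c(u = bil(state$u, xi, yj - 0.5), v = bil(state$v, xi - 0.5, yj))
}

#' Streamlines of a flow state
#'
#' Fourth-order Runge-Kutta integration of the interpolated velocity field
#' with a fixed step, from each seed until the trajectory leaves the flow
#' domain, hits a wall, or reaches `max_steps`. Each polyline carries the
#' local speed.
#'
#' @inheritParams sac_wall_mean_pressure
#' @param seeds numeric matrix (n x 2) of seed points, mm.
#' @param step integration step as a fraction of dx.
#' @param max_steps maximum integration steps per streamline.
#' @return list of data.frames with columns `x`, `y` (mm), `speed` (m/s).
#' @export
streamlines <- function(state, mask, seeds, step = 0.25, max_steps = 5000) {
  seeds <- matrix(as.numeric(seeds), ncol = 2)
  g <- mask$grid
  act <- active_cells(mask)
  inside <- function(x, y) {
    i <- floor((x - g$origin[1]) / g$dx) + 1
    j <- floor((y - g$origin[2]) / g$dx) + 1
    i >= 1 && i <= g$nx && j >= 1 && j <= g$ny && act[i, j]
  }
  h_mm <- step * g$dx
  lapply(seq_len(nrow(seeds)), function(s) {
    x <- seeds[s, 1]; y <- seeds[s, 2]
    if (!inside(x, y))
      stop_aneuflow(sprintf("seed (%g, %g) outside the flow domain", x, y),
                    "aneuflow_seed_error")
    xs <- numeric(0); ys <- numeric(0); sp <- numeric(0)
    for (k in seq_len(max_steps)) {
      uv <- interp_velocity(state, mask, x, y)
      spd <- sqrt(sum(uv^2))
      xs <- c(xs, x); ys <- c(ys, y); sp <- c(sp, spd)
      if (spd < 1e-12) break
      # RK4 on the direction field scaled to a fixed mm step
      f <- function(px, py) {
        w <- interp_velocity(state, mask, px, py)
        n <- sqrt(sum(w^2))
        if (n < 1e-12) c(0, 0) else w / n * h_mm
      }
      k1 <- f(x, y)
      k2 <- f(x + k1[1] / 2, y + k1[2] / 2)
      k3 <- f(x + k2[1] / 2, y + k2[2] / 2)
      k4 <- f(x + k3[1], y + k3[2])
      x1 <- x + (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]) / 6
      y1 <- y + (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]) / 6
      if (!inside(x1, y1)) break
      x <- x1; y <- y1
    }
    data.frame(x = xs, y = ys, speed = sp)
  })
}

#' Per-run hemodynamic summary
#'
#' The scalar responses of one simulated run, all from the final cycle:
#' mean sac-wall gauge pressure and sac velocity statistics at peak systole
#' (instant of maximum inlet flux), mean sac-wall WSS magnitude at the same
#' instant, maximum OSI over the wall, and the sac velocity-exceedance
#' fraction.
#'
#' @param sim a `flow_result` from [simulate_flow()].
#' @param mask a `geometry_mask`.
#' @param props a [blood_properties()].
#' @param threshold exceedance speed threshold, m/s.
#' @return an object of class `hemodynamic_summary`.
#' @export
hemodynamic_summary <- function(sim, mask, props, threshold = 0.15) {
  ps <- sim$peak_state
  wss_peak <- wall_shear_stress(ps, mask, props)
  sac_wall <- wss_peak$region == REGION_SAC
  osi_fields <- lapply(sim$osi_snapshots, function(sn) {
    st <- structure(list(u = sn$u, v = sn$v, p = ps$p, t = sn$t),
                    class = "flow_state")
    wall_shear_stress(st, mask, props)
  })
  osi <- oscillatory_shear_index(osi_fields,
                                 vapply(sim$osi_snapshots, `[[`, 0, "t"))
  structure(list(
    mean_sac_wall_pressure = sac_wall_mean_pressure(ps, mask),
    mean_sac_velocity = sac_mean_velocity(ps, mask),
    max_sac_velocity = sac_max_velocity(ps, mask),
    mean_sac_wall_wss = if (any(sac_wall)) mean(abs(wss_peak$tau[sac_wall]))
                        else NA_real_,
    max_osi = max(osi$osi),
    exceedance_fraction = exceedance_fraction(ps, mask, threshold),
    peak_systole_time_used = ps$t,
    threshold = threshold
  ), class = "hemodynamic_summary")
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat("hemodynamic_summary (peak systole of final cycle):\n")
  cat(sprintf("  mean sac-wall pressure : %.4g Pa gauge (%.3f mmHg)\n",
              x$mean_sac_wall_pressure, Pa_to_mmHg(x$mean_sac_wall_pressure)))
  cat(sprintf("  mean sac velocity      : %.4g m/s (max %.4g)\n",
              x$mean_sac_velocity, x$max_sac_velocity))
  cat(sprintf("  mean sac-wall WSS      : %.4g Pa\n", x$mean_sac_wall_wss))
  cat(sprintf("  max OSI                : %.4g\n", x$max_osi))
  cat(sprintf("  fraction |u| > %.2f   : %.4g\n", x$threshold,
              x$exceedance_fraction))
  cat(sprintf("  peak systole at t = %.4f s\n", x$peak_systole_time_used))
  invisible(x)
}
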