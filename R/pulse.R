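# Periodic Catmull-Rom (C1 cubic Hermite) machinery for the cardiac
# pressure waveform: four phase knots per period, periodic slopes.

catmull_rom_slopes <- function(tk, yk, period) {
  n <- length(tk)
  tprev <- c(tk[n] - period, tk[-n])
  tnext <- c(tk[-1], tk[1] + period)
  yprev <- c(yk[n], yk[-n])
  ynext <- c(yk[-1], yk[1])
  (ynext - yprev) / (tnext - tprev)
}

# Evaluate the periodic Hermite spline at times t (any real >= 0).
hermite_periodic_eval <- function(t, tk, yk, mk, period) {
  tt <- t - floor(t / period) * period
  n <- length(tk)
  t_ext <- c(tk, tk[1] + period)
  y_ext <- c(yk, yk[1])
  m_ext <- c(mk, mk[1])
  seg <- findInterval(tt, t_ext, rightmost.closed = TRUE)
  seg[seg < 1] <- 1; seg[seg > n] <- n
  h <- t_ext[seg + 1] - t_ext[seg]
  s <- (tt - t_ext[seg]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y_ext[seg] + h10 * h * m_ext[seg] +
    h01 * y_ext[seg + 1] + h11 * h * m_ext[seg + 1]
}

# Exact period mean of the Hermite spline (cubic integrals in closed form).
hermite_periodic_mean <- function(tk, yk, mk, period) {
  n <- length(tk)
  t_ext <- c(tk, tk[1] + period)
  y_ext <- c(yk, yk[1])
  m_ext <- c(mk, mk[1])
  h <- diff(t_ext)
  segint <- h * ((y_ext[-(n + 1)] + y_ext[-1]) / 2 +
                   h * (m_ext[-(n + 1)] - m_ext[-1]) / 12)
  sum(segint) / period
}

#' Pulsatile cardiac pressure waveform
#'
#' A T-periodic, C1-continuous pressure profile built as a periodic cubic
#' Hermite (Catmull-Rom) interpolant through four phase knots — the four
#' distinct stages of the cardiac cycle (late-diastolic upstroke, systolic
#' peak, dicrotic phase, diastolic decay) — scaled so the period mean equals
#' `mean_pressure` and the systolic maximum is `mean_pressure +
#' pulse_amplitude`. The waveform has exactly one global maximum per period;
#' its time defines peak systole `t_ps`.
#'
#' @param period cardiac period T, s.
#' @param mean_pressure period-mean pressure, Pa (default 100 mmHg).
#' @param pulse_amplitude systolic excess over the mean, Pa (default
#'   20 mmHg).
#' @param phase_knots 4 x 2 matrix: time fractions in `[0, 1)` (first
#'   column, strictly increasing) and dimensionless shape values (second).
#' @param n_cycles number of cardiac cycles to simulate (>= 1).
#' @return an object of class `waveform` with derived `peak_systole_time`.
#' @export
waveform <- function(period = 0.857,
                     mean_pressure = mmHg_to_Pa(100),
                     pulse_amplitude = mmHg_to_Pa(20),
                     phase_knots = cbind(c(0, 0.15, 0.45, 0.75),
                                         c(-0.2, 1, 0.1, -0.35)),
                     n_cycles = 3) {
  if (period <= 0) stop_aneuflow("period must be > 0", "aneuflow_domain_error")
  if (n_cycles < 1) stop_aneuflow("n_cycles must be >= 1", "aneuflow_domain_error")
  phase_knots <- as.matrix(phase_knots)
  if (nrow(phase_knots) != 4 || ncol(phase_knots) != 2)
    stop_aneuflow("phase_knots must be a 4 x 2 matrix", "aneuflow_domain_error")
  tf <- phase_knots[, 1]
  if (any(tf < 0) || any(tf >= 1) || any(diff(tf) <= 0))
    stop_aneuflow("knot time fractions must be strictly increasing in [0, 1)",
                  "aneuflow_domain_error")
  tk <- tf * period
  yk <- phase_knots[, 2]
  mk <- catmull_rom_slopes(tk, yk, period)
  s_mean <- hermite_periodic_mean(tk, yk, mk, period)

  # locate the (unique) global maximum of the shape
  tg <- seq(0, period, length.out = 4097)[-4097]
  sg <- hermite_periodic_eval(tg, tk, yk, mk, period)
  imax <- which.max(sg)
  lo <- tg[if (imax == 1) length(tg) else imax - 1]
  hi <- tg[if (imax == length(tg)) 1 else imax + 1]
  if (lo > hi) { lo <- lo - period }
  opt <- optimize(function(t) hermite_periodic_eval(t, tk, yk, mk, period),
                  c(lo, hi), maximum = TRUE, tol = 1e-12)
  t_ps <- opt$maximum %% period
  s_max <- opt$objective

  # single-global-max check: samples near the max must form one arc
  thr <- s_max - 1e-6 * max(1, abs(s_max - s_mean))
  near <- which(sg >= s_mean + (s_max - s_mean) * 0.999)
  if (length(near) > 1 && any(diff(near) > 1) &&
      !(near[1] == 1 && near[length(near)] == length(sg)))
    stop_aneuflow("waveform has more than one global maximum per period",
                  "aneuflow_domain_error")
  if (s_max - s_mean <= 0)
    stop_aneuflow("degenerate waveform shape (flat)", "aneuflow_domain_error")

  structure(list(period = period, mean_pressure = mean_pressure,
                 pulse_amplitude = pulse_amplitude,
                 phase_knots = phase_knots, n_cycles = as.integer(n_cycles),
                 tk = tk, yk = yk, mk = mk,
                 s_mean = s_mean, s_max = s_max,
                 peak_systole_time = t_ps),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: T = %.4g s, mean %.4g Pa (%.1f mmHg), amp %.4g Pa\n",
              x$period, x$mean_pressure, Pa_to_mmHg(x$mean_pressure),
              x$pulse_amplitude))
  cat(sprintf("  peak systole at t_ps = %.4f s (t/T = %.3f), %d cycle(s)\n",
              x$peak_systole_time, x$peak_systole_time / x$period, x$n_cycles))
  invisible(x)
}

#' Inlet pressure at time t
#'
#' Evaluates the periodic waveform: `p(t + T) = p(t)` to machine precision,
#' period mean equal to `mean_pressure` (exact cubic quadrature), maximum
#' equal to `mean_pressure + pulse_amplitude`.
#'
#' @param t time(s), s (>= 0; vectorized).
#' @param w a [waveform()].
#' @return pressure, Pa.
#' @export
inlet_pressure <- function(t, w) {
  s <- hermite_periodic_eval(t, w$tk, w$yk, w$mk, w$period)
  w$mean_pressure + w$pulse_amplitude * (s - w$s_mean) / (w$s_max - w$s_mean)
}

#' Peak-systole instant of a given cycle
#'
#' @param w a [waveform()].
#' @param cycle_index 0-based cycle index (`< n_cycles`).
#' @return `cycle_index * T + t_ps`, s.
#' @export
peak_systole_instant <- function(w, cycle_index = 0) {
  if (cycle_index < 0 || cycle_index >= w$n_cycles)
    stop_aneuflow("cycle_index out of range", "aneuflow_index_error")
  cycle_index * w$period + w$peak_systole_time
}

#' Export a waveform as a two-column CSV (t, p)
#'
#' @param w a [waveform()].
#' @param path output file path.
#' @param n number of samples over one period.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path, n = 200) {
  t <- seq(0, w$period, length.out = n)
  write.csv(data.frame(t = t, p = inlet_pressure(t, w)), path,
            row.names = FALSE)
  invisible(path)
}

#' Generic periodic pressure drive for the flow solver
#'
#' The solver is driven by the gauge pressure imposed at the inlet (the
#' outlet is held at 0 gauge). A drive is either derived from a physiological
#' [waveform()] via [as_pressure_drive()] or built directly from a periodic
#' function of time — handy for validation runs (constant or sinusoidal
#' pressure drops).
#'
#' @param period period, s.
#' @param fn function of time returning the inlet gauge pressure, Pa; must be
#'   `period`-periodic.
#' @param n_cycles number of periods to simulate.
#' @return an object of class `pressure_drive`.
#' @export
pressure_drive <- function(period, fn, n_cycles = 1) {
  stopifnot(is.function(fn), period > 0, n_cycles >= 1)
  structure(list(period = period, fn = fn, n_cycles = as.integer(n_cycles)),
            class = "pressure_drive")
}

#' Scale a physiological waveform into a gauge inlet drive
#'
#' The simulated channel is driven by the gauge pressure drop between inlet
#' and outlet, so the physiological waveform (mean about 100 mmHg) is scaled
#' down to a mean gauge drop `mean_drop` while keeping its relative
#' pulsatility: `p_drive(t) = (mean_drop / mean_pressure) * p(t)`.
#'
#' @param w a [waveform()].
#' @param mean_drop mean inlet-to-outlet gauge pressure drop, Pa.
#' @return a [pressure_drive()] with the waveform's period and cycle count.
#' @export
as_pressure_drive <- function(w, mean_drop) {
  scale <- mean_drop / w$mean_pressure
  d <- pressure_drive(w$period, function(t) scale * inlet_pressure(t, w),
                      n_cycles = w$n_cycles)
  d$peak_systole_time <- w$peak_systole_time
  d
}

# Dense lookup table (linear-interpolated inside the C++ core).
drive_table <- function(drive, n = 4096) {
  t <- seq(0, drive$period, length.out = n + 1)
  cbind(t = t, p = drive$fn(t))
}
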