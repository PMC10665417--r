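# Campaign orchestration: CCD design -> per-run geometry + simulation ->
# response extraction -> response-surface fits, with incremental results and
# resume.

default_factors <- function() {
  list(sac_area = factor_spec("sac_area", 11.65, 94.57, "mm^2"),
       parent_radius = factor_spec("parent_radius", 1.59, 2.24, "mm"),
       hct = factor_spec("hct", 0.35, 0.5, ""),
       porosity = factor_spec("porosity", 0.73, 0.96, ""))
}

#' Campaign configuration
#'
#' Bundles every tunable of the study: the four factor ranges (defaulting to
#' the study ranges 11.65-94.57 mm^2, 1.59-2.24 mm, 0.35-0.5, 0.73-0.96),
#' grid resolution preset, domain proportions, waveform, rheology and coil
#' constants, solver settings and output/bookkeeping options.
#'
#' @param factors named list of four [factor_spec()]s.
#' @param preset grid resolution preset: `"coarse"` (dx = 0.2 mm),
#'   `"default"` (0.15 mm) or `"fine"` (0.1 mm).
#' @param dx explicit grid spacing in mm, overriding the preset.
#' @param lu_widths,ld_widths domain length upstream/downstream of the neck
#'   center, in channel widths.
#' @param neck_ratio neck width / sac diameter.
#' @param period cardiac period, s.
#' @param mean_pressure_mmHg,pulse_amplitude_mmHg physiological waveform
#'   scale (shape only; the gauge drive is calibrated separately).
#' @param n_cycles cardiac cycles per run (metrics from the last).
#' @param plasma_viscosity,k_y,density,regularization_m rheology constants
#'   passed to [derive_casson_parameters()].
#' @param coil_wire_diameter_mm coil wire diameter, mm.
#' @param coil_enabled model the coil porous sink?
#' @param target_peak_velocity calibration target for the peak parent-vessel
#'   velocity, m/s; the mean gauge pressure drop is set per run from
#'   plane-Poiseuille so the peak velocity lands near this value
#'   (physiological 0.4-0.6 m/s window).
#' @param exceed_threshold sac speed threshold for the exceedance fraction,
#'   m/s.
#' @param n_center CCD center points.
#' @param solver a [solver_config()].
#' @param outdir output directory for incremental results (`NULL`: keep in
#'   memory only).
#' @param seed integer seed recorded in the manifest (the solver itself is
#'   deterministic).
#' @param resume skip runs already present in the results file.
#' @return an object of class `campaign_config`.
#' @export
campaign_config <- function(factors = default_factors(),
                            preset = c("coarse", "default", "fine"),
                            dx = NULL, lu_widths = 10, ld_widths = 5,
                            neck_ratio = 0.8,
                            period = 0.857, mean_pressure_mmHg = 100,
                            pulse_amplitude_mmHg = 20, n_cycles = 3,
                            plasma_viscosity = 0.00145, k_y = 0.117,
                            density = 1050, regularization_m = 100,
                            coil_wire_diameter_mm = 0.25, coil_enabled = TRUE,
                            target_peak_velocity = 0.5,
                            exceed_threshold = 0.15, n_center = 1,
                            solver = solver_config(), outdir = NULL,
                            seed = 1, resume = FALSE) {
  preset <- match.arg(preset)
  if (is.null(dx))
    dx <- c(coarse = 0.2, default = 0.15, fine = 0.1)[[preset]]
  stopifnot(length(factors) >= 2,
            all(vapply(factors, inherits, TRUE, "factor_spec")))
  structure(list(factors = factors, preset = preset, dx = dx,
                 lu_widths = lu_widths, ld_widths = ld_widths,
                 neck_ratio = neck_ratio, period = period,
                 mean_pressure_mmHg = mean_pressure_mmHg,
                 pulse_amplitude_mmHg = pulse_amplitude_mmHg,
                 n_cycles = as.integer(n_cycles),
                 plasma_viscosity = plasma_viscosity, k_y = k_y,
                 density = density, regularization_m = regularization_m,
                 coil_wire_diameter_mm = coil_wire_diameter_mm,
                 coil_enabled = coil_enabled,
                 target_peak_velocity = target_peak_velocity,
                 exceed_threshold = exceed_threshold,
                 n_center = as.integer(n_center), solver = solver,
                 outdir = outdir, seed = seed, resume = resume),
            class = "campaign_config")
}

#' @export
print.campaign_config <- function(x, ...) {
  cat(sprintf("campaign_config: preset %s (dx = %.3g mm), %d cycles, seed %s\n",
              x$preset, x$dx, x$n_cycles, format(x$seed)))
  for (f in x$factors)
    cat(sprintf("  %-14s %g .. %g %s\n", f$name, f$low, f$high, f$units))
  invisible(x)
}

factor_center <- function(f) (f$low + f$high) / 2

config_waveform <- function(config) {
  waveform(period = config$period,
           mean_pressure = mmHg_to_Pa(config$mean_pressure_mmHg),
           pulse_amplitude = mmHg_to_Pa(config$pulse_amplitude_mmHg),
           n_cycles = config$n_cycles)
}

#' Calibrate the mean gauge pressure drop for one run
#'
#' Plane-Poiseuille calibration: the centerline velocity of a channel of
#' half-width a under gradient G is `G a^2 / (2 mu)`, so the gradient that
#' yields the target peak velocity at the systolic maximum of the drive is
#' `G = 2 mu_c u_target / a^2` scaled down by the waveform's peak-to-mean
#' ratio. Calibrating per run (with the run's Casson viscosity and parent
#' radius) keeps every run's peak velocity near the physiological target.
#'
#' @param params an [aneurysm_params()].
#' @param props a [blood_properties()].
#' @param config a [campaign_config()].
#' @return mean inlet gauge pressure drop, Pa.
#' @export
calibrate_pressure_drop <- function(params, props, config) {
  a <- mm_to_m(params$parent_radius)
  L <- mm_to_m((config$lu_widths + config$ld_widths) * 2 * params$parent_radius)
  G <- 2 * props$casson_viscosity * config$target_peak_velocity / a^2
  peak_factor <- 1 + config$pulse_amplitude_mmHg / config$mean_pressure_mmHg
  G * L / peak_factor
}

params_from_config <- function(config, values) {
  centers <- lapply(default_factors(), factor_center)
  for (nm in names(config$factors))
    centers[[nm]] <- factor_center(config$factors[[nm]])
  for (nm in names(values)) centers[[nm]] <- values[[nm]]
  aneurysm_params(sac_section_area = centers$sac_area,
                  parent_radius = centers$parent_radius,
                  hct = centers$hct, porosity = centers$porosity,
                  neck_ratio = config$neck_ratio,
                  coil_wire_diameter = config$coil_wire_diameter_mm)
}

#' Simulate a single campaign case
#'
#' Builds the geometry, rheology, coil and drive for one factor combination
#' and runs the full pulsatile simulation plus response extraction.
#'
#' @param config a [campaign_config()].
#' @param values named list/vector of physical factor values
#'   (`sac_area`, `parent_radius`, `hct`, `porosity`); missing factors sit
#'   at their range centers.
#' @return list with `summary` ([hemodynamic_summary()]), `diagnostics`,
#'   `pressure_drop` (Pa) and the `params` used.
#' @export
run_single_case <- function(config, values = list()) {
  params <- params_from_config(config, values)
  mask <- build_idealized_geometry(params, dx = config$dx,
                                   lu_widths = config$lu_widths,
                                   ld_widths = config$ld_widths,
                                   coiled = config$coil_enabled)
  props <- derive_casson_parameters(params$hct,
                                    plasma_viscosity = config$plasma_viscosity,
                                    k_y = config$k_y,
                                    density = config$density,
                                    regularization_m = config$regularization_m)
  coil <- if (config$coil_enabled && params$porosity < 1)
    coil_model(params$porosity, mm_to_m(params$coil_wire_diameter))
  else coil_model(NA, enabled = FALSE)
  w <- config_waveform(config)
  drop <- calibrate_pressure_drop(params, props, config)
  drive <- as_pressure_drive(w, drop)
  sim <- simulate_flow(mask, props, coil, drive, config$solver)
  summ <- hemodynamic_summary(sim, mask, props, config$exceed_threshold)
  list(summary = summ, diagnostics = sim$diagnostics,
       pressure_drop = drop, params = params, peak_flux = sim$peak_flux)
}

response_cols <- c("mean_sac_wall_pressure", "mean_sac_velocity",
                   "max_sac_velocity", "mean_sac_wall_wss", "max_osi",
                   "exceedance_fraction", "peak_systole_time_used")

case_row <- function(run, coded, phys, res, status = "ok") {
  row <- data.frame(run = run, status = status)
  for (nm in names(coded)) row[[paste0("coded_", nm)]] <- coded[[nm]]
  for (nm in names(phys)) row[[nm]] <- phys[[nm]]
  for (nm in response_cols)
    row[[nm]] <- if (is.null(res)) NA_real_ else res$summary[[nm]]
  row$pressure_drop <- if (is.null(res)) NA_real_ else res$pressure_drop
  row$final_residual <- if (is.null(res)) NA_real_ else res$diagnostics$final_residual
  row$cycle_delta <- if (is.null(res)) NA_real_ else res$diagnostics$cycle_delta
  row$steps <- if (is.null(res)) NA_real_ else res$diagnostics$steps
  row
}

#' Run the full design campaign
#'
#' Generates the face-centered CCD over the configured factors, simulates
#' every run (deterministically, writing per-run rows incrementally when an
#' output directory is set; `resume = TRUE` skips completed runs), and fits
#' quadratic response surfaces for mean sac-wall pressure and mean sac
#' velocity. A run whose solver diverges is recorded as a failed row and the
#' campaign continues; each fit refuses when fewer successful rows remain
#' than model coefficients plus one.
#'
#' @param config a [campaign_config()].
#' @param verbose print per-run progress lines?
#' @return an object of class `campaign_result`: `rows` (one per run), the
#'   `design`, `fit_pressure` and `fit_velocity` (an `rsm_fit` or the fit
#'   error message), and the `config`.
#' @export
run_campaign <- function(config, verbose = interactive()) {
  set.seed(config$seed)
  design <- ccd_design(unname(config$factors), config$n_center)
  n <- nrow(design$coded_matrix)
  nms <- colnames(design$coded_matrix)

  results_path <- if (!is.null(config$outdir))
    file.path(config$outdir, "results.csv") else NULL
  prev <- NULL
  if (!is.null(results_path) && config$resume && file.exists(results_path))
    prev <- read.csv(results_path, stringsAsFactors = FALSE)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(package = "aneuflow",
                     version = as.character(utils::packageVersion("aneuflow")),
                     seed = config$seed, preset = config$preset,
                     dx_mm = config$dx, n_runs = n,
                     factors = lapply(config$factors, unclass))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  rows <- vector("list", n)
  for (r in seq_len(n)) {
    if (!is.null(prev) && r <= nrow(prev) && prev$status[r] == "ok") {
      rows[[r]] <- prev[r, , drop = FALSE]
      if (verbose) message(sprintf("run %d/%d: resumed", r, n))
      next
    }
    coded <- as.list(design$coded_matrix[r, ])
    phys <- as.list(design$physical_matrix[r, ])
    res <- tryCatch(run_single_case(config, phys),
                    aneuflow_error = function(e) e,
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[r]] <- case_row(r, coded, phys, NULL,
                            status = paste0("failed: ", conditionMessage(res)))
      if (verbose) message(sprintf("run %d/%d: FAILED (%s)", r, n,
                                   conditionMessage(res)))
    } else {
      rows[[r]] <- case_row(r, coded, phys, res)
      if (verbose)
        message(sprintf(
          "run %d/%d: p_sac = %.3g Pa, v_sac = %.3g m/s (%d steps)",
          r, n, res$summary$mean_sac_wall_pressure,
          res$summary$mean_sac_velocity, as.integer(res$diagnostics$steps)))
    }
    if (!is.null(results_path)) {
      all_rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
      write.csv(all_rows, results_path, row.names = FALSE)
    }
  }
  rows <- do.call(rbind, rows)

  fit_response <- function(col) {
    ok <- rows$status == "ok" & !is.na(rows[[col]])
    p <- 1 + 2 * length(nms) + choose(length(nms), 2)
    if (sum(ok) < p + 1)
      return(sprintf("fit refused: %d successful rows < %d required",
                     sum(ok), p + 1))
    sub <- design
    sub$coded_matrix <- design$coded_matrix[ok, , drop = FALSE]
    sub$physical_matrix <- design$physical_matrix[ok, , drop = FALSE]
    tryCatch(fit_quadratic_surface(sub, rows[[col]][ok]),
             aneuflow_fit_error = function(e) conditionMessage(e))
  }
  fit_p <- fit_response("mean_sac_wall_pressure")
  fit_v <- fit_response("mean_sac_velocity")

  if (!is.null(config$outdir)) {
    for (nm in c("pressure", "velocity")) {
      f <- if (nm == "pressure") fit_p else fit_v
      if (inherits(f, "rsm_fit"))
        write_effects_report(effects_report(f),
                             file.path(config$outdir,
                                       paste0("effects_", nm, ".csv")),
                             file.path(config$outdir,
                                       paste0("effects_", nm, ".json")))
    }
  }
  structure(list(rows = rows, design = design, fit_pressure = fit_p,
                 fit_velocity = fit_v, config = config),
            class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  ok <- sum(x$rows$status == "ok")
  cat(sprintf("campaign_result: %d/%d runs successful\n", ok, nrow(x$rows)))
  for (nm in c("fit_pressure", "fit_velocity")) {
    f <- x[[nm]]
    if (inherits(f, "rsm_fit")) {
      k <- length(x$design$factors)
      lin <- f$standardized_effects[2:(1 + k)]
      cat(sprintf("  %s linear effects (t): %s\n", nm,
                  paste(sprintf("%s %+0.2f", f$terms[2:(1 + k)], lin),
                        collapse = ", ")))
    } else cat(sprintf("  %s: %s\n", nm, f))
  }
  invisible(x)
}

#' Two-point factor contrast
#'
#' Runs exactly two simulations that differ only in the named factor (all
#' other factors at their range centers) and returns the relative difference
#' `(response_a - response_b) / response_a` of the chosen response — e.g.
#' the relative reduction of peak-systolic mean sac-wall gauge pressure when
#' the sac section area grows from 36.6 to 75.4 mm^2.
#'
#' @param config a [campaign_config()].
#' @param factor one of the configured factor names.
#' @param value_a,value_b physical factor values inside the factor range.
#' @param response response column, default `"mean_sac_wall_pressure"`.
#' @return list with the relative difference `relative`, and both run
#'   summaries `a`, `b`.
#' @export
two_point_contrast <- function(config, factor, value_a, value_b,
                               response = "mean_sac_wall_pressure") {
  if (!factor %in% names(config$factors))
    stop_aneuflow(sprintf("unknown factor '%s'", factor), "aneuflow_spec_error")
  f <- config$factors[[factor]]
  for (v in c(value_a, value_b))
    if (v < f$low || v > f$high)
      stop_aneuflow(sprintf("value %g outside range of factor '%s'", v, factor),
                    "aneuflow_spec_error")
  if (value_a == value_b) {
    warning("value_a equals value_b: contrast is 0 by construction")
    res <- run_single_case(config, stats::setNames(list(value_a), factor))
    return(list(relative = 0, a = res$summary, b = res$summary))
  }
  ra <- run_single_case(config, stats::setNames(list(value_a), factor))
  rb <- run_single_case(config, stats::setNames(list(value_b), factor))
  va <- ra$summary[[response]]
  vb <- rb$summary[[response]]
  list(relative = (va - vb) / va, a = ra$summary, b = rb$summary)
}

#' Write / read a campaign configuration as JSON
#'
#' @param config a [campaign_config()].
#' @param path JSON file path.
#' @return `path` invisibly (write); a `campaign_config` (read).
#' @export
write_campaign_config <- function(config, path) {
  x <- unclass(config)
  x$factors <- lapply(x$factors, unclass)
  x$solver <- unclass(x$solver)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_campaign_config
#' @export
read_campaign_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  factors <- lapply(x$factors, function(f)
    factor_spec(f$name, f$low, f$high, f$units %||% ""))
  names(factors) <- vapply(factors, `[[`, "", "name")
  sc <- x$solver
  campaign_config(
    factors = factors, preset = x$preset, dx = x$dx,
    lu_widths = x$lu_widths, ld_widths = x$ld_widths,
    neck_ratio = x$neck_ratio, period = x$period,
    mean_pressure_mmHg = x$mean_pressure_mmHg,
    pulse_amplitude_mmHg = x$pulse_amplitude_mmHg, n_cycles = x$n_cycles,
    plasma_viscosity = x$plasma_viscosity, k_y = x$k_y,
    density = x$density, regularization_m = x$regularization_m,
    coil_wire_diameter_mm = x$coil_wire_diameter_mm,
    coil_enabled = x$coil_enabled,
    target_peak_velocity = x$target_peak_velocity,
    exceed_threshold = x$exceed_threshold, n_center = x$n_center,
    solver = solver_config(dt_cfl_safety = sc$dt_cfl_safety,
                           poisson_tol = sc$poisson_tol,
                           outer_residual_tol = sc$outer_residual_tol,
                           max_poisson_iters = sc$max_poisson_iters,
                           mu_cap = sc$mu_cap, u_floor = sc$u_floor,
                           max_steps = sc$max_steps,
                           flux_every = sc$flux_every),
    outdir = x$outdir, seed = x$seed, resume = x$resume)
}
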