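#' Blood material properties for the Casson constitutive model
#'
#' Blood is modelled as a Casson fluid, `sqrt(tau) = sqrt(tau_y) +
#' sqrt(mu_c * gdot)`, regularized in the Papanastasiou style so the
#' effective viscosity stays finite at vanishing shear. `casson_viscosity`
#' is the high-shear asymptote; `yield_stress` the Casson yield stress.
#'
#' @param density blood density, kg/m^3.
#' @param plasma_viscosity plasma viscosity, Pa.s.
#' @param hct hematocrit (dimensionless volume fraction).
#' @param yield_stress Casson yield stress, Pa (>= 0).
#' @param casson_viscosity high-shear asymptotic viscosity, Pa.s
#'   (>= `plasma_viscosity`).
#' @param regularization_m Papanastasiou regularization time scale, s (> 0).
#' @return an object of class `blood_properties`.
#' @export
blood_properties <- function(density = 1050, plasma_viscosity = 0.00145,
                             hct = 0.45, yield_stress = 0,
                             casson_viscosity = plasma_viscosity,
                             regularization_m = 100) {
  if (density <= 0 || plasma_viscosity <= 0)
    stop_aneuflow("density and plasma_viscosity must be > 0", "aneuflow_rheology_error")
  if (yield_stress < 0)
    stop_aneuflow("yield_stress must be >= 0", "aneuflow_rheology_error")
  if (casson_viscosity < plasma_viscosity)
    stop_aneuflow("casson_viscosity must be >= plasma_viscosity", "aneuflow_rheology_error")
  if (regularization_m <= 0)
    stop_aneuflow("regularization_m must be > 0", "aneuflow_rheology_error")
  structure(list(density = density, plasma_viscosity = plasma_viscosity,
                 hct = hct, yield_stress = yield_stress,
                 casson_viscosity = casson_viscosity,
                 regularization_m = regularization_m),
            class = "blood_properties")
}

#' @export
print.blood_properties <- function(x, ...) {
  cat("blood_properties (Casson):\n")
  cat(sprintf("  rho = %g kg/m^3, hct = %.3f\n", x$density, x$hct))
  cat(sprintf("  mu_p = %.4g Pa.s, mu_c = %.4g Pa.s, tau_y = %.4g Pa\n",
              x$plasma_viscosity, x$casson_viscosity, x$yield_stress))
  cat(sprintf("  regularization m = %g s\n", x$regularization_m))
  invisible(x)
}

#' Derive Casson parameters from hematocrit
#'
#' Hematocrit coupling of the Casson parameters:
#' `tau_y = k_y * max(H - H0, 0)^3` (cubic above the aggregation threshold
#' `H0 = 0.1`) and a polynomial high-shear viscosity
#' `mu_c = mu_p * (1 + 2.5 H + 7.35 H^2)`. The defaults give physiological
#' magnitudes (`tau_y` about 5 mPa and `mu_c` about 5 mPa.s at H = 0.45);
#' both correlations are overridable via the coefficients.
#'
#' @param hct hematocrit in `[0, 0.67)`.
#' @param plasma_viscosity plasma viscosity, Pa.s.
#' @param k_y yield-stress coefficient, Pa.
#' @param density blood density, kg/m^3.
#' @param regularization_m Papanastasiou time scale, s.
#' @return a [blood_properties()] object.
#' @export
derive_casson_parameters <- function(hct, plasma_viscosity = 0.00145,
                                     k_y = 0.117, density = 1050,
                                     regularization_m = 100) {
  if (hct < 0 || hct >= 0.67)
    stop_aneuflow("hct must be in [0, 0.67) (packing limit)", "aneuflow_rheology_error")
  tau_y <- k_y * max(hct - 0.1, 0)^3
  mu_c <- plasma_viscosity * (1 + 2.5 * hct + 7.35 * hct^2)
  blood_properties(density = density, plasma_viscosity = plasma_viscosity,
                   hct = hct, yield_stress = tau_y, casson_viscosity = mu_c,
                   regularization_m = regularization_m)
}

#' Regularized Casson effective viscosity
#'
#' `mu_eff(gdot) = (sqrt(mu_c) + sqrt(tau_y / gdot) *
#' (1 - exp(-sqrt(m * gdot))))^2`, finite and continuous on `gdot >= 0` with
#' limit `(sqrt(mu_c) + sqrt(tau_y * m))^2` at zero shear, monotonically
#' non-increasing in shear rate, tending to `mu_c` at high shear.
#'
#' @param shear_rate shear-rate magnitude(s), 1/s (>= 0; vectorized).
#' @param props a [blood_properties()] object.
#' @return effective viscosity, Pa.s.
#' @export
effective_viscosity <- function(shear_rate, props) {
  if (any(shear_rate < 0))
    stop_aneuflow("shear_rate must be >= 0", "aneuflow_domain_error")
  mu_c <- props$casson_viscosity
  tau_y <- props$yield_stress
  m <- props$regularization_m
  mg <- m * shear_rate
  # sqrt(tau_y/g) * (1 - exp(-sqrt(m g))) -> sqrt(tau_y * m) as g -> 0
  fac <- ifelse(mg < 1e-24,
                sqrt(tau_y * m),
                sqrt(tau_y / pmax(shear_rate, .Machine$double.xmin)) *
                  (1 - exp(-sqrt(mg))))
  (sqrt(mu_c) + fac)^2
}
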