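#' Porous-medium model of the endovascular coil mass
#'
#' The packed coil is modelled as an isotropic porous medium occupying the
#' whole sac, adding a Darcy momentum sink `S = -(mu_eff / K) u` in COIL
#' cells. Permeability follows a Kozeny-Carman closure in the coil wire
#' diameter and porosity.
#'
#' @param porosity void fraction of the coil mass, in `(0, 1)` when enabled.
#' @param wire_diameter coil wire diameter, m.
#' @param enabled logical; `FALSE` disables the sink entirely.
#' @return an object of class `coil_model` with the permeability `K` (m^2).
#' @export
coil_model <- function(porosity, wire_diameter = 0.25e-3, enabled = TRUE) {
  if (!enabled)
    return(structure(list(porosity = NA_real_, wire_diameter = wire_diameter,
                          permeability = Inf, enabled = FALSE),
                     class = "coil_model"))
  K <- permeability_from_porosity(porosity, wire_diameter)
  structure(list(porosity = porosity, wire_diameter = wire_diameter,
                 permeability = K, enabled = TRUE),
            class = "coil_model")
}

#' @export
print.coil_model <- function(x, ...) {
  if (!x$enabled) cat("coil_model: disabled (uncoiled sac)\n")
  else cat(sprintf(
    "coil_model: porosity %.3f, wire %.3g mm, K = %.4g m^2\n",
    x$porosity, x$wire_diameter * 1e3, x$permeability))
  invisible(x)
}

#' Kozeny-Carman permeability of the coil mass
#'
#' `K = d_w^2 * eps^3 / (180 * (1 - eps)^2)`, strictly increasing in
#' porosity at fixed wire diameter.
#'
#' @param porosity void fraction in `(0, 1)`.
#' @param wire_diameter coil wire diameter, m (> 0).
#' @return permeability, m^2.
#' @export
permeability_from_porosity <- function(porosity, wire_diameter) {
  if (any(porosity <= 0) || any(porosity >= 1))
    stop_aneuflow("porosity must be in (0, 1)", "aneuflow_domain_error")
  if (any(wire_diameter <= 0))
    stop_aneuflow("wire_diameter must be > 0", "aneuflow_domain_error")
  wire_diameter^2 * porosity^3 / (180 * (1 - porosity)^2)
}

#' Darcy momentum sink
#'
#' Momentum source per unit volume opposing the local velocity,
#' `S = -(mu_eff / K) u`, applied in COIL cells only.
#'
#' @param velocity_component local velocity component, m/s (vectorized).
#' @param local_viscosity local effective viscosity, Pa.s.
#' @param coil a [coil_model()]; must be enabled with positive permeability.
#' @return momentum sink, N/m^3.
#' @export
darcy_sink <- function(velocity_component, local_viscosity, coil) {
  if (!inherits(coil, "coil_model") || !coil$enabled)
    stop_aneuflow("darcy_sink requires an enabled coil_model", "aneuflow_model_error")
  if (!is.finite(coil$permeability) || coil$permeability <= 0)
    stop_aneuflow("coil permeability must be finite and > 0", "aneuflow_model_error")
  -(local_viscosity / coil$permeability) * velocity_component
}
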