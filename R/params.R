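#' Thermal and perfusion properties of a tissue region
#'
#' Parameters of the Pennes bioheat equation for one tissue compartment:
#' conduction (\code{k}), heat capacity (\code{rho}, \code{c}), volumetric
#' metabolic heat generation (\code{q_met}) and the perfusion heat sink
#' \eqn{\omega_b \rho_b c_b (T - T_a)} that exchanges heat with blood at
#' temperature \code{T_a}.
#'
#' @param k Thermal conductivity, W/(m K).
#' @param rho Tissue density, kg/m^3 (used by the transient term).
#' @param c Tissue specific heat, J/(kg K) (used by the transient term).
#' @param q_met Metabolic volumetric heat generation, W/m^3.
#' @param omega_b Blood perfusion rate, 1/s.
#' @param rho_b Blood density, kg/m^3.
#' @param c_b Blood specific heat, J/(kg K).
#' @param T_a Blood (arterial) temperature, K.
#' @return An object of class \code{"tissue_props"}.
#' @export
tissue_props <- function(k, rho, c, q_met = 0, omega_b = 0,
                         rho_b = 1100, c_b = 3300, T_a = 293) {
  vals <- list(k = k, rho = rho, c = c, q_met = q_met, omega_b = omega_b,
               rho_b = rho_b, c_b = c_b, T_a = T_a)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("tissue property '%s' must be a single finite number", nm),
           call. = FALSE)
  }
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (rho <= 0 || c <= 0 || rho_b <= 0 || c_b <= 0)
    stop("rho, c, rho_b, c_b must be positive", call. = FALSE)
  if (omega_b < 0) stop("omega_b must be non-negative", call. = FALSE)
  if (q_met < 0) stop("q_met must be non-negative", call. = FALSE)
  if (T_a <= 0) stop("T_a must be positive (Kelvin)", call. = FALSE)
  structure(vals, class = "tissue_props")
}

#' Boundary conditions of the breast phantom
#'
#' The flat base is held at the core (chest-wall) temperature \code{T_core};
#' the curved skin surface loses heat to ambient air by convection
#' \eqn{h_f (T_s - T_f)} and radiation
#' \eqn{\sigma \varepsilon (T_s^4 - T_f^4)}.
#'
#' @param h_f Convection coefficient, W/(m^2 K).
#' @param epsilon Skin emissivity, dimensionless in [0, 1].
#' @param sigma Stefan--Boltzmann constant, W/(m^2 K^4).
#' @param T_f Ambient air temperature, K.
#' @param T_core Flat-base (core) temperature, K.
#' @return An object of class \code{"boundary_spec"}.
#' @export
boundary_spec <- function(h_f = 15, epsilon = 0.98, sigma = 5.69e-8,
                          T_f = 293, T_core = 309.5) {
  vals <- list(h_f = h_f, epsilon = epsilon, sigma = sigma,
               T_f = T_f, T_core = T_core)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("boundary parameter '%s' must be a single finite number",
                   nm), call. = FALSE)
  }
  if (h_f < 0) stop("h_f must be non-negative", call. = FALSE)
  if (epsilon < 0 || epsilon > 1)
    stop("epsilon must lie in [0, 1]", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (T_f <= 0 || T_core <= 0)
    stop("T_f and T_core must be positive (Kelvin)", call. = FALSE)
  structure(vals, class = "boundary_spec")
}

#' Default tissue properties
#'
#' The healthy-tissue defaults are the study's published parameter set:
#' k = 0.48 W/(m K), perfusion 1e-4 1/s with blood density 1100 kg/m^3 and
#' blood specific heat 3300 J/(kg K), no metabolic source, and blood
#' temperature equal to the ambient 293 K (that data set identifies the two;
#' set \code{T_a} to the core temperature for a physiological Pennes model).
#' Tissue density/specific heat default to the blood values. The tumor
#' compartment differs only by a literature-scale metabolic heat source of
#' 65000 W/m^3, which is what creates the surface thermal contrast.
#'
#' @param region \code{"healthy"} or \code{"tumor"}.
#' @return A \code{\link{tissue_props}} object.
#' @export
default_tissue_props <- function(region = c("healthy", "tumor")) {
  region <- match.arg(region)
  q <- if (region == "tumor") 65000 else 0
  tissue_props(k = 0.48, rho = 1100, c = 3300, q_met = q,
               omega_b = 1e-4, rho_b = 1100, c_b = 3300, T_a = 293)
}

#' Default boundary conditions (published parameter set)
#'
#' h_f = 15 W/(m^2 K), emissivity 0.98, Stefan--Boltzmann constant
#' 5.69e-8 W/(m^2 K^4) (as printed in the source data set), ambient 293 K,
#' core 309.5 K.
#'
#' @return A \code{\link{boundary_spec}} object.
#' @export
default_boundary_spec <- function() boundary_spec()

#' @export
print.tissue_props <- function(x, ...) {
  cat(sprintf(paste0(
    "tissue_props: k=%g W/(m K), rho=%g kg/m^3, c=%g J/(kg K), ",
    "q_met=%g W/m^3,\n  omega_b=%g 1/s, rho_b=%g, c_b=%g, T_a=%g K\n"),
    x$k, x$rho, x$c, x$q_met, x$omega_b, x$rho_b, x$c_b, x$T_a))
  invisible(x)
}

#' @export
print.boundary_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "boundary_spec: h_f=%g W/(m^2 K), epsilon=%g, sigma=%g, ",
    "T_f=%g K, T_core=%g K\n"), x$h_f, x$epsilon, x$sigma, x$T_f, x$T_core))
  invisible(x)
}
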