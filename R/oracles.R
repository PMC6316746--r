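# Closed-form test oracles. These are implemented directly from the analytic
# solutions and share no code with the production assembly; the test suite
# additionally cross-checks them against dense ODE integrations.

#' Closed-form oracle: uniformly heated disc with a fixed rim
#'
#' Steady radial conduction in a full disc of radius \code{R} with uniform
#' volumetric source \code{q} and Dirichlet rim temperature \code{T_b}:
#' \deqn{T(r) = T_b + q (R^2 - r^2) / (4 k).}
#' Because the solution is radially symmetric its normal derivative on any
#' diameter vanishes, so the same temperatures solve the semicircular problem
#' with an insulated base and a Dirichlet rim — which is how the production
#' solver is compared against this oracle.
#'
#' @param R_mm Disc radius, mm.
#' @param k Thermal conductivity, W/(m K).
#' @param q Volumetric source, W/m^3.
#' @param T_b Rim temperature, K.
#' @return An \code{"oracle_case"} with an \code{evaluate(r_mm)} closure and
#'   the center excess \code{q R^2 / (4k)} in K.
#' @export
disc_conduction_oracle <- function(R_mm, k, q, T_b) {
  stopifnot(R_mm > 0, k > 0)
  R_m <- R_mm * MM
  structure(list(
    name = "disc_conduction",
    params = list(R_mm = R_mm, k = k, q = q, T_b = T_b),
    center_excess = q * R_m^2 / (4 * k),
    evaluate = function(r_mm) {
      r_m <- r_mm * MM
      if (any(r_mm < -1e-12 | r_mm > R_mm + 1e-12))
        stop("r_mm outside [0, R_mm]", call. = FALSE)
      T_b + q * (R_m^2 - r_m^2) / (4 * k)
    }), class = "oracle_case")
}

#' Closed-form oracle: perfused 1D slab with a heated base
#'
#' Steady Pennes equation in one dimension,
#' \eqn{k T'' - \omega_b \rho_b c_b (T - T_a) = 0}, with Dirichlet
#' \code{T0} at x = 0 and an insulated far end at x = L:
#' \deqn{T(x) = T_a + (T_0 - T_a) \cosh(m (L - x)) / \cosh(m L),}
#' \eqn{m = \sqrt{\omega_b \rho_b c_b / k}}. Realized on a
#' \code{\link{build_strip_mesh}} grid with insulated lateral faces.
#'
#' @param L_mm Slab thickness, mm.
#' @param k Thermal conductivity, W/(m K).
#' @param omega_b Perfusion rate, 1/s.
#' @param rho_b Blood density, kg/m^3.
#' @param c_b Blood specific heat, J/(kg K).
#' @param T0 Base temperature, K.
#' @param T_a Blood temperature, K.
#' @return An \code{"oracle_case"} with an \code{evaluate(x_mm)} closure and
#'   the decay parameter \code{m} (1/m).
#' @export
perfused_slab_oracle <- function(L_mm, k, omega_b, rho_b, c_b, T0, T_a) {
  stopifnot(L_mm > 0, k > 0, omega_b >= 0, rho_b > 0, c_b > 0)
  L_m <- L_mm * MM
  m <- sqrt(omega_b * rho_b * c_b / k)
  structure(list(
    name = "perfused_slab",
    params = list(L_mm = L_mm, k = k, omega_b = omega_b, rho_b = rho_b,
                  c_b = c_b, T0 = T0, T_a = T_a),
    m = m,
    evaluate = function(x_mm) {
      x_m <- x_mm * MM
      if (any(x_mm < -1e-12 | x_mm > L_mm + 1e-12))
        stop("x_mm outside [0, L_mm]", call. = FALSE)
      if (m == 0) return(rep(T0, length(x_m)))
      T_a + (T0 - T_a) * cosh(m * (L_m - x_m)) / cosh(m * L_m)
    }), class = "oracle_case")
}

#' @export
print.oracle_case <- function(x, ...) {
  cat(sprintf("oracle_case '%s'\n", x$name))
  cat("  ", paste(names(x$params), unlist(x$params), sep = " = ",
                  collapse = ", "), "\n")
  invisible(x)
}
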