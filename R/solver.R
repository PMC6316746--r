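# Steady and transient Pennes bioheat solver on a rasterized grid.
#
# Discretization: conservative cell-centered finite volumes on the uniform
# grid (5-point stencil, harmonic-mean conductivity across region
# interfaces), written per unit depth so every equation is an energy balance
# in W/m. The flat base enters through half-cell Dirichlet face fluxes; the
# curved skin surface through Robin faces (convective part in the matrix,
# radiative part lagged in a fixed-point outer iteration) whose staircase
# lengths are rescaled to the analytic arc length.

MM <- 1e-3  # mm -> m

# Per-unknown property vectors for a grid + region property list.
region_props <- function(grid, props) {
  if (is.null(props$healthy))
    stop("props must contain a 'healthy' tissue_props entry", call. = FALSE)
  has_tumor <- any(grid$region == REGION_TUMOR)
  if (has_tumor && is.null(props$tumor))
    stop("grid contains tumor cells but props has no 'tumor' entry",
         call. = FALSE)
  reg <- grid$region[grid$in_cells]
  pick <- function(field) {
    v <- rep(props$healthy[[field]], length(reg))
    if (has_tumor) v[reg == REGION_TUMOR] <- props$tumor[[field]]
    v
  }
  list(k = pick("k"), rho = pick("rho"), c = pick("c"),
       q_met = pick("q_met"),
       sink = pick("omega_b") * pick("rho_b") * pick("c_b"),
       T_a = pick("T_a"))
}

#' Assemble the steady-state bioheat system
#'
#' Builds the sparse linear operator and right-hand side of the steady Pennes
#' equation on \code{grid}, leaving the quartic radiative surface term as a
#' separable nonlinear flux evaluated by the returned closure. Conduction uses
#' a conservative 5-point stencil with harmonic-mean interface conductivity;
#' perfusion is a diagonal sink toward the blood temperature; the flat base is
#' a Dirichlet condition at \code{bc$T_core} imposed through half-cell face
#' fluxes; curved-surface cells carry convective (matrix) and radiative
#' (lagged) fluxes over their exposed face length, rescaled so the staircase
#' boundary has the analytic arc length.
#'
#' @param grid A \code{\link{build_mesh}} / \code{\link{build_strip_mesh}}
#'   grid.
#' @param props Named list with \code{healthy} (and, if the grid has tumor
#'   cells, \code{tumor}) \code{\link{tissue_props}}.
#' @param bc A \code{\link{boundary_spec}}.
#' @param surface_bc \code{"robin"} (convective + radiative, the physical
#'   skin condition) or \code{"dirichlet"} (surface pinned to
#'   \code{surface_T}; used by analytic-oracle comparisons).
#' @param base_bc \code{"dirichlet"} (base at \code{bc$T_core}) or
#'   \code{"insulated"}.
#' @param surface_T Surface temperature (K) when
#'   \code{surface_bc = "dirichlet"}; defaults to \code{bc$T_f}.
#' @return A list with the sparse matrix \code{A}, linear right-hand side
#'   \code{b_lin}, radiative flux closure \code{rad_flux(T)}, and the
#'   bookkeeping vectors used for energy audits.
#' @export
assemble_steady <- function(grid, props, bc,
                            surface_bc = c("robin", "dirichlet"),
                            base_bc = c("dirichlet", "insulated"),
                            surface_T = bc$T_f) {
  stopifnot(inherits(grid, "bioheat_grid"), inherits(bc, "boundary_spec"))
  surface_bc <- match.arg(surface_bc)
  base_bc <- match.arg(base_bc)
  n <- length(grid$in_cells)
  if (n < 1L) stop("grid has no interior cells", call. = FALSE)
  p <- region_props(grid, props)
  h_m <- grid$spacing * MM
  vol <- h_m * h_m                       # cell area per unit depth, m^2

  idx <- grid$index
  nx <- grid$nx; ny <- grid$ny

  # interior faces (right and top neighbors), harmonic-mean conductance;
  # A/d = (h_m * 1)/h_m = 1 so g is just the interface conductivity.
  ur <- idx[-nx, , drop = FALSE]; vr <- idx[-1L, , drop = FALSE]
  sr <- ur > 0L & vr > 0L
  ut <- idx[, -ny, drop = FALSE]; vt <- idx[, -1L, drop = FALSE]
  st <- ut > 0L & vt > 0L
  uu <- c(ur[sr], ut[st]); vv <- c(vr[sr], vt[st])
  g <- 2 / (1 / p$k[uu] + 1 / p$k[vv])

  diag_add <- p$sink * vol               # perfusion sink
  b <- p$q_met * vol + p$sink * vol * p$T_a

  # curved-surface (exposed) faces
  nexp <- grid$n_exposed[grid$in_cells]
  exp_len <- nexp * h_m * grid$arc_correction   # exposed length, m
  rad_coef <- numeric(n)
  if (surface_bc == "robin") {
    diag_add <- diag_add + bc$h_f * exp_len
    b <- b + bc$h_f * exp_len * bc$T_f
    rad_coef <- bc$sigma * bc$epsilon * exp_len
  } else {
    # Dirichlet rim: conductance uses the distance from the cell center to
    # the analytic circle (embedded-boundary correction); strips fall back
    # to the half-cell distance.
    w <- which(nexp > 0L)
    if (length(w)) {
      d_m <- rep(h_m / 2, length(w))
      if (grid$kind == "semicircle") {
        cc <- cell_centers(grid, w)
        d_mm <- grid$spec$R1 - sqrt(cc[, "x"]^2 + cc[, "y"]^2)
        d_m <- pmax(d_mm, 1e-3 * grid$spacing) * MM
      }
      g_d <- p$k[w] * nexp[w] * h_m / d_m
      diag_add[w] <- diag_add[w] + g_d
      b[w] <- b[w] + g_d * surface_T
    }
  }

  # flat base
  base_u <- idx[grid$base]
  base_g <- numeric(0)
  if (base_bc == "dirichlet" && length(base_u)) {
    base_g <- 2 * p$k[base_u]            # k * h_m / (h_m/2)
    diag_add[base_u] <- diag_add[base_u] + base_g
    b[base_u] <- b[base_u] + base_g * bc$T_core
  }

  ii <- c(uu, vv, uu, vv, seq_len(n))
  jj <- c(vv, uu, uu, vv, seq_len(n))
  xx <- c(-g, -g, g, g, diag_add)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))

  well_posed <- (base_bc == "dirichlet" && length(base_u)) ||
    (surface_bc == "dirichlet") ||
    (surface_bc == "robin" && bc$h_f > 0) || any(p$sink > 0)
  if (!well_posed)
    stop(paste("assembled system is singular: need a Dirichlet boundary,",
               "surface convection, or perfusion"), call. = FALSE)

  Tf4 <- bc$T_f^4
  list(A = A, b_lin = b, n = n,
       rad_flux = function(T) rad_coef * (T^4 - Tf4),
       has_radiation = any(rad_coef > 0),
       props_vec = p, vol = vol, exp_len = exp_len,
       base_u = base_u, base_g = base_g,
       surface_bc = surface_bc, base_bc = base_bc, surface_T = surface_T,
       bc = bc)
}

new_temperature_field <- function(grid, values, meta, props = NULL, bc = NULL,
                                  sys_opts = NULL) {
  structure(list(grid = grid, values = values, meta = meta,
                 props = props, bc = bc, sys_opts = sys_opts),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("temperature_field (%s): %d cells, T in [%.3f, %.3f] K\n",
              x$meta$type, length(x$values), min(x$values), max(x$values)))
  if (!is.null(x$meta$iterations))
    cat(sprintf("  %d outer iterations, residual %.3g\n",
                x$meta$iterations, x$meta$residual))
  invisible(x)
}

solve_factored <- function(A) {
  ch <- try(Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE),
            silent = TRUE)
  if (inherits(ch, "try-error"))
    stop("sparse factorization failed: the assembled system may be singular",
         call. = FALSE)
  function(b) as.numeric(Matrix::solve(ch, b))
}

#' Solve the steady-state Pennes bioheat equation
#'
#' Fixed-point outer iteration on the radiative surface term: the quartic
#' flux is evaluated at the previous iterate and moved to the right-hand
#' side, and the (constant) linear system is re-solved from a single sparse
#' Cholesky factorization until the relative nonlinear residual falls below
#' \code{tol}. Deterministic for fixed inputs.
#'
#' @inheritParams assemble_steady
#' @param tol Relative residual convergence threshold.
#' @param max_iter Maximum outer iterations.
#' @param T_init Optional initial iterate (K), scalar or per-cell vector.
#' @return A \code{"temperature_field"} whose \code{meta} records the solve
#'   type, outer iteration count and final relative residual.
#' @examples
#' g <- build_mesh(domain_spec(40, c(0, 10), 4), spacing = 2)
#' props <- list(healthy = default_tissue_props("healthy"),
#'               tumor = default_tissue_props("tumor"))
#' fld <- solve_steady(g, props, default_boundary_spec())
#' surface_delta_t(extract_surface_profile(fld))
#' @export
solve_steady <- function(grid, props, bc, tol = 1e-8, max_iter = 100L,
                         surface_bc = "robin", base_bc = "dirichlet",
                         surface_T = bc$T_f, T_init = NULL) {
  sys <- assemble_steady(grid, props, bc, surface_bc = surface_bc,
                         base_bc = base_bc, surface_T = surface_T)
  slv <- solve_factored(sys$A)
  T_cur <- if (is.null(T_init)) rep(bc$T_core, sys$n)
           else if (length(T_init) == 1L) rep(T_init, sys$n)
           else T_init
  b_norm <- max(sqrt(sum(sys$b_lin^2)), .Machine$double.xmin)
  rel <- Inf; it <- 0L
  repeat {
    it <- it + 1L
    b <- sys$b_lin - sys$rad_flux(T_cur)
    T_cur <- slv(b)
    if (any(!is.finite(T_cur)))
      stop("non-finite temperatures during steady solve", call. = FALSE)
    resid <- as.numeric(sys$A %*% T_cur) - (sys$b_lin - sys$rad_flux(T_cur))
    rel <- sqrt(sum(resid^2)) / b_norm
    if (rel < tol || (!sys$has_radiation)) break
    if (it >= max_iter)
      stop(sprintf(
        "steady solve did not converge: residual %.3g after %d iterations",
        rel, it), call. = FALSE)
  }
  if (rel >= tol && sys$has_radiation)
    stop(sprintf(
      "steady solve did not converge: residual %.3g after %d iterations",
      rel, it), call. = FALSE)
  new_temperature_field(grid, T_cur,
                        meta = list(type = "steady", iterations = it,
                                    residual = rel),
                        props = props, bc = bc,
                        sys_opts = list(surface_bc = surface_bc,
                                        base_bc = base_bc,
                                        surface_T = surface_T))
}

#' Solve the transient Pennes bioheat equation
#'
#' Implicit (backward Euler) time stepping with the radiative flux lagged by
#' one step; the linearized step matrix is factored once. As \code{t_end}
#' grows the state contracts toward the steady solution.
#'
#' @inheritParams solve_steady
#' @param T_init Initial state: a \code{"temperature_field"} or a uniform
#'   temperature in K.
#' @param dt Time step, s.
#' @param t_end Final time, s (number of steps = \code{round(t_end/dt)}).
#' @return A \code{"temperature_field"} for the final time; when the grid has
#'   curved-surface bookkeeping, \code{meta$series} is a data frame of the
#'   surface temperature difference (degrees C) after every step.
#' @export
solve_transient <- function(grid, props, bc, T_init, dt, t_end,
                            surface_bc = "robin", base_bc = "dirichlet",
                            surface_T = bc$T_f) {
  if (dt <= 0 || t_end < dt)
    stop("need dt > 0 and t_end >= dt", call. = FALSE)
  sys <- assemble_steady(grid, props, bc, surface_bc = surface_bc,
                         base_bc = base_bc, surface_T = surface_T)
  T_cur <- if (inherits(T_init, "temperature_field")) T_init$values
           else rep(as.numeric(T_init), sys$n)
  if (length(T_cur) != sys$n)
    stop("T_init does not match the grid", call. = FALSE)
  m_coef <- sys$props_vec$rho * sys$props_vec$c * sys$vol / dt
  slv <- solve_factored(sys$A + Matrix::Diagonal(sys$n, m_coef))
  nstep <- max(1L, as.integer(round(t_end / dt)))
  track <- !is.null(grid$surface) && nrow(grid$surface) > 0
  series <- if (track) numeric(nstep) else NULL
  for (s in seq_len(nstep)) {
    b <- sys$b_lin - sys$rad_flux(T_cur) + m_coef * T_cur
    T_cur <- slv(b)
    if (any(!is.finite(T_cur)))
      stop(sprintf("non-finite temperatures at time step %d", s),
           call. = FALSE)
    if (track) {
      Ts <- T_cur[grid$surface$ucell]
      series[s] <- max(Ts) - min(Ts)
    }
  }
  meta <- list(type = "transient", steps = nstep, dt = dt, t_end = t_end)
  if (track) meta$series <- data.frame(t_s = dt * seq_len(nstep),
                                       delta_T_C = series)
  new_temperature_field(grid, T_cur, meta, props = props, bc = bc,
                        sys_opts = list(surface_bc = surface_bc,
                                        base_bc = base_bc,
                                        surface_T = surface_T))
}

#' Audit the steady-state energy balance of a solved field
#'
#' Recomputes, from the converged temperatures, the conductive influx across
#' the flat base, the metabolic source, the perfusion sink and the surface
#' convective and radiative losses (all W per unit depth), together with the
#' net imbalance. For a converged steady field the relative imbalance is at
#' the level of the solver residual.
#'
#' @param field A steady \code{"temperature_field"} from
#'   \code{\link{solve_steady}}.
#' @return A list of named components plus \code{imbalance} and
#'   \code{rel_imbalance}.
#' @export
energy_balance <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  grid <- field$grid
  sys <- assemble_steady(grid, field$props, field$bc,
                         surface_bc = field$sys_opts$surface_bc,
                         base_bc = field$sys_opts$base_bc,
                         surface_T = field$sys_opts$surface_T)
  T <- field$values
  p <- sys$props_vec
  base_in <- if (length(sys$base_u))
    sum(sys$base_g * (sys$bc$T_core - T[sys$base_u])) else 0
  metabolic <- sum(p$q_met * sys$vol)
  perfusion <- sum(p$sink * sys$vol * (T - p$T_a))
  if (sys$surface_bc == "robin") {
    convective <- sum(sys$bc$h_f * sys$exp_len * (T - sys$bc$T_f))
    radiative <- sum(sys$rad_flux(T))
  } else {
    # Dirichlet rim: the conductive outflux through the rim faces plays the
    # role of the surface loss.
    w <- which(grid$n_exposed[grid$in_cells] > 0L)
    h_m <- grid$spacing * MM
    d_m <- rep(h_m / 2, length(w))
    if (grid$kind == "semicircle") {
      cc <- cell_centers(grid, w)
      d_mm <- grid$spec$R1 - sqrt(cc[, "x"]^2 + cc[, "y"]^2)
      d_m <- pmax(d_mm, 1e-3 * grid$spacing) * MM
    }
    nexp <- grid$n_exposed[grid$in_cells][w]
    convective <- sum(p$k[w] * nexp * h_m / d_m * (T[w] - sys$surface_T))
    radiative <- 0
  }
  out <- base_in + metabolic
  loss <- convective + radiative + perfusion
  list(base_influx = base_in, metabolic = metabolic,
       convective = convective, radiative = radiative,
       perfusion = perfusion,
       imbalance = out - loss,
       rel_imbalance = abs(out - loss) /
         max(abs(c(base_in, metabolic, convective, radiative, perfusion,
                   .Machine$double.xmin))))
}
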