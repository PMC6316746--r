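# Run configuration: a nested key-value structure (read from YAML) that
# fully determines a simulation. Unknown keys are rejected; temperatures may
# be given with an explicit _K or _C suffix and are stored in Kelvin.

#' Default run configuration
#'
#' A fully-populated configuration whose physical block equals the published
#' study parameter set: k = 0.48 W/(m K), core 309.5 K, ambient 293 K,
#' perfusion 1e-4 1/s, blood density 1100 kg/m^3, h_f = 15 W/(m^2 K), blood
#' specific heat 3300 J/(kg K), Stefan--Boltzmann constant 5.69e-8, skin
#' emissivity 0.98, healthy metabolic source 0. The scenario block defaults
#' to a 60 mm phantom with a 3 mm tumor at (10, 0) mm.
#'
#' @return A named nested list of class \code{"run_config"}.
#' @export
default_run_config <- function() {
  structure(list(
    scenario = list(R1_mm = 60, tumor_x_mm = 10, tumor_y_mm = 0, R2_mm = 3),
    solver = list(spacing_mm = 0.5, tol = 1e-8, max_iter = 100,
                  mode = "steady", dt_s = 100, t_end_s = 10000),
    tissue = list(
      healthy = list(k_W_mK = 0.48, rho_kg_m3 = 1100, c_J_kgK = 3300,
                     q_met_W_m3 = 0, omega_b_per_s = 1e-4,
                     rho_b_kg_m3 = 1100, c_b_J_kgK = 3300, T_a_K = 293),
      tumor = list(k_W_mK = 0.48, rho_kg_m3 = 1100, c_J_kgK = 3300,
                   q_met_W_m3 = 65000, omega_b_per_s = 1e-4,
                   rho_b_kg_m3 = 1100, c_b_J_kgK = 3300, T_a_K = 293)),
    boundary = list(h_f_W_m2K = 15, epsilon = 0.98, sigma_W_m2K4 = 5.69e-8,
                    T_f_K = 293, T_core_K = 309.5),
    output = list(field = NULL, profile = NULL, chart = NULL),
    sweep = list(position = c(10, 0), R1_mm = c(40, 50, 60, 70, 80),
                 R2_mm = 1:10),
    log_level = "info"), class = "run_config")
}

# Temperature keys that accept a _K or _C suffix, per block.
temp_keys <- list(tissue = "T_a", boundary = c("T_f", "T_core"))

normalize_temps <- function(block, base_names, where) {
  for (bn in base_names) {
    kk <- paste0(bn, "_K"); kc <- paste0(bn, "_C")
    if (!is.null(block[[kc]])) {
      if (!is.null(block[[kk]]))
        stop(sprintf("%s: give %s or %s, not both", where, kk, kc),
             call. = FALSE)
      block[[kk]] <- celsius_to_kelvin(block[[kc]])
      block[[kc]] <- NULL
    }
  }
  block
}

check_keys <- function(given, allowed, where) {
  extra <- setdiff(names(given), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
}

#' Validate (and normalize) a run configuration
#'
#' Rejects unknown keys, converts Celsius-suffixed temperatures to Kelvin
#' and checks every physical value through the \code{\link{tissue_props}} /
#' \code{\link{boundary_spec}} / \code{\link{domain_spec}} invariants.
#' Missing keys inherit the defaults of \code{\link{default_run_config}}.
#'
#' @param config A named nested list (e.g. parsed from YAML).
#' @return The validated, fully-populated \code{"run_config"}.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a named list", call. = FALSE)
  def <- unclass(default_run_config())
  check_keys(config, names(def), "config")
  tissue_keys <- c("k_W_mK", "rho_kg_m3", "c_J_kgK", "q_met_W_m3",
                   "omega_b_per_s", "rho_b_kg_m3", "c_b_J_kgK",
                   "T_a_K", "T_a_C")
  bnd_keys <- c("h_f_W_m2K", "epsilon", "sigma_W_m2K4",
                "T_f_K", "T_f_C", "T_core_K", "T_core_C")
  if (!is.null(config$scenario))
    check_keys(config$scenario, names(def$scenario), "scenario")
  if (!is.null(config$solver))
    check_keys(config$solver, names(def$solver), "solver")
  if (!is.null(config$tissue)) {
    check_keys(config$tissue, c("healthy", "tumor"), "tissue")
    for (rg in names(config$tissue)) {
      check_keys(config$tissue[[rg]], tissue_keys, paste0("tissue$", rg))
      config$tissue[[rg]] <- normalize_temps(config$tissue[[rg]], "T_a",
                                             paste0("tissue$", rg))
    }
  }
  if (!is.null(config$boundary)) {
    check_keys(config$boundary, bnd_keys, "boundary")
    config$boundary <- normalize_temps(config$boundary, c("T_f", "T_core"),
                                       "boundary")
  }
  if (!is.null(config$output))
    check_keys(config$output, names(def$output), "output")
  if (!is.null(config$sweep))
    check_keys(config$sweep, names(def$sweep), "sweep")

  merged <- def
  for (top in names(config)) {
    if (is.list(config[[top]]) && is.list(merged[[top]]))
      merged[[top]] <- modifyList(merged[[top]], config[[top]])
    else merged[[top]] <- config[[top]]
  }
  if (!merged$solver$mode %in% c("steady", "transient"))
    stop("solver$mode must be 'steady' or 'transient'", call. = FALSE)
  if (merged$solver$spacing_mm <= 0)
    stop("solver$spacing_mm must be positive", call. = FALSE)
  # these constructors enforce the physical invariants
  config_domain(merged)
  config_props(merged)
  config_bc(merged)
  structure(merged, class = "run_config")
}

config_domain <- function(cfg) {
  s <- cfg$scenario
  if (s$R2_mm > 0) domain_spec(s$R1_mm, c(s$tumor_x_mm, s$tumor_y_mm),
                               s$R2_mm)
  else domain_spec(s$R1_mm)
}

config_props <- function(cfg) {
  mk <- function(b) tissue_props(k = b$k_W_mK, rho = b$rho_kg_m3,
                                 c = b$c_J_kgK, q_met = b$q_met_W_m3,
                                 omega_b = b$omega_b_per_s,
                                 rho_b = b$rho_b_kg_m3, c_b = b$c_b_J_kgK,
                                 T_a = b$T_a_K)
  list(healthy = mk(cfg$tissue$healthy), tumor = mk(cfg$tissue$tumor))
}

config_bc <- function(cfg) {
  b <- cfg$boundary
  boundary_spec(h_f = b$h_f_W_m2K, epsilon = b$epsilon,
                sigma = b$sigma_W_m2K4, T_f = b$T_f_K,
                T_core = b$T_core_K)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file path.
#' @return A validated \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such config file: %s", path), call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

#' Deterministic hash of a configuration
#'
#' A short polynomial rolling hash over the canonical deparse of the object;
#' used to stamp chart files so identical configurations produce identical
#' provenance strings.
#'
#' @param x Any R object.
#' @return An 8-hex-digit character scalar.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
             collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run a single forward simulation from a configuration
#'
#' Solves the configured scenario, extracts the surface profile and the
#' diagnostic quantities, writes any configured output files atomically, and
#' prints one machine-parseable summary line
#' (\code{simulate: key=value ...}). When the scenario has a tumor, a
#' tumor-free companion solve provides the baseline used for the
#' thermal-contrast and presence outputs.
#'
#' @param config A \code{"run_config"}, a named list, or a YAML path.
#' @param quiet Suppress the summary line.
#' @return Invisibly, a list with the solved field, profile, \code{delta_T_C},
#'   \code{baseline_delta_T_C}, \code{contrast_C}, \code{T_max_C} and
#'   \code{tumor_present}.
#' @export
run_simulate <- function(config = default_run_config(), quiet = FALSE) {
  cfg <- resolve_config(config)
  spec <- config_domain(cfg)
  props <- config_props(cfg)
  bc <- config_bc(cfg)
  grid <- build_mesh(spec, cfg$solver$spacing_mm)
  slv <- function(g) {
    if (cfg$solver$mode == "transient")
      solve_transient(g, props, bc, T_init = bc$T_f,
                      dt = cfg$solver$dt_s, t_end = cfg$solver$t_end_s)
    else solve_steady(g, props, bc, tol = cfg$solver$tol,
                      max_iter = cfg$solver$max_iter)
  }
  field <- slv(grid)
  profile <- extract_surface_profile(field)
  dt_obs <- surface_delta_t(profile)
  base_dt <- if (spec$R2 > 0) {
    surface_delta_t(slv(build_mesh(domain_spec(spec$R1),
                                   cfg$solver$spacing_mm)))
  } else dt_obs
  contrast <- dt_obs - base_dt
  mx <- max_temperature(field)
  if (!is.null(cfg$output$field)) write_field_table(field, cfg$output$field)
  if (!is.null(cfg$output$profile))
    write_profile_table(profile, cfg$output$profile)
  if (!quiet)
    cat(sprintf(
      "simulate: delta_T_C=%.6f baseline_delta_T_C=%.6f contrast_C=%.6f T_max_C=%.6f tumor_present=%s\n",
      dt_obs, base_dt, contrast, mx$T_max_C,
      tolower(contrast > 0.05)))
  invisible(list(field = field, profile = profile, delta_T_C = dt_obs,
                 baseline_delta_T_C = base_dt, contrast_C = contrast,
                 T_max_C = mx$T_max_C, max_location_mm = mx$location,
                 tumor_present = contrast > 0.05))
}

#' Build and write an estimation chart from a configuration
#'
#' Uses the \code{sweep} block (position, R1 and R2 grids) together with the
#' configured tissue/boundary/solver blocks; writes the chart to
#' \code{output$chart} when set.
#'
#' @inheritParams run_simulate
#' @return Invisibly, the \code{"estimation_chart"}.
#' @export
run_chart <- function(config, quiet = FALSE) {
  cfg <- resolve_config(config)
  sw <- cfg$sweep
  chart <- build_chart(as.numeric(sw$position), as.numeric(sw$R1_mm),
                       as.numeric(sw$R2_mm),
                       props = config_props(cfg), bc = config_bc(cfg),
                       spacing = cfg$solver$spacing_mm,
                       tol = cfg$solver$tol,
                       max_iter = cfg$solver$max_iter)
  if (!is.null(cfg$output$chart)) write_chart(chart, cfg$output$chart)
  if (!quiet)
    cat(sprintf("chart: position=(%g,%g) entries=%d provenance=%s\n",
                chart$position[["x"]], chart$position[["y"]],
                nrow(chart$entries), chart$provenance))
  invisible(chart)
}

#' Estimate tumor size from a chart file or the packaged reference charts
#'
#' @param chart \code{"reference"} (use the packaged published charts) or a
#'   path to a chart file written by \code{\link{write_chart}}.
#' @param position Tumor-position key: numeric (x, y) in mm. Required (and
#'   checked) for \code{"reference"}; for chart files it is checked against
#'   the file's position when supplied.
#' @param R1 Breast radius, mm.
#' @param delta_t Observed surface temperature difference, degrees C.
#' @param baseline_margin Presence margin, degrees C.
#' @param quiet Suppress the printed estimate.
#' @return Invisibly, the \code{"tumor_estimate"}.
#' @export
run_estimate <- function(chart, position = NULL, R1, delta_t,
                         baseline_margin = 0.05, quiet = FALSE) {
  if (identical(chart, "reference")) {
    charts <- load_reference_charts()
    if (is.null(position))
      stop("position (x, y) is required with the reference charts",
           call. = FALSE)
    key <- chart_position_key(position[[1]], position[[2]])
    if (!key %in% names(charts))
      stop(sprintf("no reference chart at position (%g, %g); available: %s",
                   position[[1]], position[[2]],
                   paste(names(charts), collapse = ", ")), call. = FALSE)
    ch <- charts[[key]]
  } else {
    ch <- read_chart(chart)
    if (!is.null(position) &&
        !isTRUE(all.equal(as.numeric(ch$position), as.numeric(position))))
      stop(sprintf("chart file is for position (%g, %g), not (%g, %g)",
                   ch$position[["x"]], ch$position[["y"]],
                   position[[1]], position[[2]]), call. = FALSE)
  }
  est <- estimate_tumor(ch, R1, delta_t, baseline_margin = baseline_margin)
  if (!quiet) print(est)
  invisible(est)
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    return(read_run_config(config))
  if (inherits(config, "run_config")) return(validate_run_config(unclass(config)))
  validate_run_config(config)
}
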