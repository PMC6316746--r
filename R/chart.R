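# Estimation charts: tables mapping (tumor position, breast radius R1,
# tumor radius R2) to the surface temperature difference, plus the inverse
# lookup that turns an observed difference into a size estimate.

#' Construct an estimation chart
#'
#' @param position Numeric length-2 tumor center (x, y), mm.
#' @param entries Data frame with columns \code{R1_mm}, \code{R2_mm},
#'   \code{delta_T_C}; every (R1, R2) pair must be unique and all
#'   differences non-negative.
#' @param provenance \code{"reference_fixture"} for packaged published
#'   tables, or \code{"simulated:<config hash>"} for solver-built charts.
#' @param baseline Optional named numeric: tumor-free surface temperature
#'   difference per R1 value (names are the R1 values). Used by the
#'   presence decision in \code{\link{estimate_tumor}}; reference fixtures
#'   have no baseline (treated as 0).
#' @return An object of class \code{"estimation_chart"}.
#' @export
estimation_chart <- function(position, entries,
                             provenance = "reference_fixture",
                             baseline = NULL) {
  stopifnot(is.numeric(position), length(position) == 2L)
  need <- c("R1_mm", "R2_mm", "delta_T_C")
  if (!is.data.frame(entries) || !all(need %in% names(entries)))
    stop("entries must be a data frame with columns R1_mm, R2_mm, delta_T_C",
         call. = FALSE)
  entries <- entries[order(entries$R1_mm, entries$R2_mm), need,
                     drop = FALSE]
  rownames(entries) <- NULL
  if (anyDuplicated(entries[c("R1_mm", "R2_mm")]))
    stop("duplicate (R1, R2) pairs in chart entries", call. = FALSE)
  if (any(!is.finite(entries$delta_T_C)) || any(entries$delta_T_C < 0))
    stop("chart delta_T_C values must be finite and non-negative",
         call. = FALSE)
  structure(list(position = c(x = position[[1]], y = position[[2]]),
                 entries = entries, provenance = provenance,
                 baseline = baseline),
            class = "estimation_chart")
}

#' @export
print.estimation_chart <- function(x, ...) {
  cat(sprintf(
    "estimation_chart at position (%g, %g) mm [%s]\n  %d entries: R1 in {%s} mm, R2 in {%s} mm\n",
    x$position[["x"]], x$position[["y"]], x$provenance, nrow(x$entries),
    paste(sort(unique(x$entries$R1_mm)), collapse = ", "),
    paste(sort(unique(x$entries$R2_mm)), collapse = ", ")))
  invisible(x)
}

#' Canonical key for a tumor position
#'
#' @param x,y Tumor center coordinates in mm.
#' @return Character key such as \code{"x10_y0"}.
#' @export
chart_position_key <- function(x, y) sprintf("x%g_y%g", x, y)

#' Load the packaged published estimation charts
#'
#' Returns the three reference charts (tumor positions (10, 0), (10, 10) and
#' (0, 10) mm) transcribed from the published theoretical estimation tables:
#' 5 breast radii (40--80 mm) by 10 tumor radii (1--10 mm), surface
#' temperature differences in degrees Celsius at two-decimal precision.
#'
#' @return Named list of three \code{"estimation_chart"} objects; names are
#'   \code{\link{chart_position_key}} keys.
#' @examples
#' charts <- load_reference_charts()
#' estimate_tumor(charts$x10_y0, R1 = 50, delta_t_obs = 0.60)
#' @export
load_reference_charts <- function() {
  files <- c(x10_y0 = "chart_x10_y0.csv",
             x10_y10 = "chart_x10_y10.csv",
             x0_y10 = "chart_x0_y10.csv")
  out <- lapply(files, function(f) {
    path <- system.file("extdata", f, package = "bioheat2d", mustWork = TRUE)
    read_chart(path)
  })
  names(out) <- names(files)
  out
}

#' Build an estimation chart with the forward solver
#'
#' Sweeps the steady-state solver over all combinations of breast radius and
#' tumor radius at a fixed tumor position and records the surface
#' temperature difference of each solve. A tumor-free baseline solve per R1
#' is stored alongside (used by the presence decision).
#'
#' @param position Tumor center (x, y), mm.
#' @param R1_grid Breast radii to sweep, mm.
#' @param R2_grid Tumor radii to sweep, mm (positive).
#' @param props Tissue property list as in \code{\link{solve_steady}};
#'   defaults to \code{\link{default_tissue_props}} for both regions.
#' @param bc Boundary conditions; defaults to
#'   \code{\link{default_boundary_spec}}.
#' @param spacing Mesh spacing, mm.
#' @param tol,max_iter Passed to \code{\link{solve_steady}}.
#' @param include_baseline Solve the tumor-free baseline per R1 (default
#'   TRUE; calibration loops switch it off).
#' @return An \code{"estimation_chart"} with provenance
#'   \code{"simulated:<hash>"} where the hash digests the full sweep
#'   configuration.
#' @export
build_chart <- function(position, R1_grid, R2_grid,
                        props = list(healthy = default_tissue_props("healthy"),
                                     tumor = default_tissue_props("tumor")),
                        bc = default_boundary_spec(),
                        spacing = 0.5, tol = 1e-8, max_iter = 100L,
                        include_baseline = TRUE) {
  stopifnot(length(R1_grid) >= 1L, length(R2_grid) >= 1L, all(R2_grid > 0))
  # validate the whole sweep before any solve
  for (R1 in R1_grid) for (R2 in R2_grid) {
    ok <- tryCatch({ domain_spec(R1, position, R2); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      stop(sprintf("invalid sweep member R1=%g mm, R2=%g mm at (%g, %g): %s",
                   R1, R2, position[[1]], position[[2]],
                   conditionMessage(ok)), call. = FALSE)
  }
  cfg <- list(position = as.numeric(position), R1_grid = R1_grid,
              R2_grid = R2_grid, props = props, bc = bc, spacing = spacing,
              tol = tol, max_iter = max_iter)
  delta_for <- function(R1, R2) {
    spec <- if (R2 > 0) domain_spec(R1, position, R2) else domain_spec(R1)
    fld <- solve_steady(build_mesh(spec, spacing), props, bc,
                        tol = tol, max_iter = max_iter)
    surface_delta_t(extract_surface_profile(fld))
  }
  grid_df <- expand.grid(R2_mm = R2_grid, R1_mm = R1_grid,
                         KEEP.OUT.ATTRS = FALSE)
  grid_df$delta_T_C <- mapply(function(r1, r2) delta_for(r1, r2),
                              grid_df$R1_mm, grid_df$R2_mm)
  baseline <- NULL
  if (include_baseline) {
    baseline <- vapply(R1_grid, function(r1) delta_for(r1, 0), numeric(1))
    names(baseline) <- as.character(R1_grid)
  }
  estimation_chart(position, grid_df[c("R1_mm", "R2_mm", "delta_T_C")],
                   provenance = paste0("simulated:", config_hash(cfg)),
                   baseline = baseline)
}

#' Estimate tumor size from an observed surface temperature difference
#'
#' Inverse chart lookup: within the chart column for the given breast radius
#' \code{R1}, finds the tumor radius whose tabulated surface temperature
#' difference is nearest the observation. Ties (several tumor radii at the
#' same minimal residual) are resolved toward the smallest radius, matching
#' how the published worked examples resolve repeated column values. No
#' interpolation is performed across R1 or between tabulated differences.
#'
#' The tumor-present flag compares the observation against the chart's
#' stored tumor-free baseline (0 for reference fixtures) plus
#' \code{baseline_margin}.
#'
#' @param chart An \code{"estimation_chart"}.
#' @param R1 Breast radius, mm; must be one of the chart's tabulated radii.
#' @param delta_t_obs Observed surface temperature difference, degrees C
#'   (non-negative).
#' @param baseline_margin Presence margin in degrees C (default 0.05).
#' @return An object of class \code{"tumor_estimate"}: \code{R2_est} (mm),
#'   \code{residual} (degrees C), \code{tumor_present}, and
#'   \code{candidates} (all radii tied at the minimal residual).
#' @examples
#' charts <- load_reference_charts()
#' estimate_tumor(charts$x0_y10, R1 = 70, delta_t_obs = 0.55)  # tie -> 6 mm
#' @export
estimate_tumor <- function(chart, R1, delta_t_obs, baseline_margin = 0.05) {
  stopifnot(inherits(chart, "estimation_chart"))
  if (!is.numeric(delta_t_obs) || length(delta_t_obs) != 1L ||
      !is.finite(delta_t_obs) || delta_t_obs < 0)
    stop("delta_t_obs must be a single non-negative temperature difference",
         call. = FALSE)
  col <- chart$entries[chart$entries$R1_mm == R1, , drop = FALSE]
  if (!nrow(col))
    stop(sprintf(
      "R1 = %g mm is not tabulated in this chart (available: %s mm); no interpolation is performed",
      R1, paste(sort(unique(chart$entries$R1_mm)), collapse = ", ")),
      call. = FALSE)
  res <- abs(col$delta_T_C - delta_t_obs)
  mres <- min(res)
  cand <- sort(col$R2_mm[res <= mres + 1e-9])
  base <- 0
  if (!is.null(chart$baseline)) {
    b <- chart$baseline[as.character(R1)]
    if (!is.na(b)) base <- unname(b)
  }
  structure(list(R2_est = cand[[1]], residual = mres,
                 tumor_present = delta_t_obs > base + baseline_margin,
                 candidates = cand, R1 = R1, delta_t_obs = delta_t_obs,
                 baseline = base),
            class = "tumor_estimate")
}

#' @export
print.tumor_estimate <- function(x, ...) {
  cat(sprintf(
    "tumor_estimate: R2 = %g mm (residual %.4g C) at R1 = %g mm, obs %.4g C\n",
    x$R2_est, x$residual, x$R1, x$delta_t_obs))
  cat(sprintf("  tumor_present: %s; candidates: %s mm\n",
              x$tumor_present, paste(x$candidates, collapse = ", ")))
  invisible(x)
}

#' Calibrate tumor tissue properties against a target chart
#'
#' Fits the tumor metabolic heat (and optionally perfusion rate) so that
#' charts produced by the forward solver match a target chart in the
#' least-squares sense. A deterministic coarse grid search over the bounds
#' brackets the optimum, which is then refined with \code{stats::optimize}
#' (one free parameter) or Nelder--Mead (two). Bounds are enforced; if the
#' optimum lies outside them the fit lands on the nearest bound.
#'
#' @param target An \code{"estimation_chart"} supplying the (position, R1,
#'   R2) combinations and target differences.
#' @param free Character subset of \code{c("q_met", "omega_b")}: the tumor
#'   parameters to fit.
#' @param lower,upper Named numeric bounds for the free parameters.
#' @param props Tissue property list; the fitted parameters overwrite the
#'   tumor entry.
#' @param bc Boundary conditions for the forward solves.
#' @param spacing Mesh spacing for the forward solves, mm.
#' @param n_grid Grid-search points per free parameter (default 7).
#' @param subset Optional logical/integer index selecting target entries to
#'   fit against (default: all).
#' @return A list of class \code{"tumor_calibration"}: fitted \code{par},
#'   tumor \code{\link{tissue_props}}, objective value, and a per-entry
#'   residual \code{report}.
#' @export
calibrate_tumor_props <- function(target, free = "q_met",
                                  lower, upper,
                                  props = list(
                                    healthy = default_tissue_props("healthy"),
                                    tumor = default_tissue_props("tumor")),
                                  bc = default_boundary_spec(),
                                  spacing = 2, n_grid = 7L, subset = NULL) {
  stopifnot(inherits(target, "estimation_chart"))
  free <- match.arg(free, c("q_met", "omega_b"), several.ok = TRUE)
  lower <- unlist(lower)[free]; upper <- unlist(upper)[free]
  if (any(is.na(lower)) || any(is.na(upper)) || any(!is.finite(lower)) ||
      any(!is.finite(upper)) || any(lower >= upper))
    stop("finite named bounds with lower < upper required for every free parameter",
         call. = FALSE)
  entries <- target$entries
  if (!is.null(subset)) entries <- entries[subset, , drop = FALSE]
  if (!nrow(entries)) stop("no target entries selected", call. = FALSE)
  pos <- as.numeric(target$position)

  chart_for <- function(par) {
    tum <- props$tumor
    for (nm in names(par)) tum[[nm]] <- unname(par[[nm]])
    tum <- do.call(tissue_props, unclass(tum))
    build_chart(pos, unique(entries$R1_mm), unique(entries$R2_mm),
                props = list(healthy = props$healthy, tumor = tum),
                bc = bc, spacing = spacing, include_baseline = FALSE)
  }
  objective <- function(parvec) {
    par <- setNames(as.list(parvec), free)
    sim <- chart_for(par)
    m <- merge(entries, sim$entries, by = c("R1_mm", "R2_mm"),
               suffixes = c("_target", "_sim"))
    if (nrow(m) != nrow(entries))
      stop("simulated chart does not cover all target entries", call. = FALSE)
    val <- sum((m$delta_T_C_sim - m$delta_T_C_target)^2)
    if (!is.finite(val))
      stop(sprintf("non-finite calibration objective at %s",
                   paste(free, signif(parvec, 6), sep = "=",
                         collapse = ", ")), call. = FALSE)
    val
  }

  # deterministic coarse grid search (endpoints included)
  grids <- lapply(free, function(nm)
    seq(lower[[nm]], upper[[nm]], length.out = n_grid))
  cand <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(cand) <- free
  fgrid <- apply(cand, 1L, objective)
  best <- which.min(fgrid)
  best_par <- cand[best, , drop = TRUE]
  best_val <- fgrid[best]

  if (length(free) == 1L) {
    lo <- max(lower[[1]], best_par - diff(range(grids[[1]])) / (n_grid - 1))
    hi <- min(upper[[1]], best_par + diff(range(grids[[1]])) / (n_grid - 1))
    opt <- optimize(objective, c(lo, hi),
                    tol = max(1e-8, (hi - lo) * 1e-5))
    if (opt$objective < best_val) {
      best_par <- setNames(opt$minimum, free)
      best_val <- opt$objective
    }
  } else {
    ctl <- list(maxit = 200L, reltol = 1e-8)
    opt <- optim(best_par, function(pv) {
      pv <- pmin(pmax(pv, lower), upper)   # box clamp
      objective(pv)
    }, method = "Nelder-Mead", control = ctl)
    pv <- pmin(pmax(opt$par, lower), upper)
    if (opt$value < best_val) { best_par <- setNames(pv, free); best_val <- opt$value }
  }

  fitted_chart <- chart_for(setNames(as.list(best_par), free))
  rep_df <- merge(entries, fitted_chart$entries, by = c("R1_mm", "R2_mm"),
                  suffixes = c("_target", "_fit"))
  rep_df$residual_C <- rep_df$delta_T_C_fit - rep_df$delta_T_C_target
  tum <- props$tumor
  for (nm in free) tum[[nm]] <- unname(best_par[[nm]])
  tum <- do.call(tissue_props, unclass(tum))
  structure(list(par = setNames(as.numeric(best_par), free),
                 tumor_props = tum, objective = best_val,
                 report = rep_df[order(rep_df$R1_mm, rep_df$R2_mm), ]),
            class = "tumor_calibration")
}

#' @export
print.tumor_calibration <- function(x, ...) {
  cat("tumor_calibration:\n  fitted:",
      paste(names(x$par), signif(x$par, 6), sep = " = ", collapse = ", "),
      sprintf("\n  objective (sum sq C^2): %.4g over %d entries\n",
              x$objective, nrow(x$report)))
  invisible(x)
}

#' Write an estimation chart to a delimited file
#'
#' Plain-text format with a commented header (position, provenance,
#' baseline) followed by a comma-separated table with columns
#' \code{position_x_mm, position_y_mm, R1_mm, R2_mm, delta_T_C,
#' delta_T_2dp}. \code{delta_T_C} is written at full precision (round-trip
#' bit-exact); \code{delta_T_2dp} is a two-decimal display column matching
#' the published tables' precision.
#'
#' @param chart An \code{"estimation_chart"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_chart <- function(chart, path) {
  stopifnot(inherits(chart, "estimation_chart"))
  e <- chart$entries
  atomic_write(path, function(con) {
    writeLines(c("# bioheat2d estimation chart",
                 sprintf("# position_x_mm: %.17g", chart$position[["x"]]),
                 sprintf("# position_y_mm: %.17g", chart$position[["y"]]),
                 sprintf("# provenance: %s", chart$provenance)), con)
    if (!is.null(chart$baseline))
      writeLines(sprintf("# baseline_R1_%s: %.17g", names(chart$baseline),
                         chart$baseline), con)
    writeLines(paste("position_x_mm", "position_y_mm", "R1_mm", "R2_mm",
                     "delta_T_C", "delta_T_2dp", sep = ","), con)
    writeLines(sprintf("%.17g,%.17g,%.17g,%.17g,%.17g,%.2f",
                       chart$position[["x"]], chart$position[["y"]],
                       e$R1_mm, e$R2_mm, e$delta_T_C, e$delta_T_C), con)
  })
  invisible(path)
}

#' Read an estimation chart written by \code{\link{write_chart}}
#'
#' @param path Chart file path.
#' @return An \code{"estimation_chart"}.
#' @export
read_chart <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such chart file: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z0-9_.]+):\\s*(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3L) m[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3L) m[3] else NA_character_,
                 character(1))
  getv <- function(key) vals[match(key, keys)]
  df <- read.table(text = lines[!grepl("^#", lines)], sep = ",",
                   header = TRUE)
  need <- c("position_x_mm", "position_y_mm", "R1_mm", "R2_mm", "delta_T_C")
  if (!all(need %in% names(df)))
    stop("chart file is missing required columns", call. = FALSE)
  for (nm in need) df[[nm]] <- as.numeric(df[[nm]])
  px <- df$position_x_mm[[1]]; py <- df$position_y_mm[[1]]
  bl_idx <- grep("^baseline_R1_", keys)
  baseline <- NULL
  if (length(bl_idx)) {
    baseline <- as.numeric(vals[bl_idx])
    names(baseline) <- sub("^baseline_R1_", "", keys[bl_idx])
  }
  prov <- getv("provenance")
  if (is.na(prov)) prov <- "reference_fixture"
  estimation_chart(c(px, py), df[c("R1_mm", "R2_mm", "delta_T_C")],
                   provenance = prov, baseline = baseline)
}
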