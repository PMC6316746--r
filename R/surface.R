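#' Extract the curved-surface (skin) temperature profile
#'
#' Reads the temperatures of the curved-surface cells of a solved (or
#' synthetic) field, ordered by polar angle theta in [0, pi]. The flat base
#' is a boundary condition, not skin, and is excluded; the corner cells at
#' theta near 0 and pi are skin and are included.
#'
#' @param field A \code{"temperature_field"} on a semicircular grid.
#' @return An object of class \code{"surface_profile"} with \code{theta}
#'   (radians, strictly increasing), \code{arc_mm} (arc position
#'   \code{R1 * theta}) and \code{T_surface} (K).
#' @export
extract_surface_profile <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  grid <- field$grid
  if (is.null(grid$surface) || nrow(grid$surface) < 3L)
    stop(paste("grid has no curved-surface bookkeeping (need a semicircular",
               "mesh with at least 3 surface cells)"), call. = FALSE)
  Ts <- field$values[grid$surface$ucell]
  if (any(!is.finite(Ts)))
    stop("non-finite surface temperatures", call. = FALSE)
  structure(list(theta = grid$surface$theta,
                 arc_mm = grid$spec$R1 * grid$surface$theta,
                 T_surface = Ts,
                 cell = grid$surface$cell),
            class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  cat(sprintf(
    "surface_profile: %d cells, theta in [%.3f, %.3f] rad, T in [%.3f, %.3f] K\n",
    length(x$theta), min(x$theta), max(x$theta),
    min(x$T_surface), max(x$T_surface)))
  invisible(x)
}

#' Surface temperature difference (the diagnostic statistic)
#'
#' Maximum minus minimum temperature along the curved skin arc, reported in
#' degrees Celsius (numerically equal to the difference in Kelvin). This is
#' the quantity tabulated in estimation charts and inverted by
#' \code{\link{estimate_tumor}}.
#'
#' @param profile A \code{"surface_profile"} (or a \code{"temperature_field"},
#'   from which the profile is extracted first).
#' @return Non-negative numeric, degrees Celsius.
#' @export
surface_delta_t <- function(profile) {
  if (inherits(profile, "temperature_field"))
    profile <- extract_surface_profile(profile)
  stopifnot(inherits(profile, "surface_profile"))
  if (!length(profile$T_surface)) stop("empty surface profile", call. = FALSE)
  max(profile$T_surface) - min(profile$T_surface)
}

#' Maximum temperature of a field and its location
#'
#' @param field A \code{"temperature_field"}.
#' @return List with \code{T_max_C} (degrees Celsius) and \code{location}
#'   (cell-center x, y in mm). Ties are broken toward the lowest cell index.
#' @export
max_temperature <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  k <- which.max(field$values)          # first maximum = lowest cell index
  cc <- cell_centers(field$grid, k)
  list(T_max_C = kelvin_to_celsius(field$values[[k]]),
       location = c(x = unname(cc[1, "x"]), y = unname(cc[1, "y"])))
}

#' Populate a temperature field from an analytic expression
#'
#' Evaluates \code{f(x, y)} (mm coordinates, result in K) at every interior
#' cell center, bypassing the solver. Used to give the surface-analysis
#' operations inputs with known exact answers.
#'
#' @param grid A \code{"bioheat_grid"}.
#' @param f Vectorized function of (x, y) in mm returning temperature in K.
#' @return A \code{"temperature_field"} with \code{meta$type = "synthetic"}.
#' @export
make_synthetic_field <- function(grid, f) {
  stopifnot(inherits(grid, "bioheat_grid"), is.function(f))
  cc <- cell_centers(grid)
  vals <- f(cc[, "x"], cc[, "y"])
  if (length(vals) == 1L) vals <- rep(vals, nrow(cc))
  if (length(vals) != nrow(cc) || any(!is.finite(vals)))
    stop("synthetic expression must evaluate to finite values at every cell",
         call. = FALSE)
  new_temperature_field(grid, as.numeric(vals),
                        meta = list(type = "synthetic"))
}

#' Export a temperature field as a gridded delimited table
#'
#' Writes one row per interior cell: \code{x_mm, y_mm, region, T_K, T_C}.
#' The file is written atomically (temporary file + rename).
#'
#' @param field A \code{"temperature_field"}.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_field_table <- function(field, path, sep = "\t") {
  stopifnot(inherits(field, "temperature_field"))
  cc <- cell_centers(field$grid)
  reg <- c("OUTSIDE", "HEALTHY", "TUMOR")[
    field$grid$region[field$grid$in_cells] + 1L]
  df <- data.frame(x_mm = cc[, "x"], y_mm = cc[, "y"], region = reg,
                   T_K = field$values,
                   T_C = kelvin_to_celsius(field$values))
  atomic_write(path, function(con) {
    write.table(format(df, digits = 17, trim = TRUE), con, sep = sep,
                quote = FALSE, row.names = FALSE)
  })
  invisible(path)
}

#' Export a surface profile as a delimited table
#'
#' Columns: \code{theta_rad, arc_mm, T_K, T_C}.
#'
#' @param profile A \code{"surface_profile"}.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_profile_table <- function(profile, path, sep = "\t") {
  stopifnot(inherits(profile, "surface_profile"))
  df <- data.frame(theta_rad = profile$theta, arc_mm = profile$arc_mm,
                   T_K = profile$T_surface,
                   T_C = kelvin_to_celsius(profile$T_surface))
  atomic_write(path, function(con) {
    write.table(format(df, digits = 17, trim = TRUE), con, sep = sep,
                quote = FALSE, row.names = FALSE)
  })
  invisible(path)
}

# Write via a temporary file in the same directory, then rename.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "w")
  ok <- FALSE
  tryCatch({ writer(con); ok <- TRUE }, finally = close(con))
  if (ok && !suppressWarnings(file.rename(tmp, path))) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
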