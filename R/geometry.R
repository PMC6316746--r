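# Region codes used in rasterized grids.
REGION_OUTSIDE <- 0L
REGION_HEALTHY <- 1L
REGION_TUMOR   <- 2L

#' Specify the semicircular breast domain with an embedded circular tumor
#'
#' The phantom is the upper half-disc of radius \code{R1} centered at the
#' origin (the flat diameter lies on the x-axis, the curved arc is the skin
#' surface). A tumor, when present, is a disc of radius \code{R2} centered at
#' \code{tumor_center}. \code{R2 = 0} encodes a tumor-free phantom. A tumor
#' centered on the flat base (e.g. center \code{(10, 0)}) is allowed; the part
#' of the disc below the base is clipped away during rasterization.
#'
#' @param R1 Breast (phantom) radius in mm; positive.
#' @param tumor_center Numeric length-2, tumor center \code{(x, y)} in mm.
#'   Must satisfy \code{y >= 0}.
#' @param R2 Tumor radius in mm; non-negative. When positive the tumor disc
#'   must lie strictly inside the curved boundary:
#'   \code{sqrt(x^2 + y^2) + R2 < R1}.
#' @return An object of class \code{"domain_spec"}.
#' @examples
#' domain_spec(60, c(10, 0), 3)
#' domain_spec(60)           # tumor-free baseline
#' @export
domain_spec <- function(R1, tumor_center = c(0, 0), R2 = 0) {
  if (!is.numeric(R1) || length(R1) != 1L || !is.finite(R1) || R1 <= 0)
    stop("R1 must be a single positive breast radius in mm", call. = FALSE)
  if (!is.numeric(R2) || length(R2) != 1L || !is.finite(R2) || R2 < 0)
    stop("R2 must be a single non-negative tumor radius in mm", call. = FALSE)
  if (!is.numeric(tumor_center) || length(tumor_center) != 2L ||
      any(!is.finite(tumor_center)))
    stop("tumor_center must be a finite numeric (x, y) pair in mm",
         call. = FALSE)
  cx <- tumor_center[[1]]; cy <- tumor_center[[2]]
  if (cy < 0)
    stop("tumor_center must lie in the closed upper half-plane (y >= 0)",
         call. = FALSE)
  if (R2 > 0 && sqrt(cx^2 + cy^2) + R2 >= R1)
    stop(sprintf(paste0(
      "tumor disc crosses the curved boundary: |center| + R2 = %.3f mm ",
      "must be < R1 = %.3f mm"), sqrt(cx^2 + cy^2) + R2, R1), call. = FALSE)
  structure(list(R1 = R1, tumor_center = c(x = cx, y = cy), R2 = R2),
            class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf("Semicircular breast domain: R1 = %g mm\n", x$R1))
  if (x$R2 > 0)
    cat(sprintf("  tumor: R2 = %g mm at (%g, %g) mm\n",
                x$R2, x$tumor_center[["x"]], x$tumor_center[["y"]]))
  else cat("  tumor-free\n")
  invisible(x)
}

#' Reflect a domain about the vertical axis
#'
#' Negates the x-coordinate of the tumor center; all other fields are kept.
#' Because the phantom is symmetric about x = 0, mirrored domains produce
#' mirrored temperature fields and identical surface temperature differences.
#'
#' @param spec A \code{\link{domain_spec}}.
#' @return The mirrored \code{domain_spec}.
#' @export
mirror_domain <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  domain_spec(spec$R1, c(-spec$tumor_center[["x"]], spec$tumor_center[["y"]]),
              spec$R2)
}

# Shared grid bookkeeping: exposure counts, base row, surface ordering.
# `region` is an nx-by-ny integer matrix (i indexes x, j indexes y).
finish_grid <- function(kind, spec, spacing, xc, yc, region,
                        arc_length_mm = NULL) {
  nx <- length(xc); ny <- length(yc)
  in_dom <- region != REGION_OUTSIDE
  # A face is "exposed" when its neighbor cell is outside the domain or beyond
  # the grid edge. The bottom edge (j = 1) is the flat base, never exposed;
  # for j > 1 the cell below an in-domain cell is always in-domain (the domain
  # is star-shaped from the base), so only right/left/top need checking.
  right_out <- rbind(!in_dom[-1L, , drop = FALSE], rep(TRUE, ny))
  left_out  <- rbind(rep(TRUE, ny), !in_dom[-nx, , drop = FALSE])
  top_out   <- cbind(!in_dom[, -1L, drop = FALSE], rep(TRUE, nx))
  n_exposed <- (right_out + left_out + top_out) * in_dom
  storage.mode(n_exposed) <- "integer"

  in_cells <- which(in_dom)                  # column-major linear indices
  index <- matrix(0L, nx, ny)
  index[in_cells] <- seq_along(in_cells)

  base <- in_dom & (col(region) == 1L)       # j == 1 row

  surf_lin <- which(in_dom & n_exposed > 0L)
  surface <- NULL
  if (kind == "semicircle" && length(surf_lin)) {
    si <- ((surf_lin - 1L) %% nx) + 1L
    sj <- ((surf_lin - 1L) %/% nx) + 1L
    theta <- atan2(yc[sj], xc[si])
    ord <- order(theta, xc[si]^2 + yc[sj]^2)
    surface <- data.frame(cell = surf_lin[ord],
                          ucell = index[surf_lin][ord],
                          i = si[ord], j = sj[ord],
                          theta = theta[ord],
                          n_exposed = n_exposed[surf_lin][ord])
  }

  staircase_mm <- sum(n_exposed) * spacing
  arc_correction <- if (!is.null(arc_length_mm) && staircase_mm > 0)
    arc_length_mm / staircase_mm else 1

  structure(list(kind = kind, spec = spec, spacing = spacing,
                 nx = nx, ny = ny, xc = xc, yc = yc,
                 region = region, in_cells = in_cells, index = index,
                 n_exposed = n_exposed, base = base, surface = surface,
                 arc_correction = arc_correction),
            class = "bioheat_grid")
}

#' Rasterize a breast domain onto a uniform cell-centered Cartesian grid
#'
#' Cells are labelled \code{OUTSIDE}, \code{HEALTHY} or \code{TUMOR} by the
#' position of their center relative to the analytic shapes (no
#' partial-volume weighting); accuracy is controlled by mesh refinement. The
#' grid spans \code{[-R1, R1] x [0, R1]} and is symmetric about x = 0, so
#' mirrored domains rasterize to exactly x-flipped grids.
#'
#' @param spec A \code{\link{domain_spec}}.
#' @param spacing Cell size in mm. Must satisfy \code{spacing <= R2/2} when a
#'   tumor is present so the tumor spans at least two cells across.
#' @return An object of class \code{"bioheat_grid"} with the region matrix,
#'   an ordered table of curved-surface cells (with polar angle
#'   \code{theta}), the flat-base row, and per-cell exposed-face counts.
#' @examples
#' g <- build_mesh(domain_spec(60, c(10, 0), 3), spacing = 1)
#' table(g$region)
#' @export
build_mesh <- function(spec, spacing = 0.5) {
  stopifnot(inherits(spec, "domain_spec"))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive cell size in mm", call. = FALSE)
  if (spec$R2 > 0 && spacing > spec$R2 / 2 + 1e-12)
    stop(sprintf(paste0(
      "spacing %.3g mm is too coarse for a tumor of radius %.3g mm; ",
      "use spacing <= R2/2 so the tumor spans at least two cells"),
      spacing, spec$R2), call. = FALSE)

  half_n <- as.integer(ceiling(spec$R1 / spacing - 1e-9))
  nx <- 2L * half_n; ny <- half_n
  xc <- (seq_len(nx) - 0.5 - half_n) * spacing
  yc <- (seq_len(ny) - 0.5) * spacing
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)

  region <- matrix(REGION_OUTSIDE, nx, ny)
  inside <- X * X + Y * Y < spec$R1^2
  region[inside] <- REGION_HEALTHY
  if (spec$R2 > 0) {
    dx <- X - spec$tumor_center[["x"]]
    dy <- Y - spec$tumor_center[["y"]]
    region[inside & (dx * dx + dy * dy <= spec$R2^2)] <- REGION_TUMOR
  }
  finish_grid("semicircle", spec, spacing, xc, yc, region,
              arc_length_mm = pi * spec$R1)
}

#' Rasterize a rectangular tissue strip (1D test geometry)
#'
#' A width-by-height rectangle with the flat base at y = 0. With lateral and
#' top faces insulated (convection coefficient and emissivity zero) the
#' steady solution is one-dimensional in y, which makes this geometry the
#' test bed for the perfused-slab closed form.
#'
#' @param height_mm Strip height (the 1D direction), mm.
#' @param width_mm Strip width, mm.
#' @param spacing Cell size, mm; must divide both extents.
#' @return A \code{"bioheat_grid"} of kind \code{"strip"} (no curved-surface
#'   bookkeeping).
#' @export
build_strip_mesh <- function(height_mm, width_mm, spacing = 0.5) {
  if (height_mm <= 0 || width_mm <= 0 || spacing <= 0)
    stop("height_mm, width_mm and spacing must be positive", call. = FALSE)
  nx <- as.integer(round(width_mm / spacing))
  ny <- as.integer(round(height_mm / spacing))
  if (abs(nx * spacing - width_mm) > 1e-9 || abs(ny * spacing - height_mm) > 1e-9)
    stop("spacing must divide width_mm and height_mm exactly", call. = FALSE)
  xc <- (seq_len(nx) - 0.5) * spacing
  yc <- (seq_len(ny) - 0.5) * spacing
  region <- matrix(REGION_HEALTHY, nx, ny)
  finish_grid("strip", NULL, spacing, xc, yc, region)
}

#' @export
print.bioheat_grid <- function(x, ...) {
  counts <- tabulate(x$region + 1L, nbins = 3L)
  cat(sprintf("bioheat_grid (%s): %d x %d cells at %g mm\n",
              x$kind, x$nx, x$ny, x$spacing))
  cat(sprintf("  outside %d, healthy %d, tumor %d; %d surface cells\n",
              counts[1], counts[2], counts[3],
              if (is.null(x$surface)) 0L else nrow(x$surface)))
  invisible(x)
}

# Cell-center coordinates (mm) of the k-th unknowns (vectorized).
cell_centers <- function(grid, ucells = seq_along(grid$in_cells)) {
  lin <- grid$in_cells[ucells]
  i <- ((lin - 1L) %% grid$nx) + 1L
  j <- ((lin - 1L) %/% grid$nx) + 1L
  cbind(x = grid$xc[i], y = grid$yc[j])
}
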