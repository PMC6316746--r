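# Shared fixtures: default property sets and small solver wrappers used
# across the suite. Coarse spacings keep individual solves at millisecond
# scale; accuracy-sensitive checks refine locally.

default_props <- function() {
  list(healthy = default_tissue_props("healthy"),
       tumor = default_tissue_props("tumor"))
}

# properties with the perfusion sink and metabolic source switched off
inert_props <- function(k = 0.48) {
  p <- tissue_props(k = k, rho = 1100, c = 3300, q_met = 0, omega_b = 0)
  list(healthy = p, tumor = p)
}

solve_scenario <- function(R1, center = c(0, 0), R2 = 0, spacing = 1,
                           props = default_props(),
                           bc = default_boundary_spec(), ...) {
  spec <- if (R2 > 0) domain_spec(R1, center, R2) else domain_spec(R1)
  solve_steady(build_mesh(spec, spacing), props, bc, ...)
}

delta_t_of <- function(field) surface_delta_t(extract_surface_profile(field))

# y coordinates (mm) of a field's interior cell centers
cell_centers_of <- function(field) {
  g <- field$grid
  j <- ((g$in_cells - 1L) %/% g$nx) + 1L
  g$yc[j]
}

# nx-by-ny matrix view of a field (NA outside the domain)
field_matrix <- function(field) {
  g <- field$grid
  M <- matrix(NA_real_, g$nx, g$ny)
  M[g$in_cells] <- field$values
  M
}
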