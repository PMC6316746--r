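test_that("constant boundary data yields the constant solution", {
  # all boundaries Dirichlet at 300 K, no sources or sinks
  bc <- boundary_spec(h_f = 0, epsilon = 0, T_f = 300, T_core = 300)
  f <- solve_scenario(40, spacing = 1, props = inert_props(), bc = bc,
                      surface_bc = "dirichlet", surface_T = 300)
  expect_lt(max(abs(f$values - 300)), 1e-8)

  # insulated curved surface, base Dirichlet: unique constant solution
  bc2 <- boundary_spec(h_f = 0, epsilon = 0, T_f = 293, T_core = 309.5)
  f2 <- solve_scenario(40, spacing = 1, props = inert_props(), bc = bc2)
  expect_lt(max(abs(f2$values - 309.5)), 1e-8)
})

test_that("flux stencil conserves: interior row sums vanish", {
  g <- build_mesh(domain_spec(40, c(0, 10), 3), spacing = 1)
  bc <- boundary_spec(h_f = 0, epsilon = 0)
  sys <- assemble_steady(g, inert_props(), bc)
  rs <- as.numeric(sys$A %*% rep(1, sys$n))
  interior <- which(g$n_exposed[g$in_cells] == 0L & !g$base[g$in_cells])
  expect_gt(length(interior), 100L)
  expect_lt(max(abs(rs[interior])), 1e-12)
})

test_that("assembly is invariant under x-reflection for an on-axis tumor", {
  g <- build_mesh(domain_spec(40, c(0, 10), 4), spacing = 1)
  sys <- assemble_steady(g, default_props(), default_boundary_spec())
  # unknown permutation induced by i -> nx + 1 - i
  lin <- g$in_cells
  i <- ((lin - 1L) %% g$nx) + 1L
  j <- ((lin - 1L) %/% g$nx) + 1L
  mlin <- (j - 1L) * g$nx + (g$nx + 1L - i)
  p <- g$index[mlin]
  expect_true(all(p > 0L))
  Ap <- sys$A[p, p]
  expect_equal(max(abs(Ap - sys$A)), 0)
  expect_identical(sys$b_lin[p], sys$b_lin)
})

test_that("1D strip solve matches the perfused-slab closed form", {
  orc <- perfused_slab_oracle(40, 0.48, 1e-4, 1100, 3300, 309.5, 293)
  g <- build_strip_mesh(40, 1, 0.25)
  bc <- boundary_spec(h_f = 0, epsilon = 0, T_f = 293, T_core = 309.5)
  f <- solve_steady(g, list(healthy = default_tissue_props("healthy")), bc)
  y <- cell_centers_of(f)
  err <- max(abs(f$values - orc$evaluate(y)))
  expect_lt(err / (309.5 - 293), 0.005)
})

test_that("a metabolic tumor source with insulated skin lifts T above the core", {
  # no perfusion, no surface loss: positive source must exceed the base data
  p <- inert_props()
  p$tumor <- tissue_props(k = 0.48, rho = 1100, c = 3300, q_met = 65000,
                          omega_b = 0)
  bc <- boundary_spec(h_f = 0, epsilon = 0, T_f = 293, T_core = 309.5)
  f <- solve_scenario(60, c(0, 30), 5, spacing = 1, props = p, bc = bc)
  mx <- max_temperature(f)
  expect_gt(mx$T_max_C, 309.5 - 273.15)
  expect_lt(sqrt(sum((mx$location - c(0, 30))^2)), 2 * 5)
})

test_that("source-free fields obey the discrete maximum principle", {
  # default (source-free healthy) props; blood temperature equals ambient
  p <- list(healthy = default_tissue_props("healthy"),
            tumor = default_tissue_props("healthy"))
  bc <- default_boundary_spec()
  f <- solve_scenario(60, c(10, 0), 3, spacing = 1, props = p, bc = bc)
  expect_gte(min(f$values), min(bc$T_core, bc$T_f) - 1e-9)
  expect_lte(max(f$values), max(bc$T_core, bc$T_f) + 1e-9)
})

test_that("steady-state energy balance closes", {
  f <- solve_scenario(60, c(10, 0), 3, spacing = 1)
  eb <- energy_balance(f)
  expect_lt(eb$rel_imbalance, 1e-3)
  expect_gt(eb$base_influx, 0)
  expect_gt(eb$metabolic, 0)
})

test_that("raising skin emissivity never warms the surface", {
  f_lo <- solve_scenario(60, spacing = 1, bc = boundary_spec(epsilon = 0.5))
  f_hi <- solve_scenario(60, spacing = 1, bc = boundary_spec(epsilon = 0.98))
  expect_lte(max(extract_surface_profile(f_hi)$T_surface -
                 extract_surface_profile(f_lo)$T_surface), 1e-10)
})

test_that("mirrored scenarios solve to exactly x-flipped fields", {
  s <- domain_spec(60, c(10, 10), 3)
  f1 <- solve_scenario(60, c(10, 10), 3, spacing = 1)
  f2 <- solve_scenario(60, c(-10, 10), 3, spacing = 1)
  M1 <- field_matrix(f1); M2 <- field_matrix(f2)
  expect_lt(max(abs(M1 - M2[f2$grid$nx:1, ]), na.rm = TRUE), 1e-10)
})

test_that("non-convergent configurations raise rather than return garbage", {
  g <- build_mesh(domain_spec(40), spacing = 2)
  expect_error(
    solve_steady(g, default_props(), default_boundary_spec(), max_iter = 1L),
    "did not converge")
})

test_that("the steady state is a fixed point of the transient scheme", {
  st <- solve_scenario(40, c(0, 10), 4, spacing = 2, tol = 1e-13)
  tr <- solve_transient(st$grid, default_props(), default_boundary_spec(),
                        T_init = st, dt = 10, t_end = 100)
  expect_lt(max(abs(tr$values - st$values)), 1e-6)
})

test_that("uniform Dirichlet data is constant in time", {
  bc <- boundary_spec(h_f = 0, epsilon = 0, T_f = 300, T_core = 300)
  g <- build_mesh(domain_spec(40), spacing = 2)
  tr <- solve_transient(g, inert_props(), bc, T_init = 300, dt = 10,
                        t_end = 200, surface_bc = "dirichlet",
                        surface_T = 300)
  expect_lt(max(abs(tr$values - 300)), 1e-8)
})

test_that("transient solutions contract monotonically toward steady state", {
  g <- build_mesh(domain_spec(40, c(0, 10), 4), spacing = 2)
  st <- solve_steady(g, default_props(), default_boundary_spec())
  errs <- sapply(c(1e3, 1e4, 1e5), function(te) {
    tr <- solve_transient(g, default_props(), default_boundary_spec(),
                          T_init = default_boundary_spec()$T_f,
                          dt = te / 100, t_end = te)
    max(abs(tr$values - st$values))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("transient solves report a surface delta-T time series", {
  g <- build_mesh(domain_spec(40, c(0, 10), 4), spacing = 2)
  tr <- solve_transient(g, default_props(), default_boundary_spec(),
                        T_init = 293, dt = 100, t_end = 1000)
  expect_s3_class(tr$meta$series, "data.frame")
  expect_equal(nrow(tr$meta$series), 10L)
  expect_true(all(is.finite(tr$meta$series$delta_T_C)))
})
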