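test_that("domain validation accepts the study geometries and rejects impossible ones", {
  expect_s3_class(domain_spec(60, c(10, 0), 3), "domain_spec")
  expect_s3_class(domain_spec(60, c(0, 0), 0), "domain_spec")
  expect_error(domain_spec(60, c(59, 0), 5), "crosses the curved boundary")
  expect_error(domain_spec(-5), "positive")
  expect_error(domain_spec(60, c(10, -1), 3), "upper half-plane")
  expect_error(domain_spec(60, c(0, 10), -1), "non-negative")
})

test_that("mirroring negates x, fixes the axis case, and is an involution", {
  s <- domain_spec(60, c(10, 10), 3)
  m <- mirror_domain(s)
  expect_equal(unname(m$tumor_center), c(-10, 10))
  expect_equal(m$R1, 60)
  expect_equal(m$R2, 3)
  axis <- domain_spec(60, c(0, 10), 3)
  expect_equal(mirror_domain(axis), axis)
  expect_equal(mirror_domain(mirror_domain(s)), s)
})

test_that("rasterized areas converge to the analytic shapes", {
  # tumor-free: semicircle area within 2% at 1 mm spacing
  g <- build_mesh(domain_spec(60), spacing = 1)
  area <- sum(g$region == 1L) * g$spacing^2
  expect_lt(abs(area - pi * 60^2 / 2) / (pi * 60^2 / 2), 0.02)
  expect_equal(sum(g$region == 2L), 0L)

  # tumor area within 5% of pi R2^2 at spacing R2/10 (interior tumor)
  for (R2 in c(3, 5)) {
    gt <- build_mesh(domain_spec(60, c(0, 20), R2), spacing = R2 / 10)
    t_area <- sum(gt$region == 2L) * gt$spacing^2
    expect_lt(abs(t_area - pi * R2^2) / (pi * R2^2), 0.05)
  }

  # finer-grid point-in-disc count at the flagship scenario
  gt <- build_mesh(domain_spec(60, c(0, 10), 3), spacing = 0.5)
  expect_lt(abs(sum(gt$region == 2L) * 0.25 - pi * 9) / (pi * 9), 0.05)
})

test_that("region labels partition the grid and meshing is deterministic", {
  g1 <- build_mesh(domain_spec(60, c(10, 0), 3), spacing = 0.5)
  g2 <- build_mesh(domain_spec(60, c(10, 0), 3), spacing = 0.5)
  expect_identical(g1$region, g2$region)
  expect_identical(g1$surface, g2$surface)
  expect_equal(sum(tabulate(g1$region + 1L, 3L)), g1$nx * g1$ny)
})

test_that("too-coarse meshes for the tumor are rejected with advice", {
  expect_error(build_mesh(domain_spec(60, c(0, 10), 3), spacing = 2),
               "finer|too coarse|R2/2")
})

test_that("surface cells are ordered by strictly increasing polar angle", {
  g <- build_mesh(domain_spec(60, c(10, 0), 3), spacing = 1)
  expect_true(all(diff(g$surface$theta) > 0))
  expect_true(all(g$surface$theta > 0 & g$surface$theta < pi))
})

test_that("boundary rasterization error shrinks under refinement", {
  errs <- sapply(c(1, 0.5, 0.25), function(h) {
    g <- build_mesh(domain_spec(60), spacing = h)
    abs(sum(g$region == 1L) * h^2 - pi * 60^2 / 2)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("mirrored domains rasterize to exactly x-flipped grids", {
  g <- build_mesh(domain_spec(60, c(10, 10), 3), spacing = 1)
  gm <- build_mesh(mirror_domain(domain_spec(60, c(10, 10), 3)), spacing = 1)
  expect_identical(gm$region, g$region[g$nx:1, ])
})

test_that("strip meshes are fully interior with a flat base", {
  g <- build_strip_mesh(40, 2, 0.5)
  expect_equal(g$nx, 4L)
  expect_equal(g$ny, 80L)
  expect_true(all(g$region == 1L))
  expect_equal(sum(g$base), 4L)
  expect_error(build_strip_mesh(40, 2, 0.3), "divide")
})
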