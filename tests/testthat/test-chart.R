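test_that("the packaged reference charts have the published structure and values", {
  charts <- load_reference_charts()
  expect_named(charts, c("x10_y0", "x10_y10", "x0_y10"))
  for (ch in charts) {
    expect_s3_class(ch, "estimation_chart")
    expect_equal(sort(unique(ch$entries$R1_mm)), c(40, 50, 60, 70, 80))
    expect_equal(sort(unique(ch$entries$R2_mm)), 1:10)
    expect_equal(nrow(ch$entries), 50L)
    expect_equal(ch$provenance, "reference_fixture")
    expect_true(all(ch$entries$delta_T_C >= 0))
  }
  lookup <- function(ch, r1, r2)
    ch$entries$delta_T_C[ch$entries$R1_mm == r1 & ch$entries$R2_mm == r2]
  expect_equal(lookup(charts$x10_y0, 50, 3), 0.60)
  expect_equal(lookup(charts$x10_y10, 60, 4), 0.54)
  expect_equal(lookup(charts$x0_y10, 70, 6), 0.55)
})

test_that("estimate_tumor reproduces the published worked lookups", {
  charts <- load_reference_charts()
  est <- estimate_tumor(charts$x10_y0, 50, 0.60)
  expect_equal(est$R2_est, 3)
  expect_equal(est$residual, 0)
  expect_true(est$tumor_present)

  # four tied entries at 0.55 C resolve to the smallest radius, 6 mm
  tie <- estimate_tumor(charts$x0_y10, 70, 0.55)
  expect_equal(tie$candidates, c(6, 7, 8, 9))
  expect_equal(tie$R2_est, 6)

  # no thermal contrast: no tumor flagged
  none <- estimate_tumor(charts$x10_y0, 60, 0.00)
  expect_false(none$tumor_present)

  expect_error(estimate_tumor(charts$x10_y0, 55, 0.60), "not tabulated")
  expect_error(estimate_tumor(charts$x10_y0, 50, -0.1), "non-negative")
})

test_that("estimate_tumor is an exact inverse on every fixture entry", {
  # brute-force linear-scan oracle, independent of the estimator internals
  charts <- load_reference_charts()
  for (ch in charts) {
    for (k in seq_len(nrow(ch$entries))) {
      r1 <- ch$entries$R1_mm[k]
      r2 <- ch$entries$R2_mm[k]
      dt <- ch$entries$delta_T_C[k]
      col_r2 <- ch$entries$R2_mm[ch$entries$R1_mm == r1]
      col_dt <- ch$entries$delta_T_C[ch$entries$R1_mm == r1]
      expected <- min(col_r2[abs(col_dt - dt) < 1e-12])  # smallest tied R2
      est <- estimate_tumor(ch, r1, dt)
      expect_equal(est$residual, 0)
      expect_equal(est$R2_est, expected)
    }
  }
})

test_that("simulated charts agree with manual single solves", {
  props <- default_props(); bc <- default_boundary_spec()
  ch <- build_chart(c(0, 10), R1_grid = c(40, 50), R2_grid = c(4, 6),
                    props = props, bc = bc, spacing = 2)
  expect_equal(nrow(ch$entries), 4L)
  expect_match(ch$provenance, "^simulated:")
  for (k in seq_len(nrow(ch$entries))) {
    manual <- delta_t_of(solve_scenario(ch$entries$R1_mm[k], c(0, 10),
                                        ch$entries$R2_mm[k], spacing = 2,
                                        props = props, bc = bc))
    expect_equal(ch$entries$delta_T_C[k], manual, tolerance = 1e-12)
  }
  # stored tumor-free baselines match direct baseline solves
  expect_equal(unname(ch$baseline[["40"]]),
               delta_t_of(solve_scenario(40, spacing = 2, props = props,
                                         bc = bc)), tolerance = 1e-12)
})

test_that("an inert tumor leaves chart entries at the baseline", {
  ch <- build_chart(c(0, 10), 40, c(4, 6), props = inert_props(),
                    bc = default_boundary_spec(), spacing = 2)
  expect_lt(max(abs(ch$entries$delta_T_C - ch$baseline[["40"]])), 1e-12)
})

test_that("mirrored positions produce identical charts", {
  a <- build_chart(c(10, 10), 40, 4, spacing = 2)
  b <- build_chart(c(-10, 10), 40, 4, spacing = 2)
  expect_lt(max(abs(a$entries$delta_T_C - b$entries$delta_T_C)), 1e-10)
})

test_that("invalid sweep members are reported with the offending pair", {
  expect_error(build_chart(c(30, 0), c(40, 60), c(5, 12), spacing = 2),
               "R1=40.*R2=12|invalid sweep")
})

test_that("chart files round-trip bit-exactly and deterministically", {
  ch <- build_chart(c(0, 10), c(40, 50), c(4, 6), spacing = 2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_chart(ch, f1)
  back <- read_chart(f1)
  expect_identical(back$entries$delta_T_C, ch$entries$delta_T_C)
  expect_identical(back$entries$R1_mm, ch$entries$R1_mm)
  expect_identical(unname(back$baseline), unname(ch$baseline))
  expect_identical(back$provenance, ch$provenance)
  expect_identical(as.numeric(back$position), as.numeric(ch$position))
  write_chart(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  # identical configuration -> identical provenance hash and file bytes
  ch2 <- build_chart(c(0, 10), c(40, 50), c(4, 6), spacing = 2)
  expect_identical(ch2$provenance, ch$provenance)
  f3 <- tempfile(fileext = ".csv")
  write_chart(ch2, f3)
  expect_identical(readLines(f3), readLines(f1))
})

test_that("calibration recovers a known tumor heat source", {
  q_true <- 50000
  props <- default_props()
  props$tumor <- tissue_props(k = 0.48, rho = 1100, c = 3300,
                              q_met = q_true, omega_b = 1e-4)
  target <- build_chart(c(0, 10), 50, c(4, 6), props = props, spacing = 2,
                        include_baseline = FALSE)
  fit <- calibrate_tumor_props(target, free = "q_met",
                               lower = c(q_met = 10000),
                               upper = c(q_met = 150000),
                               spacing = 2, n_grid = 7L)
  expect_lt(abs(fit$par[["q_met"]] - q_true) / q_true, 0.05)
  expect_s3_class(fit$report, "data.frame")
  expect_true(all(abs(fit$report$residual_C) < 0.01))
})

test_that("calibration bounds that exclude the truth pin the fit to a bound", {
  q_true <- 50000
  props <- default_props()
  props$tumor <- tissue_props(k = 0.48, rho = 1100, c = 3300,
                              q_met = q_true, omega_b = 1e-4)
  target <- build_chart(c(0, 10), 50, 4, props = props, spacing = 2,
                        include_baseline = FALSE)
  fit <- calibrate_tumor_props(target, free = "q_met",
                               lower = c(q_met = 60000),
                               upper = c(q_met = 120000),
                               spacing = 2, n_grid = 4L)
  expect_equal(fit$par[["q_met"]], 60000)
})
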