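test_that("EQD2 forward conversion reproduces hand-computed values", {
  expect_equal(eqd2_forward(30, 10, 3), 36)          # 30*(3+3)/(2+3)
  expect_equal(eqd2_forward(40, 20, 5), 40)          # 2 Gy/fx fixed point
  expect_equal(eqd2_forward(0, 10, 3), 0)
  expect_error(eqd2_forward(10, 5, 0), "alpha_beta")
  expect_error(eqd2_forward(-1, 5, 3), ">= 0")
})

test_that("EQD2 inverse solves the quadratic exactly", {
  expect_equal(eqd2_inverse(36, 10, 3), 30)
  expect_equal(eqd2_inverse(40, 20, 3), 40)
  expect_equal(eqd2_inverse(0, 10, 3), 0)
  expect_error(eqd2_inverse(-1, 10, 3), ">= 0")
})

test_that("forward/inverse round trip holds across the parameter sweep", {
  for (ab in c(1, 2, 3, 5, 10)) {
    for (n in 1:40) {
      D <- seq(0, 100, by = 5)
      back <- eqd2_inverse(eqd2_forward(D, n, ab), n, ab)
      expect_lt(max(abs(back - D) / pmax(D, 1)), 1e-9)
    }
  }
})

test_that("EQD2 sits on the correct side of physical dose by fraction size", {
  # d > 2 Gy -> EQD2 > D; d < 2 Gy -> EQD2 < D; equality at 2 Gy/fx
  expect_gt(eqd2_forward(30, 5, 3), 30)    # 6 Gy/fx
  expect_lt(eqd2_forward(30, 30, 3), 30)   # 1 Gy/fx
  expect_equal(eqd2_forward(30, 15, 3), 30)
  # strictly increasing in D
  D <- seq(0, 80, by = 0.5)
  expect_true(all(diff(eqd2_forward(D, 10, 3)) > 0))
})

test_that("grid conversion applies per-voxel alpha/beta by priority", {
  g <- small_geom(c(6, 6, 2))
  d <- uniform_dose(30, g)
  scheme <- fractionation(10)
  whole <- full_mask(g, "tissue")
  abm <- alpha_beta_map(data.frame(structure = "tissue", ab = 3, priority = 1))
  out <- eqd2_convert_grid(d, scheme, abm, list(whole))
  expect_equal(out$dose_kind, "EQD2")
  expect_lt(max(abs(out$values - 36)), 1e-12)
  # overlap resolved by priority: ab 2 (rank 1) wins over ab 10 (rank 2)
  half <- structure_mask("half", array(rep(c(TRUE, FALSE), each = prod(g$shape) / 2),
                                       g$shape), g)
  abm2 <- alpha_beta_map(data.frame(structure = c("half", "tissue"),
                                    ab = c(2, 10), priority = c(1, 2)))
  out2 <- eqd2_convert_grid(d, scheme, abm2, list(whole, half))
  expect_lt(max(abs(out2$values[half$mask] - 30 * (3 + 2) / (2 + 2))), 1e-12)
  expect_lt(max(abs(out2$values[!half$mask] - 30 * (3 + 10) / (2 + 10))), 1e-12)
})

test_that("2 Gy/fraction grids convert to themselves", {
  g <- small_geom()
  d <- uniform_dose(40, g)
  out <- eqd2_convert_grid(d, fractionation(20), alpha_beta_map(), list())
  expect_lt(max(abs(out$values - d$values)), 1e-12)
})

test_that("missing mapped structures are skipped with a warning", {
  g <- small_geom()
  d <- uniform_dose(30, g)
  abm <- alpha_beta_map(data.frame(structure = "ghost", ab = 2, priority = 1),
                        default_ab = 3)
  expect_warning(out <- eqd2_convert_grid(d, fractionation(10), abm, list()),
                 "ghost")
  expect_lt(max(abs(out$values - 36)), 1e-12)
})

test_that("dose scaling factors multiply EQD2 within scope", {
  g <- small_geom()
  eq <- uniform_dose(40, g, kind = "EQD2")
  expect_identical(apply_dsf(eq, 1)$values, eq$values)
  expect_lt(max(abs(apply_dsf(eq, 0.75)$values - 30)), 1e-12)
  half <- structure_mask("half", array(rep(c(TRUE, FALSE),
                                           each = prod(g$shape) / 2),
                                       g$shape), g)
  out <- apply_dsf(eq, 0.5, half)
  expect_lt(max(abs(out$values[half$mask] - 20)), 1e-12)
  expect_lt(max(abs(out$values[!half$mask] - 40)), 1e-12)
  expect_error(dose_scaling_factor(0), "\\(0, 1\\]")
  expect_error(dose_scaling_factor(1.2), "\\(0, 1\\]")
})

test_that("EQD2 summation is voxel-wise, commutative, and type-checked", {
  g <- small_geom()
  a <- uniform_dose(36, g, kind = "EQD2")
  b <- uniform_dose(14, g, kind = "EQD2")
  expect_identical(sum_eqd2(list(a))$values, a$values)
  expect_lt(max(abs(sum_eqd2(list(a, b))$values - 50)), 1e-12)
  expect_identical(sum_eqd2(list(a, b))$values, sum_eqd2(list(b, a))$values)
  phys <- uniform_dose(10, g, kind = "PHYSICAL")
  expect_error(sum_eqd2(list(a, phys)), "EQD2")
})

test_that("point-dose feasibility reproduces the worksheet example", {
  r <- point_dose_feasibility(60, 35, fractionation(5), 3)
  expect_equal(r$budget_B, 25)
  expect_equal(r$allowed_per_fraction, (-3 + sqrt(109)) / 2, tolerance = 1e-9)
  expect_equal(r$allowed_total, 5 * (-3 + sqrt(109)) / 2, tolerance = 1e-9)
  # forward substitution closes the loop
  expect_equal(eqd2_forward(r$allowed_total, 5, 3), 25, tolerance = 1e-9)
})

test_that("exhausted budgets and the large-alpha/beta limit behave", {
  r <- point_dose_feasibility(40, 45, fractionation(10), 3)
  expect_equal(r$budget_B, 0)
  expect_equal(r$allowed_total, 0)
  big <- point_dose_feasibility(60, 35, fractionation(5), 1e6)
  expect_lt(abs(big$allowed_total - big$budget_B) / big$budget_B, 1e-3)
})

test_that("feasibility closed loop recovers the constraint exactly", {
  set.seed(101)
  for (i in 1:200) {
    A <- runif(1, 20, 90)
    P <- runif(1, 0, A - 0.1)
    n <- sample(1:40, 1)
    ab <- runif(1, 1, 10)
    r <- point_dose_feasibility(A, P, fractionation(n), ab)
    cum <- P + eqd2_forward(r$allowed_total, n, ab)
    expect_lt(abs(cum - A), 1e-6)
  }
})

test_that("the worksheet fills calculated columns and round-trips CSV", {
  ws <- data.frame(oar = c("cord", "brainstem"), A = c(60, 55),
                   P = c(35, 60), n = c(5, 10), alpha_beta = c(3, 2))
  out_csv <- tempfile(fileext = ".csv")
  out <- pointdose_worksheet(ws, out_csv)
  expect_equal(out$B, c(25, 0))
  expect_equal(out$allowed_total[1], 18.60083, tolerance = 1e-4)
  expect_equal(out$allowed_total[2], 0)
  back <- utils::read.csv(out_csv)
  expect_equal(back$allowed_per_fraction, out$allowed_per_fraction,
               tolerance = 1e-9)
  expect_error(pointdose_worksheet(data.frame(x = 1)), "columns")
})
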