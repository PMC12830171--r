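test_that("a 2 Gy/fraction identity-chain course accumulates to its physical dose", {
  g <- small_geom(c(10, 10, 5))
  d <- uniform_dose(40, g)
  cr <- course_record("c1", d, fractionation(20))
  res <- accumulate(list(cr), g, list(full_mask(g)), alpha_beta_map())
  expect_lt(max(abs(res$summed_eqd2$values - 40)), 1e-9)
  expect_equal(res$summed_eqd2$dose_kind, "EQD2")
  expect_equal(res$provenance[[1]]$out_of_extent_voxels, 0)
})

test_that("two identical courses double and a DSF scales the contribution", {
  g <- small_geom()
  d <- uniform_dose(30, g)           # 36 EQD2 at n=10, ab=3
  c1 <- course_record("a", d, fractionation(10))
  c2 <- course_record("b", d, fractionation(10))
  res <- accumulate(list(c1, c2), g, list(), alpha_beta_map())
  expect_lt(max(abs(res$summed_eqd2$values - 72)), 1e-9)
  c3 <- course_record("c", uniform_dose(40, g), fractionation(20),
                      dsf = dose_scaling_factor(0.75))
  res2 <- accumulate(list(c3), g, list(), alpha_beta_map())
  expect_lt(max(abs(res2$summed_eqd2$values - 30)), 1e-9)
})

test_that("accumulation is order-invariant and ignores zero-dose courses", {
  set.seed(21)
  g <- small_geom(c(8, 8, 4))
  c1 <- course_record("a", random_dose(g, 50), fractionation(25))
  c2 <- course_record("b", random_dose(g, 30), fractionation(5))
  zero <- course_record("z", uniform_dose(0, g), fractionation(10))
  r12 <- accumulate(list(c1, c2), g, list(), alpha_beta_map())
  r21 <- accumulate(list(c2, c1), g, list(), alpha_beta_map())
  rz <- accumulate(list(c1, c2, zero), g, list(), alpha_beta_map())
  expect_identical(r12$summed_eqd2$values, r21$summed_eqd2$values)
  expect_lt(max(abs(rz$summed_eqd2$values - r12$summed_eqd2$values)), 1e-12)
})

test_that("errors propagate with course context and empty lists are rejected", {
  g <- small_geom()
  expect_error(accumulate(list(), g, list(), alpha_beta_map()),
               "at least one course")
  bad <- course_record("cX", uniform_dose(10, g), fractionation(5),
                       dsf_scope_structure = "missing")
  expect_error(accumulate(list(bad), g, list(), alpha_beta_map()), "cX")
})

test_that("per-course provenance records transform, dsf and coverage", {
  g <- small_geom(c(8, 8, 4))
  big <- grid_geometry(origin = c(-4, -4, -4), spacing = c(2, 2, 2),
                       shape = c(12, 12, 8))
  cr <- course_record("p", uniform_dose(12, big), fractionation(6),
                      transform = transform_translation(c(1, 0, 0)),
                      dsf = dose_scaling_factor(0.9), source_tps = "TPS-A")
  res <- accumulate(list(cr), g, list(), alpha_beta_map(version = "v2"))
  p <- res$provenance[[1]]
  expect_equal(p$transform_kind, "AFFINE")
  expect_equal(p$dsf, 0.9)
  expect_equal(p$ab_map_version, "v2")
  expect_equal(p$source_tps, "TPS-A")
})

test_that("feasibility screen classifies constraints with safe boundaries", {
  g <- small_geom()
  mk <- function(value) {
    eq <- uniform_dose(value, g, kind = "EQD2")
    structure(list(summed_eqd2 = eq, per_course_eqd2 = list(eq),
                   provenance = list()),
              class = "accumulation_result")
  }
  cons <- list(constraint("OAR", "DMAX", 60))
  masks <- list(full_mask(g, "OAR"))
  # zero prior: achievable
  scr0 <- feasibility_screen(mk(0), cons, 20, masks)
  expect_equal(scr0$flag, "ACHIEVABLE")
  # prior at the limit: infeasible even with zero prescription
  scr1 <- feasibility_screen(mk(60), cons, 0, masks)
  expect_equal(scr1$flag, "INFEASIBLE")
  # the worked-example triple P=57, R=60, A=60: gradient required
  scr2 <- feasibility_screen(mk(57), cons, 60, masks)
  expect_equal(scr2$flag, "GRADIENT_REQUIRED")
  expect_equal(scr2$remaining_budget_eqd2, 3)
  expect_error(feasibility_screen(mk(0), list(constraint("ghost", "DMAX", 1)),
                                  10, masks), "available")
})
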