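# Hand-computed formula oracle for the nested-structure parameters.
oracle_levels <- function(P, R, A, N) {
  d <- ((P + R) - A) / N
  thresholds <- pmax(P - (1:N) * d, 0)
  assumed <- c(P, thresholds[-N])
  list(d = d, thresholds = thresholds, assumed = assumed,
       limits = A - assumed)
}

test_that("worked-example thresholds and limits match the formula oracle", {
  f <- fig4_accumulated()
  s5 <- generate_opt_structures(57, 60, 60, 5, f$res$summed_eqd2, f$oar,
                                fractionation(30), 3)
  o5 <- oracle_levels(57, 60, 60, 5)
  expect_equal(s5$d, 11.4, tolerance = 1e-12)
  expect_equal(vapply(s5$structures, `[[`, 0, "threshold"),
               c(45.6, 34.2, 22.8, 11.4, 0), tolerance = 1e-9)
  expect_equal(vapply(s5$structures, `[[`, 0, "eqd2_limit"),
               c(3, 14.4, 25.8, 37.2, 48.6), tolerance = 1e-9)
  expect_equal(vapply(s5$structures, `[[`, 0, "threshold"), o5$thresholds,
               tolerance = 1e-12)
  s3 <- generate_opt_structures(57, 60, 60, 3, f$res$summed_eqd2, f$oar,
                                fractionation(30), 3)
  expect_equal(vapply(s3$structures, `[[`, 0, "threshold"), c(38, 19, 0),
               tolerance = 1e-9)
  expect_equal(vapply(s3$structures, `[[`, 0, "eqd2_limit"), c(3, 22, 41),
               tolerance = 1e-9)
})

test_that("physical limits invert back to the EQD2 limits", {
  f <- fig4_accumulated()
  scheme <- fractionation(30)
  s <- generate_opt_structures(57, 60, 60, 3, f$res$summed_eqd2, f$oar,
                               scheme, 3)
  for (st in s$structures)
    expect_equal(eqd2_forward(st$physical_limit, scheme$n_fractions, 3),
                 st$eqd2_limit, tolerance = 1e-9)
})

test_that("P + R <= A yields an empty set; equality included", {
  f <- fig4_accumulated()
  s <- generate_opt_structures(10, 20, 40, 3, f$res$summed_eqd2, f$oar,
                               fractionation(10), 3)
  expect_length(s$structures, 0)
  expect_identical(s$rest_mask$mask, f$oar$mask)
  seq_empty <- generate_opt_structures(20, 20, 40, 3, f$res$summed_eqd2,
                                       f$oar, fractionation(10), 3)
  expect_length(seq_empty$structures, 0)
  expect_length(export_opt_structures(seq_empty), 0)
})

test_that("near-target Dmax uses the OAR within the dilated target region", {
  g <- grid_geometry(origin = c(0, 0, 0), spacing = c(2, 2, 2),
                     shape = c(30, 30, 6))
  vals <- array(0, g$shape)
  oar <- array(FALSE, g$shape)
  oar[5:25, 15, 3] <- TRUE
  vals[8, 15, 3] <- 45    # inside near region (close to target)
  vals[25, 15, 3] <- 62   # inside OAR but far from target
  tgt <- array(FALSE, g$shape)
  tgt[6:8, 10:12, 3] <- TRUE
  d <- dose_grid(vals, g, dose_kind = "EQD2")
  P <- compute_near_target_dmax(d, structure_mask("oar", oar, g),
                                structure_mask("t", tgt, g),
                                near_margin_mm = 10)
  expect_equal(P, 45)
  # disjoint near region falls back to whole-OAR Dmax with a warning
  far_tgt <- array(FALSE, g$shape); far_tgt[28, 28, 1] <- TRUE
  expect_warning(
    Pw <- compute_near_target_dmax(d, structure_mask("oar", oar, g),
                                   structure_mask("t", far_tgt, g), 2),
    "whole OAR")
  expect_equal(Pw, 62)
  expect_error(compute_near_target_dmax(d, structure_mask("e", array(FALSE, g$shape), g),
                                        structure_mask("t", tgt, g), 5),
               "empty")
})

test_that("zero prior dose gives P = 0", {
  f <- fig4_accumulated()
  zero <- dose_grid(array(0, f$case$geometry$shape), f$case$geometry,
                    dose_kind = "EQD2")
  expect_equal(compute_near_target_dmax(zero, f$oar, f$target, 20), 0)
})

test_that("shells partition the OAR: disjoint, telescoping, complete", {
  f <- fig4_accumulated()
  eq <- f$res$summed_eqd2
  s <- generate_opt_structures(57, 60, 60, 4, eq, f$oar, fractionation(30), 3)
  masks <- lapply(s$structures, function(x) x$mask$mask)
  # pairwise disjoint
  for (i in seq_along(masks))
    for (j in seq_len(i - 1))
      expect_false(any(masks[[i]] & masks[[j]]))
  # telescoping: union of S_1..S_k = OAR & {eqd2 >= D_k} (brute force)
  un <- array(FALSE, dim = dim(masks[[1]]))
  for (k in seq_along(masks)) {
    un <- un | masks[[k]]
    oracle <- f$oar$mask & (eq$values >= s$structures[[k]]$threshold)
    expect_identical(un, oracle, label = sprintf("k = %d", k))
  }
  # rest completes the OAR
  expect_identical(un | s$rest_mask$mask, f$oar$mask)
  expect_false(any(un & s$rest_mask$mask))
})

test_that("assumed priors dominate actual prior dose (conservativeness)", {
  f <- fig4_accumulated()
  eq <- f$res$summed_eqd2
  for (N in c(3, 5)) {
    s <- generate_opt_structures(57, 60, 60, N, eq, f$oar, fractionation(30), 3)
    for (st in s$structures) {
      if (!any(st$mask$mask)) next
      expect_gte(st$assumed_prior, max(eq$values[st$mask$mask]) - 1e-9)
      expect_equal(st$assumed_prior + st$eqd2_limit, 60)
    }
  }
})

test_that("the lowest threshold equals A - R and doubling N refines levels", {
  o1 <- oracle_levels(57, 60, 60, 3)
  expect_equal(o1$thresholds[3], 0)            # A - R = 0 here
  o2 <- oracle_levels(50, 30, 60, 4)
  expect_equal(o2$thresholds[4], 60 - 30)      # A - R, A >= R
  oN <- oracle_levels(50, 30, 60, 8)
  expect_true(all(sapply(o2$thresholds, function(t)
    any(abs(oN$thresholds - t) < 1e-9))))
})

test_that("export names, counts and annotations are deterministic", {
  f <- fig4_accumulated()
  s <- generate_opt_structures(57, 60, 60, 3, f$res$summed_eqd2, f$oar,
                               fractionation(30), 3)
  ex <- export_opt_structures(s, "cord")
  expect_length(ex, 4)
  expect_equal(vapply(ex, `[[`, "", "name"),
               c("cord_S1", "cord_S2", "cord_S3", "cord_rest"))
  expect_equal(attr(ex[[1]], "eqd2_limit"), 3)
  expect_equal(attr(ex[[1]], "physical_limit"),
               eqd2_inverse(3, 30, 3), tolerance = 1e-12)
})

test_that("parameter validation rejects degenerate requests", {
  f <- fig4_accumulated()
  expect_error(generate_opt_structures(57, 60, 60, 0, f$res$summed_eqd2,
                                       f$oar, fractionation(30), 3), "N")
  expect_error(generate_opt_structures(57, 60, 0, 3, f$res$summed_eqd2,
                                       f$oar, fractionation(30), 3), "A")
})
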