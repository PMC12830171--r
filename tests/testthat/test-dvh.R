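test_that("uniform dose gives a step-function DVH", {
  g <- small_geom()
  d <- uniform_dose(50, g, kind = "EQD2")
  curve <- compute_dvh(d, full_mask(g), bin_width = 1)
  at_or_below <- curve$dose_bins <= 50
  expect_true(all(curve$cumulative_volume_pct[at_or_below] == 100))
  expect_true(all(curve$cumulative_volume_pct[!at_or_below] == 0))
  expect_equal(curve$cumulative_volume_pct[1], 100)
})

test_that("a two-level dose distribution crosses at 50 percent", {
  g <- small_geom(c(8, 8, 4))
  vals <- array(20, g$shape)
  vals[seq_len(prod(g$shape) / 2)] <- 60
  d <- dose_grid(vals, g, dose_kind = "EQD2")
  curve <- compute_dvh(d, full_mask(g), bin_width = 0.5)
  mid <- curve$dose_bins > 20 & curve$dose_bins <= 60
  expect_true(all(curve$cumulative_volume_pct[mid] == 50))
})

test_that("the DVH is invariant to voxel ordering and non-increasing", {
  set.seed(31)
  g <- small_geom()
  v <- runif(prod(g$shape), 0, 70)
  d1 <- dose_grid(array(v, g$shape), g)
  d2 <- dose_grid(array(sample(v), g$shape), g)
  c1 <- compute_dvh(d1, full_mask(g))
  c2 <- compute_dvh(d2, full_mask(g))
  expect_equal(c1$cumulative_volume_pct, c2$cumulative_volume_pct)
  expect_true(all(diff(c1$cumulative_volume_pct) <= 0))
})

test_that("DxCC handles sub-voxel and multi-voxel hot regions", {
  g <- grid_geometry(spacing = c(1, 1, 1), shape = c(20, 20, 5))
  vals <- array(30, g$shape)
  vals[1, 1, 1] <- 70
  d <- dose_grid(vals, g)
  # one 1 mm3 voxel at 70: the hottest 0.01 cc (10 mm3) dips to 30
  expect_equal(metric_d_cc(d, full_mask(g), 0.01), 30)
  vals[1, 1:10, 1] <- 70
  d10 <- dose_grid(vals, g)
  expect_equal(metric_d_cc(d10, full_mask(g), 0.01), 70)
  # uniform dose: DxCC is that dose for any volume
  expect_equal(metric_d_cc(uniform_dose(42, g), full_mask(g), 0.01), 42)
  # structure smaller than x_cc warns and returns the minimum
  tiny <- structure_mask("tiny", array(c(TRUE, rep(FALSE, prod(g$shape) - 1)),
                                       g$shape), g)
  expect_warning(v <- metric_d_cc(d, tiny, 0.01), "volume")
  expect_equal(v, 70)
})

test_that("metrics agree with the full-sort brute-force oracle", {
  set.seed(77)
  for (i in 1:30) {
    g <- small_geom(c(10, 10, 5), spacing = runif(3, 1, 3))
    d <- random_dose(g, 80)
    m <- random_mask(g, 0.5)
    vv <- voxel_volume_cc(g)
    for (x_cc in c(0.01, 0.1, 1)) {
      # small random structures may undercut 1 cc: both sides then return
      # the structure minimum (the implementation warns, the oracle is silent)
      expect_identical(suppressWarnings(metric_d_cc(d, m, x_cc)),
                       oracle_d_cc(d$values, m$mask, vv, x_cc))
    }
    expect_identical(metric_dmax(d, m), max(d$values[m$mask]))
    expect_identical(metric_dmean(d, m), mean(d$values[m$mask]))
    expect_equal(metric_v_gy(d, m, 40),
                 100 * mean(d$values[m$mask] >= 40))
  }
})

test_that("DVH-derived Dmax and Dmean match direct values within a bin", {
  set.seed(78)
  g <- small_geom(c(9, 9, 5))
  d <- random_dose(g, 60)
  m <- random_mask(g, 0.6)
  bw <- 0.1
  curve <- compute_dvh(d, m, bin_width = bw)
  dvh_dmax <- max(curve$dose_bins[curve$cumulative_volume_pct > 0])
  expect_lt(abs(dvh_dmax - metric_dmax(d, m)), bw + 1e-12)
  # mean from the differential histogram
  diffpct <- -diff(c(curve$cumulative_volume_pct, 0)) / 100
  dvh_dmean <- sum(curve$dose_bins * diffpct)
  expect_lt(abs(dvh_dmean - metric_dmean(d, m)), bw + 1e-12)
})

test_that("the scorecard passes at equality and fails above the limit", {
  g <- small_geom()
  masks <- list(full_mask(g, "OAR"))
  d50 <- uniform_dose(50, g, kind = "EQD2")
  sc <- evaluate_scorecard(d50, masks,
                           list(constraint("OAR", "DMAX", 50),
                                constraint("OAR", "DMAX", 45),
                                constraint("OAR", "Dmean", 60)))
  expect_equal(sc$status, c("PASS", "FAIL", "PASS"))
  expect_equal(sc$margin, c(0, -5, 10))
  zero <- uniform_dose(0, g, kind = "EQD2")
  sc0 <- evaluate_scorecard(zero, masks, list(constraint("OAR", "D0.01cc", 30)))
  expect_equal(sc0$status, "PASS")
  expect_equal(sc0$margin, sc0$limit)
  expect_error(evaluate_scorecard(d50, masks,
                                  list(constraint("ghost", "DMAX", 1))),
               "available")
})

test_that("scaling dose up never turns a FAIL into a PASS", {
  set.seed(79)
  g <- small_geom()
  d <- random_dose(g, 50, kind = "EQD2")
  masks <- list(full_mask(g, "OAR"))
  cons <- list(constraint("OAR", "DMAX", 45), constraint("OAR", "D0.01cc", 40),
               constraint("OAR", "Dmean", 30))
  sc1 <- evaluate_scorecard(d, masks, cons)
  d2 <- dose_grid(d$values * 1.5, g, dose_kind = "EQD2")
  sc2 <- evaluate_scorecard(d2, masks, cons)
  expect_false(any(sc1$status == "FAIL" & sc2$status == "PASS"))
})

test_that("metric specs parse and format symmetrically", {
  expect_equal(redose:::parse_metric("D0.01cc")$type, "D_CC")
  expect_equal(redose:::parse_metric("D0.01cc")$param, 0.01)
  expect_equal(redose:::parse_metric("V20Gy"), list(type = "V_GY", param = 20))
  expect_equal(redose:::parse_metric("D2%")$param, 2)
  expect_error(redose:::parse_metric("Q5"), "unrecognized")
  expect_equal(redose:::format_metric(list(type = "D_CC", param = 0.01)),
               "D0.01cc")
})

test_that("reports are deterministic, round-trip, and carry the scorecard", {
  f <- fig4_accumulated()
  cons <- list(constraint("OAR", "DMAX", 60), constraint("OAR", "D0.01cc", 55))
  sc <- evaluate_scorecard(f$res$summed_eqd2, f$case$structures, cons)
  dvhs <- lapply(f$case$structures, function(m)
    compute_dvh(f$res$summed_eqd2, m, 0.5))
  dir1 <- file.path(tempdir(), "rep1"); dir2 <- file.path(tempdir(), "rep2")
  p1 <- render_report(f$res, sc, dvhs, case_log = list(case_id = "fig4"),
                      dir = dir1, plot = FALSE)
  p2 <- render_report(f$res, sc, dvhs, case_log = list(case_id = "fig4"),
                      dir = dir2, plot = FALSE)
  r1 <- jsonlite::fromJSON(p1$json); r2 <- jsonlite::fromJSON(p2$json)
  r1$generated_at <- r2$generated_at <- NULL
  expect_identical(r1, r2)
  expect_equal(r1$scorecard$achieved, sc$achieved, tolerance = 1e-12)
  expect_true(file.exists(p1$md))
  dvh_tab <- utils::read.csv(p1$dvh_csv)
  expect_equal(sort(unique(dvh_tab$structure)), c("OAR", "PTV"))
  # no constraints: explicit notice
  p3 <- render_report(f$res, NULL, dvhs, dir = file.path(tempdir(), "rep3"),
                      plot = FALSE)
  r3 <- jsonlite::fromJSON(p3$json)
  expect_equal(r3$notice, "no constraints evaluated")
})
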