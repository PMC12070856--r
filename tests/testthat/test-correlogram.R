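test_that("detrending removes exactly a straight line", {
  s <- annual_series_stub("c1", "count", 2000:2004, 2 * (0:4) + 3)
  out <- detrend_series(s)
  expect_true(all(abs(out$residuals$residual) < 1e-10))
  s2 <- annual_series_stub("c1", "count", 1:3, c(1, 3, 2))
  expect_equal(detrend_series(s2)$residuals$residual, c(-0.5, 1, -0.5),
               tolerance = 1e-10)
  short <- annual_series_stub("c2", "count", 1:2, c(1, 2))
  out3 <- detrend_series(short)
  expect_equal(nrow(out3$residuals), 0)
  expect_equal(out3$exclusions$reason, "fewer than 3 years")
})

test_that("pairwise correlations respect overlap, symmetry and lags", {
  cells <- cells_at_km(c(0, 100, 200))
  res <- rbind(
    resid_rows("a", "count", 2000:2009, sin(1:10)),
    resid_rows("b", "count", 2000:2009, sin(1:10)),       # identical
    resid_rows("c", "count", 2000:2003, cos(1:4)))        # 4-year overlap
  pc <- pairwise_correlations(res, cells, "count")
  ab <- pc$pairs[pc$pairs$cell_a == "a" & pc$pairs$cell_b == "b", ]
  expect_equal(ab$r, 1, tolerance = 1e-12)
  expect_equal(ab$distance_km, 100, tolerance = 0.2)
  expect_false(any(pc$pairs$cell_b == "c")) # short overlap excluded
  expect_true(any(grepl("overlap", pc$skipped$reason)))
  # congruence lag: count in year t+1 equals productivity in year t
  y <- rnorm(10)
  res2 <- rbind(resid_rows("a", "count", 2001:2010, y),
                resid_rows("b", "productivity", 2000:2009, y))
  lag1 <- pairwise_correlations(res2, cells, "count", "productivity", lag = 1)
  expect_equal(lag1$pairs$r[lag1$pairs$cell_a == "a" &
                              lag1$pairs$cell_b == "b"], 1,
               tolerance = 1e-12)
  lag0 <- pairwise_correlations(res2, cells, "count", "productivity", lag = 0)
  r0 <- lag0$pairs$r[lag0$pairs$cell_a == "a" & lag0$pairs$cell_b == "b"]
  expect_lt(r0, 0.99) # unlagged alignment does not line up
  expect_error(pairwise_correlations(res, cells, "count", "count", lag = 1),
               "lag 0")
})

test_that("zero-variance series are skipped with a log entry", {
  cells <- cells_at_km(c(0, 100))
  res <- rbind(resid_rows("a", "count", 2000:2006, rnorm(7)),
               resid_rows("b", "count", 2000:2006, rep(0, 7)))
  pc <- pairwise_correlations(res, cells, "count")
  expect_equal(nrow(pc$pairs), 0)
  expect_true(any(grepl("zero variance", pc$skipped$reason)))
})

test_that("correlograms refuse fewer than 20 pairs and fit constants exactly", {
  pairs19 <- make_spherical_pairs(19, seed = 2)
  expect_message(cg <- fit_correlogram(pairs19), "refused")
  expect_null(cg)
  flat <- data.frame(distance_km = seq(5, 500, length.out = 40), r = 0.27)
  cg2 <- fit_correlogram(flat, seed = 1)
  expect_true(all(abs(cg2$fit - 0.27) < 1e-3))
  expect_equal(cg2$n_pairs, 40)
  expect_equal(cg2$distance_km[1], 0)
  expect_lte(max(diff(cg2$distance_km)), 1)
})

test_that("scale and strength extraction matches analytic crossings", {
  cg <- correlogram_stub(0:600, 0.3 * (1 - (0:600) / 250))
  est <- extract_scale_strength(cg, 500)
  expect_equal(est$scale_km, 250, tolerance = 1e-6)
  expect_equal(est$relative_scale, 0.5, tolerance = 1e-6)
  expect_equal(est$strength, 0.3)
  expect_gt(est$weight_scale, 0)
  expect_gt(est$weight_strength, 0)
  # always-positive curve: scale replaced by the minimum distance
  cg2 <- correlogram_stub(0:600, rep(0.2, 601))
  est2 <- extract_scale_strength(cg2, 400)
  expect_equal(est2$scale_km, 400)
  expect_equal(est2$relative_scale, 1)
  # degenerate flat-zero curve
  cg3 <- correlogram_stub(0:600, rep(0, 601))
  est3 <- extract_scale_strength(cg3, 400)
  expect_equal(est3$scale_km, 0)
  expect_equal(est3$relative_scale, 0)
  expect_equal(est3$flag, "curve_nonpositive_at_zero")
})

test_that("relative scale and strength stay in their domains", {
  for (i in 1:5) {
    pairs <- make_spherical_pairs(80, range_km = 150 + 100 * i,
                                  noise_sd = 0.2, seed = 30 + i)
    cg <- fit_correlogram(pairs, seed = i)
    est <- extract_scale_strength(cg, 450)
    expect_gte(est$relative_scale, 0)
    expect_lte(est$relative_scale, 1)
    expect_gte(est$strength, -1)
    expect_lte(est$strength, 1)
    expect_gt(est$weight_scale, 0)
    expect_gt(est$weight_strength, 0)
  }
})

test_that("the posterior-simulation band brackets the mean curve", {
  pairs <- make_spherical_pairs(200, seed = 8)
  cg <- fit_correlogram(pairs, seed = 8)
  expect_true(all(cg$lower <= cg$fit + 1e-9))
  expect_true(all(cg$upper >= cg$fit - 1e-9))
  expect_true(all(cg$se > 0))
})
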