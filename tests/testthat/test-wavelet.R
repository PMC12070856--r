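noise_transforms <- function(n_cells, T, seed) {
  set.seed(seed)
  lapply(seq_len(n_cells), function(i)
    morlet_cwt(clean_series(rnorm(T)), timescale_grid(T)))
}

test_that("series cleaning removes line and mean", {
  t <- 1:20
  expect_true(all(abs(clean_series(2 * t + 5)) < 1e-10))
  x <- rnorm(16)
  cl <- clean_series(x)
  expect_lt(abs(mean(cl)), 1e-10)
  expect_lt(abs(coef(lm(cl ~ t[1:16]))[2]), 1e-10)
  # a sinusoid survives detrending nearly unchanged: the only distortion
  # is the slight aliasing of a period-4 cycle into the fitted slope
  # (analytically ~0.09 at the series ends for T = 32)
  tt <- 1:32
  y <- sin(2 * pi * tt / 4) + 0.3 * tt
  expect_lt(max(abs(clean_series(y) - sin(2 * pi * tt / 4))), 0.1)
  expect_gt(cor(clean_series(y), sin(2 * pi * tt / 4)), 0.995)
  expect_error(clean_series(rnorm(5)), "at least 8")
  expect_error(clean_series(rnorm(10), years = c(1:5, 7:11)), "gaps")
})

test_that("the Morlet transform is tuned to the signal period", {
  T <- 32
  x <- sin(2 * pi * (1:T) / 4)
  ts <- timescale_grid(T)
  cw <- morlet_cwt(x, ts)
  mid <- 16
  peak <- ts[which.max(Mod(cw$W[mid, ]))]
  expect_lt(abs(log(peak / 4)), log(1.05) + 1e-9) # within one grid step
  expect_true(all(Mod(morlet_cwt(rep(0, T), ts)$W) == 0))
  # modulus is invariant to a sign flip
  expect_equal(Mod(morlet_cwt(-x, ts)$W), Mod(cw$W), tolerance = 1e-12)
  expect_error(morlet_cwt(x, c(1, 4)), "timescales")
  expect_error(morlet_cwt(x, c(4, 20)), "timescales")
})

test_that("the cone of influence masks one e-folding time at each edge", {
  cw <- morlet_cwt(rnorm(30), c(2, 6))
  ef2 <- ceiling(sqrt(2) * 2)
  expect_false(any(cw$in_cone[1:ef2, 1]))
  expect_true(cw$in_cone[15, 1])
  expect_true(sum(cw$in_cone[, 2]) < sum(cw$in_cone[, 1])) # wider at long ts
})

test_that("phasor mean fields hit their analytic limits", {
  T <- 30
  set.seed(3)
  x <- clean_series(rnorm(T))
  ts <- timescale_grid(T)
  identical_cells <- lapply(1:5, function(i) morlet_cwt(x, ts))
  f <- wpmf(identical_cells, seed = 2)
  expect_true(all(abs(f$magnitude[!is.na(f$magnitude)] - 1) < 1e-9))
  # antiphase sinusoids cancel at their period
  s <- sin(2 * pi * (1:32) / 4)
  anti <- wpmf(list(morlet_cwt(clean_series(s), timescale_grid(32)),
                    morlet_cwt(clean_series(-s), timescale_grid(32))),
               seed = 2)
  j <- which.min(abs(anti$timescales - 4))
  expect_lt(max(anti$magnitude[, j], na.rm = TRUE), 0.05)
  # independent cells: time-average near the random-phasor expectation
  N <- 20
  f2 <- wpmf(noise_transforms(N, 40, seed = 5), seed = 2)
  expect_equal(mean(f2$magnitude, na.rm = TRUE), sqrt(pi / (4 * N)),
               tolerance = 0.25)
  expect_error(wpmf(noise_transforms(1, 40, seed = 1)), ">= 2 cells")
})

test_that("the wpmf is invariant to rescaling any one series", {
  T <- 30
  set.seed(8)
  xs <- replicate(4, clean_series(rnorm(T)), simplify = FALSE)
  ts <- timescale_grid(T)
  f1 <- wpmf(lapply(xs, morlet_cwt, timescales = ts), seed = 3)
  xs[[2]] <- 7.3 * xs[[2]]
  f2 <- wpmf(lapply(xs, morlet_cwt, timescales = ts), seed = 3)
  expect_equal(f1$magnitude, f2$magnitude, tolerance = 1e-9)
})

test_that("magnitudes stay in [0, 1] wherever defined", {
  for (i in 1:5) {
    f <- wpmf(noise_transforms(3 + i, 25, seed = 40 + i), seed = i)
    m <- f$magnitude[!is.na(f$magnitude)]
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
  }
})

test_that("the random-phase threshold behaves like the Rayleigh law", {
  expect_equal(wpmf_threshold(1, alpha = 0.5, seed = 1), 1, tolerance = 1e-9)
  th <- sapply(c(2, 5, 10, 25, 50), wpmf_threshold, alpha = 0.05,
               n_draws = 8000, seed = 4)
  expect_true(all(diff(th) < 0))
  expect_equal(wpmf_threshold(100, n_draws = 20000, seed = 2),
               sqrt(-log(0.05) / 100), tolerance = 0.05)
})

test_that("band counting uses defined in-band magnitudes", {
  ts <- timescale_grid(24)
  mag <- matrix(1, 24, length(ts))
  mag[1:3, ] <- NA
  f <- structure(list(magnitude = mag, timescales = ts, years = 1:24,
                      n_cells = 5, threshold = 0.5, alpha = 0.05),
                 class = "wpmf_field")
  out <- significant_year_counts(f)
  expect_setequal(out$band, c("short", "intermediate", "long"))
  expect_equal(out$n_significant_years, out$n_years)
  expect_true(all(out$n_years == 21))
  f$magnitude[] <- 0
  none <- significant_year_counts(f)
  expect_true(all(none$n_significant_years == 0))
  # a band wholly outside the grid is absent
  short_grid <- timescale_grid(14) # max 7: long band (6, Inf] present
  f2 <- structure(list(magnitude = matrix(1, 14, length(short_grid)),
                       timescales = short_grid, years = 1:14, n_cells = 2,
                       threshold = 0.5, alpha = 0.05), class = "wpmf_field")
  out2 <- significant_year_counts(
    f2, bands = list(short = c(2, 3), intermediate = c(3, 5),
                     long = c(8, Inf)))
  expect_false("long" %in% out2$band)
})

test_that("composite fields average species missing-aware", {
  ts <- timescale_grid(20)
  mk <- function(val, na_first = FALSE) {
    m <- matrix(val, 20, length(ts))
    if (na_first) m[1, ] <- NA
    structure(list(magnitude = m, timescales = ts, years = 1:20, n_cells = 4,
                   threshold = 0.4, alpha = 0.05), class = "wpmf_field")
  }
  one <- composite_wpmf(list(mk(0.3)))
  expect_equal(one$magnitude, mk(0.3)$magnitude)
  two <- composite_wpmf(list(mk(0.2, na_first = TRUE), mk(0.4)))
  expect_equal(two$magnitude[2, 1], 0.3)
  expect_equal(two$magnitude[1, 1], 0.4) # defined in only one species
  expect_error(composite_wpmf(list()), "empty")
})
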