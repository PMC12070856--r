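tiny_layout <- function() make_landscape(4, 200, 100, 2, seed = 11)
flat_field <- function(lay, years = 12, seed = 4) {
  simulate_rate_field(lay, years, spatial_corr_model("spherical", 300, 0.3),
                      anomaly_sd = 0.1, seed = seed)
}

test_that("perfect detection recovers every live adult and true survival", {
  lay <- tiny_layout()
  f <- flat_field(lay)
  pars <- sim_params(n_visits = 1, baseline_phi = 0.6, residency_prob = 1,
                     per_visit_capture_prob = 1,
                     initial_adults_per_site = 60, seed = 7)
  recs <- simulate_captures(lay, f, pars)
  truth <- attr(recs, "truth")
  ad <- recs[recs$age == "A", ]
  # every live adult is captured: adult captures per year match the truth
  n_by_year <- tapply(ad$ring_id, ad$year, function(z) length(unique(z)))
  truth_by_year <- tapply(truth$mean_adults * 2, truth$year, sum) # 2 sites/cell
  expect_equal(as.numeric(n_by_year), as.numeric(truth_by_year[names(n_by_year)]))
  # apparent survival in the data equals true survival up to binomial noise
  yrs <- sort(unique(ad$year))
  seen <- table(ad$ring_id, ad$year)
  ret <- sapply(seq_len(length(yrs) - 1), function(t) {
    now <- rownames(seen)[seen[, t] > 0]
    mean(seen[now, t + 1] > 0)
  })
  true_phi <- tapply(truth$true_phi, truth$year, mean)
  expect_lt(mean(abs(ret - true_phi[seq_along(ret)])), 0.08)
})

test_that("zero productivity yields no juvenile records", {
  lay <- tiny_layout()
  f <- flat_field(lay)
  pars <- sim_params(baseline_productivity = 0, seed = 8)
  recs <- simulate_captures(lay, f, pars)
  expect_equal(sum(recs$age == "J"), 0)
  expect_gt(sum(recs$age == "A"), 0)
})

test_that("capture tables are identical on rerun with a fixed seed", {
  lay <- tiny_layout()
  f <- flat_field(lay)
  pars <- sim_params(seed = 21)
  a <- simulate_captures(lay, f, pars)
  b <- simulate_captures(lay, f, pars)
  expect_identical(a, b)
})

test_that("marked individuals are internally consistent", {
  lay <- tiny_layout()
  f <- flat_field(lay)
  recs <- simulate_captures(lay, f, sim_params(residency_prob = 0.6, seed = 9))
  # a ring id never changes age class or site
  byring <- split(recs, recs$ring_id)
  expect_true(all(vapply(byring, function(z) length(unique(z$age)) == 1, TRUE)))
  expect_true(all(vapply(byring, function(z) length(unique(z$site_id)) == 1, TRUE)))
  # juveniles are captured in exactly one season
  jyears <- vapply(byring, function(z)
    if (z$age[1] == "J") length(unique(z$year)) else 1L, 1L)
  expect_true(all(jyears == 1L))
  # visit indices within the configured number of visits
  expect_true(all(recs$visit >= 1 & recs$visit <= 8))
})

test_that("all-cell extinction warns and flags truncation", {
  lay <- tiny_layout()
  f <- flat_field(lay, years = 15, seed = 6)
  pars <- sim_params(baseline_phi = 0.02, baseline_productivity = 0,
                     initial_adults_per_site = 2, per_visit_capture_prob = 1,
                     residency_prob = 1, seed = 10)
  expect_warning(recs <- simulate_captures(lay, f, pars), "extinct")
  expect_false(is.null(attr(recs, "truncated")))
})

test_that("the capture CSV round-trips exactly", {
  lay <- tiny_layout()
  f <- flat_field(lay)
  recs <- simulate_captures(lay, f, sim_params(seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_captures(recs, path)
  back <- read_captures(path)
  rownames(back) <- NULL
  cols <- c("site_id", "species", "year", "visit", "ring_id", "age")
  expect_identical(back[, cols], recs[, cols])
  expect_equal(back$lat, recs$lat, tolerance = 1e-12)
  tr <- withr::local_tempfile(fileext = ".csv")
  write_truth(attr(recs, "truth"), tr)
  expect_equal(read_truth(tr)$true_phi, attr(recs, "truth")$true_phi,
               tolerance = 1e-12)
  expect_error(read_captures(withr::local_tempfile(lines = "a,b\n1,2")),
               "missing columns")
})
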