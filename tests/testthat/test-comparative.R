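test_that("fixed effects are invariant to rescaling all weights", {
  rec <- make_sync_records(seed = 5)
  f1 <- fit_weighted_lmm(rec, "relative_scale")
  rec2 <- rec
  rec2$weight_scale <- rec2$weight_scale * 137
  f2 <- fit_weighted_lmm(rec2, "relative_scale")
  expect_equal(lme4::fixef(f1$fit), lme4::fixef(f2$fit), tolerance = 1e-6)
  expect_equal(f1$tests$chisq, f2$tests$chisq, tolerance = 1e-4)
})

test_that("without group structure the fit collapses to weighted least squares", {
  rec <- make_sync_records(re_sd = 0, noise_sd = 0.2, seed = 9)
  fit <- fit_weighted_lmm(rec, "relative_scale")
  wls <- lm(relative_scale ~ metric + migratory_status, data = rec,
            weights = weight_scale)
  b1 <- if (inherits(fit$fit, "merMod")) lme4::fixef(fit$fit) else
    coef(fit$fit)
  expect_equal(unname(b1), unname(coef(wls)), tolerance = 0.01)
})

test_that("a real metric effect is detected and reported with its df", {
  rec <- make_sync_records(effect = 0.1, seed = 2)
  fit <- fit_weighted_lmm(rec, "relative_scale")
  row <- fit$tests[fit$tests$term == "metric", ]
  expect_equal(row$df, 1)
  expect_lt(row$p_value, 0.001)
  expect_gte(min(fit$tests$chisq), 0)
  expect_error(fit_weighted_lmm(rec[rec$metric == "count", ], "strength"),
               ">= 2 levels")
})

test_that("congruence models include and test the interaction", {
  rec <- make_sync_records(seed = 3)
  rec$pairing <- ifelse(rec$metric == "count", "count-survival",
                        "count-productivity")
  fit <- fit_congruence_lmm(rec, "relative_scale")
  expect_setequal(fit$tests$term,
                  c("pairing", "migratory_status",
                    "pairing:migratory_status"))
  expect_true(all(fit$tests$df == 1))
  expect_error(fit_congruence_lmm(rec[rec$pairing == "count-survival", ]),
               "both congruence pairings")
})

test_that("the periodicity model matches its degenerate cases", {
  tab <- expand.grid(species = sprintf("sp%d", 1:8),
                     band = c("short", "intermediate", "long"),
                     metric = c("count", "productivity", "survival"),
                     stringsAsFactors = FALSE)
  tab$migratory_status <- ifelse(as.integer(factor(tab$species)) %% 2 == 0,
                                 "European-resident", "subSaharan-migrant")
  tab$n_years <- 20
  # all proportions equal: every term deviance ~ 0
  tab$n_significant_years <- 10
  fit <- fit_periodicity_glm(tab)
  expect_true(all(fit$tests$chisq < 1e-6, na.rm = TRUE))
  # proportions strictly increasing in timescale: positive coefficient
  mid <- c(short = 2.5, intermediate = 4, long = 8)
  tab$n_significant_years <- round(2 + 2 * mid[tab$band])
  fit2 <- fit_periodicity_glm(tab)
  expect_gt(coef(fit2$fit)[["timescale"]], 0)
  expect_true(all(c("f_value", "p_f") %in% names(fit2$tests)))
})

test_that("binomial data give a dispersion estimate near one", {
  set.seed(12)
  n <- 200
  tab <- data.frame(
    species = sprintf("sp%d", rep(1:50, 4)),
    band = sample(c("short", "intermediate", "long"), n, replace = TRUE),
    metric = sample(c("count", "productivity", "survival"), n, replace = TRUE),
    migratory_status = sample(c("European-resident", "subSaharan-migrant"),
                              n, replace = TRUE),
    n_years = 25, stringsAsFactors = FALSE)
  mid <- c(short = 2.5, intermediate = 4, long = 8)
  eta <- -0.5 + 0.05 * mid[tab$band] + 0.2 * (tab$metric == "survival")
  tab$n_significant_years <- rbinom(n, 25, plogis(eta))
  fit <- fit_periodicity_glm(tab)
  expect_gt(fit$dispersion, 0.7)
  expect_lt(fit$dispersion, 1.4)
})
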