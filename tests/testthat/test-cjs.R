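test_that("capture histories are 0/1 vectors over the cell's occasions", {
  recs <- rbind(rec_row("s1", 2001, 1, "b1"), rec_row("s1", 2003, 2, "b1"),
                rec_row("s1", 2001, 1, "b1"), # same season recapture
                rec_row("s1", 2002, 1, "j1", age = "J"),
                rec_row("s1", 2004, 1, "b2"))
  h <- build_capture_histories(recs, years = 2001:2004)
  expect_equal(unname(h$ch["b1", ]), c(1L, 0L, 1L, 0L))
  expect_equal(unname(h$ch["b2", ]), c(0L, 0L, 0L, 1L))
  expect_false("j1" %in% rownames(h$ch)) # juvenile-only bird absent
  expect_equal(h$first, c(1L, 4L))
  expect_equal(h$ch["b1", "2001"], 1L) # detection at first capture is 1
})

test_that("two-occasion likelihoods match hand arithmetic", {
  h11 <- as_history_set(matrix(c(1L, 1L), 1))
  h10 <- as_history_set(matrix(c(1L, 0L), 1))
  expect_equal(cjs_transient_loglik(h11, 0.5, 0.5, 1), log(0.25))
  expect_equal(cjs_transient_loglik(h10, 0.5, 0.5, 1), log(0.75))
  # with transience: never-seen-again mixes in the transient mass
  expect_equal(cjs_transient_loglik(h10, 0.5, 0.5, 0.7),
               log(0.7 * 0.75 + 0.3))
  expect_equal(cjs_transient_loglik(h11, 0.5, 0.5, 0.7), log(0.7 * 0.25))
  expect_error(cjs_transient_loglik(h11, 1.5, 0.5, 0.7), "0, 1")
})

test_that("forward recursion equals exhaustive enumeration (K = 3)", {
  grid <- expand.grid(phi1 = c(0.3, 0.8), phi2 = c(0.5), p = c(0.2, 0.9),
                      rho = c(0.6, 1))
  for (ch in all_histories(3)) {
    h <- as_history_set(ch)
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      expect_equal(
        cjs_transient_loglik(h, c(g$phi1, g$phi2), g$p, g$rho),
        enum_cjs_loglik(h$ch, h$first, c(g$phi1, g$phi2), g$p, g$rho),
        tolerance = 1e-12)
    }
  }
})

test_that("with rho = 1 and p = 1 the survival MLE is the return rate", {
  # 10 released at occasion 1; 6 seen at 2; 3 of those seen at 3
  ch <- rbind(matrix(rep(c(1L, 1L, 1L), 3), 3, byrow = TRUE),
              matrix(rep(c(1L, 1L, 0L), 3), 3, byrow = TRUE),
              matrix(rep(c(1L, 0L, 0L), 4), 4, byrow = TRUE))
  h <- as_history_set(ch)
  nll <- function(lphi) -cjs_transient_loglik(h, plogis(lphi), 1, 1)
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(plogis(opt$par), c(0.6, 0.5), tolerance = 1e-4)
})

test_that("Gelman-Rubin behaves at its limits", {
  x <- matrix(rnorm(2000), 1000, 2)
  x[, 2] <- x[, 1] # identical chains
  expect_equal(gelman_rubin(x), 1, tolerance = 1e-9)
  set.seed(1)
  same <- matrix(rnorm(20000), 10000, 2)
  expect_lt(gelman_rubin(same), 1.01)
  disjoint <- cbind(rnorm(1000, 0, 0.1), rnorm(1000, 10, 0.1))
  expect_gt(gelman_rubin(disjoint), 10)
  expect_error(gelman_rubin(matrix(rnorm(10), 10, 1)), "2 chains")
  expect_error(gelman_rubin(matrix(rnorm(10), 5, 2)), "10 draws")
})

test_that("the sampler recovers parameters on one simulated dataset", {
  h <- simulate_cjs_histories(300, 10, 0.5, 0.5, 0.7, seed = 5001)
  post <- fit_cjs(h, mcmc_config(2, 6000, 2000, 4, seed = 1))
  expect_equal(mcmc_retained_draws(post$config), 2000)
  expect_equal(dim(post$draws), c(1000, 11, 2))
  phi_idx <- 1:9
  expect_lt(abs(mean(post$mean[phi_idx]) - 0.5), 0.1)
  expect_lt(abs(post$mean[["p"]] - 0.5), 0.1)
  expect_lt(abs(post$mean[["rho"]] - 0.7), 0.1)
  expect_true(all(post$rhat < 1.1))
  expect_true(post$converged)
})

test_that("fixing rho at 1 reproduces the plain CJS fit on resident data", {
  h <- simulate_cjs_histories(250, 8, 0.6, 0.7, 1, seed = 77)
  cfg <- mcmc_config(2, 5000, 1000, 4, seed = 3)
  free <- fit_cjs(h, cfg)
  fixed <- fit_cjs(h, cfg, rho_fixed = 1)
  expect_false("rho" %in% names(fixed$mean))
  phi_idx <- 1:7
  expect_lt(max(abs(free$mean[phi_idx] - fixed$mean[phi_idx])), 0.06)
  expect_lt(abs(free$mean[["p"]] - fixed$mean[["p"]]), 0.06)
  expect_gt(free$mean[["rho"]], 0.85) # transient-free data pushes rho up
})

test_that("fit preconditions and schedule arithmetic are enforced", {
  h <- simulate_cjs_histories(10, 2, 0.5, 0.5, 1, seed = 1)
  expect_error(fit_cjs(h), ">= 3 occasions")
  h1 <- as_history_set(matrix(c(1L, 0L, 0L), 1))
  expect_error(fit_cjs(h1), ">= 2 marked")
  expect_error(mcmc_config(2, 1000, 2000, 10))
  expect_equal(mcmc_retained_draws(mcmc_config(4, 20000, 10000, 10)), 4000)
})
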