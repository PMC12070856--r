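#' Build adult capture histories for one grid cell
#'
#' One 0/1 detection vector per ringed adult over the cell's occasions
#' (years). Juvenile records are excluded; multiple captures of a bird in
#' one season collapse to a single detection.
#'
#' @param records Capture data frame for the cell (after filtering).
#' @param years Occasion years; defaults to the full range of adult record
#'   years in the cell (missing years inside the range are kept as
#'   occasions).
#' @return A `capture_history_set`: list with `ch` (individuals x occasions
#'   0/1 matrix, rownames = ring ids), `first` (first-capture occasion
#'   index per individual) and `years`.
#' @export
build_capture_histories <- function(records, years = NULL) {
  ad <- records[records$age == "A", ]
  if (nrow(ad) == 0) stop("no adult records")
  if (is.null(years)) years <- seq(min(ad$year), max(ad$year))
  ad <- ad[ad$year %in% years, ]
  ids <- sort(unique(ad$ring_id))
  ch <- matrix(0L, length(ids), length(years),
               dimnames = list(ids, as.character(years)))
  ch[cbind(match(ad$ring_id, ids), match(ad$year, years))] <- 1L
  first <- apply(ch, 1, function(z) which(z == 1L)[1])
  structure(list(ch = ch, first = as.integer(first), years = years),
            class = "capture_history_set")
}

#' @export
print.capture_history_set <- function(x, ...) {
  cat("capture_history_set:", nrow(x$ch), "individuals x", ncol(x$ch),
      "occasions (", x$years[1], "-", x$years[length(x$years)], ")\n")
  invisible(x)
}

#' Simulate capture histories from the transient-CJS process
#'
#' Direct generator for parameter-recovery studies: each individual is
#' released (first captured) at a given occasion, is a resident with
#' probability `rho`, survives occasion to occasion with probability
#' `phi[t]` and, while alive, is re-detected at each later occasion with
#' probability `p`. Transients are never seen again after release.
#'
#' @param n_individuals Number of released individuals.
#' @param n_occasions Number of occasions (years).
#' @param phi Apparent survival; scalar or vector of length
#'   `n_occasions - 1`.
#' @param p Recapture probability.
#' @param rho Residency probability.
#' @param releases Release occasion per individual; default spreads
#'   releases evenly over occasions `1..n_occasions - 1`.
#' @param seed Integer seed.
#' @return A `capture_history_set`.
#' @export
simulate_cjs_histories <- function(n_individuals, n_occasions, phi, p, rho,
                                   releases = NULL, seed = 1) {
  phi <- rep_len(phi, n_occasions - 1)
  set.seed(seed)
  if (is.null(releases)) {
    releases <- rep(seq_len(n_occasions - 1), length.out = n_individuals)
  }
  ch <- matrix(0L, n_individuals, n_occasions)
  for (i in seq_len(n_individuals)) {
    f <- releases[i]
    ch[i, f] <- 1L
    if (runif(1) > rho) next # transient
    t <- f
    while (t < n_occasions) {
      if (runif(1) > phi[t]) break
      t <- t + 1L
      if (runif(1) < p) ch[i, t] <- 1L
    }
  }
  rownames(ch) <- sprintf("I%05d", seq_len(n_individuals))
  structure(list(ch = ch, first = as.integer(releases),
                 years = seq_len(n_occasions)),
            class = "capture_history_set")
}

#' CJS log-likelihood with a transience term
#'
#' Conditional-on-first-capture Cormack-Jolly-Seber likelihood in which a
#' newly marked bird is a resident with probability `rho` (then follows the
#' standard CJS model with year-specific apparent survival `phi` and
#' constant recapture probability `p`) and a transient with probability
#' `1 - rho` (never re-encountered). Computed per individual by a forward
#' recursion over the latent alive state; identical histories are collapsed
#' to multiplicities before the recursion.
#'
#' @param histories A `capture_history_set`.
#' @param phi Numeric vector of length `n_occasions - 1`, apparent survival
#'   from occasion t to t+1, each in (0, 1\].
#' @param p Recapture probability in (0, 1\].
#' @param rho Residency probability in (0, 1\]. The closed boundary at 1
#'   admits the degenerate limits (perfect detection, no transience); the
#'   sampler itself only ever proposes interior values.
#' @return The log-likelihood (finite for interior parameters; `-Inf` for
#'   histories impossible at a boundary, e.g. an undetected year under
#'   `p = 1`).
#' @export
cjs_transient_loglik <- function(histories, phi, p, rho) {
  ch <- histories$ch
  if (length(phi) != ncol(ch) - 1) stop("phi must have length n_occasions - 1")
  if (any(phi <= 0 | phi > 1) || p <= 0 || p > 1 || rho <= 0 || rho > 1) {
    stop("phi, p and rho must lie in (0, 1]")
  }
  key <- apply(ch, 1, paste, collapse = "")
  tab <- table(key)
  u <- match(names(tab), key)
  cjs_loglik_cpp(ch[u, , drop = FALSE], histories$first[u],
                 as.numeric(phi), p, rho, as.numeric(tab))
}

#' MCMC schedule
#'
#' @param n_chains,n_iter,n_burn,thin Chains, iterations per chain, burn-in
#'   discarded per chain, thinning interval. The desk-scale default
#'   (4 chains x 20,000 iterations, burn 10,000, thin 10) keeps a cell fit
#'   in seconds; the reference schedule used for the published survival
#'   models (2 chains of 5,000,000 iterations, burn 2,000,000, thin 5,000)
#'   is available as `mcmc_config(2, 5e6, 2e6, 5000)`.
#' @param seed Integer seed.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 4, n_iter = 20000, n_burn = 10000,
                        thin = 10, seed = 1) {
  stopifnot(n_chains >= 1, n_iter > n_burn, thin >= 1,
            (n_iter - n_burn) %% thin == 0)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
                 thin = thin, seed = seed), class = "mcmc_config")
}

#' Retained posterior draws implied by an MCMC schedule
#'
#' `n_chains * (n_iter - n_burn) / thin`.
#'
#' @param config An [mcmc_config()].
#' @return Integer number of retained draws.
#' @export
mcmc_retained_draws <- function(config) {
  as.integer(config$n_chains * (config$n_iter - config$n_burn) / config$thin)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic PSRF of Brooks & Gelman, computed per parameter from two or
#' more chains. Because the estimator can fall marginally below 1 by
#' sampling noise (and equals sqrt((n-1)/n) exactly when all chains are
#' identical), values below 1 are truncated to 1.
#'
#' @param chains A draws x chains matrix for one parameter, or a
#'   draws x parameters x chains array.
#' @return R-hat per parameter (>= 1).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- array(chains, c(nrow(chains), 1, ncol(chains)))
  m <- dim(chains)[3]
  n <- dim(chains)[1]
  if (m < 2) stop("need at least 2 chains")
  if (n < 10) stop("need at least 10 draws per chain")
  vapply(seq_len(dim(chains)[2]), function(j) {
    x <- chains[, j, ]
    W <- mean(apply(x, 2, var))
    B <- n * var(colMeans(x))
    if (W <= 0) return(1)
    vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
    max(1, sqrt(vhat / W))
  }, 0)
}

#' Fit the Bayesian CJS survival model with transience
#'
#' Posterior sampling under Uniform(0, 1) priors on the year-specific
#' apparent survival probabilities, the (year-constant) recapture
#' probability and the residency probability, by single-site random-walk
#' Metropolis on the logit scale. Convergence is assessed per parameter
#' with [gelman_rubin()]; any R-hat at or above 1.1 flags the fit.
#'
#' @param histories A `capture_history_set` with >= 3 occasions and >= 2
#'   marked adults.
#' @param config An [mcmc_config()].
#' @param step Proposal standard deviation on the logit scale.
#' @param rho_fixed Optional value at which to hold the residency
#'   probability (e.g. `rho_fixed = 1` gives the plain CJS model without a
#'   transience term); `NULL` (default) samples rho.
#' @return A `cjs_posterior`: list with `draws` (retained-draws x
#'   parameters x chains array; parameters `phi_1..phi_{K-1}`, `p`, `rho`),
#'   `mean`, `se`, 95% credible `lower`/`upper`, `rhat`, `converged`,
#'   `n_individuals` and the `config`.
#' @export
fit_cjs <- function(histories, config = mcmc_config(), step = 0.35,
                    rho_fixed = NULL) {
  ch <- histories$ch
  K <- ncol(ch)
  if (K < 3) stop("need >= 3 occasions")
  if (nrow(ch) < 2) stop("need >= 2 marked adults")
  # collapse identical histories once, up front
  key <- apply(ch, 1, paste, collapse = "")
  tab <- table(key)
  u <- match(names(tab), key)
  h <- histories
  h$ch_u <- ch[u, , drop = FALSE]
  h$first_u <- histories$first[u]
  h$mult_u <- as.numeric(tab)

  sample_rho <- is.null(rho_fixed)
  if (!sample_rho) stopifnot(rho_fixed > 0, rho_fixed <= 1)
  npar <- if (sample_rho) K + 1L else K
  parnames <- c(paste0("phi_", seq_len(K - 1)), "p",
                if (sample_rho) "rho")
  nkeep <- (config$n_iter - config$n_burn) %/% config$thin
  draws <- array(NA_real_, c(nkeep, npar, config$n_chains),
                 dimnames = list(NULL, parnames, NULL))
  for (chain in seq_len(config$n_chains)) {
    set.seed(derive_seed(config$seed, paste0("chain", chain)))
    x <- qlogis(runif(npar, 0.2, 0.8))
    draws[, , chain] <- cjs_metropolis_cpp(h$ch_u, h$first_u, h$mult_u,
                                           config$n_iter, config$n_burn,
                                           config$thin, step, x,
                                           if (sample_rho) -1 else rho_fixed)
  }
  flat <- apply(draws, 2, c)
  rhat <- if (config$n_chains >= 2) gelman_rubin(draws) else
    rep(NA_real_, npar)
  structure(list(
    draws = draws,
    mean = colMeans(flat),
    se = apply(flat, 2, sd),
    lower = apply(flat, 2, quantile, 0.025),
    upper = apply(flat, 2, quantile, 0.975),
    rhat = setNames(rhat, dimnames(draws)[[2]]),
    converged = all(is.na(rhat)) || all(rhat < 1.1),
    n_individuals = nrow(ch), years = histories$years, config = config
  ), class = "cjs_posterior")
}

#' @export
print.cjs_posterior <- function(x, ...) {
  cat("cjs_posterior:", x$n_individuals, "individuals,",
      mcmc_retained_draws(x$config), "retained draws",
      if (!x$converged) "(NOT CONVERGED: R-hat >= 1.1)" else "", "\n")
  print(round(rbind(mean = x$mean, se = x$se, rhat = x$rhat), 3))
  invisible(x)
}

#' Annual survival estimates from a CJS posterior
#'
#' Posterior means and standard deviations of the year-specific apparent
#' survival probabilities, as an `annual_series` (survival from year t to
#' t+1 is indexed at year t).
#'
#' @param post A `cjs_posterior`.
#' @param cell_id Label recorded in the output.
#' @return An `annual_series` data frame with metric `"survival"`.
#' @export
survival_series <- function(post, cell_id = "cell") {
  K <- length(post$years)
  idx <- seq_len(K - 1)
  annual_series_frame(cell_id, "survival", post$years[idx],
                      unname(post$mean[idx]), unname(post$se[idx]),
                      NA_integer_,
                      flag = if (post$converged) "" else "not_converged")
}
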