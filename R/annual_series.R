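# Shared machinery for the per-cell annual count and productivity models:
# year enters as a categorical fixed effect; site is a random intercept when
# the cell holds more than `site_threshold` sites, otherwise a plain GLM is
# fitted. Returns response-scale year estimates with delta-method SEs.
fit_year_effect_model <- function(df, formula_fix, formula_mix, family,
                                  site_threshold = 5) {
  n_sites <- length(unique(df$site_id))
  use_mixed <- n_sites > site_threshold
  fit <- NULL
  if (use_mixed) {
    fit <- tryCatch(
      lme4::glmer(formula_mix, data = df, family = family),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) {
      warning("mixed model failed; falling back to fixed-effect GLM")
    } else if (lme4::isSingular(fit, tol = 1e-5)) {
      warning("singular random-intercept fit; falling back to fixed-effect GLM")
      fit <- NULL
    }
  }
  if (is.null(fit)) fit <- glm(formula_fix, data = df, family = family)
  beta <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  V <- as.matrix(vcov(fit))
  list(fit = fit, beta = beta, se_eta = sqrt(diag(V)), n_sites = n_sites,
       mixed = inherits(fit, "merMod"))
}

annual_series_frame <- function(cell_id, metric, year, estimate, se, n_sites,
                                flag = "") {
  structure(
    data.frame(cell_id = cell_id, metric = metric, year = year,
               estimate = estimate, se = se, n_sites = n_sites, flag = flag,
               stringsAsFactors = FALSE),
    class = c("annual_series", "data.frame")
  )
}

#' Annual count estimates for one grid cell
#'
#' Fits the number of adults captured per site-season with a Poisson error
#' structure and a log link, year as a categorical fixed effect, and a site
#' random intercept when the cell has more than `site_threshold` sites
#' (otherwise a plain GLM). Estimates are returned on the response scale
#' (expected adults per site-season) with delta-method standard errors.
#' Years in which every site caught zero adults sit on the boundary of the
#' log link; they are reported as estimate 0 with `flag = "boundary"`.
#'
#' @param sy Site-year data frame with `site_id`, `year`, `n_adults`
#'   (e.g. from [summarize_site_years()]), already restricted to one cell.
#' @param cell_id Label recorded in the output.
#' @param site_threshold Maximum number of sites for the plain-GLM path.
#' @return An `annual_series` data frame (`cell_id`, `metric`, `year`,
#'   `estimate`, `se`, `n_sites`, `flag`).
#' @export
fit_annual_counts <- function(sy, cell_id = "cell", site_threshold = 5) {
  stopifnot(all(c("site_id", "year", "n_adults") %in% names(sy)))
  if (length(unique(sy$year)) < 2) stop("need >= 2 years of data")
  tot <- tapply(sy$n_adults, sy$year, sum)
  zero_years <- as.integer(names(tot)[tot == 0])
  df <- sy[!sy$year %in% zero_years, ]
  df$fyear <- factor(df$year)
  m <- fit_year_effect_model(
    df, n_adults ~ 0 + fyear, n_adults ~ 0 + fyear + (1 | site_id),
    poisson(), site_threshold
  )
  yrs <- as.integer(levels(df$fyear))
  est <- exp(m$beta)
  se <- est * m$se_eta
  out <- annual_series_frame(cell_id, "count", yrs, unname(est), unname(se),
                             m$n_sites)
  if (length(zero_years)) {
    out <- rbind(out, annual_series_frame(cell_id, "count", zero_years, 0,
                                          NA_real_, m$n_sites, "boundary"))
  }
  out[order(out$year), ]
}

#' Annual productivity estimates for one grid cell
#'
#' Fits the number of juveniles captured per site-season with a binomial
#' error structure, the total birds (juveniles + adults) as the denominator,
#' year as a categorical fixed effect and the same site random-intercept
#' rule as [fit_annual_counts()]. The estimate is the juvenile proportion
#' of all birds captured. Years with zero birds are missing (not zero);
#' years with all or no juveniles are boundary estimates, flagged.
#'
#' @inheritParams fit_annual_counts
#' @param sy Site-year data frame with `site_id`, `year`, `n_adults`,
#'   `n_juveniles`.
#' @return An `annual_series` data frame with metric `"productivity"`.
#' @export
fit_annual_productivity <- function(sy, cell_id = "cell", site_threshold = 5) {
  stopifnot(all(c("site_id", "year", "n_adults", "n_juveniles") %in% names(sy)))
  sy$total <- sy$n_adults + sy$n_juveniles
  juv <- tapply(sy$n_juveniles, sy$year, sum)
  tot <- tapply(sy$total, sy$year, sum)
  if (sum(tot > 0) < 2) stop("need >= 2 years with birds captured")
  bound0 <- as.integer(names(tot)[tot > 0 & juv == 0])
  bound1 <- as.integer(names(tot)[tot > 0 & juv == tot])
  df <- sy[sy$total > 0 & !sy$year %in% c(bound0, bound1), ]
  out <- NULL
  if (length(unique(df$year)) >= 1) {
    df$fyear <- factor(df$year)
    m <- fit_year_effect_model(
      df, cbind(n_juveniles, total - n_juveniles) ~ 0 + fyear,
      cbind(n_juveniles, total - n_juveniles) ~ 0 + fyear + (1 | site_id),
      binomial(), site_threshold
    )
    yrs <- as.integer(levels(df$fyear))
    est <- plogis(m$beta)
    se <- est * (1 - est) * m$se_eta
    out <- annual_series_frame(cell_id, "productivity", yrs, unname(est),
                               unname(se), m$n_sites)
  }
  n_sites <- length(unique(sy$site_id))
  for (b in list(list(bound0, 0), list(bound1, 1))) {
    if (length(b[[1]])) {
      out <- rbind(out, annual_series_frame(cell_id, "productivity", b[[1]],
                                            b[[2]], NA_real_, n_sites,
                                            "boundary"))
    }
  }
  out[order(out$year), ]
}
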