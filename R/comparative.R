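# Fit a weighted Gaussian mixed model by ML, dropping random terms that are
# singular or have too few groups (flagged), and report likelihood-ratio
# chi-squares for the requested fixed terms against nested ML refits.
weighted_lmm_lrt <- function(data, response, fixed_terms, test_terms,
                             random, weights_col, min_groups = 5) {
  stopifnot(weights_col %in% names(data), all(data[[weights_col]] > 0))
  data$.w <- data[[weights_col]]
  flags <- character()
  keep_random <- character()
  for (r in random) {
    if (length(unique(data[[r]])) >= min_groups) keep_random <- c(keep_random, r)
    else flags <- c(flags, sprintf("random term %s dropped: < %d groups", r,
                                   min_groups))
  }
  fixed_rhs <- paste(fixed_terms, collapse = " + ")
  fit_one <- function(rhs, rand, allow_singular = FALSE) {
    if (length(rand)) {
      f <- as.formula(paste(response, "~", rhs, "+",
                            paste(sprintf("(1 | %s)", rand), collapse = " + ")))
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(f, data = data, weights = .w, REML = FALSE)
      ))
      if (!allow_singular && lme4::isSingular(fit, tol = 1e-5)) return(NULL)
      fit
    } else {
      lm(as.formula(paste(response, "~", rhs)), data = data, weights = .w)
    }
  }
  full <- NULL
  rand <- keep_random
  while (is.null(full)) {
    full <- tryCatch(fit_one(fixed_rhs, rand), error = function(e) NULL)
    if (is.null(full)) {
      if (!length(rand)) stop("weighted model could not be fitted")
      flags <- c(flags, sprintf("random term %s dropped: singular fit",
                                rand[length(rand)]))
      rand <- rand[-length(rand)]
      full <- NULL
      if (!length(rand)) full <- fit_one(fixed_rhs, rand)
    }
  }
  nfix <- function(fit) {
    if (inherits(fit, "merMod")) length(lme4::fixef(fit)) else
      sum(!is.na(coef(fit)))
  }
  ll_full <- as.numeric(logLik(full))
  rows <- lapply(test_terms, function(tt) {
    # Type-II style: drop the term (and, for a main effect, keep others).
    # Reduced fits keep the full model's random structure even when their
    # variance estimates sit on the boundary: the LRT needs nested fits.
    reduced_terms <- setdiff(fixed_terms, tt)
    rhs <- if (length(reduced_terms)) paste(reduced_terms, collapse = " + ")
           else "1"
    red <- tryCatch(fit_one(rhs, rand, allow_singular = TRUE),
                    error = function(e) fit_one(rhs, character()))
    chi <- max(0, 2 * (ll_full - as.numeric(logLik(red))))
    df <- nfix(full) - nfix(red)
    data.frame(term = tt, chisq = chi, df = df,
               p_value = pchisq(chi, df, lower.tail = FALSE))
  })
  vc <- if (inherits(full, "merMod")) {
    v <- as.data.frame(lme4::VarCorr(full))
    setNames(v$vcov, ifelse(is.na(v$var1), v$grp, paste(v$grp, v$var1)))
  } else c(residual = summary(full)$sigma^2)
  structure(list(tests = do.call(rbind, rows), varcomp = vc, fit = full,
                 random_used = rand, flags = flags),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  print(transform(x$tests, chisq = round(chisq, 3),
                  p_value = signif(p_value, 3)))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Weighted mixed model for relative scale or strength of synchrony
#'
#' Gaussian linear mixed model with the per-cell (or per-species) synchrony
#' estimates as response, the stated fixed effects (by default the
#' count/rate metric and migratory status), grid cell and species as random
#' intercepts, and observation weights scaling the residual precision
#' (the inverse-SE weights produced by [extract_scale_strength()]). Term
#' chi-squares come from likelihood-ratio tests between nested ML fits.
#' Random terms with fewer than `min_groups` levels, or whose inclusion
#' makes the fit singular, are dropped and flagged.
#'
#' @param records Data frame of synchrony records: `species`,
#'   `migratory_status`, `cell_id`, `metric` (or pairing), the response
#'   column and its weight column.
#' @param response `"relative_scale"` or `"strength"`.
#' @param fixed Character vector of fixed-effect terms.
#' @param random Character vector of random-intercept grouping factors.
#' @param weights_col Name of the weight column; defaults to the
#'   scale/strength weight matching the response.
#' @param min_groups Minimum levels for a random factor.
#' @return A `model_report`: `tests` (term, chisq, df, p_value),
#'   `varcomp`, the fitted model, and `flags`.
#' @export
fit_weighted_lmm <- function(records,
                             response = c("relative_scale", "strength"),
                             fixed = c("metric", "migratory_status"),
                             random = c("cell_id", "species"),
                             weights_col = NULL, min_groups = 5) {
  response <- match.arg(response)
  if (is.null(weights_col)) {
    weights_col <- if (response == "relative_scale") "weight_scale" else
      "weight_strength"
  }
  for (f in fixed) {
    if (length(unique(records[[f]])) < 2) {
      stop("fixed factor ", f, " needs >= 2 levels")
    }
  }
  weighted_lmm_lrt(records, response, fixed, fixed, random, weights_col,
                   min_groups)
}

#' Weighted mixed model for count-rate congruence
#'
#' As [fit_weighted_lmm()] but with congruence pairing (count-survival vs
#' count-productivity), migratory status and their interaction as the
#' explanatory terms. The interaction is tested against the
#' main-effects-only model; main effects are tested within the
#' no-interaction model (type-II likelihood-ratio tests).
#'
#' @inheritParams fit_weighted_lmm
#' @param records Congruence synchrony records with a `pairing` column.
#' @export
fit_congruence_lmm <- function(records,
                               response = c("relative_scale", "strength"),
                               random = c("cell_id", "species"),
                               weights_col = NULL, min_groups = 5) {
  response <- match.arg(response)
  if (is.null(weights_col)) {
    weights_col <- if (response == "relative_scale") "weight_scale" else
      "weight_strength"
  }
  if (length(unique(records$pairing)) < 2) stop("need both congruence pairings")
  main <- weighted_lmm_lrt(records, response,
                           c("pairing", "migratory_status"),
                           c("pairing", "migratory_status"),
                           random, weights_col, min_groups)
  full <- weighted_lmm_lrt(records, response,
                           c("pairing", "migratory_status",
                             "pairing:migratory_status"),
                           "pairing:migratory_status",
                           random, weights_col, min_groups)
  structure(list(tests = rbind(main$tests, full$tests),
                 varcomp = full$varcomp, fit = full$fit,
                 random_used = full$random_used,
                 flags = unique(c(main$flags, full$flags))),
            class = "model_report")
}

#' Quasibinomial model of synchrony periodicity
#'
#' Binomial GLM of the number of years with significant phasor mean field
#' magnitudes in each timescale band, with the total in-cone years as the
#' denominator and a quasibinomial error structure to absorb
#' overdispersion. Timescale enters as a continuous covariate (the band
#' midpoint); demographic metric, migratory status and all two-way
#' interactions complete the model. Both the F tests customary under
#' quasibinomial fits and dispersion-adjusted chi-square statistics are
#' reported, per analysis-of-deviance term.
#'
#' @param table Data frame with `species`, `migratory_status`, `metric`,
#'   `band`, `n_significant_years`, `n_years` (rows from
#'   [significant_year_counts()] stacked over species and metrics).
#' @param band_midpoints Named numeric giving each band's timescale
#'   midpoint in years.
#' @return A `model_report` whose `tests` carry `chisq`, `df`, `p_value`
#'   (dispersion-adjusted) plus `f_value` and `p_f`; `dispersion` is
#'   attached.
#' @export
fit_periodicity_glm <- function(table,
                                band_midpoints = c(short = 2.5,
                                                   intermediate = 4,
                                                   long = 8)) {
  stopifnot(all(table$n_years >= 1),
            all(table$band %in% names(band_midpoints)))
  table$timescale <- band_midpoints[table$band]
  if (length(unique(table$timescale)) < 2) stop("need >= 2 timescale values")
  rhs <- "(timescale + metric + migratory_status)^2"
  keep2 <- length(unique(table$metric)) >= 2 &&
    length(unique(table$migratory_status)) >= 2
  if (!keep2) rhs <- "timescale + metric + migratory_status"
  f <- as.formula(paste(
    "cbind(n_significant_years, n_years - n_significant_years) ~", rhs))
  fit <- glm(f, data = table, family = stats::quasibinomial())
  disp <- summary(fit)$dispersion
  aod <- anova(fit, test = "F")
  aod <- aod[-1, , drop = FALSE] # drop the NULL row
  tests <- data.frame(
    term = rownames(aod),
    chisq = aod$Deviance / disp,
    df = aod$Df,
    p_value = pchisq(aod$Deviance / disp, aod$Df, lower.tail = FALSE),
    f_value = aod$F,
    p_f = aod$`Pr(>F)`
  )
  structure(list(tests = tests, varcomp = NULL, fit = fit,
                 dispersion = disp, flags = character()),
            class = "model_report")
}
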