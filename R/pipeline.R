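#' Build and validate a pipeline run configuration
#'
#' A plain-list (YAML-compatible) configuration for [run_pipeline()].
#' Unspecified entries take the defaults below; `resolution_km` must be
#' one of 25, 50 or 100 and all filter thresholds must be positive.
#'
#' @param config Named list (e.g. from [yaml::read_yaml()]) overriding any
#'   of: `resolution_km`, `master_seed`, `species` (list of
#'   `list(name, migratory_status)`), `simulate` (generator settings or
#'   `NULL` to read `input_captures`), `input_captures` (path to a capture
#'   CSV), `filters`, `mcmc`, `correlogram`, `wavelet`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(config = list()) {
  def <- list(
    resolution_km = 100,
    master_seed = 1,
    species = list(
      list(name = "SPA", migratory_status = "subSaharan-migrant"),
      list(name = "SPB", migratory_status = "European-resident")
    ),
    input_captures = NULL,
    simulate = list(
      n_cells = 9, extent_km = 300, sites_per_cell = 2, years = 20,
      spatial = list(family = "spherical", range_km = 250, sill = 0.5),
      temporal = list(ar1_coef = 0, sine_period_years = 4,
                      sine_amplitude = 0.15),
      trend_slopes = list(productivity = 0.01, survival = 0.01,
                          abundance = 0.01),
      anomaly_sd = 0.25,
      params = list(n_visits = 8, baseline_phi = 0.5,
                    baseline_productivity = 1.0, residency_prob = 0.7,
                    per_visit_capture_prob = 0.25,
                    initial_adults_per_site = 40)
    ),
    filters = list(min_visits = 7, min_half_visits = 3, min_years = 5,
                   min_adults = 2),
    mcmc = list(n_chains = 2, n_iter = 6000, n_burn = 2000, thin = 4),
    correlogram = list(min_pairs = 20, n_posterior_sims = 1000,
                       pool = "species", min_overlap = 5),
    wavelet = list(alpha = 0.05, n_draws = 10000)
  )
  cfg <- utils::modifyList(def, config)
  if (!cfg$resolution_km %in% c(25, 50, 100)) {
    stop("resolution_km must be one of 25, 50, 100")
  }
  if (any(unlist(cfg$filters) <= 0)) stop("filter thresholds must be positive")
  if (!cfg$correlogram$pool %in% c("species", "cell")) {
    stop("correlogram pool must be 'species' or 'cell'")
  }
  stopifnot(length(cfg$species) >= 1)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  derive_seed(0L, jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))
}

pipe_path <- function(dir, ...) file.path(dir, paste0(...))

stage_write <- function(df, dir, name) {
  write.csv(df, pipe_path(dir, name, ".csv"), row.names = FALSE)
}

#' Run the synchrony pipeline end-to-end
#'
#' Executes the stages simulate (optional) -> filter -> rates -> synchrony
#' (detrend, pairwise correlations, correlograms, congruence) -> wavelet ->
#' compare, writing every intermediate artifact as tidy CSV under
#' `output_dir` plus a JSON run manifest. Identical configuration and seed
#' give bit-identical outputs. A stage whose inputs are missing or whose
#' preconditions fail is recorded as failed in the manifest and later
#' stages are skipped.
#'
#' @param config A [run_config()] (or plain list passed through it).
#' @param output_dir Output directory (created if needed).
#' @param stages Which stages to run; earlier stages' outputs are read from
#'   `output_dir` when not rerun.
#' @param seed Optional override of `config$master_seed` (recorded in the
#'   manifest).
#' @param quiet Suppress progress messages.
#' @return The run manifest (list), invisibly also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = run_config(), output_dir,
                         stages = c("simulate", "filter", "rates",
                                    "synchrony", "wavelet", "compare"),
                         seed = NULL, quiet = TRUE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (!is.null(seed)) config$master_seed <- seed
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(config_hash = config_hash(config),
                   master_seed = config$master_seed,
                   resolution_km = config$resolution_km,
                   version = as.character(utils::packageVersion("cessync")),
                   stages = list(), seeds = list(), counts = list(),
                   exclusions = list(), outputs = character(),
                   inputs = character())
  failed <- FALSE
  mark <- function(stage, status, note = NULL) {
    manifest$stages[[stage]] <<- c(list(status = status),
                                   if (!is.null(note)) list(note = note))
    if (status != "ok") failed <<- TRUE
  }
  spnames <- vapply(config$species, `[[`, "", "name")
  status_of <- setNames(vapply(config$species, `[[`, "", "migratory_status"),
                        spnames)

  ## ---- simulate ----
  if ("simulate" %in% stages && !failed) {
    say("stage simulate")
    if (is.null(config$simulate)) {
      mark("simulate", "skipped", "using input_captures")
    } else {
      sim <- config$simulate
      lay_seed <- derive_seed(config$master_seed, "landscape")
      layout <- make_landscape(sim$n_cells, sim$extent_km,
                               config$resolution_km, sim$sites_per_cell,
                               seed = lay_seed)
      manifest$seeds$landscape <- lay_seed
      for (sp in spnames) {
        fs <- derive_seed(config$master_seed, paste0("field_", sp))
        cs <- derive_seed(config$master_seed, paste0("captures_", sp))
        field <- simulate_rate_field(
          layout, sim$years,
          spatial = spatial_corr_model(sim$spatial$family,
                                       sim$spatial$range_km,
                                       sim$spatial$sill),
          temporal = temporal_model(sim$temporal$ar1_coef,
                                    sim$temporal$sine_period_years,
                                    sim$temporal$sine_amplitude),
          trend_slopes = unlist(sim$trend_slopes),
          anomaly_sd = sim$anomaly_sd, seed = fs)
        pars <- do.call(sim_params, c(sim$params, list(seed = cs)))
        recs <- simulate_captures(layout, field, pars, species = sp)
        write_captures(recs, pipe_path(output_dir, "captures_", sp, ".csv"))
        write_truth(attr(recs, "truth"),
                    pipe_path(output_dir, "truth_", sp, ".csv"))
        manifest$seeds[[paste0("field_", sp)]] <- fs
        manifest$seeds[[paste0("captures_", sp)]] <- cs
        manifest$counts[[paste0("records_", sp)]] <- nrow(recs)
      }
      mark("simulate", "ok")
    }
  }

  ## ---- filter ----
  filtered <- list()
  if ("filter" %in% stages && !failed) {
    say("stage filter")
    ok <- TRUE
    excl_total <- 0L
    for (sp in spnames) {
      path <- if (!is.null(config$input_captures)) config$input_captures else
        pipe_path(output_dir, "captures_", sp, ".csv")
      if (!file.exists(path)) {
        mark("filter", "failed", paste("missing capture input:", path))
        ok <- FALSE
        break
      }
      manifest$inputs <- union(manifest$inputs, path)
      recs <- read_captures(path)
      fl <- filter_site_years(recs, species = sp,
                              min_visits = config$filters$min_visits,
                              min_half_visits = config$filters$min_half_visits,
                              min_years = config$filters$min_years,
                              min_adults = config$filters$min_adults)
      filtered[[sp]] <- fl
      stage_write(fl$exclusions, output_dir, paste0("exclusions_", sp))
      excl_total <- excl_total + nrow(fl$exclusions)
      manifest$counts[[paste0("site_years_", sp)]] <- nrow(fl$summary)
      if (nrow(fl$counts) == 0) {
        mark("filter", "failed", paste("no records survive filtering for", sp))
        ok <- FALSE
        break
      }
    }
    manifest$exclusions$filter <- excl_total
    if (ok) mark("filter", "ok")
  }

  ## ---- rates ----
  if ("rates" %in% stages && !failed) {
    say("stage rates")
    all_series <- list()
    post_rows <- list()
    for (sp in spnames) {
      fl <- filtered[[sp]]
      if (is.null(fl)) {
        mark("rates", "failed", "filter outputs not available in this run")
        break
      }
      grid <- assign_grid_cells(unique(fl$counts[, c("site_id", "lat", "lon")]),
                                config$resolution_km)
      site_cell <- setNames(grid$sites$cell_id, grid$sites$site_id)
      stage_write(grid$cells, output_dir, paste0("cells_", sp))
      sy_counts <- summarize_site_years(fl$counts, sp)
      sy_counts$cell_id <- site_cell[sy_counts$site_id]
      sy_rates <- summarize_site_years(fl$rates, sp)
      sy_rates$cell_id <- site_cell[sy_rates$site_id]
      for (cc in unique(sy_counts$cell_id)) {
        sub <- sy_counts[sy_counts$cell_id == cc, ]
        if (length(unique(sub$year)) >= 2) {
          all_series[[length(all_series) + 1L]] <-
            cbind(species = sp, fit_annual_counts(sub, cell_id = cc))
        }
        subr <- sy_rates[sy_rates$cell_id == cc, ]
        if (nrow(subr) && sum(subr$n_adults + subr$n_juveniles) > 0 &&
            length(unique(subr$year)) >= 2) {
          all_series[[length(all_series) + 1L]] <-
            cbind(species = sp, fit_annual_productivity(subr, cell_id = cc))
        }
        rr <- fl$rates[fl$rates$site_id %in%
                         names(site_cell)[site_cell == cc] &
                         fl$rates$age == "A", ]
        if (nrow(rr)) {
          hist <- build_capture_histories(rr)
          if (ncol(hist$ch) >= 3 && nrow(hist$ch) >= 2) {
            cfgm <- mcmc_config(config$mcmc$n_chains, config$mcmc$n_iter,
                                config$mcmc$n_burn, config$mcmc$thin,
                                seed = derive_seed(config$master_seed,
                                                   paste0("cjs_", sp, "_", cc)))
            post <- fit_cjs(hist, cfgm)
            all_series[[length(all_series) + 1L]] <-
              cbind(species = sp, survival_series(post, cell_id = cc))
            post_rows[[length(post_rows) + 1L]] <- data.frame(
              species = sp, cell_id = cc,
              parameter = names(post$mean), mean = unname(post$mean),
              se = unname(post$se), lower = unname(post$lower),
              upper = unname(post$upper), rhat = unname(post$rhat),
              converged = post$converged)
          }
        }
      }
    }
    if (!length(all_series)) {
      mark("rates", "failed", "no annual series could be estimated")
    } else if (is.null(manifest$stages$rates)) {
      series <- do.call(rbind, all_series)
      stage_write(series, output_dir, "annual_series")
      if (length(post_rows)) {
        stage_write(do.call(rbind, post_rows), output_dir,
                    "survival_posteriors")
      }
      manifest$counts$annual_series <- nrow(series)
      mark("rates", "ok")
    }
  }

  ## ---- synchrony ----
  if ("synchrony" %in% stages && !failed) {
    say("stage synchrony")
    spath <- pipe_path(output_dir, "annual_series.csv")
    if (!file.exists(spath)) {
      mark("synchrony", "failed", "annual_series.csv missing (run rates first)")
    } else {
      series <- read.csv(spath, stringsAsFactors = FALSE)
      pair_rows <- list()
      sync_rows <- list()
      curve_rows <- list()
      excl_n <- 0L
      pairings <- list(
        list(a = "count", b = "count", lag = 0, label = "count"),
        list(a = "productivity", b = "productivity", lag = 0,
             label = "productivity"),
        list(a = "survival", b = "survival", lag = 0, label = "survival"),
        list(a = "count", b = "productivity", lag = 1,
             label = "count-productivity"),
        list(a = "count", b = "survival", lag = 1, label = "count-survival")
      )
      for (sp in spnames) {
        sub <- series[series$species == sp & series$flag %in% c("", NA), ]
        det <- detrend_series(sub)
        excl_n <- excl_n + nrow(det$exclusions)
        cells <- read.csv(pipe_path(output_dir, "cells_", sp, ".csv"),
                          stringsAsFactors = FALSE)
        occ <- cells[cells$cell_id %in% unique(det$residuals$cell_id), ]
        if (nrow(occ) < 2) next
        mind <- minimum_distance(occ)
        for (pr in pairings) {
          pc <- pairwise_correlations(det$residuals, cells, pr$a, pr$b,
                                      lag = pr$lag,
                                      min_overlap = config$correlogram$min_overlap)
          excl_n <- excl_n + nrow(pc$skipped)
          if (!nrow(pc$pairs)) next
          pair_rows[[length(pair_rows) + 1L]] <-
            cbind(species = sp, pairing = pr$label, pc$pairs)
          groups <- if (config$correlogram$pool == "species")
            list(pooled = pc$pairs) else
            split(pc$pairs, pc$pairs$cell_a)
          for (gn in names(groups)) {
            cg <- suppressMessages(fit_correlogram(
              groups[[gn]],
              n_posterior_sims = config$correlogram$n_posterior_sims,
              min_pairs = config$correlogram$min_pairs,
              seed = derive_seed(config$master_seed,
                                 paste0("cg_", sp, "_", pr$label, "_", gn))))
            if (is.null(cg)) { excl_n <- excl_n + 1L; next }
            est <- extract_scale_strength(cg, mind)
            sync_rows[[length(sync_rows) + 1L]] <- cbind(
              species = sp, migratory_status = unname(status_of[sp]),
              cell_id = gn, resolution_km = config$resolution_km,
              metric_or_pairing = pr$label, est)
            curve_rows[[length(curve_rows) + 1L]] <- data.frame(
              species = sp, pairing = pr$label, cell_id = gn,
              distance_km = cg$distance_km, fit = cg$fit, lower = cg$lower,
              upper = cg$upper, se = cg$se, n_pairs = cg$n_pairs)
          }
        }
      }
      manifest$exclusions$synchrony <- excl_n
      if (!length(sync_rows)) {
        mark("synchrony", "failed", "no correlogram could be fitted")
      } else {
        stage_write(do.call(rbind, pair_rows), output_dir, "pair_correlations")
        stage_write(do.call(rbind, curve_rows), output_dir, "correlograms")
        sync <- do.call(rbind, sync_rows)
        stage_write(sync, output_dir, "synchrony")
        manifest$counts$synchrony_estimates <- nrow(sync)
        mark("synchrony", "ok")
      }
    }
  }

  ## ---- wavelet ----
  if ("wavelet" %in% stages && !failed) {
    say("stage wavelet")
    spath <- pipe_path(output_dir, "annual_series.csv")
    if (!file.exists(spath)) {
      mark("wavelet", "failed", "annual_series.csv missing (run rates first)")
    } else {
      series <- read.csv(spath, stringsAsFactors = FALSE)
      ptab <- list()
      wrows <- list()
      fields <- list()
      for (sp in spnames) {
        for (metric in c("count", "productivity", "survival")) {
          sub <- series[series$species == sp & series$metric == metric &
                          series$flag %in% c("", NA), ]
          if (!nrow(sub)) next
          yrs <- sort(unique(sub$year))
          transforms <- list()
          for (cc in unique(sub$cell_id)) {
            s2 <- sub[sub$cell_id == cc, ]
            s2 <- s2[order(s2$year), ]
            if (nrow(s2) < 8 || !identical(s2$year, yrs) ||
                any(diff(s2$year) != 1)) next
            cl <- tryCatch(clean_series(s2$estimate, s2$year),
                           error = function(e) NULL)
            if (is.null(cl)) next
            transforms[[cc]] <- morlet_cwt(cl, timescale_grid(length(cl)))
          }
          if (length(transforms) < 2) next
          fld <- wpmf(transforms, years = yrs,
                      alpha = config$wavelet$alpha,
                      n_draws = config$wavelet$n_draws,
                      seed = derive_seed(config$master_seed,
                                         paste0("wpmf_", sp, "_", metric)))
          fields[[paste(sp, metric)]] <- fld
          grid <- expand.grid(year = fld$years, timescale = fld$timescales)
          wrows[[length(wrows) + 1L]] <- data.frame(
            species = sp, metric = metric, grid,
            magnitude = as.vector(fld$magnitude),
            in_cone = !is.na(as.vector(fld$magnitude)),
            significant = !is.na(as.vector(fld$magnitude)) &
              as.vector(fld$magnitude) >= fld$threshold)
          counts <- significant_year_counts(fld)
          if (!is.null(counts)) {
            ptab[[length(ptab) + 1L]] <- cbind(
              species = sp, migratory_status = unname(status_of[sp]),
              metric = metric, counts)
          }
        }
      }
      if (!length(ptab)) {
        mark("wavelet", "failed", "no wavelet field could be computed")
      } else {
        stage_write(do.call(rbind, wrows), output_dir, "wpmf")
        stage_write(do.call(rbind, ptab), output_dir, "periodicity")
        # composite fields per migratory group and overall
        comp_rows <- list()
        for (grp in unique(status_of)) {
          for (metric in c("count", "productivity", "survival")) {
            fs <- fields[paste(names(status_of)[status_of == grp], metric)]
            fs <- fs[!vapply(fs, is.null, TRUE)]
            if (!length(fs)) next
            cm <- composite_wpmf(fs)
            comp_rows[[length(comp_rows) + 1L]] <- data.frame(
              group = grp, metric = metric,
              expand.grid(year = cm$years, timescale = cm$timescales),
              magnitude = as.vector(cm$magnitude))
          }
        }
        if (length(comp_rows)) {
          stage_write(do.call(rbind, comp_rows), output_dir, "wpmf_composite")
        }
        manifest$counts$periodicity_rows <- nrow(do.call(rbind, ptab))
        mark("wavelet", "ok")
      }
    }
  }

  ## ---- compare ----
  if ("compare" %in% stages && !failed) {
    say("stage compare")
    spath <- pipe_path(output_dir, "synchrony.csv")
    ppath <- pipe_path(output_dir, "periodicity.csv")
    if (!file.exists(spath) || !file.exists(ppath)) {
      mark("compare", "failed", "synchrony/periodicity outputs missing")
    } else {
      sync <- read.csv(spath, stringsAsFactors = FALSE)
      per <- read.csv(ppath, stringsAsFactors = FALSE)
      within <- sync[sync$metric_or_pairing %in%
                       c("count", "productivity", "survival"), ]
      within$metric <- within$metric_or_pairing
      congr <- sync[grepl("-", sync$metric_or_pairing), ]
      congr$pairing <- congr$metric_or_pairing
      reports <- list()
      add_report <- function(name, expr) {
        rep <- tryCatch(expr, error = function(e) conditionMessage(e))
        if (is.character(rep)) {
          manifest$counts[[paste0("model_", name)]] <<- NA
          manifest$stages$compare_notes <<-
            c(manifest$stages$compare_notes, paste(name, "not fitted:", rep))
        } else {
          stage_write(cbind(model = name, rep$tests), output_dir,
                      paste0("model_", name))
          reports[[name]] <<- rep
        }
      }
      add_report("scale", fit_weighted_lmm(within, "relative_scale"))
      add_report("strength", fit_weighted_lmm(within, "strength"))
      add_report("congruence_scale", fit_congruence_lmm(congr, "relative_scale"))
      add_report("congruence_strength", fit_congruence_lmm(congr, "strength"))
      add_report("periodicity", fit_periodicity_glm(per))
      if (length(reports)) mark("compare", "ok") else
        mark("compare", "failed", "no comparative model could be fitted")
    }
  }

  manifest$outputs <- sort(list.files(output_dir, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, pipe_path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
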