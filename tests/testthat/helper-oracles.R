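# Independent oracles and small generators shared across tests.

# Exhaustive-enumeration log-likelihood for the transient-CJS model: sums
# over the resident/transient flag and every admissible death time, so it
# shares nothing with the forward recursion it checks.
enum_cjs_loglik <- function(ch, first, phi, p, rho) {
  K <- ncol(ch)
  ll <- 0
  for (i in seq_len(nrow(ch))) {
    y <- ch[i, ]
    f <- first[i]
    lik_res <- 0
    for (d in f:K) { # d = last occasion alive
      if (d < K && any(y[(d + 1):K] == 1)) next
      surv <- if (d > f) prod(phi[f:(d - 1)]) else 1
      death <- if (d < K) 1 - phi[d] else 1
      det <- if (d > f) {
        yy <- y[(f + 1):d]
        prod(p^yy * (1 - p)^(1 - yy))
      } else 1
      lik_res <- lik_res + surv * death * det
    }
    seen_after <- f < K && any(y[(f + 1):K] == 1)
    lik <- rho * lik_res + (1 - rho) * (!seen_after)
    ll <- ll + log(lik)
  }
  ll
}

# wrap a 0/1 matrix as a capture_history_set
as_history_set <- function(ch) {
  first <- apply(ch, 1, function(z) which(z == 1L)[1])
  structure(list(ch = ch, first = as.integer(first),
                 years = seq_len(ncol(ch))),
            class = "capture_history_set")
}

# all single capture histories of length K that start with a detection at
# some occasion (transposed to 1-row matrices)
all_histories <- function(K) {
  grid <- as.matrix(expand.grid(rep(list(0:1), K)))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    m <- matrix(as.integer(grid[i, ]), 1, K)
    m
  })
}

# true spherical correlation curve
spherical_corr <- function(d, range_km, sill) {
  u <- d / range_km
  sill * pmax(0, 1 - 1.5 * u + 0.5 * u^3)
}

# construction-style pair correlations: true spherical curve + iid noise
make_spherical_pairs <- function(n = 500, range_km = 400, sill = 0.4,
                                 dmax = 600, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  d <- runif(n, 0, dmax)
  data.frame(distance_km = d,
             r = spherical_corr(d, range_km, sill) + rnorm(n, 0, noise_sd))
}

# minimal capture-record row builder
rec_row <- function(site, year, visit, ring, age = "A", species = "SP1",
                    lat = 47, lon = 8) {
  data.frame(site_id = site, lat = lat, lon = lon, species = species,
             year = year, visit = visit, ring_id = ring, age = age,
             stringsAsFactors = FALSE)
}

# a site-year block with the given distinct visit indices (one juvenile
# capture per visit so effort is visible without adults)
effort_rows <- function(site, year, visits, species = "SP1") {
  do.call(rbind, lapply(seq_along(visits), function(i) {
    rec_row(site, year, visits[i], sprintf("%s_%d_%d", site, year, i),
            age = "J", species = species)
  }))
}

# synchrony-record generator for the comparative-model calibration tests:
# species x cell records with a metric effect on the response, weak species
# and cell random intercepts, and heteroscedastic known weights.
make_sync_records <- function(n_species = 15, n_cells = 10, effect = 0.1,
                              noise_sd = 0.05, re_sd = 0.02, seed = 1,
                              base = 0.5) {
  set.seed(seed)
  g <- expand.grid(species = sprintf("sp%02d", seq_len(n_species)),
                   cell_id = sprintf("c%02d", seq_len(n_cells)),
                   metric = c("count", "productivity"),
                   stringsAsFactors = FALSE)
  sp_re <- rnorm(n_species, 0, re_sd)
  cl_re <- rnorm(n_cells, 0, re_sd)
  w <- runif(nrow(g), 0.5, 2)
  mu <- base + effect * (g$metric == "productivity") +
    sp_re[as.integer(factor(g$species))] +
    cl_re[as.integer(factor(g$cell_id))]
  g$relative_scale <- mu + rnorm(nrow(g), 0, noise_sd / sqrt(w))
  g$strength <- g$relative_scale
  g$migratory_status <- ifelse(as.integer(factor(g$species)) %% 2 == 0,
                               "European-resident", "subSaharan-migrant")
  g$weight_scale <- w
  g$weight_strength <- w
  g
}

annual_series_stub <- function(cell, metric, years, estimates) {
  data.frame(cell_id = cell, metric = metric, year = years,
             estimate = estimates, se = 0.1, n_sites = 1, flag = "",
             stringsAsFactors = FALSE)
}

resid_rows <- function(cell, metric, years, values) {
  data.frame(cell_id = cell, metric = metric, year = years,
             residual = values, stringsAsFactors = FALSE)
}

# cells on the equator at given eastward km offsets (1 deg ~ 111.195 km)
cells_at_km <- function(x_km) {
  deg <- x_km / (6371.0088 * pi / 180)
  data.frame(cell_id = letters[seq_along(x_km)], centroid_lat = 0,
             centroid_lon = deg, stringsAsFactors = FALSE)
}

correlogram_stub <- function(d, y) {
  structure(list(distance_km = d, fit = y, lower = y - 0.05, upper = y + 0.05,
                 se = rep(0.02, length(d)), n_pairs = 100, gam = NULL),
            class = "correlogram")
}
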