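#' Simulation parameters for a constant-effort capture history
#'
#' @param n_sites_per_cell Informational; site placement is owned by
#'   [make_landscape()].
#' @param n_visits Netting visits per season at every site.
#' @param baseline_phi Adult apparent survival probability at anomaly 0.
#' @param baseline_productivity Juveniles per adult at anomaly 0.
#' @param residency_prob Probability a newly captured adult is a resident
#'   (re-encounterable) rather than a transient never seen again.
#' @param per_visit_capture_prob Capture probability of a present bird at a
#'   single visit; the seasonal encounter probability is
#'   `1 - (1 - p)^n_visits`.
#' @param initial_adults_per_site Adults alive at each site in year 1.
#' @param seed Integer seed for [simulate_captures()].
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_sites_per_cell = 2, n_visits = 8, baseline_phi = 0.5,
                       baseline_productivity = 1.0, residency_prob = 0.7,
                       per_visit_capture_prob = 0.25,
                       initial_adults_per_site = 40, seed = 1) {
  p <- list(n_sites_per_cell = n_sites_per_cell, n_visits = n_visits,
            baseline_phi = baseline_phi,
            baseline_productivity = baseline_productivity,
            residency_prob = residency_prob,
            per_visit_capture_prob = per_visit_capture_prob,
            initial_adults_per_site = initial_adults_per_site, seed = seed)
  probs <- c(p$baseline_phi, p$residency_prob, p$per_visit_capture_prob)
  stopifnot(all(probs > 0 & probs <= 1), p$baseline_productivity >= 0,
            p$n_visits >= 1, p$initial_adults_per_site >= 1)
  structure(p, class = "sim_params")
}

#' Simulate constant-effort capture records from a known rate field
#'
#' Each site carries an individually tracked adult population. From year t
#' to t+1 every adult survives with probability
#' `plogis(qlogis(baseline_phi) + survival_anomaly[t, cell])`, and
#' `Poisson(N_t * productivity_t * baseline_phi)` new adults recruit, where
#' `productivity_t = baseline_productivity * exp(productivity_anomaly)`
#' (recruits survive their first winter with the adult survival rate, so the
#' population is stationary in expectation at the defaults). Within a
#' season every present adult is caught independently at each visit with
#' `per_visit_capture_prob`; at its first-ever capture a bird is ringed and
#' flagged resident with probability `residency_prob` — transients emit that
#' season's records and then leave the population, never to be seen again.
#' Juveniles (`Poisson(N_t * productivity_t)` per site-year) are captured
#' with the same per-visit model, ringed, and never re-identified as adults.
#'
#' @param layout A `grid_layout`.
#' @param field A `rate_field` sharing the layout's cell ids.
#' @param params A [sim_params()].
#' @param species Species code written to every record.
#' @return A data frame of capture records with columns `site_id`, `lat`,
#'   `lon`, `species`, `year`, `visit`, `ring_id`, `age` (`"A"`/`"J"`), plus
#'   attribute `truth` (per cell-year true survival, productivity and mean
#'   abundance — the sidecar for recovery tests) and attribute `truncated`
#'   if every population went extinct before the final year (a warning is
#'   also raised).
#' @export
simulate_captures <- function(layout, field, params, species = "SP1") {
  stopifnot(inherits(layout, "grid_layout"), inherits(field, "rate_field"),
            inherits(params, "sim_params"))
  if (!all(layout$cells$cell_id %in% field$cell_ids)) {
    stop("layout and rate field do not share cell ids")
  }
  set.seed(params$seed)
  years <- field$years
  ny <- length(years)
  sites <- layout$sites
  p_visit <- params$per_visit_capture_prob
  nv <- params$n_visits
  phi_cell <- plogis(qlogis(params$baseline_phi) +
                       field$survival_anomaly[, sites$cell_id, drop = FALSE])
  prod_cell <- params$baseline_productivity *
    exp(field$productivity_anomaly[, sites$cell_id, drop = FALSE])

  rec <- vector("list", 2L * nrow(sites) * ny)
  truth <- vector("list", ny)
  k <- 0L
  next_ring <- 1L
  # per site: data frame of live adults (ring number NA until first capture)
  pops <- lapply(seq_len(nrow(sites)), function(s) {
    data.frame(ring = rep(NA_integer_, params$initial_adults_per_site),
               resident = NA)
  })
  extinct_year <- NA_integer_
  for (t in seq_len(ny)) {
    n_alive <- vapply(pops, nrow, 0L)
    if (all(n_alive == 0L)) { extinct_year <- t; break }
    truth[[t]] <- data.frame(
      cell_id = layout$cells$cell_id, year = years[t],
      true_phi = plogis(qlogis(params$baseline_phi) +
                          field$survival_anomaly[t, layout$cells$cell_id]),
      true_productivity = params$baseline_productivity *
        exp(field$productivity_anomaly[t, layout$cells$cell_id]),
      mean_adults = vapply(layout$cells$cell_id, function(cc) {
        mean(n_alive[sites$cell_id == cc])
      }, 0)
    )
    for (s in seq_len(nrow(sites))) {
      pop <- pops[[s]]
      n <- nrow(pop)
      if (n > 0L) {
        # seasonal capture: per-visit Bernoulli for each bird
        caught <- matrix(runif(n * nv) < p_visit, n, nv)
        any_caught <- rowSums(caught) > 0L
        newly <- any_caught & is.na(pop$ring)
        if (any(newly)) {
          nn <- sum(newly)
          pop$ring[newly] <- seq.int(next_ring, length.out = nn)
          next_ring <- next_ring + nn
          pop$resident[newly] <- runif(nn) < params$residency_prob
        }
        hit <- which(caught, arr.ind = TRUE)
        if (nrow(hit)) {
          k <- k + 1L
          rec[[k]] <- data.frame(
            site_id = sites$site_id[s], lat = sites$lat[s], lon = sites$lon[s],
            species = species, year = years[t], visit = hit[, 2L],
            ring_id = sprintf("R%06d", pop$ring[hit[, 1L]]), age = "A"
          )
        }
        # transients leave after the season of first capture
        pop <- pop[is.na(pop$resident) | pop$resident, , drop = FALSE]
      }
      # juveniles: captured, ringed, never tracked further
      nj <- rpois(1, n * prod_cell[t, s])
      if (nj > 0L) {
        jc <- matrix(runif(nj * nv) < p_visit, nj, nv)
        jhit <- which(jc, arr.ind = TRUE)
        if (nrow(jhit)) {
          jring <- next_ring + jhit[, 1L] - 1L
          k <- k + 1L
          rec[[k]] <- data.frame(
            site_id = sites$site_id[s], lat = sites$lat[s], lon = sites$lon[s],
            species = species, year = years[t], visit = jhit[, 2L],
            ring_id = sprintf("R%06d", jring), age = "J"
          )
        }
        next_ring <- next_ring + nj
      }
      # transition to next year
      if (t < ny) {
        n <- nrow(pop)
        surv <- runif(n) < phi_cell[t, s]
        recruits <- rpois(1, n * prod_cell[t, s] * params$baseline_phi)
        pop <- pop[surv, , drop = FALSE]
        if (recruits > 0L) {
          pop <- rbind(pop, data.frame(ring = rep(NA_integer_, recruits),
                                       resident = NA))
        }
        pops[[s]] <- pop
      }
    }
  }
  records <- do.call(rbind, rec[seq_len(k)])
  if (is.null(records)) {
    records <- data.frame(site_id = character(), lat = double(), lon = double(),
                          species = character(), year = integer(),
                          visit = integer(), ring_id = character(),
                          age = character())
  }
  rownames(records) <- NULL
  attr(records, "truth") <- do.call(rbind, truth)
  if (!is.na(extinct_year)) {
    warning("all populations extinct before the final year; output truncated at year index ",
            extinct_year)
    attr(records, "truncated") <- extinct_year
  }
  records
}

#' Read and write the capture-table CSV
#'
#' The on-disk schema is exactly `site_id, lat, lon, species, year, visit,
#' ring_id, age` with `age` in `{A, J}`. `write_truth()`/`read_truth()`
#' handle the per-cell-year true-rate sidecar produced by
#' [simulate_captures()] for recovery tests.
#'
#' @param records Capture data frame.
#' @param path File path.
#' @return `read_captures()` returns the capture data frame.
#' @export
write_captures <- function(records, path) {
  cols <- c("site_id", "lat", "lon", "species", "year", "visit", "ring_id", "age")
  stopifnot(all(cols %in% names(records)))
  write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_captures
#' @export
read_captures <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("site_id", "lat", "lon", "species", "year", "visit", "ring_id", "age")
  missing <- setdiff(cols, names(x))
  if (length(missing)) stop("capture CSV missing columns: ",
                            paste(missing, collapse = ", "))
  if (!all(x$age %in% c("A", "J"))) stop("age must be 'A' or 'J'")
  x[, cols]
}

#' @rdname write_captures
#' @param truth Truth sidecar data frame (attribute `truth` of a simulated
#'   capture table).
#' @export
write_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_captures
#' @export
read_truth <- function(path) read.csv(path, stringsAsFactors = FALSE)
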