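#' Summarise capture records by site and year
#'
#' Visit effort is inferred from the records: `n_visits` is the number of
#' distinct visit indices seen at the site-year (over all species), and the
#' two season halves split each site's observed visit-index range at its
#' midpoint (calendar dates are not modelled). Adult and juvenile counts
#' are distinct ringed individuals per site-year for the focal species.
#'
#' @param records Capture data frame (see [read_captures()]).
#' @param species Optional species code; counts are restricted to it while
#'   effort still uses all records.
#' @return Data frame with `site_id`, `year`, `n_visits`,
#'   `n_visits_first_half`, `n_visits_second_half`, `n_adults`,
#'   `n_juveniles`.
#' @export
summarize_site_years <- function(records, species = NULL) {
  stopifnot(nrow(records) > 0)
  mid <- tapply(records$visit, records$site_id,
                function(v) (min(v) + max(v)) / 2)
  key <- interaction(records$site_id, records$year, drop = TRUE)
  sp <- if (is.null(species)) records else records[records$species == species, ]
  spkey <- interaction(sp$site_id, sp$year, drop = TRUE)
  uv <- function(sub) length(unique(sub$visit))
  out <- do.call(rbind, lapply(split(records, key), function(sub) {
    m <- mid[[sub$site_id[1]]]
    data.frame(site_id = sub$site_id[1], year = sub$year[1],
               n_visits = uv(sub),
               n_visits_first_half = uv(sub[sub$visit <= m, ]),
               n_visits_second_half = uv(sub[sub$visit > m, ]))
  }))
  cnt <- do.call(rbind, lapply(split(sp, spkey), function(sub) {
    data.frame(site_id = sub$site_id[1], year = sub$year[1],
               n_adults = length(unique(sub$ring_id[sub$age == "A"])),
               n_juveniles = length(unique(sub$ring_id[sub$age == "J"])))
  }))
  out <- merge(out, cnt, by = c("site_id", "year"), all.x = TRUE)
  out$n_adults[is.na(out$n_adults)] <- 0L
  out$n_juveniles[is.na(out$n_juveniles)] <- 0L
  out[order(out$site_id, out$year), ]
}

#' Apply the constant-effort inclusion rules
#'
#' Retains site-years with at least `min_visits` visits including at least
#' `min_half_visits` in each half of the season, then sites with at least
#' `min_years` qualifying years. The adult threshold (`min_adults` adults
#' captured at the site in total, the minimum needed to estimate vital
#' rates) applies only to productivity/survival estimation, not to counts.
#'
#' @param records Capture data frame.
#' @param species Focal species code (default: the only species present).
#' @param min_visits,min_half_visits,min_years,min_adults Inclusion
#'   thresholds; defaults 7, 3, 5, 2.
#' @return List with `counts` (records at site-years usable for counts),
#'   `rates` (the subset also passing the adult rule, for
#'   productivity/survival), `summary` (retained site-year summary) and
#'   `exclusions` (one row per dropped site-year or site, with the violated
#'   rule named). If nothing survives, the data frames are empty — an
#'   explicit empty-output status, not an error.
#' @export
filter_site_years <- function(records, species = NULL, min_visits = 7,
                              min_half_visits = 3, min_years = 5,
                              min_adults = 2) {
  if (is.null(species)) {
    species <- unique(records$species)
    if (length(species) != 1) stop("multiple species present; pass `species`")
  }
  sy <- summarize_site_years(records, species)
  excl <- list()
  bad_visits <- sy$n_visits < min_visits
  bad_half <- !bad_visits & (sy$n_visits_first_half < min_half_visits |
                               sy$n_visits_second_half < min_half_visits)
  if (any(bad_visits)) {
    excl[[length(excl) + 1L]] <- data.frame(
      site_id = sy$site_id[bad_visits], year = sy$year[bad_visits],
      rule = sprintf("n_visits < %d", min_visits))
  }
  if (any(bad_half)) {
    excl[[length(excl) + 1L]] <- data.frame(
      site_id = sy$site_id[bad_half], year = sy$year[bad_half],
      rule = sprintf("fewer than %d visits in a season half", min_half_visits))
  }
  keep <- sy[!bad_visits & !bad_half, ]
  yrs <- table(keep$site_id)
  short <- names(yrs)[yrs < min_years]
  if (length(short)) {
    excl[[length(excl) + 1L]] <- data.frame(
      site_id = short, year = NA_integer_,
      rule = sprintf("site has fewer than %d qualifying years", min_years))
    keep <- keep[!keep$site_id %in% short, ]
  }
  ad <- tapply(keep$n_adults, keep$site_id, sum)
  few_adults <- names(ad)[ad < min_adults]
  if (length(few_adults)) {
    excl[[length(excl) + 1L]] <- data.frame(
      site_id = few_adults, year = NA_integer_,
      rule = sprintf("fewer than %d adults ever captured (rates only)", min_adults))
  }
  sel <- records$species == species &
    interaction(records$site_id, records$year, drop = FALSE) %in%
      interaction(keep$site_id, keep$year, drop = FALSE)
  counts <- records[sel, ]
  rates <- counts[!counts$site_id %in% few_adults, ]
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(site_id = character(), year = integer(), rule = character())
  rownames(exclusions) <- NULL
  list(counts = counts, rates = rates, summary = keep, exclusions = exclusions)
}
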