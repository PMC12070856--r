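#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius), the distance metric used for all cell-pair and site-cell
#' geometry in this package.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees. Vectorised.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 90) # quarter meridian, ~10007.5 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = 6371.0088)
}

# Inverse local equirectangular projection: km offsets from an origin to
# lat/lon. Longitude is scaled by the cosine at the point's own latitude,
# keeping haversine distances within ~1% of the planar km offsets over the
# few-hundred-km extents simulated here.
km_to_lonlat <- function(x_km, y_km, lat0 = 47, lon0 = 8) {
  lat <- lat0 + y_km / .KM_PER_DEG
  lon <- lon0 + x_km / (.KM_PER_DEG * cos(lat * pi / 180))
  data.frame(lat = lat, lon = lon)
}

#' Lay out a square-cell grid landscape with ringing sites
#'
#' Builds a regular grid of square cells of side `resolution_km` inside a
#' square extent, and scatters `sites_per_cell` ringing sites uniformly
#' inside each cell. Cells are filled row by row from the south-west corner
#' of the extent; site positions are jittered uniformly within their cell.
#' The layout is deterministic for a fixed `seed`.
#'
#' @param n_cells Number of grid cells (>= 2).
#' @param extent_km Side length of the square study extent, km.
#' @param resolution_km Cell side length, km (the analysis resolutions are
#'   25, 50 and 100 km).
#' @param sites_per_cell Number of sites placed in each cell.
#' @param seed Integer seed; the same arguments and seed give a
#'   byte-identical layout.
#' @param lat0,lon0 Geographic origin of the local projection (degrees).
#' @return A `grid_layout`: list with `resolution_km`, `cells` (data frame
#'   `cell_id`, `centroid_lat`, `centroid_lon`, local `x_km`, `y_km`) and
#'   `sites` (data frame `site_id`, `lat`, `lon`, `cell_id`).
#' @export
make_landscape <- function(n_cells, extent_km, resolution_km, sites_per_cell,
                           seed, lat0 = 47, lon0 = 8) {
  stopifnot(n_cells >= 2, resolution_km > 0, sites_per_cell >= 1)
  per_side <- floor(extent_km / resolution_km)
  if (per_side < 1 || per_side^2 < n_cells) {
    stop("cannot pack ", n_cells, " cells of side ", resolution_km,
         " km into a ", extent_km, " km extent")
  }
  set.seed(seed)
  idx <- seq_len(n_cells) - 1L
  col <- idx %% per_side
  row <- idx %/% per_side
  cx <- (col + 0.5) * resolution_km
  cy <- (row + 0.5) * resolution_km
  cll <- km_to_lonlat(cx, cy, lat0, lon0)
  cells <- data.frame(
    cell_id = sprintf("C%03d", idx + 1L),
    centroid_lat = cll$lat, centroid_lon = cll$lon,
    x_km = cx, y_km = cy, stringsAsFactors = FALSE
  )
  ns <- n_cells * sites_per_cell
  scell <- rep(seq_len(n_cells), each = sites_per_cell)
  sx <- cx[scell] + runif(ns, -0.5, 0.5) * resolution_km
  sy <- cy[scell] + runif(ns, -0.5, 0.5) * resolution_km
  sll <- km_to_lonlat(sx, sy, lat0, lon0)
  sites <- data.frame(
    site_id = sprintf("S%04d", seq_len(ns)),
    lat = sll$lat, lon = sll$lon,
    cell_id = cells$cell_id[scell], stringsAsFactors = FALSE
  )
  structure(
    list(resolution_km = resolution_km, cells = cells, sites = sites,
         extent_km = extent_km, seed = seed),
    class = "grid_layout"
  )
}

#' @export
print.grid_layout <- function(x, ...) {
  cat("grid_layout:", nrow(x$cells), "cells of side", x$resolution_km,
      "km,", nrow(x$sites), "sites\n")
  invisible(x)
}

#' Assign sites to grid cells at a chosen resolution
#'
#' Projects site coordinates onto a local equirectangular plane centred on
#' the data and snaps them to square cells of side `resolution_km`
#' (the supported analysis resolutions are 25, 50 and 100 km). This is how
#' an arbitrary capture table is gridded when no simulated layout exists.
#'
#' @param sites Data frame with `site_id`, `lat`, `lon` (one row per site).
#' @param resolution_km Cell side length in km.
#' @return List with `sites` (input plus `cell_id`) and `cells`
#'   (`cell_id`, `centroid_lat`, `centroid_lon`).
#' @export
assign_grid_cells <- function(sites, resolution_km) {
  stopifnot(all(c("site_id", "lat", "lon") %in% names(sites)),
            resolution_km > 0)
  lat0 <- mean(range(sites$lat))
  lon0 <- mean(range(sites$lon))
  y <- (sites$lat - lat0) * .KM_PER_DEG
  x <- (sites$lon - lon0) * .KM_PER_DEG * cos(sites$lat * pi / 180)
  ix <- floor(x / resolution_km)
  iy <- floor(y / resolution_km)
  cell_id <- sprintf("G%d_%d_%d", resolution_km, ix, iy)
  ux <- !duplicated(cell_id)
  ccx <- (ix[ux] + 0.5) * resolution_km
  ccy <- (iy[ux] + 0.5) * resolution_km
  clat <- lat0 + ccy / .KM_PER_DEG
  clon <- lon0 + ccx / (.KM_PER_DEG * cos(clat * pi / 180))
  cells <- data.frame(cell_id = cell_id[ux], centroid_lat = clat,
                      centroid_lon = clon, stringsAsFactors = FALSE)
  cells <- cells[order(cells$cell_id), ]
  rownames(cells) <- NULL
  sites$cell_id <- cell_id
  list(sites = sites, cells = cells)
}

#' Minimum distance of a set of occupied cells
#'
#' For each focal cell the maximum great-circle distance to any other cell
#' is found; the minimum of those maxima over focal cells is the
#' "minimum distance" used to normalise the scale of synchrony into a
#' relative scale. The literal two-step procedure is used, not a
#' diameter-based shortcut.
#'
#' @param cells Data frame with `centroid_lat` and `centroid_lon` (one row
#'   per occupied cell), or a `grid_layout`.
#' @return Minimum distance in km. Errors with fewer than 2 cells.
#' @export
minimum_distance <- function(cells) {
  if (inherits(cells, "grid_layout")) cells <- cells$cells
  n <- nrow(cells)
  if (n < 2) stop("minimum distance undefined for fewer than 2 cells")
  d <- cell_distance_matrix(cells)
  min(apply(d, 1, max))
}

# Symmetric haversine distance matrix between cell centroids.
cell_distance_matrix <- function(cells) {
  n <- nrow(cells)
  d <- matrix(0, n, n, dimnames = list(cells$cell_id, cells$cell_id))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- haversine_km(
      cells$centroid_lat[i], cells$centroid_lon[i],
      cells$centroid_lat[j], cells$centroid_lon[j]
    )
  }
  d
}
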