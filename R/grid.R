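# Grid, calendar and field containers shared by the model, the observation
# operator and the diagnostics. A 365-day (no-leap) calendar is used
# throughout.

#' Build a regular latitude-longitude grid
#'
#' Cell areas come from a spherical Earth (radius 6371 km):
#' `A = R^2 * dlon * (sin(lat + dlat/2) - sin(lat - dlat/2))`.
#'
#' @param n_lat,n_lon number of rows / columns.
#' @param lat_range,lon_range outer edges in degrees.
#' @return list with `lat`, `lon` (cell-centre vectors), and `cells`
#'   (data.frame: cell, lat, lon, area in m2); cells are ordered
#'   longitude-fastest.
#' @export
make_grid <- function(n_lat = 24, n_lon = 36, lat_range = c(-60, 80),
                      lon_range = c(-180, 180)) {
  dlat <- diff(lat_range) / n_lat
  dlon <- diff(lon_range) / n_lon
  lat <- lat_range[1] + dlat * (seq_len(n_lat) - 0.5)
  lon <- lon_range[1] + dlon * (seq_len(n_lon) - 0.5)
  Re <- 6371e3
  band_area <- Re^2 * (dlon * pi / 180) *
    (sin((lat + dlat / 2) * pi / 180) - sin((lat - dlat / 2) * pi / 180))
  cells <- data.frame(
    cell = seq_len(n_lat * n_lon),
    lat = rep(lat, each = n_lon),
    lon = rep(lon, times = n_lat),
    area = rep(band_area, each = n_lon))
  list(lat = lat, lon = lon, n_lat = n_lat, n_lon = n_lon,
       dlat = dlat, dlon = dlon, cells = cells)
}

#' Daily calendar for a run of whole years (365-day years)
#'
#' @param years integer vector of consecutive years.
#' @return data.frame with `year`, `doy` (1-365), `month` (1-12) and
#'   `month_id` (consecutive month counter across years).
#' @export
make_calendar <- function(years) {
  mlen <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  month_of_doy <- rep(seq_len(12), times = mlen)
  cal <- data.frame(year = rep(years, each = 365),
                    doy = rep(seq_len(365), times = length(years)))
  cal$month <- month_of_doy[cal$doy]
  cal$month_id <- match(paste(cal$year, cal$month),
                        unique(paste(cal$year, cal$month)))
  cal
}

#' Forcing container
#'
#' @param grid a grid from [make_grid()].
#' @param calendar a calendar from [make_calendar()].
#' @param tair,sw,sm matrices (n_cell x n_day): air temperature (degC),
#'   downward shortwave (W m-2), relative soil moisture (0-1).
#' @return object of class `sifda_forcing`.
#' @export
make_forcing <- function(grid, calendar, tair, sw, sm) {
  n_cell <- nrow(grid$cells); n_day <- nrow(calendar)
  stopifnot(identical(dim(tair), c(n_cell, n_day)),
            identical(dim(sw), c(n_cell, n_day)),
            identical(dim(sm), c(n_cell, n_day)))
  if (anyNA(tair) || anyNA(sw) || anyNA(sm))
    stop("forcing series must have no missing days")
  if (min(sm) < -1e-9 || max(sm) > 1 + 1e-9)
    stop("soil moisture must lie in [0, 1]")
  structure(list(grid = grid, calendar = calendar,
                 tair = tair, sw = sw, sm = sm),
            class = "sifda_forcing")
}

#' Subset a forcing object to a set of cells (and optionally days)
#' @param forcing a `sifda_forcing`.
#' @param cells integer cell indices.
#' @param days optional integer day indices.
#' @export
subset_forcing <- function(forcing, cells, days = NULL) {
  if (is.null(days)) days <- seq_len(nrow(forcing$calendar))
  g <- forcing$grid
  g$cells <- g$cells[cells, , drop = FALSE]
  make_forcing(g, forcing$calendar[days, , drop = FALSE],
               forcing$tair[cells, days, drop = FALSE],
               forcing$sw[cells, days, drop = FALSE],
               forcing$sm[cells, days, drop = FALSE])
}

#' PFT cover map container
#'
#' @param grid a grid from [make_grid()].
#' @param frac matrix (n_cell x 12) of PFT fractions, columns named by PFT
#'   index 2-13.
#' @param bare numeric vector of bare-soil fractions.
#' @return object of class `sifda_pft_map`. Fractions plus bare must sum to
#'   1 within 1e-9 in every cell.
#' @export
make_pft_map <- function(grid, frac, bare) {
  stopifnot(nrow(frac) == nrow(grid$cells), ncol(frac) == 12,
            length(bare) == nrow(grid$cells))
  if (min(frac) < -1e-12 || max(frac) > 1 + 1e-12 || min(bare) < -1e-12)
    stop("fractions must lie in [0, 1]")
  tot <- rowSums(frac) + bare
  if (any(abs(tot - 1) > 1e-9))
    stop("PFT fractions plus bare soil must sum to 1 in every cell")
  colnames(frac) <- as.character(2:13)
  structure(list(grid = grid, frac = frac, bare = bare),
            class = "sifda_pft_map")
}

#' SIF field container
#'
#' Monthly SIF (mW m-2 sr-1 nm-1) on a set of cells, with per-value
#' observation error and a missing-data mask.
#'
#' @param cells integer cell indices into the parent grid.
#' @param months data.frame with `year`, `month` (strictly increasing).
#' @param sif matrix (n_cell x n_month).
#' @param sigma per-value observation error (matrix or scalar, > 0 where
#'   data present).
#' @param mask logical matrix, TRUE where data present.
#' @param grid optional parent grid.
#' @return object of class `sifda_sif_field`.
#' @export
make_sif_field <- function(cells, months, sif, sigma, mask = NULL,
                           grid = NULL) {
  sif <- as.matrix(sif)
  if (length(sigma) == 1) sigma <- matrix(sigma, nrow(sif), ncol(sif))
  if (is.null(mask)) mask <- !is.na(sif)
  stopifnot(nrow(sif) == length(cells), ncol(sif) == nrow(months),
            identical(dim(sigma), dim(sif)), identical(dim(mask), dim(sif)))
  tkey <- months$year * 12 + months$month
  if (any(diff(tkey) <= 0)) stop("time axis must be strictly increasing")
  if (any(sigma[mask] <= 0)) stop("sigma must be > 0 where data present")
  structure(list(cells = cells, months = months, sif = sif,
                 sigma = sigma, mask = mask, grid = grid),
            class = "sifda_sif_field")
}
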