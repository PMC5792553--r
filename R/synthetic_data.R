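# Synthetic world for twin experiments: seasonally sinusoidal forcing with
# latitudinal gradients, latitudinally structured PFT cover with bare soil,
# a Koeppen-Geiger-style class map, truth parameters drawn around the prior,
# and noisy SIF pseudo-observations. Every generator is a pure function of
# (configuration, seed).

#' Generate daily meteorological forcing
#'
#' Air temperature: `T(t) = T_mean(lat) + A(lat) sin(2 pi (doy - phi)/365)`
#' plus AR(1) noise (`rho = 0.8`, `sd = 2` degC); mean decreases and
#' amplitude increases poleward; the seasonal phase is shifted half a year
#' in the southern hemisphere. Shortwave from a solar-geometry proxy
#' (daily-mean insolation from solar declination, no clouds). Soil moisture
#' is a smooth seasonal cycle in \[0, 1\], drier (with a pronounced dry
#' season) in the configured arid cells.
#'
#' @param grid a grid from [make_grid()].
#' @param years integer vector of years.
#' @param seed integer seed.
#' @param noise_sd AR(1) innovation standard deviation (degC; 0 gives the
#'   exact sinusoid).
#' @param ar1 AR(1) coefficient.
#' @param dry logical per-cell flag (default from
#'   [generate_pft_and_kg_maps()]'s convention: none); dry cells get a
#'   deeper moisture dry season.
#' @return a `sifda_forcing`.
#' @export
generate_forcing <- function(grid, years, seed = 1L, noise_sd = 2,
                             ar1 = 0.8, dry = NULL) {
  set.seed(seed)
  cal <- make_calendar(years)
  n_cell <- nrow(grid$cells)
  n_day <- nrow(cal)
  lat <- grid$cells$lat
  if (is.null(dry)) dry <- rep(FALSE, n_cell)

  t_mean <- 28 - 0.40 * abs(lat)
  t_amp <- 2 + 0.35 * abs(lat)
  doy <- cal$doy
  # northern-hemisphere peak around day 196; southern shifted half a year
  phase <- outer(ifelse(lat >= 0, 105, 105 + 182.5), rep(1, n_day))
  seas <- sin(2 * pi * (matrix(doy, n_cell, n_day, byrow = TRUE) - phase) / 365)
  tair <- t_mean + t_amp * seas
  if (noise_sd > 0) {
    eps <- matrix(rnorm(n_cell * n_day, sd = noise_sd), n_cell, n_day)
    noise <- matrix(0, n_cell, n_day)
    noise[, 1] <- eps[, 1] / sqrt(1 - ar1^2)
    for (t in 2:n_day) noise[, t] <- ar1 * noise[, t - 1] + eps[, t]
    tair <- tair + noise
  }

  # daily-mean top-of-atmosphere-style insolation from solar declination,
  # scaled by a clear-sky transmission of 0.55
  # daily-mean insolation proxy: S0/pi at overhead sun, clear-sky
  # transmission 0.55, falling with the latitude-declination offset
  decl <- 23.44 * sin(2 * pi * (doy - 81) / 365)
  sw <- (1361 / pi) * 0.55 * pmax(cos(outer(lat, decl, "-") * pi / 180), 0)

  # soil moisture: seasonal cycle peaking a month after midsummer rains;
  # arid cells sit lower with a deeper dry season
  w_mean <- ifelse(dry, 0.35, 0.55)
  w_amp <- ifelse(dry, 0.30, 0.25)
  wphase <- ifelse(lat >= 0, 135, 135 + 182.5)
  wseas <- sin(2 * pi * (matrix(doy, n_cell, n_day, byrow = TRUE) -
                           outer(wphase, rep(1, n_day))) / 365)
  sm <- pmin(pmax(w_mean + w_amp * wseas, 0), 1)

  make_forcing(grid, cal, tair, sw, sm)
}

#' Generate PFT cover and Koeppen-Geiger class maps
#'
#' Latitudinally structured cover: tropical PFTs dominate near the equator,
#' temperate at mid-latitudes, boreal poleward, with grasses/crops in
#' between and bare soil making the mosaic sum to 1. For every PFT except
#' boreal broadleaved deciduous (BoBD) at least `min_sites` cells carry a
#' dominant fraction > 0.6 (BoBD: > 0.2 — its cover never reaches 0.3).
#' KG classes by latitude and dryness: A for |lat| < 15 (unless dry),
#' B for dry cells, C for 15-45, D for 45-65, E beyond 65.
#'
#' @param grid a grid from [make_grid()].
#' @param seed integer seed.
#' @param min_sites guaranteed number of high-cover cells per PFT.
#' @param dominant_frac cover fraction of the dominant PFT (BoBD uses
#'   `bobd_frac`).
#' @param bobd_frac dominant fraction for BoBD.
#' @return list with `pft_map` (a `sifda_pft_map`), `kg` (a
#'   `sifda_kg_map`: per-cell class letter + group) and `dry` (logical).
#' @export
generate_pft_and_kg_maps <- function(grid, seed = 1L, min_sites = 15L,
                                     dominant_frac = 0.7, bobd_frac = 0.25) {
  set.seed(seed + 1L)
  cells <- grid$cells
  n_cell <- nrow(cells)
  alat <- abs(cells$lat)

  # dryness: two longitude windows inside the subtropics
  dry <- alat >= 15 & alat < 35 &
    (cells$lon >= -30 & cells$lon < 60 | cells$lon >= 120)

  band <- cut(alat, c(-0.1, 15, 30, 50, 65, 90),
              labels = c("tropical", "subtropical", "temperate",
                         "boreal", "polar"))
  band_pfts <- list(
    tropical = c(2, 3, 11, 13),
    subtropical = c(3, 11, 13, 5),
    temperate = c(4, 5, 6, 10, 12),
    boreal = c(7, 8, 9, 10),
    polar = c(9, 10))

  dominant <- integer(n_cell)
  for (b in names(band_pfts)) {
    idx <- which(band == b)
    # cycle the band's PFT list across its cells: guarantees an even, ample
    # number of dominant cells per PFT on the default grid
    dominant[idx] <- rep_len(band_pfts[[b]], length(idx))
  }

  frac <- matrix(0, n_cell, 12, dimnames = list(NULL, as.character(2:13)))
  bare <- numeric(n_cell)
  for (i in seq_len(n_cell)) {
    d <- dominant[i]
    fd <- if (d == 8) bobd_frac else dominant_frac
    others <- setdiff(band_pfts[[as.character(band[i])]], d)
    rest <- 1 - fd
    bare_i <- if (dry[i]) 0.45 * rest else 0.15 * rest
    veg_rest <- rest - bare_i
    frac[i, as.character(d)] <- fd
    frac[i, as.character(others)] <- veg_rest / length(others)
    bare[i] <- bare_i
  }

  thr <- ifelse(as.integer(colnames(frac)) == 8, 0.2, 0.6)
  counts <- sapply(seq_len(12), function(j) sum(frac[, j] > thr[j]))
  if (any(counts < min_sites))
    stop("grid too small to guarantee ", min_sites,
         " high-cover cells per PFT; need a larger grid (deficient PFTs: ",
         paste(colnames(frac)[counts < min_sites], collapse = ", "), ")")

  kg_class <- ifelse(dry, "B",
              ifelse(alat < 15, "A",
              ifelse(alat < 45, "C",
              ifelse(alat < 65, "D", "E"))))
  kg <- structure(list(cells = cells$cell, class = kg_class,
                       group = kg_group(kg_class)$group,
                       grid = grid),
                  class = "sifda_kg_map")
  list(pft_map = make_pft_map(grid, frac, bare), kg = kg, dry = dry)
}

#' Draw truth parameters around the prior
#'
#' `truth_i = clip(x_b_i + perturbation * sigma_i * z_i, bounds)` with
#' standard-normal `z`; perturbation 0 returns the prior exactly.
#'
#' @param table parameter table.
#' @param perturbation fraction of the prior sigma (>= 0).
#' @param seed integer seed.
#' @return a `sifda_parameter_vector` whose `values` are the truth.
#' @export
make_truth_scenario <- function(table = default_parameter_table(),
                                perturbation = 0.5, seed = 1L) {
  stopifnot(perturbation >= 0)
  set.seed(seed + 2L)
  vec <- build_prior(build_parameter_vector(table))
  z <- rnorm(length(vec$values))
  vec$values <- pmin(vec$upper,
                     pmax(vec$lower,
                          vec$prior + perturbation * vec$prior_sigma * z))
  vec
}

#' Generate noisy SIF pseudo-observations
#'
#' Runs the surrogate model and the SIF operator with the truth parameters
#' and adds independent Gaussian noise per (cell, month); the noise sd is
#' recorded as the field's observation error.
#'
#' @param truth a `sifda_parameter_vector` (values within bounds).
#' @param forcing,pft_map model inputs.
#' @param noise_sd observation noise standard deviation (SIF units); if
#'   `NULL`, set to `noise_frac` of the clean-signal range.
#' @param noise_frac fraction of the signal range used when `noise_sd` is
#'   NULL (default 0.05).
#' @param seed integer seed.
#' @param cells optional cell subset.
#' @param config surrogate constants.
#' @return a `sifda_sif_field`; `attr(, "noise_sd")` records the sd used,
#'   `attr(, "clean")` the noise-free signal.
#' @export
make_observations <- function(truth, forcing, pft_map, noise_sd = NULL,
                              noise_frac = 0.05, seed = 1L, cells = NULL,
                              config = surrogate_config()) {
  if (is.null(cells)) cells <- seq_len(nrow(forcing$grid$cells))
  sub_forc <- subset_forcing(forcing, cells)
  sub_map <- pft_map
  sub_map$frac <- pft_map$frac[cells, , drop = FALSE]
  sub_map$bare <- pft_map$bare[cells]
  sub_map$grid <- sub_forc$grid
  fwd <- make_forward_model(truth, sub_forc, sub_map, config)
  clean <- matrix(fwd(truth$values), nrow = length(cells))
  if (is.null(noise_sd))
    noise_sd <- noise_frac * (max(clean) - min(clean))
  set.seed(seed + 3L)
  noisy <- clean + if (noise_sd > 0)
    matrix(rnorm(length(clean), sd = noise_sd), nrow = nrow(clean))
  else 0
  field <- make_sif_field(forcing$grid$cells$cell[cells],
                          attr(fwd, "months"), noisy,
                          sigma = max(noise_sd, 1e-12),
                          grid = forcing$grid)
  attr(field, "noise_sd") <- noise_sd
  attr(field, "clean") <- clean
  field
}

#' Build a complete twin-experiment scenario
#'
#' Desk-scale default: a 24 x 36 grid over 5 years (the length of the
#' satellite window emulated), truth drawn at `perturbation` prior sigmas,
#' site selection per PFT, and noisy pseudo-observations at the site cells.
#'
#' @param n_lat,n_lon grid size.
#' @param years integer vector of years (default 2007-2011).
#' @param seed master seed; all internal draws derive from it.
#' @param perturbation truth displacement in prior sigmas.
#' @param noise_frac observation noise as a fraction of the clean signal
#'   range (0 for a noise-free twin).
#' @param n_sites sites per PFT.
#' @param table parameter table.
#' @param config surrogate constants.
#' @return list with `grid`, `forcing`, `pft_map`, `kg`, `truth`, `sites`,
#'   `observations`, `noise_sd`, `seed`.
#' @export
make_scenario <- function(n_lat = 24, n_lon = 36, years = 2007:2011,
                          seed = 1L, perturbation = 0.5, noise_frac = 0.05,
                          n_sites = 15L, table = default_parameter_table(),
                          config = surrogate_config()) {
  grid <- make_grid(n_lat, n_lon)
  maps <- generate_pft_and_kg_maps(grid, seed = seed, min_sites = n_sites)
  forcing <- generate_forcing(grid, years, seed = seed, dry = maps$dry)
  truth <- make_truth_scenario(table, perturbation, seed = seed)
  sites <- do.call(rbind, lapply(table$pfts$index, function(p)
    select_sites(maps$pft_map, p, n = n_sites,
                 threshold = if (p == 8) 0.2 else 0.6,
                 seed = seed + 10L + p)))
  obs <- make_observations(truth, forcing, maps$pft_map,
                           noise_frac = noise_frac, seed = seed,
                           cells = sort(unique(sites$cell)),
                           config = config)
  list(grid = grid, forcing = forcing, pft_map = maps$pft_map,
       kg = maps$kg, dry = maps$dry, truth = truth, sites = sites,
       observations = obs, noise_sd = attr(obs, "noise_sd"), seed = seed)
}
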