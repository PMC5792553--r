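# Shared fixtures: all tiny, built in code at test time.

# constant-forcing object: n cells, whole years, fixed T/R/W
constant_forcing <- function(n_cell = 1, years = 2007, T = 25, R = 100,
                             W = 1, lat = 45) {
  grid <- make_grid(n_lat = max(1, n_cell), n_lon = 1,
                    lat_range = c(lat - 5, lat + 5))
  grid$cells <- grid$cells[seq_len(n_cell), , drop = FALSE]
  grid$cells$lat <- rep(lat, n_cell)
  cal <- make_calendar(years)
  n_day <- nrow(cal)
  make_forcing(grid, cal,
               matrix(T, n_cell, n_day), matrix(R, n_cell, n_day),
               matrix(W, n_cell, n_day))
}

# strongly seasonal single-cell forcing (northern mid-latitudes)
seasonal_forcing <- function(years = 2007, lat = 55, n_cell = 1) {
  grid <- make_grid(n_lat = 1, n_lon = n_cell,
                    lat_range = c(lat - 5, lat + 5))
  grid$cells$lat <- lat
  cal <- make_calendar(years)
  doy <- cal$doy
  T <- 5 + 18 * sin(2 * pi * (doy - 105) / 365)
  R <- pmax(150 + 120 * sin(2 * pi * (doy - 105) / 365), 10)
  W <- rep(0.8, length(doy))
  make_forcing(grid, cal,
               matrix(T, n_cell, length(doy), byrow = TRUE),
               matrix(R, n_cell, length(doy), byrow = TRUE),
               matrix(W, n_cell, length(doy), byrow = TRUE))
}

# small complete parameter list for one PFT
test_params <- function(...) {
  p <- list(vcmax = 40, gs_slope = 9, t_opt = 25, t_min = 0, t_max = 45,
            f_stress_h = 1, sla = 0.015, lai_max = 5, k_lai_happy = 0.5,
            k_pheno_crit = 1, m_tmin = 30, l_age_crit = 180, t_senes = 7,
            m_senes_nosenes = 0.3, l_fall = 0.1)
  mods <- list(...)
  p[names(mods)] <- mods
  p
}

# small shared twin scenario (cached per test run)
tiny_scenario <- local({
  cache <- NULL
  function(seed = 1, ...) {
    if (is.null(cache))
      cache <<- make_scenario(n_lat = 12, n_lon = 18, years = 2007:2008,
                              seed = seed, n_sites = 3, ...)
    cache
  }
})

# hand-enumerated applicability of the 17 parameters (independent of the
# package's own pft_list parsing)
manual_applicability <- function() {
  all12 <- 2:13
  list(vcmax = all12, gs_slope = all12, t_opt = all12, t_min = all12,
       t_max = all12, f_stress_h = all12, sla = all12, lai_max = all12,
       k_lai_happy = all12, k_pheno_crit = c(6, 8:13),
       m_tmin = c(3, 10:13), l_age_crit = all12, t_senes = c(6, 8:13),
       m_senes_nosenes = c(3, 10:13), l_fall = c(3, 6, 8, 9),
       sif_a = all12, sif_b = all12)
}
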