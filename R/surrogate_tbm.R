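# Surrogate terrestrial biosphere model: daily GPP per PFT per grid cell
# with a prognostic LAI phenology. This is an explicitly documented stand-in
# for a full process model — its parameters carry the optimisation table's
# names, units and roles so the assimilation machinery is exercised
# faithfully, but the process equations are deliberately simple (tent
# temperature response, Beer-Lambert canopy, saturating light response,
# supply/demand co-limitation).

#' Photosynthesis rate modifiers
#'
#' Dimensionless multipliers in \[0, 1\] applied to the maximum carboxylation
#' rate: a piecewise-linear (tent) temperature response peaking at `t_opt`,
#' a linear soil-moisture stress `clip(1 - f_stress_h (1 - W), 0, 1)`, a
#' saturating light response `R / (R + R_half)` and a Beer-Lambert canopy
#' absorption `1 - exp(-k_ext lai)`.
#'
#' @param T air temperature (degC); vectorised.
#' @param t_min,t_opt,t_max tent-function temperature limits (degC),
#'   `t_min < t_opt < t_max`.
#' @return numeric in \[0, 1\].
#' @export
temperature_response <- function(T, t_min, t_opt, t_max) {
  if (!(t_min < t_opt && t_opt < t_max))
    stop("temperature response requires t_min < t_opt < t_max")
  up <- (T - t_min) / (t_opt - t_min)
  down <- (t_max - T) / (t_max - t_opt)
  pmax(0, pmin(up, down, 1))
}

#' @rdname temperature_response
#' @param W relative soil moisture in \[0, 1\].
#' @param f_stress_h hydric-stress parameter (>= 0); 0 removes the
#'   limitation entirely.
#' @export
water_stress <- function(W, f_stress_h) {
  if (any(W < 0 | W > 1)) stop("soil moisture must lie in [0, 1]")
  if (any(f_stress_h < 0)) stop("f_stress_h must be >= 0")
  pmax(0, pmin(1, 1 - f_stress_h * (1 - W)))
}

#' @rdname temperature_response
#' @param R downward shortwave flux (W m-2, >= 0).
#' @param R_half half-saturation flux (W m-2, > 0).
#' @export
light_response <- function(R, R_half = 100) {
  if (any(R < 0)) stop("shortwave flux must be >= 0")
  if (any(R_half <= 0)) stop("R_half must be > 0")
  R / (R + R_half)
}

#' @rdname temperature_response
#' @param lai leaf area index (m2 m-2, >= 0).
#' @param k_ext extinction coefficient.
#' @export
canopy_absorption <- function(lai, k_ext = 0.5) {
  1 - exp(-k_ext * lai)
}

#' Daily GPP for one PFT
#'
#' Demand/supply co-limitation:
#' `A_c = c_day * vcmax * f_T * f_R * f_L * f_age` (carboxylation-limited,
#' with `f_age = max(0, 1 - mean_leaf_age / (2 l_age_crit))`) and
#' `A_w = g0 * gs_slope * W * f_L` (stomatal-supply-limited);
#' `GPP = min(A_c, A_w) * f_W`.
#'
#' @param params named list for one PFT (see [pft_params()]); missing
#'   non-applicable entries are filled by [complete_pft_params()].
#' @param T,R,W daily air temperature (degC), shortwave (W m-2), relative
#'   soil moisture.
#' @param lai leaf area index (m2 m-2).
#' @param mean_leaf_age mean leaf age (days).
#' @param config surrogate constants ([surrogate_config()]).
#' @return GPP in gC m-2 day-1 (vectorised over forcing/state).
#' @export
daily_gpp <- function(params, T, R, W, lai, mean_leaf_age = 0,
                      config = surrogate_config()) {
  p <- complete_pft_params(params, config)
  f_T <- temperature_response(T, p$t_min, p$t_opt, p$t_max)
  f_W <- water_stress(W, p$f_stress_h)
  f_R <- light_response(R, config$R_half)
  f_L <- canopy_absorption(lai, config$k_ext)
  f_age <- pmax(0, 1 - mean_leaf_age / (2 * p$l_age_crit))
  A_c <- config$c_day * p$vcmax * f_T * f_R * f_L * f_age
  A_w <- config$g0 * p$gs_slope * W * f_L
  pmin(A_c, A_w) * f_W
}

#' Fill non-applicable parameters with fixed defaults
#'
#' The kernel needs every parameter name; PFTs to which a phenology
#' parameter does not apply receive a fixed default (the table prior, or
#' `l_fall_default` for the leaf-fall rate) that their phenology pathway
#' never reads.
#' @param params named list of the PFT's applicable parameters.
#' @param config surrogate constants.
#' @return complete named list.
#' @export
complete_pft_params <- function(params, config = surrogate_config()) {
  defaults <- list(vcmax = 50, gs_slope = 9, t_opt = 25, t_min = 0,
                   t_max = 45, f_stress_h = 1, sla = 0.015, lai_max = 5,
                   k_lai_happy = 0.5, k_pheno_crit = 1, m_tmin = 30,
                   l_age_crit = 180, t_senes = 7, m_senes_nosenes = 0.3,
                   l_fall = config$l_fall_default)
  defaults[names(params)] <- params
  defaults
}

#' Fresh phenology state for n cells
#'
#' @param n number of cells.
#' @param lai,mean_leaf_age,phase optional initial values (recycled).
#' @return list of per-cell state vectors: `lai`, `mean_leaf_age`, `gdd`,
#'   `days_since_moisture_min`, `wmin`, `phase` (0 dormant, 1 growth,
#'   2 mature, 3 senescent), `reserve_flag`, `onset_done`, `days_in_phase`.
#' @export
new_pheno_state <- function(n, lai = 0, mean_leaf_age = 0, phase = 0L) {
  list(lai = rep(lai, length.out = n),
       mean_leaf_age = rep(mean_leaf_age, length.out = n),
       gdd = rep(0, n), days_since_moisture_min = rep(0, n),
       wmin = rep(1, n), phase = rep(as.integer(phase), length.out = n),
       reserve_flag = rep(FALSE, n), onset_done = rep(FALSE, n),
       days_in_phase = rep(0L, n))
}

pft_traits <- function(pft, pft_table = default_pft_table()) {
  row <- pft_table[pft_table$index == pft, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown PFT index: ", pft)
  list(evergreen = row$evergreen, trig_temp = row$trig_temp,
       trig_moist = row$trig_moist)
}

# low-level: run the kernel for one PFT over given cells/days
run_pft <- function(params, traits, forcing, state, config, keep_lai = FALSE) {
  .sim_pft_core(forcing$tair, forcing$sw, forcing$sm,
                as.integer(forcing$calendar$doy), forcing$grid$cells$lat,
                complete_pft_params(params, config), traits, config, state,
                keep_lai)
}

#' Advance the phenology state by one day
#'
#' Single-day wrapper around the simulation kernel (the same code path used
#' by [simulate_gpp()]): leaf onset by growing-degree-day or
#' moisture-recovery triggers, LAI growth with a reserve phase, senescence
#' by 7-day temperature/moisture thresholds, exponential leaf fall, and an
#' age-turnover pathway for evergreens.
#'
#' @param state state from [new_pheno_state()] (or a previous step).
#' @param day list with `T`, `R`, `W`, `doy`, `lat` (each length n or 1).
#' @param params named list of the PFT's parameters.
#' @param traits list with `evergreen`, `trig_temp`, `trig_moist` (or a PFT
#'   index, resolved via the default PFT table).
#' @param config surrogate constants.
#' @return list with `state` (advanced) and `gpp` (that day's GPP,
#'   gC m-2 day-1).
#' @export
step_phenology <- function(state, day, params, traits,
                           config = surrogate_config()) {
  if (is.numeric(traits)) traits <- pft_traits(traits)
  n <- length(state$lai)
  grid <- list(cells = data.frame(lat = rep(day$lat, length.out = n)))
  forcing <- list(tair = matrix(rep(day$T, length.out = n), n, 1),
                  sw = matrix(rep(day$R, length.out = n), n, 1),
                  sm = matrix(rep(day$W, length.out = n), n, 1),
                  calendar = data.frame(doy = day$doy), grid = grid)
  out <- run_pft(params, traits, forcing, state, config)
  list(state = out$state, gpp = as.numeric(out$gpp))
}

#' Spin up the vegetation state to equilibrium
#'
#' Cycles the first full year of the forcing until the maximum absolute
#' year-over-year difference of the daily LAI trajectory falls below
#' `config$spinup_tol`, or `config$spinup_max_cycles` cycles are reached
#' (then a warning is issued and the state returned with
#' `attr(, "converged") = FALSE`).
#'
#' @param params named list of one PFT's parameters.
#' @param forcing a `sifda_forcing` covering at least one full year.
#' @param traits PFT traits (or PFT index).
#' @param config surrogate constants.
#' @param state optional starting state.
#' @return equilibrated state with attributes `converged` and `cycles`.
#' @export
spin_up <- function(params, forcing, traits, config = surrogate_config(),
                    state = NULL) {
  if (is.numeric(traits)) traits <- pft_traits(traits)
  if (nrow(forcing$calendar) < 365)
    stop("spin-up forcing must cover at least one full year")
  year1 <- subset_forcing(forcing, seq_len(nrow(forcing$grid$cells)),
                          seq_len(365))
  n <- nrow(year1$grid$cells)
  if (is.null(state)) state <- new_pheno_state(n)
  prev_lai <- NULL
  prev2_lai <- NULL
  converged <- FALSE
  cycles <- 0L
  for (cyc in seq_len(config$spinup_max_cycles)) {
    out <- run_pft(params, traits, year1, state, config, keep_lai = TRUE)
    state <- out$state
    cycles <- cyc
    # equilibrium, or a period-2 limit cycle (possible when the growth
    # rate halves exactly at the reserve threshold): either is a valid
    # attractor of the annual map
    if ((!is.null(prev_lai) &&
         max(abs(out$lai - prev_lai)) < config$spinup_tol) ||
        (!is.null(prev2_lai) &&
         max(abs(out$lai - prev2_lai)) < config$spinup_tol)) {
      converged <- TRUE
      break
    }
    prev2_lai <- prev_lai
    prev_lai <- out$lai
  }
  if (!converged)
    warning("spin-up did not converge within ", config$spinup_max_cycles,
            " cycles")
  attr(state, "converged") <- converged
  attr(state, "cycles") <- cycles
  state
}

#' Simulate daily GPP for all PFTs on a grid
#'
#' Runs the surrogate model per PFT over all cells where the PFT's cover
#' fraction exceeds `config$frac_min`, after an internal spin-up on the
#' first forcing year. Deterministic given inputs.
#'
#' @param vector a `sifda_parameter_vector` (values must lie within bounds).
#' @param forcing a `sifda_forcing`.
#' @param pft_map a `sifda_pft_map` on the same grid.
#' @param config surrogate constants.
#' @param values optional replacement parameter values.
#' @param daily_pft if TRUE, keep the full daily per-PFT GPP matrices
#'   (memory-heavy; default FALSE keeps monthly per-PFT means plus the
#'   daily fraction-weighted aggregate).
#' @param spinup run the spin-up (default TRUE).
#' @return object of class `sifda_gpp_field`: list with `monthly_pft`
#'   (array n_cell x n_month x 12, monthly-mean GPP in gC m-2 day-1 per
#'   PFT), `daily_agg` (matrix n_cell x n_day, fraction-weighted cell GPP),
#'   `months`, `calendar`, `grid`, `pft_map` and optionally `daily_pft`.
#' @export
simulate_gpp <- function(vector, forcing, pft_map,
                         config = surrogate_config(),
                         values = vector$values, daily_pft = FALSE,
                         spinup = TRUE) {
  stopifnot(inherits(vector, "sifda_parameter_vector"))
  if (any(values < vector$lower - 1e-12) ||
      any(values > vector$upper + 1e-12))
    stop("parameter values outside bounds")
  n_cell <- nrow(forcing$grid$cells)
  n_day <- nrow(forcing$calendar)
  stopifnot(nrow(pft_map$frac) == n_cell)
  cal <- forcing$calendar
  mid <- cal$month_id
  months <- unique(cal[, c("year", "month")])
  n_month <- nrow(months)
  mlen <- as.numeric(table(mid))

  monthly_pft <- array(0, dim = c(n_cell, n_month, 12),
                       dimnames = list(NULL, NULL, as.character(2:13)))
  daily_agg <- matrix(0, n_cell, n_day)
  daily_list <- if (daily_pft) rep(list(NULL), 12) else NULL

  pfts_here <- sort(unique(vector$index$pft))
  for (pft in pfts_here) {
    frac <- pft_map$frac[, as.character(pft)]
    use <- which(frac > config$frac_min)
    if (!length(use)) next
    params <- pft_params(vector, pft, values)
    traits <- pft_traits(pft, vector$pfts)
    sub <- subset_forcing(forcing, use)
    state <- if (spinup) spin_up(params, sub, traits, config)
             else new_pheno_state(length(use))
    out <- run_pft(params, traits, sub, state, config)
    gpp <- out$gpp                       # n_use x n_day
    # monthly means: rowsum over month id on the transposed matrix
    msum <- t(rowsum(t(gpp), mid, reorder = FALSE))
    monthly_pft[use, , as.character(pft)] <-
      sweep(msum, 2, mlen, "/")
    daily_agg[use, ] <- daily_agg[use, ] + frac[use] * gpp
    if (daily_pft) {
      full <- matrix(0, n_cell, n_day)
      full[use, ] <- gpp
      daily_list[[pft - 1L]] <- full
    }
  }
  structure(list(monthly_pft = monthly_pft, daily_agg = daily_agg,
                 months = months, calendar = cal, grid = forcing$grid,
                 pft_map = pft_map, daily_pft = daily_list),
            class = "sifda_gpp_field")
}
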