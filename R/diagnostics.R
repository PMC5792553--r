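# Site selection, Koeppen-Geiger biome aggregation, and results-style
# diagnostics: carbon budgets, productivity ratios, seasonal cycles,
# latitudinal profiles, SIF-GPP correlations, uncertainty summaries.

#' Group a Koeppen-Geiger main class into analysis biomes
#'
#' A -> tropical, B -> arid, C/D/E -> temperate+boreal; D and E form the
#' boreal sub-group.
#'
#' @param class character vector of KG main classes ("A".."E").
#' @return list with `group` (character) and `boreal` (logical).
#' @export
kg_group <- function(class) {
  if (!all(class %in% c("A", "B", "C", "D", "E")))
    stop("unknown Koeppen-Geiger class: ",
         paste(setdiff(class, c("A", "B", "C", "D", "E")), collapse = ", "))
  group <- c(A = "tropical", B = "arid", C = "temperate+boreal",
             D = "temperate+boreal", E = "temperate+boreal")[class]
  list(group = unname(group), boreal = class %in% c("D", "E"))
}

#' Select optimisation sites for one PFT
#'
#' A seeded uniform random sample of at most `n` distinct cells whose PFT
#' cover fraction exceeds `threshold`, stratified over latitude terciles of
#' the eligible cells so the sites represent the PFT's spatial
#' distribution.
#'
#' @param pft_map a `sifda_pft_map`.
#' @param pft PFT index (2-13).
#' @param n maximum number of sites (default 15).
#' @param threshold cover-fraction threshold (default 0.6; use 0.2 for
#'   BoBD, whose cover never exceeds 0.3).
#' @param seed integer seed.
#' @return data.frame with `cell`, `pft`, `fraction`, `lat`, `lon` (empty,
#'   with a warning, if no cell is eligible).
#' @export
select_sites <- function(pft_map, pft, n = 15L, threshold = 0.6, seed = 1L) {
  stopifnot(n >= 1)
  frac <- pft_map$frac[, as.character(pft)]
  elig <- which(frac > threshold)
  if (!length(elig)) {
    warning("no eligible cells for PFT ", pft, " at threshold ", threshold)
    return(data.frame(cell = integer(0), pft = integer(0),
                      fraction = numeric(0), lat = numeric(0),
                      lon = numeric(0)))
  }
  set.seed(seed)
  lat <- pft_map$grid$cells$lat[elig]
  terc <- cut(rank(lat, ties.method = "first"),
              breaks = 3, labels = FALSE)
  per <- diff(round(seq(0, n, length.out = 4)))  # n split across terciles
  pick <- integer(0)
  for (k in 1:3) {
    pool <- elig[terc == k]
    pick <- c(pick, sample(pool, min(length(pool), per[k])))
  }
  # top up from the remaining pool if a tercile was short
  short <- n - length(pick)
  if (short > 0) {
    pool <- setdiff(elig, pick)
    pick <- c(pick, sample(pool, min(length(pool), short)))
  }
  pick <- sort(pick)
  data.frame(cell = pft_map$grid$cells$cell[pick], pft = pft,
             fraction = frac[pick], lat = pft_map$grid$cells$lat[pick],
             lon = pft_map$grid$cells$lon[pick])
}

#' Annual carbon budget of a region
#'
#' `sum_cells gpp * area / 1e15` PgC yr-1 (1 Pg = 1e15 g), averaged over
#' the analysis years.
#'
#' @param annual matrix (n_cell x n_year) of annual GPP in gC m-2 yr-1
#'   (daily values summed within each year), or a vector for one year.
#' @param area cell areas (m2).
#' @param mask logical region mask (default all cells).
#' @return mean annual total in PgC yr-1.
#' @export
annual_budget <- function(annual, area, mask = NULL) {
  annual <- as.matrix(annual)
  if (is.null(mask)) mask <- rep(TRUE, nrow(annual))
  mean(colSums(annual[mask, , drop = FALSE] * area[mask]) / 1e15)
}

#' Annual per-cell GPP totals from a simulated field
#'
#' @param gpp_field a `sifda_gpp_field`.
#' @return matrix (n_cell x n_year) of gC m-2 yr-1.
#' @export
annual_gpp <- function(gpp_field) {
  yr <- gpp_field$calendar$year
  t(rowsum(t(gpp_field$daily_agg), yr, reorder = TRUE))
}

#' Prior/posterior productivity metrics
#'
#' Differences and productivity ratios between biome budgets:
#' tropical:(temperate+boreal) and tropical:boreal, with relative ratio
#' changes; a zero denominator masks the metric (NA).
#'
#' @param prior,posterior named numeric vectors of budgets (PgC yr-1) with
#'   at least `global`, `tropical`, `temperate+boreal` and optionally
#'   `boreal`.
#' @return list with `difference` (prior - posterior per region),
#'   `ratio_prior`, `ratio_post` (each with `trop_tempboreal`,
#'   `trop_boreal`), and `ratio_change` (relative).
#' @export
productivity_metrics <- function(prior, posterior) {
  if (!setequal(names(prior), names(posterior)))
    stop("prior and posterior budgets must cover the same regions")
  posterior <- posterior[names(prior)]
  safe_ratio <- function(a, b) if (!is.na(b) && b != 0) a / b else NA_real_
  ratios <- function(b) c(
    trop_tempboreal = safe_ratio(b[["tropical"]], b[["temperate+boreal"]]),
    trop_boreal = if ("boreal" %in% names(b))
      safe_ratio(b[["tropical"]], b[["boreal"]]) else NA_real_)
  rp <- ratios(prior); rq <- ratios(posterior)
  list(difference = prior - posterior,
       ratio_prior = rp, ratio_post = rq,
       ratio_change = (rq - rp) / rp)
}

#' Mean seasonal cycle of a region's monthly totals
#'
#' Per-calendar-month mean of the region-integrated monthly GPP
#' (PgC month-1) over whole years.
#'
#' @param gpp_field a `sifda_gpp_field`.
#' @param area cell areas (m2).
#' @param mask logical region mask.
#' @return numeric vector of length 12 (PgC month-1).
#' @export
seasonal_cycle <- function(gpp_field, area = gpp_field$grid$cells$area,
                           mask = NULL) {
  cal <- gpp_field$calendar
  if (nrow(cal) %% 365 != 0)
    stop("seasonal cycle requires whole years of daily data")
  if (is.null(mask)) mask <- rep(TRUE, nrow(gpp_field$daily_agg))
  # region-integrated daily totals (gC day-1) -> monthly totals -> PgC
  daily_tot <- colSums(gpp_field$daily_agg[mask, , drop = FALSE] *
                         area[mask])
  monthly_tot <- rowsum(daily_tot, cal$month_id, reorder = FALSE) / 1e15
  month_of <- cal$month[!duplicated(cal$month_id)]
  as.numeric(tapply(monthly_tot, month_of, mean))
}

#' Area-weighted latitudinal profile of annual GPP
#'
#' @param annual_mean per-cell mean annual GPP (gC m-2 yr-1).
#' @param grid the grid.
#' @param mask logical cell mask.
#' @return data.frame with `lat` and `gpp` (kgC m-2 yr-1).
#' @export
latitudinal_profile <- function(annual_mean, grid, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(annual_mean))
  lat <- grid$cells$lat
  area <- grid$cells$area
  w <- area * mask
  num <- rowsum(annual_mean * w, lat)
  den <- rowsum(w, lat)
  data.frame(lat = as.numeric(rownames(num)),
             gpp = ifelse(den > 0, num / den, NA_real_) / 1000)
}

#' Per-cell monthly SIF-GPP Pearson correlation
#'
#' Pearson r over all months per cell; constant series are excluded (and
#' counted) rather than propagated as NaN.
#'
#' @param sif matrix (n_cell x n_month).
#' @param gpp_monthly matrix (n_cell x n_month), aligned time axis.
#' @param mask logical region mask over cells.
#' @return list with `r` (per-cell, NA where undefined), `mean` (region
#'   mean over defined cells) and `n_excluded`.
#' @export
monthly_correlation <- function(sif, gpp_monthly, mask = NULL) {
  if (!identical(dim(sif), dim(gpp_monthly)))
    stop("SIF and GPP monthly fields are misaligned")
  if (is.null(mask)) mask <- rep(TRUE, nrow(sif))
  r <- rep(NA_real_, nrow(sif))
  for (i in which(mask)) {
    ok <- is.finite(sif[i, ]) & is.finite(gpp_monthly[i, ])
    if (sum(ok) >= 3 && sd(sif[i, ok]) > 0 && sd(gpp_monthly[i, ok]) > 0)
      r[i] <- cor(sif[i, ok], gpp_monthly[i, ok])
  }
  list(r = r, mean = mean(r[mask], na.rm = TRUE),
       n_excluded = sum(mask & is.na(r)))
}

#' Uncertainty maps and parameter summary
#'
#' Per-cell state error reduction (averaged over months) and the
#' per-(parameter, PFT) table of prior/posterior values, % sigma reduction
#' and at-bound flags, plus the headline counts.
#'
#' @param result a `sifda_posterior` from [assimilate()].
#' @return list with `param_table` (data.frame), `cell_reduction`
#'   (data.frame cell, reduction), `n_over_50` (parameters with > 50%
#'   sigma reduction) and `n_edge` (edge-hitting count).
#' @export
uncertainty_maps_and_param_summary <- function(result) {
  stopifnot(inherits(result, "sifda_posterior"))
  pt <- data.frame(
    param = result$index$param, pft = result$index$pft,
    prior = result$prior$prior, posterior = result$x_post,
    prior_sigma = result$prior$prior_sigma,
    post_sigma = result$prior$prior_sigma *
      sqrt(pmax(diag(result$P_post_std), 0)),
    reduction_pct = 100 * result$error_reduction_params,
    at_bound = result$at_bound)
  agg <- stats::aggregate(reduction ~ cell, data = result$state_error,
                          FUN = mean)
  list(param_table = pt,
       cell_reduction = agg,
       n_over_50 = sum(pt$reduction_pct > 50),
       n_edge = sum(pt$at_bound))
}

#' Trend, inter-annual variability and phase of an annual series
#'
#' Ordinary-least-squares slope against year, detrended (residual)
#' standard deviation, and Pearson correlation against a reference series.
#'
#' @param annual numeric vector of annual totals (PgC yr-1), >= 3 years.
#' @param reference optional reference series of equal length.
#' @return list with `slope` (PgC yr-2), `iav_sd`, `phase_r` (NA without a
#'   reference).
#' @export
iav_trend <- function(annual, reference = NULL) {
  if (length(annual) < 3) stop("need at least 3 years for trend/IAV")
  yr <- seq_along(annual)
  fit <- lm(annual ~ yr)
  phase_r <- NA_real_
  if (!is.null(reference)) {
    stopifnot(length(reference) == length(annual))
    phase_r <- if (sd(annual) > 0 && sd(reference) > 0)
      cor(annual, reference) else NA_real_
  }
  list(slope = unname(coef(fit)[2]), iav_sd = sd(residuals(fit)),
       phase_r = phase_r)
}
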