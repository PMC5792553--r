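# Parameter space: the optimisable parameter table, the concatenated
# (parameter, PFT) vector with priors / bounds / diagonal prior covariance,
# and the standardisation used by the minimiser.

PFT_INDICES <- 2:13

#' PFT descriptor table
#'
#' The twelve vegetated plant functional types (PFTs), numbered 2-13
#' (index 1 is bare soil and carries no parameters).
#'
#' @return data.frame with columns `index`, `acronym`, `name`, `evergreen`,
#'   `c4`, `trig_temp`, `trig_moist` (leaf-onset trigger pathways; evergreen
#'   PFTs have neither — their leaf turnover is a function of leaf age only).
#' @export
default_pft_table <- function() {
  data.frame(
    index = 2:13,
    acronym = c("TrBE", "TrBR", "TeNE", "TeBE", "TeBD", "BoNE",
                "BoBD", "BoND", "NC3", "NC4", "AC3", "AC4"),
    name = c("tropical broadleaved evergreen",
             "tropical broadleaved raingreen",
             "temperate needleleaved evergreen",
             "temperate broadleaved evergreen",
             "temperate broadleaved deciduous",
             "boreal needleleaved evergreen",
             "boreal broadleaved deciduous",
             "boreal needleleaved deciduous",
             "natural C3 grass", "natural C4 grass",
             "C3 crops", "C4 crops"),
    evergreen = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
                  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    c4 = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
           FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    # onset triggered by growing-degree days (6, 8-13) and/or by time since
    # the annual soil-moisture minimum (3, 10-13)
    trig_temp = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                  TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    trig_moist = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Default optimisable parameter table
#'
#' The 17 parameters of the surrogate model: 6 photosynthesis, 9 phenology,
#' and the per-PFT slope/intercept of the linear SIF-GPP relationship.
#' Twelve parameters apply to all 12 PFTs; `k_pheno_crit` and `t_senes` to
#' PFTs 6, 8-13; `m_tmin` and `m_senes_nosenes` to PFTs 3, 10-13; `l_fall`
#' to PFTs 3, 6, 8, 9 — 172 (parameter, PFT) pairs in total.
#'
#' Photosynthesis/phenology prior values are surrogate defaults (the original
#' model's internal priors are not public); the SIF slope prior is 0.25 with
#' bounds \[-0.5, 1\] and the intercept prior 0.25 with bounds \[-1.5, 2.5\].
#' Prior uncertainty is always 40% of the bound range (see [build_prior()]).
#' Every entry can be overridden via CSV ([read_parameter_table()]).
#'
#' @return An object of class `sifda_parameter_table`: list with elements
#'   `defs` (data.frame: name, group, units, pft_list, prior, lower, upper,
#'   description) and `pfts` (see [default_pft_table()]).
#' @export
default_parameter_table <- function() {
  defs <- rbind(
    data.frame(name = "vcmax", group = "photosynthesis",
               units = "umol m-2 s-1", pft_list = "all",
               prior = "60;55;45;50;50;40;45;40;55;70;60;70",
               lower = 10, upper = 120,
               description = "Maximum carboxylation rate"),
    data.frame(name = "gs_slope", group = "photosynthesis",
               units = "dimensionless", pft_list = "all", prior = "9",
               lower = 3, upper = 15,
               description = "Ball-Berry slope of the stomatal conductance model"),
    data.frame(name = "t_opt", group = "photosynthesis", units = "degC",
               pft_list = "all", prior = "25", lower = 12, upper = 38,
               description = "Optimal photosynthesis temperature"),
    data.frame(name = "t_min", group = "photosynthesis", units = "degC",
               pft_list = "all", prior = "0", lower = -10, upper = 8,
               description = "Minimum photosynthesis temperature"),
    data.frame(name = "t_max", group = "photosynthesis", units = "degC",
               pft_list = "all", prior = "45", lower = 39, upper = 55,
               description = "Maximum photosynthesis temperature"),
    data.frame(name = "f_stress_h", group = "photosynthesis",
               units = "dimensionless", pft_list = "all", prior = "1",
               lower = 0, upper = 2,
               description = "Parameter reducing the hydric limitation of photosynthesis"),
    data.frame(name = "sla", group = "phenology", units = "m2 g-1",
               pft_list = "all", prior = "0.015", lower = 0.005, upper = 0.05,
               description = "Specific leaf area"),
    data.frame(name = "lai_max", group = "phenology", units = "m2 m-2",
               pft_list = "all", prior = "5", lower = 1, upper = 8,
               description = "Maximum leaf area index"),
    data.frame(name = "k_lai_happy", group = "phenology",
               units = "fraction of lai_max", pft_list = "all", prior = "0.5",
               lower = 0.2, upper = 0.9,
               description = "LAI threshold to stop using carbohydrate reserves during growth"),
    data.frame(name = "k_pheno_crit", group = "phenology",
               units = "dimensionless", pft_list = "6;8;9;10;11;12;13",
               prior = "1", lower = 0.5, upper = 2,
               description = "Multiplicative parameter of the growing-degree-day threshold that determines the start of the growing season"),
    data.frame(name = "m_tmin", group = "phenology", units = "days",
               pft_list = "3;10;11;12;13", prior = "30", lower = 5, upper = 90,
               description = "Time since moisture minimum for leaf growth"),
    data.frame(name = "l_age_crit", group = "phenology", units = "days",
               pft_list = "all", prior = "180", lower = 80, upper = 730,
               description = "Average critical age of leaves"),
    data.frame(name = "t_senes", group = "phenology", units = "degC",
               pft_list = "6;8;9;10;11;12;13", prior = "7", lower = -2,
               upper = 20,
               description = "Temperature threshold for senescence"),
    data.frame(name = "m_senes_nosenes", group = "phenology",
               units = "relative moisture", pft_list = "3;10;11;12;13",
               prior = "0.3", lower = 0.05, upper = 0.8,
               description = "Moisture threshold for senescence"),
    data.frame(name = "l_fall", group = "phenology", units = "day-1",
               pft_list = "3;6;8;9", prior = "0.1", lower = 0.02, upper = 0.5,
               description = "Rate of leaf fall during senescence"),
    data.frame(name = "sif_a", group = "sif_link",
               units = "mW m-2 sr-1 nm-1 per gC m-2 day-1", pft_list = "all",
               prior = "0.25", lower = -0.5, upper = 1,
               description = "Slope parameter of the linear GPP-SIF relationship"),
    data.frame(name = "sif_b", group = "sif_link",
               units = "mW m-2 sr-1 nm-1", pft_list = "all", prior = "0.25",
               lower = -1.5, upper = 2.5,
               description = "Intercept parameter of the linear GPP-SIF relationship")
  )
  structure(list(defs = defs, pfts = default_pft_table()),
            class = "sifda_parameter_table")
}

validate_parameter_table <- function(table) {
  stopifnot(inherits(table, "sifda_parameter_table"))
  defs <- table$defs
  if (anyDuplicated(defs$name))
    stop("parameter names must be unique")
  if (anyDuplicated(table$pfts$index) ||
      !all(table$pfts$index %in% PFT_INDICES))
    stop("PFT indices must be unique and within 2-13")
  if (!all(defs$lower < defs$upper))
    stop("every parameter must have lower_bound < upper_bound")
  for (i in seq_len(nrow(defs))) {
    pr <- parse_prior(defs$prior[i], parse_pft_list(defs$pft_list[i],
                                                    table$pfts$index))
    if (any(pr < defs$lower[i] - 1e-12) || any(pr > defs$upper[i] + 1e-12))
      stop("prior value outside bounds for parameter ", defs$name[i])
  }
  invisible(table)
}

# "all" or "6;8;9" -> integer PFT indices
parse_pft_list <- function(s, all_pfts) {
  if (identical(tolower(trimws(s)), "all")) return(all_pfts)
  idx <- as.integer(strsplit(trimws(s), ";")[[1]])
  if (anyNA(idx) || !all(idx %in% PFT_INDICES))
    stop("invalid pft_list entry: ", s)
  idx
}

# prior string: single value or semicolon list matching the pft list
parse_prior <- function(s, pfts) {
  v <- as.numeric(strsplit(trimws(s), ";")[[1]])
  if (anyNA(v)) stop("invalid prior entry: ", s)
  if (length(v) == 1) return(rep(v, length(pfts)))
  if (length(v) != length(pfts))
    stop("prior list length does not match pft list length")
  v
}

#' Build the concatenated (parameter, PFT) vector
#'
#' One entry per (parameter, PFT) pair permitted by the applicability column,
#' ordered parameter-major (table order) then by PFT index, so vector
#' positions are stable across runs.
#'
#' @param table a `sifda_parameter_table`.
#' @param pfts integer PFT indices to optimise (subset of `table$pfts$index`).
#' @return An object of class `sifda_parameter_vector`: list with `values`,
#'   `prior`, `lower`, `upper`, `prior_sigma` (NA until [build_prior()]),
#'   and `index` (data.frame `param`, `pft`, `pos`).
#' @export
build_parameter_vector <- function(table, pfts = table$pfts$index) {
  validate_parameter_table(table)
  pfts <- as.integer(pfts)
  unknown <- setdiff(pfts, table$pfts$index)
  if (length(unknown))
    stop("unknown PFT index: ", paste(unknown, collapse = ", "))
  defs <- table$defs
  rows <- list()
  for (i in seq_len(nrow(defs))) {
    applicable <- parse_pft_list(defs$pft_list[i], table$pfts$index)
    prior_all <- parse_prior(defs$prior[i], applicable)
    keep <- applicable %in% pfts
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      param = defs$name[i], pft = applicable[keep],
      prior = prior_all[keep], lower = defs$lower[i], upper = defs$upper[i],
      stringsAsFactors = FALSE)
  }
  idx <- do.call(rbind, rows)
  idx$pos <- seq_len(nrow(idx))
  structure(list(
    values = idx$prior, prior = idx$prior,
    lower = idx$lower, upper = idx$upper,
    prior_sigma = rep(NA_real_, nrow(idx)),
    index = idx[, c("param", "pft", "pos")],
    pfts = table$pfts[table$pfts$index %in% pfts, , drop = FALSE]),
    class = "sifda_parameter_vector")
}

#' Fill the diagonal prior covariance
#'
#' Prior uncertainty for every parameter is 40% of its bound range:
#' `sigma_i = 0.4 (upper_i - lower_i)`; the prior covariance `P_b` is
#' diagonal with entries `sigma_i^2` (parameters are assumed independent).
#'
#' @param vector a `sifda_parameter_vector`.
#' @param fraction fraction of the range (default 0.4).
#' @return The vector with `prior_sigma` filled.
#' @export
build_prior <- function(vector, fraction = 0.4) {
  stopifnot(inherits(vector, "sifda_parameter_vector"))
  if (!all(is.finite(vector$lower)) || !all(is.finite(vector$upper)))
    stop("bounds must be finite to derive prior uncertainties")
  vector$prior_sigma <- fraction * (vector$upper - vector$lower)
  vector
}

#' Standardise a parameter vector
#'
#' Maps to the dimensionless space `x' = P_b^{-1/2} (x - x_b)` in which the
#' minimiser operates; Euclidean distance in `x'` equals Mahalanobis distance
#' under the diagonal prior covariance.
#'
#' @param x numeric values on the natural scale (defaults to
#'   `vector$values`).
#' @param vector a `sifda_parameter_vector` with `prior_sigma` filled.
#' @return numeric vector `x'`.
#' @export
standardise <- function(vector, x = vector$values) {
  sig <- vector$prior_sigma
  if (anyNA(sig)) stop("prior_sigma not set; call build_prior() first")
  if (any(sig <= 0)) stop("prior_sigma must be strictly positive")
  (x - vector$prior) / sig
}

#' @rdname standardise
#' @param xprime numeric values on the standardised scale.
#' @export
unstandardise <- function(vector, xprime) {
  sig <- vector$prior_sigma
  if (anyNA(sig)) stop("prior_sigma not set; call build_prior() first")
  if (any(sig <= 0)) stop("prior_sigma must be strictly positive")
  vector$prior + sig * xprime
}

#' Extract one PFT's parameters as a named list
#'
#' Parameters not applicable to the PFT are absent from the result; the
#' surrogate model substitutes fixed defaults for them (see
#' [surrogate_config()]).
#'
#' @param vector a `sifda_parameter_vector`.
#' @param pft integer PFT index.
#' @param values optional replacement values (same length/order as
#'   `vector$values`).
#' @return named list, e.g. `list(vcmax = 60, gs_slope = 9, ...)`.
#' @export
pft_params <- function(vector, pft, values = vector$values) {
  sel <- vector$index$pft == pft
  if (!any(sel)) stop("PFT ", pft, " not present in parameter vector")
  as.list(setNames(values[sel], vector$index$param[sel]))
}

#' Read / write a parameter table as CSV
#'
#' Columns: name, group, units, pft_list (semicolon-separated integers or
#' "all"), prior (single value or semicolon list matching pft_list), lower,
#' upper, description. Round-trips exactly.
#'
#' @param path file path.
#' @param table a `sifda_parameter_table`.
#' @param pfts optional PFT descriptor table (defaults to
#'   [default_pft_table()] on read).
#' @return `read_parameter_table()` returns a `sifda_parameter_table`.
#' @export
write_parameter_table <- function(table, path) {
  validate_parameter_table(table)
  data.table::fwrite(table$defs, path)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path, pfts = default_pft_table()) {
  defs <- as.data.frame(data.table::fread(path,
                                          colClasses = list(character = c("name", "group", "units", "pft_list", "prior", "description"))))
  tab <- structure(list(defs = defs, pfts = pfts),
                   class = "sifda_parameter_table")
  validate_parameter_table(tab)
  tab
}

#' Snapshot a parameter vector to JSON
#'
#' One record per (parameter, PFT): name, pft, value, sigma and an
#' `at_bound` flag marking edge-hitting estimates.
#'
#' @param vector a `sifda_parameter_vector`.
#' @param path output path.
#' @param tol relative tolerance (of the bound range) for the at-bound flag.
#' @export
write_parameter_vector <- function(vector, path, tol = 1e-6) {
  rng <- vector$upper - vector$lower
  snap <- data.frame(
    name = vector$index$param, pft = vector$index$pft,
    value = vector$values, sigma = vector$prior_sigma,
    at_bound = (vector$values - vector$lower <= tol * rng) |
      (vector$upper - vector$values <= tol * rng))
  jsonlite::write_json(snap, path, digits = NA)
  invisible(path)
}
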