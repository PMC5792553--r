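# Observation operator H(x): per-PFT daily GPP -> grid-cell monthly SIF via
# the PFT-specific linear relationship SIF = a * GPP + b, fraction-weighted
# over the cell's PFT mosaic. Bare soil emits zero SIF: the per-PFT
# intercept b already absorbs additive retrieval biases.

#' Linear per-PFT SIF from GPP
#'
#' `SIF = a * GPP + b`, assumed to hold from daily to monthly time steps.
#'
#' @param gpp GPP (gC m-2 day-1); vectorised.
#' @param a slope (mW m-2 sr-1 nm-1 per gC m-2 day-1).
#' @param b intercept (mW m-2 sr-1 nm-1).
#' @return SIF (mW m-2 sr-1 nm-1).
#' @export
pft_sif <- function(gpp, a, b) {
  a * gpp + b
}

#' Fraction-weighted cell SIF
#'
#' `sum_p f_p * sif_p`; the bare-soil fraction contributes zero. Weights are
#' total-cell fractions (not renormalised over the vegetated part).
#'
#' @param sif_pft per-PFT SIF values.
#' @param frac per-PFT cover fractions.
#' @param bare bare-soil fraction.
#' @return scalar cell SIF.
#' @export
cell_sif <- function(sif_pft, frac, bare = 1 - sum(frac)) {
  if (abs(sum(frac) + bare - 1) > 1e-9)
    stop("PFT fractions plus bare soil must sum to 1")
  sum(frac * sif_pft)
}

#' Calendar-month aggregation of a daily series
#'
#' Arithmetic mean per calendar month. Days masked (NA) within a month are
#' skipped; an all-masked month is masked in the output. A trailing partial
#' month is excluded with a warning.
#'
#' @param x daily values (vector, possibly with NA) aligned with `calendar`.
#' @param calendar data.frame from [make_calendar()] (may be a leading
#'   subset ending mid-month).
#' @return list with `values` (monthly means, NA where all-masked) and
#'   `months` (data.frame year, month).
#' @export
monthly_aggregate <- function(x, calendar) {
  stopifnot(length(x) == nrow(calendar))
  mlen_full <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  key <- paste(calendar$year, calendar$month)
  counts <- table(factor(key, levels = unique(key)))
  full <- as.integer(counts) ==
    mlen_full[calendar$month[!duplicated(key)]]
  if (!full[length(full)]) {
    warning("trailing partial month excluded from monthly aggregation")
  }
  if (any(!full[-length(full)]))
    stop("non-trailing partial month in daily series")
  keep_key <- unique(key)[full]
  means <- tapply(x, factor(key, levels = keep_key),
                  function(v) if (all(is.na(v))) NA_real_
                              else mean(v, na.rm = TRUE))
  months <- unique(calendar[, c("year", "month")])
  months <- months[full, , drop = FALSE]
  list(values = as.numeric(means), months = months)
}

# slope/intercept per PFT from a parameter value vector
sif_link_params <- function(vector, values = vector$values) {
  ia <- vector$index$param == "sif_a"
  ib <- vector$index$param == "sif_b"
  list(pft = vector$index$pft[ia],
       a = setNames(values[ia], vector$index$pft[ia]),
       b = setNames(values[ib], vector$index$pft[ib]))
}

#' Predict monthly cell SIF from a simulated GPP field
#'
#' Applies the per-PFT linear map to the monthly-mean per-PFT GPP and
#' fraction-weights over the cell. Because the map is affine and the
#' weights fixed, this equals the monthly mean of the daily cell SIF.
#'
#' @param gpp_field a `sifda_gpp_field` from [simulate_gpp()].
#' @param vector the `sifda_parameter_vector` holding `sif_a` / `sif_b`.
#' @param values optional replacement parameter values.
#' @param cells optional subset of cell indices.
#' @return matrix (n_cell x n_month) of SIF (mW m-2 sr-1 nm-1).
#' @export
predict_sif <- function(gpp_field, vector, values = vector$values,
                        cells = seq_len(dim(gpp_field$monthly_pft)[1])) {
  link <- sif_link_params(vector, values)
  frac <- gpp_field$pft_map$frac[cells, , drop = FALSE]
  n_month <- dim(gpp_field$monthly_pft)[2]
  out <- matrix(0, length(cells), n_month)
  for (k in seq_along(link$pft)) {
    p <- as.character(link$pft[k])
    f <- frac[, p]
    if (all(f == 0)) next
    g <- gpp_field$monthly_pft[cells, , p, drop = FALSE]
    dim(g) <- c(length(cells), n_month)
    out <- out + f * (link$a[[k]] * g + link$b[[k]])
  }
  out
}
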