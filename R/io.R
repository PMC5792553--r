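# Plain-text serialisation (CSV via data.table + JSON manifests) for the
# gridded containers. The scenario directory layout is:
#   grid.json, forcing.csv, pft_map.csv, kg.csv, sif_obs.csv, truth.json,
#   sites.csv, scenario.json

#' Write / read a forcing object as CSV
#'
#' Long format: cell, day, tair, sw, sm; grid and calendar in a JSON
#' sidecar (`<path>.meta.json`).
#' @param forcing a `sifda_forcing`.
#' @param path CSV path.
#' @export
write_forcing <- function(forcing, path) {
  n_cell <- nrow(forcing$grid$cells)
  n_day <- nrow(forcing$calendar)
  dt <- data.table::data.table(
    cell = rep(seq_len(n_cell), times = n_day),
    day = rep(seq_len(n_day), each = n_cell),
    tair = as.numeric(forcing$tair), sw = as.numeric(forcing$sw),
    sm = as.numeric(forcing$sm))
  data.table::fwrite(dt, path)
  meta <- list(grid = forcing$grid[c("lat", "lon", "n_lat", "n_lon",
                                     "dlat", "dlon")],
               cells = forcing$grid$cells,
               calendar = forcing$calendar)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  grid <- as.list(meta$grid)
  grid$cells <- as.data.frame(meta$cells)
  cal <- as.data.frame(meta$calendar)
  dt <- data.table::fread(path)
  n_cell <- nrow(grid$cells); n_day <- nrow(cal)
  shape <- function(v) matrix(v, n_cell, n_day)
  make_forcing(grid, cal, shape(dt$tair), shape(dt$sw), shape(dt$sm))
}

#' Write / read a PFT map as CSV
#' @param pft_map a `sifda_pft_map`.
#' @param path CSV path (grid sidecar as for [write_forcing()]).
#' @export
write_pft_map <- function(pft_map, path) {
  dt <- data.table::as.data.table(pft_map$frac)
  names(dt) <- paste0("pft_", 2:13)
  dt <- cbind(data.table::data.table(cell = pft_map$grid$cells$cell), dt,
              bare = pft_map$bare)
  data.table::fwrite(dt, path)
  meta <- list(grid = pft_map$grid[c("lat", "lon", "n_lat", "n_lon",
                                     "dlat", "dlon")],
               cells = pft_map$grid$cells)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA)
  invisible(path)
}

#' @rdname write_pft_map
#' @export
read_pft_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  grid <- as.list(meta$grid)
  grid$cells <- as.data.frame(meta$cells)
  dt <- data.table::fread(path)
  frac <- as.matrix(dt[, paste0("pft_", 2:13), with = FALSE])
  colnames(frac) <- as.character(2:13)
  make_pft_map(grid, frac, dt$bare)
}

#' Write / read a SIF field as CSV
#'
#' Long format: cell, year, month, sif, sigma, mask.
#' @param field a `sifda_sif_field`.
#' @param path CSV path.
#' @export
write_sif_field <- function(field, path) {
  n_cell <- length(field$cells); n_month <- nrow(field$months)
  dt <- data.table::data.table(
    cell = rep(field$cells, times = n_month),
    year = rep(field$months$year, each = n_cell),
    month = rep(field$months$month, each = n_cell),
    sif = as.numeric(field$sif), sigma = as.numeric(field$sigma),
    mask = as.logical(field$mask))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_sif_field
#' @export
read_sif_field <- function(path) {
  dt <- data.table::fread(path)
  cells <- unique(dt$cell)
  months <- unique(dt[, c("year", "month")])
  n_cell <- length(cells); n_month <- nrow(months)
  make_sif_field(cells, as.data.frame(months),
                 matrix(dt$sif, n_cell, n_month),
                 matrix(dt$sigma, n_cell, n_month),
                 matrix(dt$mask, n_cell, n_month))
}

#' Write / read a scenario directory
#'
#' @param scenario list from [make_scenario()].
#' @param dir directory path (created if absent).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_forcing(scenario$forcing, file.path(dir, "forcing.csv"))
  write_pft_map(scenario$pft_map, file.path(dir, "pft_map.csv"))
  data.table::fwrite(data.frame(cell = scenario$kg$cells,
                                class = scenario$kg$class),
                     file.path(dir, "kg.csv"))
  write_sif_field(scenario$observations, file.path(dir, "sif_obs.csv"))
  data.table::fwrite(scenario$sites, file.path(dir, "sites.csv"))
  jsonlite::write_json(
    list(values = scenario$truth$values, index = scenario$truth$index),
    file.path(dir, "truth.json"), digits = NA)
  jsonlite::write_json(list(seed = scenario$seed,
                            noise_sd = scenario$noise_sd),
                       file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scenario
#' @param table parameter table used to rebuild the truth vector.
#' @export
read_scenario <- function(dir, table = default_parameter_table()) {
  forcing <- read_forcing(file.path(dir, "forcing.csv"))
  pft_map <- read_pft_map(file.path(dir, "pft_map.csv"))
  kgdt <- data.table::fread(file.path(dir, "kg.csv"))
  kg <- structure(list(cells = kgdt$cell, class = kgdt$class,
                       group = kg_group(kgdt$class)$group,
                       grid = forcing$grid),
                  class = "sifda_kg_map")
  obs <- read_sif_field(file.path(dir, "sif_obs.csv"))
  sites <- as.data.frame(data.table::fread(file.path(dir, "sites.csv")))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  truth <- build_prior(build_parameter_vector(table))
  stopifnot(identical(truth$index$param, tr$index$param))
  truth$values <- tr$values
  man <- jsonlite::read_json(file.path(dir, "scenario.json"),
                             simplifyVector = TRUE)
  list(grid = forcing$grid, forcing = forcing, pft_map = pft_map, kg = kg,
       truth = truth, sites = sites, observations = obs,
       noise_sd = man$noise_sd, seed = man$seed)
}
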