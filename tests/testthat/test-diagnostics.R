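test_that("KG grouping maps classes to analysis biomes", {
  out <- kg_group(c("A", "B", "C", "D", "E"))
  expect_equal(out$group, c("tropical", "arid", "temperate+boreal",
                            "temperate+boreal", "temperate+boreal"))
  expect_equal(out$boreal, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_error(kg_group("F"), "unknown")
})

test_that("site selection respects threshold, count, seed and spread", {
  sc <- tiny_scenario()
  s <- select_sites(sc$pft_map, 6, n = 15, threshold = 0.6, seed = 3)
  expect_lte(nrow(s), 15)
  expect_true(all(s$fraction > 0.6))
  expect_identical(s, select_sites(sc$pft_map, 6, n = 15, threshold = 0.6,
                                   seed = 3))
  expect_false(anyDuplicated(s$cell) > 0)

  # latitude-tercile stratification: sites span the eligible range
  elig_lat <- sc$pft_map$grid$cells$lat[sc$pft_map$frac[, "6"] > 0.6]
  if (nrow(s) >= 3 && length(unique(elig_lat)) > 2) {
    terc <- quantile(elig_lat, c(1 / 3, 2 / 3))
    expect_true(any(s$lat <= terc[1]))
    expect_true(any(s$lat > terc[2]))
  }

  expect_warning(empty <- select_sites(sc$pft_map, 2, threshold = 0.99),
                 "no eligible")
  expect_equal(nrow(empty), 0)
})

test_that("annual budgets integrate area and partition additively", {
  # uniform 1000 gC m-2 yr-1 over 1e12 m2 -> 1 PgC yr-1
  ann <- matrix(1000, 4, 2)
  area <- rep(2.5e11, 4)
  expect_equal(annual_budget(ann, area), 1)
  expect_equal(annual_budget(matrix(0, 4, 2), area), 0)

  set.seed(21)
  ann <- matrix(runif(20, 0, 2000), 10, 2)
  area <- runif(10, 1e10, 1e12)
  mask_a <- c(rep(TRUE, 4), rep(FALSE, 6))
  expect_equal(annual_budget(ann, area, mask_a) +
                 annual_budget(ann, area, !mask_a),
               annual_budget(ann, area), tolerance = 1e-12)
})

test_that("productivity metrics reproduce published-table arithmetic", {
  prior <- c(global = 194.4, tropical = 92.2, `temperate+boreal` = 88.6,
             arid = 13.6)
  post <- c(global = 165.6, tropical = 86.1, `temperate+boreal` = 67.1,
            arid = 12.4)
  m <- productivity_metrics(prior, post)
  expect_equal(unname(m$difference["global"]), 28.8, tolerance = 1e-9)
  expect_equal(round(unname(m$ratio_post["trop_tempboreal"]), 2), 1.28)

  # identical budgets: zero difference and ratio change
  m0 <- productivity_metrics(prior, prior)
  expect_true(all(m0$difference == 0))
  expect_equal(unname(m0$ratio_change["trop_tempboreal"]), 0)

  # zero denominator masks the ratio
  z <- c(global = 1, tropical = 1, `temperate+boreal` = 0)
  expect_true(is.na(productivity_metrics(z, z)$ratio_prior[["trop_tempboreal"]]))
})

test_that("seasonal cycle and latitudinal profile satisfy their identities", {
  vec <- build_prior(build_parameter_vector(default_parameter_table()))
  fo <- constant_forcing(2, years = 2007:2008, T = 25, R = 200, W = 1)
  frac <- matrix(0, 2, 12); frac[, 1] <- 0.8          # PFT 2, evergreen
  pm <- make_pft_map(fo$grid, frac, bare = rep(0.2, 2))
  gf <- simulate_gpp(vec, fo, pm)

  cyc <- seasonal_cycle(gf)
  expect_length(cyc, 12)
  # constant forcing, equilibrated evergreen -> near-equal monthly rates
  daily_rate <- cyc / c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  expect_lt(diff(range(daily_rate)) / mean(daily_rate), 0.05)
  # climatology sums to the mean annual total
  ann <- annual_gpp(gf)
  expect_equal(sum(cyc), annual_budget(ann, fo$grid$cells$area),
               tolerance = 1e-6)
  expect_error(seasonal_cycle(list(calendar = gf$calendar[1:100, ],
                                   daily_agg = gf$daily_agg[, 1:100],
                                   grid = gf$grid)), "whole years")

  # profiles
  grid <- make_grid(6, 4)
  flat <- rep(1500, nrow(grid$cells))
  prof <- latitudinal_profile(flat, grid)
  expect_equal(prof$gpp, rep(1.5, 6))
  w_mean <- sum(flat * grid$cells$area) / sum(grid$cells$area) / 1000
  expect_equal(sum(prof$gpp * rowsum(grid$cells$area, grid$cells$lat)) /
                 sum(grid$cells$area), w_mean)
  # masking one hemisphere leaves the other unchanged
  m <- grid$cells$lat > 0
  prof_n <- latitudinal_profile(flat, grid, mask = m)
  expect_equal(prof_n$gpp[prof_n$lat > 0], prof$gpp[prof$lat > 0])
  expect_true(all(is.na(prof_n$gpp[prof_n$lat < 0])))
})

test_that("monthly correlation handles proportional, inverted, constant series", {
  set.seed(31)
  g <- matrix(runif(5 * 24, 1, 5), 5, 24)
  s <- 0.3 * g + 0.2
  out <- monthly_correlation(s, g)
  expect_equal(out$r, rep(1, 5), tolerance = 1e-12)
  out_neg <- monthly_correlation(-g, g)
  expect_equal(out_neg$r, rep(-1, 5), tolerance = 1e-12)

  g2 <- g; g2[3, ] <- 2                               # constant cell
  out2 <- monthly_correlation(s, g2)
  expect_true(is.na(out2$r[3]))
  expect_equal(out2$n_excluded, 1)
  expect_equal(out2$mean, mean(out2$r[-3]))
})

test_that("trend and IAV statistics match simple series", {
  out <- iav_trend(1:6)
  expect_equal(out$slope, 1)
  expect_equal(out$iav_sd, 0)
  expect_equal(iav_trend(rep(5, 4))$slope, 0)
  expect_equal(iav_trend(c(1, 3, 2, 5), reference = c(1, 3, 2, 5))$phase_r, 1)
  expect_error(iav_trend(1:2), "3 years")
})
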