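test_that("forcing generation is reproducible with stated structure", {
  grid <- make_grid(8, 10)
  f1 <- generate_forcing(grid, 2007, seed = 4)
  f2 <- generate_forcing(grid, 2007, seed = 4)
  expect_identical(f1$tair, f2$tair)
  expect_identical(f1$sm, f2$sm)

  # zero noise -> exact sinusoid with range 2A
  f0 <- generate_forcing(grid, 2007, seed = 4, noise_sd = 0)
  amp <- 2 + 0.35 * abs(grid$cells$lat)
  rng <- apply(f0$tair, 1, function(v) diff(range(v)))
  expect_equal(rng, 2 * amp, tolerance = 0.01)

  # equatorial amplitude below polar amplitude
  eq <- which.min(abs(grid$cells$lat))
  po <- which.max(abs(grid$cells$lat))
  expect_lt(diff(range(f0$tair[eq, ])), diff(range(f0$tair[po, ])))

  # moisture bounded, no missing days
  expect_true(all(f1$sm >= 0 & f1$sm <= 1))
  expect_false(anyNA(f1$tair))
})

test_that("PFT map fractions close and high-cover site guarantees hold", {
  grid <- make_grid(24, 36)
  maps <- generate_pft_and_kg_maps(grid, seed = 2)
  pm <- maps$pft_map
  expect_equal(rowSums(pm$frac) + pm$bare, rep(1, nrow(pm$frac)),
               tolerance = 1e-9)
  expect_true(all(pm$frac >= 0 & pm$frac <= 1))

  for (p in as.character(2:13)) {
    thr <- if (p == "8") 0.2 else 0.6
    expect_gte(sum(pm$frac[, p] > thr), 15)
  }
  # BoBD cover never exceeds 0.3
  expect_lt(max(pm$frac[, "8"]), 0.3)

  # grid too small -> informative rejection
  expect_error(generate_pft_and_kg_maps(make_grid(4, 4), seed = 2),
               "grid too small")
})

test_that("KG classes follow the latitude/dryness rules", {
  grid <- make_grid(24, 36)
  maps <- generate_pft_and_kg_maps(grid, seed = 2)
  lat <- grid$cells$lat
  wet_trop <- which(abs(lat) < 15 & !maps$dry)
  expect_true(all(maps$kg$class[wet_trop] == "A"))
  expect_true(all(maps$kg$class[maps$dry] == "B"))
  polar <- which(abs(lat) > 65)
  expect_true(all(maps$kg$class[polar] == "E"))
  mid <- which(abs(lat) > 45 & abs(lat) < 65 & !maps$dry)
  expect_true(all(maps$kg$class[mid] == "D"))
})

test_that("truth draws respect bounds and the zero-perturbation identity", {
  tab <- default_parameter_table()
  t0 <- make_truth_scenario(tab, perturbation = 0, seed = 1)
  expect_identical(t0$values, t0$prior)

  t1 <- make_truth_scenario(tab, perturbation = 1.5, seed = 1)
  expect_true(all(t1$values >= t1$lower & t1$values <= t1$upper))
  t1b <- make_truth_scenario(tab, perturbation = 1.5, seed = 1)
  expect_identical(t1$values, t1b$values)
  t2 <- make_truth_scenario(tab, perturbation = 1.5, seed = 2)
  expect_false(identical(t1$values, t2$values))
})

test_that("pseudo-observations carry the stated noise model", {
  sc <- tiny_scenario()
  truth <- sc$truth
  cells <- sort(unique(sc$sites$cell))

  # noise-free observations equal the model output exactly
  obs0 <- make_observations(truth, sc$forcing, sc$pft_map, noise_sd = 0,
                            seed = 3, cells = cells)
  expect_equal(obs0$sif, attr(obs0, "clean"), tolerance = 1e-12)

  # same seed, same realisation; different seed differs
  o1 <- make_observations(truth, sc$forcing, sc$pft_map, noise_sd = 0.2,
                          seed = 3, cells = cells)
  o2 <- make_observations(truth, sc$forcing, sc$pft_map, noise_sd = 0.2,
                          seed = 3, cells = cells)
  expect_identical(o1$sif, o2$sif)
  o3 <- make_observations(truth, sc$forcing, sc$pft_map, noise_sd = 0.2,
                          seed = 4, cells = cells)
  expect_false(identical(o1$sif, o3$sif))
})

test_that("empirical residual sd matches the requested noise sd", {
  # large-sample statistics oracle: >= 1e4 noise draws
  grid <- make_grid(16, 24)
  maps <- generate_pft_and_kg_maps(grid, seed = 5, min_sites = 3)
  forcing <- generate_forcing(grid, 2007:2009, seed = 5, dry = maps$dry)
  truth <- make_truth_scenario(perturbation = 0.3, seed = 5)
  obs <- make_observations(truth, forcing, maps$pft_map, noise_sd = 0.25,
                           seed = 5)
  resid <- obs$sif - attr(obs, "clean")
  expect_gte(length(resid), 1e4)
  expect_equal(sd(resid), 0.25, tolerance = 0.05 * 0.25)
})

test_that("scenario directory round-trips through plain-text files", {
  sc <- tiny_scenario()
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  expect_true(all(file.exists(file.path(dir,
    c("forcing.csv", "pft_map.csv", "kg.csv", "sif_obs.csv",
      "truth.json", "sites.csv", "scenario.json")))))
  back <- read_scenario(dir)
  expect_equal(back$forcing$tair, sc$forcing$tair, tolerance = 1e-6)
  expect_equal(back$pft_map$frac, sc$pft_map$frac, tolerance = 1e-6)
  expect_equal(back$truth$values, sc$truth$values, tolerance = 1e-12)
  expect_equal(back$observations$sif, sc$observations$sif,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back$kg$class, sc$kg$class)
})
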