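test_that("photosynthesis rate modifiers follow their closed forms", {
  # tent temperature response
  expect_equal(temperature_response(25, 0, 25, 45), 1)
  expect_equal(temperature_response(c(0, 45), 0, 25, 45), c(0, 0))
  expect_equal(temperature_response(12.5, 0, 25, 45), 0.5)
  expect_equal(temperature_response(-10, 0, 25, 45), 0)
  expect_error(temperature_response(20, 10, 5, 45), "t_min < t_opt")

  # water stress
  expect_equal(water_stress(1, 2), 1)
  expect_equal(water_stress(0.3, 0), 1)
  expect_equal(water_stress(0.5, 1), 0.5)
  W <- seq(0, 1, 0.05)
  expect_true(all(diff(water_stress(W, 1.3)) >= 0))
  expect_error(water_stress(1.2, 1), "\\[0, 1\\]")

  # light response and canopy absorption
  expect_equal(light_response(100, 100), 0.5)
  expect_equal(light_response(0), 0)
  expect_equal(light_response(300, 100), 0.75)
  expect_error(light_response(-1), ">= 0")
  expect_equal(canopy_absorption(0), 0)
  expect_equal(canopy_absorption(2, 0.5), 1 - exp(-1))
  lai <- seq(0, 8, 0.5)
  expect_true(all(diff(canopy_absorption(lai)) > 0))
})

test_that("daily GPP reproduces the hand-computed co-limitation case", {
  # independently hand-derived: f_T = 1 (T at optimum), f_R = 0.5
  # (R = R_half), f_L = 1 - e^-1, f_age = 1, f_W = 1
  p <- test_params(vcmax = 30, gs_slope = 9)
  f_L <- 1 - exp(-1)
  A_c <- 1.0368 * 30 * 1 * 0.5 * f_L        # 9.8307...
  A_w <- 2.0 * 9 * 1 * f_L                  # 11.378...
  got <- daily_gpp(p, T = 25, R = 100, W = 1, lai = 2)
  expect_equal(got, min(A_c, A_w), tolerance = 1e-12)
  expect_equal(round(got, 2), 9.83)

  # temperature shut-off
  expect_equal(daily_gpp(p, T = -5, R = 100, W = 1, lai = 2), 0)

  # min() structure: when supply-limited, vcmax has no effect
  p_lowR <- test_params(vcmax = 100, gs_slope = 3)
  g1 <- daily_gpp(p_lowR, T = 25, R = 400, W = 0.9, lai = 3)
  p_lowR$vcmax <- 200
  g2 <- daily_gpp(p_lowR, T = 25, R = 400, W = 0.9, lai = 3)
  expect_equal(g1, g2)
})

test_that("single-day kernel step matches the standalone GPP formula", {
  st <- new_pheno_state(1, lai = 3, mean_leaf_age = 40, phase = 2L)
  p <- test_params()
  out <- step_phenology(st, list(T = 20, R = 180, W = 0.7, doy = 150,
                                 lat = 48), p, traits = 6)
  expect_equal(out$gpp,
               daily_gpp(p, 20, 180, 0.7, out$state$lai,
                         out$state$mean_leaf_age),
               tolerance = 1e-12)
})

test_that("phenology state machine behaves at its edges", {
  p <- test_params()
  # dormant below the GDD threshold: LAI stays zero
  st <- new_pheno_state(1)
  out <- step_phenology(st, list(T = 2, R = 50, W = 0.8, doy = 30,
                                 lat = 50), p, traits = 6)
  expect_equal(out$state$lai, 0)
  expect_equal(out$state$phase, 0L)

  # senescent decay: 2.0 -> 1.8 at l_fall = 0.1
  st <- new_pheno_state(1, lai = 2, mean_leaf_age = 100, phase = 3L)
  out <- step_phenology(st, list(T = 2, R = 50, W = 0.8, doy = 280,
                                 lat = 50), p, traits = 6)
  expect_equal(out$state$lai, 1.8)

  # senescent canopy below the dormancy cutoff resets to dormant
  st <- new_pheno_state(1, lai = 0.05, mean_leaf_age = 120, phase = 3L)
  out <- step_phenology(st, list(T = 2, R = 50, W = 0.8, doy = 300,
                                 lat = 50), p, traits = 6)
  expect_equal(out$state$phase, 0L)
  expect_equal(out$state$lai, 0)
})

test_that("LAI trajectory respects cap and phases over a seasonal year", {
  fo <- seasonal_forcing(2007:2008)
  p <- test_params(lai_max = 4)
  st <- new_pheno_state(1)
  lai <- numeric(nrow(fo$calendar))
  phases <- integer(nrow(fo$calendar))
  for (t in seq_len(nrow(fo$calendar))) {
    out <- step_phenology(st, list(T = fo$tair[1, t], R = fo$sw[1, t],
                                   W = fo$sm[1, t],
                                   doy = fo$calendar$doy[t], lat = 55),
                          p, traits = 6)
    st <- out$state
    lai[t] <- st$lai
    phases[t] <- st$phase
  }
  expect_true(all(lai <= 4 + 1e-9))
  expect_true(all(lai >= 0))
  expect_true(all(phases %in% 0:3))
  # a deciduous PFT under strongly seasonal forcing returns to dormancy
  # in each forcing year
  expect_true(any(phases[1:365] == 2))
  expect_equal(phases[365], 0L)
  expect_equal(phases[730], 0L)
})

test_that("spin-up is deterministic and reaches the evergreen fixed point", {
  # interior fixed point: growth g = r_grow * sla * B_day = 0.05 stays in
  # the full-rate region because g * l_age_crit = 2 < k_lai_happy * lai_max
  p <- test_params(sla = 0.005, l_age_crit = 40, lai_max = 5)
  fo <- constant_forcing(1, T = 25, R = 200, W = 1)
  st1 <- spin_up(p, fo, traits = 2)
  st2 <- spin_up(p, fo, traits = 2)
  expect_identical(st1$lai, st2$lai)
  expect_true(attr(st1, "converged"))
  expect_equal(st1$lai, 0.05 * 40, tolerance = 1e-2)

  # a converged state re-spun converges immediately
  st3 <- spin_up(p, fo, traits = 2, state = st1)
  expect_true(attr(st3, "converged"))
  expect_lte(attr(st3, "cycles"), 2L)
})

test_that("simulate_gpp conserves the PFT-weighted aggregate", {
  sc <- tiny_scenario()
  vec <- build_prior(build_parameter_vector(default_parameter_table()))
  cells <- sort(unique(sc$sites$cell))[1:5]
  fo <- subset_forcing(sc$forcing, cells)
  pm <- sc$pft_map
  pm$frac <- pm$frac[cells, , drop = FALSE]
  pm$bare <- pm$bare[cells]
  pm$grid <- fo$grid
  gf <- simulate_gpp(vec, fo, pm, daily_pft = TRUE)

  agg <- matrix(0, length(cells), nrow(fo$calendar))
  for (p in 2:13) {
    d <- gf$daily_pft[[p - 1]]
    if (!is.null(d)) agg <- agg + pm$frac[, as.character(p)] * d
  }
  expect_equal(gf$daily_agg, agg, tolerance = 1e-9)
  expect_true(all(gf$daily_agg >= 0))

  # bit-reproducible
  gf2 <- simulate_gpp(vec, fo, pm)
  expect_identical(gf$daily_agg, gf2$daily_agg)
})

test_that("a bare cell yields zero GPP and out-of-bound values are rejected", {
  vec <- build_prior(build_parameter_vector(default_parameter_table()))
  fo <- constant_forcing(1, T = 25, R = 200, W = 0.9)
  pm <- make_pft_map(fo$grid, matrix(0, 1, 12), bare = 1)
  gf <- simulate_gpp(vec, fo, pm)
  expect_true(all(gf$daily_agg == 0))

  bad <- vec$values
  bad[1] <- vec$upper[1] + 1
  expect_error(simulate_gpp(vec, fo, pm, values = bad), "bounds")
})

test_that("GPP is monotone in moisture and light; vcmax sensitivity signs", {
  p <- test_params(vcmax = 30, gs_slope = 9, f_stress_h = 1)
  gW <- sapply(seq(0.1, 1, 0.1), function(w)
    daily_gpp(p, 22, 150, w, lai = 3))
  expect_true(all(diff(gW) >= 0))
  gR <- sapply(seq(0, 400, 50), function(r)
    daily_gpp(p, 22, r, 0.9, lai = 3))
  expect_true(all(diff(gR) >= 0))

  # finite-difference sensitivity to vcmax
  base <- daily_gpp(p, 25, 100, 1, lai = 2)     # carboxylation-limited
  p2 <- p; p2$vcmax <- p$vcmax + 1
  expect_gt(daily_gpp(p2, 25, 100, 1, lai = 2), base)
  psup <- test_params(vcmax = 100, gs_slope = 3) # supply-limited
  b1 <- daily_gpp(psup, 25, 400, 0.9, lai = 3)
  psup$vcmax <- 101
  expect_equal(daily_gpp(psup, 25, 400, 0.9, lai = 3), b1)
})
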