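# scalar/toy fixtures for the variational engine
toy_vector <- function(prior = 0, sigma = 1, lower = -10, upper = 10, n = 1) {
  structure(list(values = rep(prior, n), prior = rep(prior, n),
                 lower = rep(lower, n), upper = rep(upper, n),
                 prior_sigma = rep(sigma, n),
                 index = data.frame(param = paste0("p", seq_len(n)),
                                    pft = 2L, pos = seq_len(n))),
            class = "sifda_parameter_vector")
}

test_that("cost decomposes into observation and prior terms", {
  vec <- toy_vector()
  model <- function(x) 2 * x

  # perfect fit at the prior
  out <- cost(0, vec, y = 0, r_diag = 1, model = model)
  expect_equal(out$J, 0)

  # scalar case: H(x) = 2, y = 1, r = 1, x = x_b
  vec2 <- toy_vector(prior = 1)
  out <- cost(1, vec2, y = 1, r_diag = 1, model = function(x) 2 * x)
  expect_equal(out$J_obs, 0.5)
  expect_equal(out$J_prior, 0)
  expect_equal(out$J, 0.5)

  # a 1-sigma prior displacement adds exactly 0.5
  out2 <- cost(2, vec2, y = 3, r_diag = 1, model = function(x) 2 * x)
  # H(2) = 4, y = 3 -> J_obs = 0.5; displacement (2-1)/1 -> J_prior = 0.5
  expect_equal(out2$J_prior, 0.5)
  expect_equal(out2$J, out2$J_obs + out2$J_prior)

  expect_error(cost(1, vec2, y = c(1, 2), r_diag = 1,
                    model = function(x) 2 * x), "misaligned")

  # decomposition holds for random evaluations
  set.seed(3)
  vecn <- toy_vector(n = 4, sigma = 2)
  modn <- function(x) c(sum(x), x[1] - x[3], x[2]^2)
  for (k in 1:5) {
    x <- rnorm(4)
    ev <- cost(x, vecn, y = rnorm(3), r_diag = c(1, 2, 0.5), model = modn)
    expect_equal(ev$J, ev$J_obs + ev$J_prior)
    expect_gte(ev$J_obs, 0)
    expect_gte(ev$J_prior, 0)
  }
})

test_that("finite-difference Jacobian matches linear and quadratic oracles", {
  lin <- function(x) 3 * x
  J <- jacobian_fd(lin, c(1, 2), sigma = c(1, 1))
  expect_equal(as.numeric(J$H), c(3, 0, 0, 3), tolerance = 1e-9)

  quad <- function(x) x^2
  J2 <- jacobian_fd(quad, 1, sigma = 1, step = 0.01)
  central <- (quad(1 + 0.01) - quad(1 - 0.01)) / 0.02   # oracle: 2 + O(d^2)
  expect_equal(as.numeric(J2$H), 2, tolerance = 0.02)
  expect_equal(central, 2, tolerance = 1e-4)

  # step flips inward at the upper bound
  J3 <- jacobian_fd(lin, 2, sigma = 1, lower = -5, upper = 2, step = 0.01)
  expect_lt(J3$fd_step, 0)
  expect_equal(as.numeric(J3$H), 3, tolerance = 1e-9)
})

test_that("bounded minimisation finds interior and bound-constrained optima", {
  fn <- function(x) 0.5 * (x - 3)^2
  out <- minimise(fn, x0 = 0, lower = 0, upper = 10)
  expect_equal(out$x_post, 3, tolerance = 1e-6)
  expect_false(any(out$at_bound))
  expect_true(all(diff(out$trajectory) <= 0))

  out2 <- minimise(fn, x0 = 0, lower = 0, upper = 2)
  expect_equal(out2$x_post, 2, tolerance = 1e-8)
  expect_true(any(out2$at_bound))

  expect_error(minimise(fn, x0 = 5, lower = 0, upper = 2), "outside bounds")
  expect_error(minimise(function(x) NaN, x0 = 1, lower = 0, upper = 2),
               "non-finite")
})

test_that("closed-form posterior matches its scalar identities and a brute-force fit", {
  # h = 1, r = 1, p = 1, y = xb + 1 -> x_post = xb + 0.5
  out <- closed_form_posterior(matrix(1), 1, 1, y = 3, xb = 2)
  expect_equal(out$x_post, 2.5)
  expect_equal(as.numeric(out$P_post), 0.5)

  # y = H xb -> no update
  set.seed(5)
  H <- matrix(rnorm(15), 5, 3)
  xb <- rnorm(3)
  out2 <- closed_form_posterior(H, rep(1, 5), rep(1, 3),
                                y = as.numeric(H %*% xb), xb = xb)
  expect_equal(out2$x_post, xb, tolerance = 1e-10)

  # random small system vs direct numerical minimisation of the cost
  r <- runif(5, 0.5, 2); p <- runif(3, 0.5, 2)
  y <- as.numeric(H %*% xb) + rnorm(5)
  cf <- closed_form_posterior(H, r, p, y, xb)
  Jfun <- function(x) 0.5 * (sum((H %*% x - y)^2 / r) + sum((x - xb)^2 / p))
  bf <- stats::optim(xb, Jfun, method = "BFGS",
                     control = list(reltol = 1e-14))
  expect_equal(cf$x_post, bf$par, tolerance = 1e-5)

  expect_error(closed_form_posterior(matrix(0, 2, 2), c(1, 1), c(Inf, Inf),
                                     c(0, 0), c(0, 0)),
               "singular")
})

test_that("minimiser agrees with the closed-form linear-Gaussian posterior", {
  set.seed(9)
  H <- matrix(rnorm(5 * 3), 5, 3)
  xb <- c(0.5, -1, 2)
  r <- runif(5, 0.5, 2)
  p <- runif(3, 0.5, 2)
  y <- as.numeric(H %*% (xb + c(1, -0.5, 0.2))) + rnorm(5, sd = 0.1)
  cf <- closed_form_posterior(H, r, p, y, xb)
  fn <- function(x) 0.5 * (sum((H %*% x - y)^2 / r) + sum((x - xb)^2 / p))
  gr <- function(x) as.numeric(t(H) %*% ((H %*% x - y) / r)) + (x - xb) / p
  out <- minimise(fn, x0 = xb, lower = rep(-50, 3), upper = rep(50, 3),
                  gr = gr)
  expect_equal(out$x_post, cf$x_post, tolerance = 1e-6)
})

test_that("posterior covariance limits and properties hold", {
  expect_equal(as.numeric(posterior_covariance(matrix(1), 1, 1)), 0.5)
  expect_equal(as.numeric(posterior_covariance(matrix(0), 1, 1)), 1)
  expect_lt(as.numeric(posterior_covariance(matrix(1), 1e-12, 1)), 1e-10)

  set.seed(13)
  for (k in 1:10) {
    n_obs <- sample(3:12, 1); n_par <- sample(2:6, 1)
    H <- matrix(rnorm(n_obs * n_par), n_obs, n_par)
    r <- runif(n_obs, 0.2, 3)
    p <- runif(n_par, 0.2, 3)
    P <- posterior_covariance(H, r, p)
    expect_equal(P, t(P), tolerance = 1e-10)
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10))
    expect_true(all(diag(P) <= p + 1e-10))
  }
})

test_that("uncertainty propagation returns diag(H P H')", {
  P <- diag(c(1, 2))
  expect_equal(propagate_uncertainty(diag(2), P), c(1, 2))
  expect_equal(propagate_uncertainty(matrix(2), 1), 4)

  # rank-1 operator: all state variances proportional to the single
  # parameter variance
  h <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(propagate_uncertainty(h, 0.7), 0.7 * c(1, 4, 9))
})

test_that("error reduction reproduces the headline sigma ratio", {
  expect_equal(error_reduction(57.2, 9.8), 1 - 9.8 / 57.2)
  expect_equal(round(100 * error_reduction(57.2, 9.8), 1), 82.9)
  expect_equal(error_reduction(3, 3), 0)
  expect_equal(error_reduction(3, 0), 1)
  expect_error(error_reduction(0, 1), "> 0")
})
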