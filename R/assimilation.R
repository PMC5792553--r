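# Variational Bayesian engine: Gaussian cost function, finite-difference
# Jacobian, bounded quasi-Newton (L-BFGS-B) minimisation in standardised
# parameter space, posterior covariance, uncertainty propagation and
# error-reduction metrics.

#' Assimilation configuration
#'
#' @param fd_step relative finite-difference step (fraction of the prior
#'   sigma; the step is flipped inward at a bound).
#' @param maxit maximum L-BFGS-B iterations for the joint minimisation.
#' @param pgtol projected-gradient-norm stopping tolerance.
#' @param j_reltol relative cost-change stopping tolerance.
#' @param noise_floor minimum observation error (SIF units) used in the
#'   diagonal R when the data provide none or smaller.
#' @param edge_tol at-bound flag tolerance, relative to the bound range.
#' @param globalise run the globalisation stages before the final L-BFGS-B
#'   polish (see Details of [assimilate()]): coarse lattice searches over
#'   the day-quantised phenology-trigger parameters interleaved with damped
#'   Gauss-Newton steps, a local trigger refinement and a per-PFT block
#'   polish. Without it, a cold L-BFGS-B reliably strands whole PFT blocks
#'   in poor basins of the staircase-shaped cost surface.
#' @param gn_iters damped Gauss-Newton iteration cap per stage.
#' @param lattice_points lattice resolution per trigger dimension (reduced
#'   to 5 for PFTs with more than two trigger parameters).
#' @param refine_span half-width of the local trigger refinement, as a
#'   fraction of the bound range.
#' @param restarts maximum restarts of the final L-BFGS-B polish after an
#'   abnormal line-search termination (restarting resets the quasi-Newton
#'   memory; stops early when the cost no longer improves).
#' @return named list.
#' @export
assim_config <- function(fd_step = 0.01, maxit = 200L, pgtol = 1e-6,
                         j_reltol = 1e-9, noise_floor = 0.1,
                         edge_tol = 1e-6, globalise = TRUE,
                         gn_iters = 12L, lattice_points = 5L,
                         refine_span = 0.15, restarts = 2L) {
  list(fd_step = fd_step, maxit = as.integer(maxit), pgtol = pgtol,
       j_reltol = j_reltol, noise_floor = noise_floor, edge_tol = edge_tol,
       globalise = isTRUE(globalise), gn_iters = as.integer(gn_iters),
       lattice_points = as.integer(lattice_points),
       refine_span = refine_span, restarts = as.integer(restarts))
}

# parameters whose cost response is a staircase (day-quantised triggers)
TRIGGER_PARAMS <- c("k_pheno_crit", "m_tmin", "t_senes", "m_senes_nosenes")

#' Evaluate the Bayesian cost function
#'
#' `J(x) = 1/2 [ (H(x) - y)' R^-1 (H(x) - y) + (x - x_b)' P_b^-1 (x - x_b) ]`
#' with diagonal R and P_b. Masked observations are excluded from the
#' observation term.
#'
#' @param values parameter values (natural scale).
#' @param vector a `sifda_parameter_vector` with priors/sigmas (supplies
#'   `x_b` and diagonal `P_b`).
#' @param y observation vector.
#' @param r_diag diagonal of R (observation error variances), length of `y`.
#' @param model forward operator: function(values) -> predicted vector
#'   aligned with `y`.
#' @param mask logical vector, TRUE where the observation is present.
#' @return list with `J`, `J_obs`, `J_prior` and `residuals`
#'   (`H(x) - y`, NA where masked).
#' @export
cost <- function(values, vector, y, r_diag, model, mask = NULL) {
  yhat <- model(values)
  if (length(yhat) != length(y))
    stop("model output and observation vector are misaligned")
  if (length(r_diag) == 1) r_diag <- rep(r_diag, length(y))
  if (is.null(mask)) mask <- !is.na(y)
  res <- yhat - y
  J_obs <- 0.5 * sum(res[mask]^2 / r_diag[mask])
  z <- (values - vector$prior) / vector$prior_sigma
  J_prior <- 0.5 * sum(z^2)
  res[!mask] <- NA_real_
  list(J = J_obs + J_prior, J_obs = J_obs, J_prior = J_prior,
       residuals = res)
}

#' Finite-difference Jacobian of a forward operator
#'
#' One-sided differences with per-parameter step `step * sigma_i`, flipped
#' inward when the forward step would leave the bounds.
#'
#' @param model function(values) -> predicted vector.
#' @param x evaluation point.
#' @param sigma per-parameter scales (prior sigmas; 1 in standardised
#'   space).
#' @param lower,upper bounds (default unbounded).
#' @param step relative step (default 0.01).
#' @param f0 optional pre-computed `model(x)`.
#' @return list with `H` (n_obs x n_param matrix) and `fd_step` (signed
#'   per-parameter steps).
#' @export
jacobian_fd <- function(model, x, sigma = rep(1, length(x)),
                        lower = rep(-Inf, length(x)),
                        upper = rep(Inf, length(x)),
                        step = 0.01, f0 = model(x)) {
  n <- length(x)
  delta <- step * sigma
  H <- matrix(NA_real_, length(f0), n)
  for (i in seq_len(n)) {
    d <- delta[i]
    if (x[i] + d > upper[i]) d <- -d      # flip inward at a bound
    if (x[i] + d < lower[i])
      stop("finite-difference step infeasible within bounds for parameter ", i)
    xp <- x
    xp[i] <- xp[i] + d
    H[, i] <- (model(xp) - f0) / d
    delta[i] <- d
  }
  if (!all(is.finite(H))) stop("non-finite entries in Jacobian")
  list(H = H, fd_step = delta)
}

#' Bounded quasi-Newton minimisation
#'
#' L-BFGS-B with box constraints. Stops on projected gradient norm
#' `< pgtol`, relative cost change `< j_reltol`, or `maxit` iterations.
#' The returned `trajectory` is the best-so-far (accepted) cost sequence
#' over all evaluations, hence non-increasing.
#'
#' @param fn scalar cost function.
#' @param x0 start point (must lie within bounds).
#' @param lower,upper bounds.
#' @param gr optional gradient function (numerical if NULL).
#' @param maxit,pgtol,j_reltol stopping controls.
#' @return list with `x_post`, `J`, `trajectory`, `n_iterations`,
#'   `convergence`, `message`, `at_bound` (logical).
#' @export
minimise <- function(fn, x0, lower = -Inf, upper = Inf, gr = NULL,
                     maxit = 200L, pgtol = 1e-6, j_reltol = 1e-9) {
  if (any(x0 < lower) || any(x0 > upper))
    stop("start point outside bounds")
  evals <- numeric(0)
  fn_rec <- function(x) {
    v <- fn(x)
    if (!is.finite(v))
      stop("cost function returned a non-finite value at x = ",
           paste(signif(x, 4), collapse = ", "))
    evals[length(evals) + 1L] <<- v
    v
  }
  res <- stats::optim(x0, fn_rec, gr = gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, pgtol = pgtol,
                                     factr = j_reltol / .Machine$double.eps))
  rng <- upper - lower
  list(x_post = res$par, J = res$value, trajectory = cummin(evals),
       n_iterations = res$counts[["function"]],
       convergence = res$convergence, message = res$message,
       at_bound = (res$par - lower <= 1e-8 * rng) |
         (upper - res$par <= 1e-8 * rng))
}

as_diag_inv <- function(m, n) {
  if (is.matrix(m)) {
    return(solve(m))
  }
  if (length(m) == 1) m <- rep(m, n)
  diag(1 / m, nrow = n)
}

#' Closed-form linear-Gaussian posterior
#'
#' For an affine forward operator `H`, the Bayesian posterior is available
#' in closed form:
#' `x_post = x_b + (H'R^-1 H + P_b^-1)^-1 H' R^-1 (y - H x_b)`,
#' with posterior covariance `(H'R^-1 H + P_b^-1)^-1`. Used as the
#' independent oracle for the iterative minimiser.
#'
#' @param H observation operator matrix (n_obs x n_param).
#' @param r R as a matrix or its diagonal (variances).
#' @param p P_b as a matrix or its diagonal.
#' @param y observation vector.
#' @param xb prior mean.
#' @return list with `x_post` and `P_post`.
#' @export
closed_form_posterior <- function(H, r, p, y, xb) {
  H <- as.matrix(H)
  Rinv <- as_diag_inv(r, nrow(H))
  Pinv <- as_diag_inv(p, ncol(H))
  A <- t(H) %*% Rinv %*% H + Pinv
  P <- tryCatch(solve(A), error = function(e)
    stop("singular normal matrix in closed-form posterior"))
  P <- (P + t(P)) / 2
  dx <- P %*% t(H) %*% Rinv %*% (y - H %*% xb)
  list(x_post = as.numeric(xb + dx), P_post = P)
}

#' Posterior parameter error covariance
#'
#' `P_post = (H'R^-1 H + P_b^-1)^-1` with the Jacobian evaluated at the
#' cost minimum. Symmetric positive semi-definite; its diagonal never
#' exceeds the prior diagonal. Falls back to a pseudo-inverse with a
#' warning if the normal matrix is numerically singular.
#'
#' @inheritParams closed_form_posterior
#' @return covariance matrix.
#' @export
posterior_covariance <- function(H, r, p) {
  H <- as.matrix(H)
  Rinv <- as_diag_inv(r, nrow(H))
  Pinv <- as_diag_inv(p, ncol(H))
  A <- t(H) %*% Rinv %*% H + Pinv
  P <- tryCatch(solve(A), error = function(e) {
    warning("normal matrix numerically singular; using pseudo-inverse")
    s <- svd(A)
    pos <- s$d > max(s$d) * 1e-12
    s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
      t(s$u[, pos, drop = FALSE])
  })
  (P + t(P)) / 2
}

#' Propagate parameter uncertainty to observation/state space
#'
#' `R_post = H P H'`; only the diagonal (state variances) is returned. Use
#' `P = P_b` for the prior state uncertainty and the posterior covariance
#' for the posterior one; square roots give the 1-sigma errors.
#'
#' @param H Jacobian matrix.
#' @param P parameter covariance (matrix or diagonal vector).
#' @return numeric vector `diag(H P H')`.
#' @export
propagate_uncertainty <- function(H, P) {
  H <- as.matrix(H)
  if (!is.matrix(P)) {
    if (length(P) == 1) P <- rep(P, ncol(H))
    return(rowSums(sweep(H, 2, P, "*") * H))
  }
  rowSums((H %*% P) * H)
}

#' Error reduction metric
#'
#' `1 - sigma_post / sigma_prior`, applied to 1-sigma standard deviations
#' (in `(-Inf, 1]`; 0 means no constraint, 1 a perfect one).
#'
#' @param sigma_prior,sigma_post prior/posterior standard deviations.
#' @return numeric vector.
#' @export
error_reduction <- function(sigma_prior, sigma_post) {
  if (any(sigma_prior <= 0)) stop("prior sigma must be > 0")
  1 - sigma_post / sigma_prior
}

# ---------------------------------------------------------------------------
# memoised site-level forward operator

#' Build the site-level forward operator H(x)
#'
#' Returns `function(values) -> predicted SIF vector` over
#' (site cell, month), column-major in months. Per-PFT monthly GPP blocks
#' are memoised on the PFT's parameter sub-vector, so perturbing one
#' parameter (as the finite-difference Jacobian does) re-runs only that
#' PFT's simulation.
#'
#' @param vector a `sifda_parameter_vector`.
#' @param forcing forcing restricted to the site cells.
#' @param pft_map PFT map restricted to the site cells (same row order).
#' @param config surrogate constants.
#' @return function of class `sifda_forward`; `attr(, "cells")`,
#'   `attr(, "months")` describe the output layout.
#' @export
make_forward_model <- function(vector, forcing, pft_map,
                               config = surrogate_config()) {
  n_cell <- nrow(forcing$grid$cells)
  cal <- forcing$calendar
  mid <- cal$month_id
  months <- unique(cal[, c("year", "month")])
  n_month <- nrow(months)
  mlen <- as.numeric(table(mid))
  pfts_here <- sort(unique(vector$index$pft))
  caches <- new.env(parent = emptyenv())
  blocks <- list()
  for (pft in pfts_here) {
    frac <- pft_map$frac[, as.character(pft)]
    use <- which(frac > config$frac_min)
    if (!length(use)) next
    blocks[[as.character(pft)]] <- list(
      pft = pft, use = use, frac = frac[use],
      sel = which(vector$index$pft == pft),
      traits = pft_traits(pft, vector$pfts),
      forcing = subset_forcing(forcing, use))
    assign(as.character(pft), new.env(parent = emptyenv()), envir = caches)
  }
  fwd <- function(values) {
    out <- matrix(0, n_cell, n_month)
    for (bl in blocks) {
      pv <- values[bl$sel]
      names(pv) <- vector$index$param[bl$sel]
      key <- paste(formatC(pv, digits = 17, format = "g"), collapse = ",")
      cache <- get(as.character(bl$pft), envir = caches)
      g <- cache[[key]]
      if (is.null(g)) {
        params <- as.list(pv[setdiff(names(pv), c("sif_a", "sif_b"))])
        # always cold-started: the forward operator must be a pure function
        # of the parameter values (warm-starting the spin-up would make the
        # result depend on evaluation order within the spin-up tolerance)
        state <- spin_up(params, bl$forcing, bl$traits, config)
        run <- run_pft(params, bl$traits, bl$forcing, state, config)
        msum <- t(rowsum(t(run$gpp), mid, reorder = FALSE))
        g <- sweep(msum, 2, mlen, "/")
        # modest cache: entries are tiny but a long optimisation could
        # accumulate thousands; recompute instead of hoarding
        if (length(ls(cache)) > 128) rm(list = ls(cache), envir = cache)
        cache[[key]] <- g
      }
      out[bl$use, ] <- out[bl$use, ] +
        bl$frac * (pv[["sif_a"]] * g + pv[["sif_b"]])
    }
    as.numeric(out)
  }
  attr(fwd, "cells") <- forcing$grid$cells$cell
  attr(fwd, "months") <- months
  attr(fwd, "n_cell") <- n_cell
  class(fwd) <- c("sifda_forward", class(fwd))
  fwd
}

#' Multi-site variational assimilation
#'
#' Joint optimisation of all (parameter, PFT) pairs against monthly SIF at
#' the selected site cells: minimises the Bayesian cost in standardised
#' space with L-BFGS-B, re-evaluates the finite-difference Jacobian at the
#' minimum, and derives the posterior covariance, per-parameter and
#' propagated state error reductions, and the edge-hitting set.
#'
#' @param observations a `sifda_sif_field` covering the site cells.
#' @param forcing a `sifda_forcing` on the full grid.
#' @param pft_map a `sifda_pft_map` on the full grid.
#' @param sites data.frame with columns `cell`, `pft` (from
#'   [select_sites()]).
#' @param table parameter table (default [default_parameter_table()]).
#' @param config assimilation controls ([assim_config()]).
#' @param surrogate surrogate-model constants ([surrogate_config()]).
#' @return object of class `sifda_posterior`: list with `vector` (posterior
#'   values), `x_post`, `P_post` (natural scale), `P_post_std`
#'   (standardised), `cost_trajectory`, `n_iterations`, `edge_hitting`,
#'   `error_reduction_params`, `state_error` (per-observation prior/post
#'   1-sigma and reduction), `fit` (y, prior/posterior predictions, mask)
#'   and `index`.
#' @export
assimilate <- function(observations, forcing, pft_map, sites,
                       table = default_parameter_table(),
                       config = assim_config(),
                       surrogate = surrogate_config()) {
  stopifnot(inherits(observations, "sifda_sif_field"))
  cells <- sort(unique(sites$cell))
  pos <- match(cells, observations$cells)
  if (anyNA(pos))
    stop("observations do not cover all site cells")

  pvec <- build_prior(build_parameter_vector(table))
  pft_cov <- colSums(pft_map$frac[cells, , drop = FALSE] > surrogate$frac_min)
  dead <- as.integer(names(pft_cov)[pft_cov == 0])
  if (length(dead))
    warning("no observations constrain PFT(s) ",
            paste(dead, collapse = ", "),
            "; their parameters stay at the prior with zero reduction")

  sub_forc <- subset_forcing(forcing, cells)
  sub_map <- pft_map
  sub_map$frac <- pft_map$frac[cells, , drop = FALSE]
  sub_map$bare <- pft_map$bare[cells]
  sub_map$grid <- sub_forc$grid

  fwd <- make_forward_model(pvec, sub_forc, sub_map, surrogate)

  # align observations with the forward layout
  fmonths <- attr(fwd, "months")
  mo <- match(paste(fmonths$year, fmonths$month),
              paste(observations$months$year, observations$months$month))
  if (anyNA(mo))
    stop("observations do not cover the assimilation window")
  y <- as.numeric(observations$sif[pos, mo, drop = FALSE])
  sig <- pmax(as.numeric(observations$sigma[pos, mo, drop = FALSE]),
              config$noise_floor)
  mask <- as.logical(observations$mask[pos, mo, drop = FALSE])
  keep <- which(mask & is.finite(y))
  y_k <- y[keep]
  r_k <- sig[keep]^2

  sigma <- pvec$prior_sigma
  model_s <- function(xs) fwd(pvec$prior + sigma * xs)[keep]
  lower_s <- (pvec$lower - pvec$prior) / sigma
  upper_s <- (pvec$upper - pvec$prior) / sigma

  fn <- function(xs) {
    res <- model_s(xs) - y_k
    0.5 * (sum(res^2 / r_k) + sum(xs^2))
  }
  gr <- function(xs) {
    f0 <- model_s(xs)
    J <- jacobian_fd(model_s, xs, sigma = rep(1, length(xs)),
                     lower = lower_s, upper = upper_s,
                     step = config$fd_step, f0 = f0)
    as.numeric(t(J$H) %*% ((f0 - y_k) / r_k)) + xs
  }

  yhat_prior <- model_s(rep(0, length(sigma)))

  # -- globalisation stages -------------------------------------------------
  # The cost surface is staircase-shaped in the day-quantised trigger
  # directions, so a cold gradient descent strands whole PFT blocks in
  # poor basins. Stages (each monotone in J): coarse per-PFT lattice
  # searches over the trigger parameters (cheap: one PFT re-simulated per
  # evaluation) interleaved with damped Gauss-Newton steps built from the
  # full finite-difference Jacobian, then a local trigger refinement and a
  # per-PFT block Gauss-Newton polish, and a final L-BFGS-B minimisation.
  stage_J <- numeric(0)

  lattice_stage <- function(xs, centres = NULL) {
    for (pft in sort(unique(pvec$index$pft))) {
      sel <- which(pvec$index$pft == pft &
                     pvec$index$param %in% TRIGGER_PARAMS)
      if (!length(sel)) next
      npt <- if (length(sel) > 2) min(5L, config$lattice_points)
             else config$lattice_points
      grids <- lapply(sel, function(i) {
        if (is.null(centres))
          seq(lower_s[i], upper_s[i], length.out = npt)
        else pmin(pmax(centres[i] + config$refine_span *
                         (upper_s[i] - lower_s[i]) *
                         seq(-1, 1, length.out = npt),
                       lower_s[i]), upper_s[i])
      })
      combos <- as.matrix(expand.grid(grids))
      best <- fn(xs)
      best_z <- xs[sel]
      for (r in seq_len(nrow(combos))) {
        z <- xs
        z[sel] <- combos[r, ]
        v <- fn(z)
        if (v < best) {
          best <- v
          best_z <- combos[r, ]
        }
      }
      xs[sel] <- best_z
      stage_J <<- c(stage_J, best)
    }
    xs
  }

  gn_stage <- function(xs, sel, iters) {
    lam <- 1e-2
    J0 <- fn(xs)
    for (k in seq_len(iters)) {
      f0 <- model_s(xs)
      H <- matrix(0, length(y_k), length(sel))
      for (j in seq_along(sel)) {
        i <- sel[j]
        d <- config$fd_step
        if (xs[i] + d > upper_s[i]) d <- -d
        zp <- xs
        zp[i] <- xs[i] + d
        H[, j] <- (model_s(zp) - f0) / d
      }
      g <- as.numeric(t(H) %*% ((f0 - y_k) / r_k)) + xs[sel]
      A <- t(H) %*% (H / r_k)
      ok <- FALSE
      for (tries in 1:8) {
        M <- A
        diag(M) <- diag(M) + 1 + lam
        dx <- tryCatch(solve(M, -g), error = function(e) NULL)
        if (!is.null(dx)) {
          xn <- xs
          xn[sel] <- pmin(pmax(xs[sel] + dx, lower_s[sel]), upper_s[sel])
          Jn <- fn(xn)
          if (Jn < J0) {
            xs <- xn
            improved <- (J0 - Jn) > 1e-4 * J0
            J0 <- Jn
            lam <- max(lam / 3, 1e-6)
            ok <- TRUE
            stage_J <<- c(stage_J, J0)
            if (!improved) return(xs)
            break
          }
        }
        lam <- lam * 10
      }
      if (!ok) break
    }
    xs
  }

  xs <- rep(0, length(sigma))
  if (config$globalise) {
    all_idx <- seq_along(sigma)
    for (cycle in 1:2) {
      xs <- lattice_stage(xs)
      xs <- gn_stage(xs, all_idx, config$gn_iters)
    }
    xs <- lattice_stage(xs, centres = xs)
    for (pft in sort(unique(pvec$index$pft))) {
      sel <- which(pvec$index$pft == pft)
      xs <- gn_stage(xs, sel, 8L)
    }
    xs <- gn_stage(xs, all_idx, config$gn_iters)
  }

  # final bounded quasi-Newton minimisation, restarted (memory reset)
  # after abnormal line-search terminations while it still improves
  opt <- minimise(fn, xs, lower_s, upper_s, gr = gr,
                  maxit = config$maxit, pgtol = config$pgtol,
                  j_reltol = config$j_reltol)
  tries <- 0L
  while (opt$convergence == 52 && tries < config$restarts) {
    tries <- tries + 1L
    opt2 <- minimise(fn, opt$x_post, lower_s, upper_s, gr = gr,
                     maxit = config$maxit, pgtol = config$pgtol,
                     j_reltol = config$j_reltol)
    improved <- (opt$J - opt2$J) > config$j_reltol * max(1, opt$J)
    opt2$trajectory <- cummin(c(opt$trajectory, opt2$trajectory))
    opt2$n_iterations <- opt$n_iterations + opt2$n_iterations
    opt <- opt2
    if (!improved) break
  }
  opt$trajectory <- cummin(c(stage_J, opt$trajectory))
  xs_post <- opt$x_post
  x_post <- pvec$prior + sigma * xs_post
  yhat_post <- model_s(xs_post)

  # Jacobian re-evaluated at the minimum; posterior covariance in
  # standardised space (prior covariance there is the identity)
  Jpost <- jacobian_fd(model_s, xs_post, sigma = rep(1, length(sigma)),
                       lower = lower_s, upper = upper_s,
                       step = config$fd_step, f0 = yhat_post)
  Ps <- posterior_covariance(Jpost$H, r_k, rep(1, length(sigma)))
  P_post <- Ps * tcrossprod(sigma)      # back to natural units

  sd_post <- sqrt(pmax(diag(Ps), 0))
  err_red <- error_reduction(rep(1, length(sigma)), pmin(sd_post, 1))

  state_var_prior <- propagate_uncertainty(Jpost$H, rep(1, length(sigma)))
  state_var_post <- propagate_uncertainty(Jpost$H, Ps)
  state_sd_prior <- sqrt(pmax(state_var_prior, 0))
  state_sd_post <- sqrt(pmax(state_var_post, 0))
  obs_grid <- expand.grid(cell = cells, month_id = seq_len(nrow(fmonths)))
  state_error <- data.frame(
    cell = obs_grid$cell[keep], month_id = obs_grid$month_id[keep],
    prior_sd = state_sd_prior, post_sd = state_sd_post,
    reduction = ifelse(state_sd_prior > 0,
                       1 - state_sd_post / state_sd_prior, 0))

  rng <- pvec$upper - pvec$lower
  at_bound <- (x_post - pvec$lower <= config$edge_tol * rng) |
    (pvec$upper - x_post <= config$edge_tol * rng)

  post_vec <- pvec
  post_vec$values <- x_post
  structure(list(
    vector = post_vec, x_post = x_post, prior = pvec,
    P_post = P_post, P_post_std = Ps,
    cost_trajectory = opt$trajectory, J = opt$J,
    n_iterations = opt$n_iterations, convergence = opt$convergence,
    index = pvec$index,
    edge_hitting = pvec$index[at_bound, , drop = FALSE],
    at_bound = at_bound,
    error_reduction_params = err_red,
    state_error = state_error,
    fit = list(y = y_k, r_diag = r_k, yhat_prior = yhat_prior,
               yhat_post = yhat_post, keep = keep, cells = cells,
               months = fmonths),
    unconstrained_pfts = dead),
    class = "sifda_posterior")
}
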