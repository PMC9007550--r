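#' Estimation configuration
#'
#' @param em_iterations maximum EM iterations per start (default 250)
#' @param newton_iterations maximum quasi-Newton (L-BFGS-B) iterations on
#'   the full marginal likelihood after EM (default 50)
#' @param n_starts number of random starting values (default 16)
#' @param refit_starts starts used when re-estimating a selected model to
#'   confirm a global optimum (default 150)
#' @param tol convergence tolerance on the log-likelihood change per EM
#'   iteration (default 1e-4)
#' @param n_nodes Gauss-Hermite nodes per random-effect dimension
#' @param integration `"quadrature"` (Gauss-Hermite tensor grid) or
#'   `"halton"` (quasi Monte-Carlo simulated likelihood)
#' @param n_draws Halton draws when `integration = "halton"`
#' @param seed base seed; start `s` uses `seed + s`
#' @param order_constraint keep the less-preferred level of ordered
#'   two-level attributes at a non-positive utility weight (box constraint
#'   during optimization)
#' @param bic_n `"participants"` (mixture-model convention for repeated
#'   measures) or `"choices"` (exploded choice records) as the BIC sample
#'   size
#' @param m_step_maxit L-BFGS-B iterations per EM M-step (partial M-steps
#'   give a generalized EM that retains monotonicity)
#' @param compute_se numerically differentiate the observed information at
#'   the optimum for standard errors (off by default; quadratic cost in
#'   the parameter count)
#' @return a `fit_config` list
#' @export
fit_config <- function(em_iterations = 250, newton_iterations = 50,
                       n_starts = 16, refit_starts = 150, tol = 1e-4,
                       n_nodes = 7, integration = c("quadrature", "halton"),
                       n_draws = 200, seed = 1, order_constraint = TRUE,
                       bic_n = c("participants", "choices"),
                       m_step_maxit = 20, compute_se = FALSE) {
  stopifnot(em_iterations >= 0, newton_iterations >= 0, n_starts >= 1, tol > 0)
  structure(list(
    em_iterations = em_iterations, newton_iterations = newton_iterations,
    n_starts = n_starts, refit_starts = refit_starts, tol = tol,
    n_nodes = n_nodes, integration = match.arg(integration),
    n_draws = n_draws, seed = seed, order_constraint = order_constraint,
    bic_n = match.arg(bic_n), m_step_maxit = m_step_maxit,
    compute_se = compute_se
  ), class = "fit_config")
}

make_grid <- function(D, config) {
  if (config$integration == "halton") halton_grid(D, config$n_draws)
  else gh_grid(D, config$n_nodes)
}

#' Random starting values
#'
#' Class utility weights are drawn with dispersion 0.5 around zero, wide
#' enough to reach distinct modes; loadings start small and positive on
#' their domain mask; membership coefficients start at zero.
#'
#' @param scheme an `attribute_scheme`
#' @param X number of classes
#' @param D number of random effects
#' @param n_cov membership-model covariates
#' @param sd_beta dispersion of the utility-weight starts
#' @return a `relcl_params`
#' @export
init_params <- function(scheme, X, D, n_cov = 1, sd_beta = 0.5) {
  P <- scheme_n_contrasts(scheme)
  beta <- matrix(stats::rnorm(X * P, 0, sd_beta), X, P)
  # respect the order constraint at the start
  cc <- contrast_cols(scheme)
  L <- scheme_n_levels(scheme)
  for (a in seq_along(cc)) {
    if (scheme$ordered[[a]] && L[a] == 2L)
      beta[, cc[[a]][1]] <- -abs(beta[, cc[[a]][1]])
  }
  lambda <- NULL
  if (D > 0) {
    lambda <- matrix(0, P, D)
    for (d in seq_len(D)) {
      cols <- domain_cols(scheme, d)
      lambda[cols, d] <- abs(stats::rnorm(length(cols), 0, 0.1)) + 0.05
    }
  }
  gamma <- if (X > 1) matrix(0, X - 1, 1 + n_cov) else NULL
  relcl_params(scheme, beta, lambda, gamma)
}

# one (generalized) EM iteration on prepared data; returns updated params
# and the marginal log-likelihood at the *incoming* params
em_iterate <- function(params, prep, grid, info, bounds, config) {
  mp <- marginal_parts(prep, params, grid)
  W <- mp$W
  # M-step, beta/lambda block: partial L-BFGS-B on the expected complete
  # log-likelihood from the current point (GEM)
  nbl <- info$n_beta + info$n_lam
  th0 <- pack_params(params, info)[seq_len(nbl)]
  cache <- new.env(parent = emptyenv()); cache$th <- NULL
  evaluate <- function(th) {
    if (!is.null(cache$th) && identical(th, cache$th)) return()
    p <- unpack_bl(th, params, info)
    g <- weighted_cll_grad(prep, p$beta, p$lambda, grid$nodes, W, info)
    cache$th <- th
    cache$value <- g$value
    cache$grad <- c(as.numeric(t(g$gbeta)), unlist(g$glam, use.names = FALSE))
  }
  obj <- function(th) { evaluate(th); -cache$value }
  grd <- function(th) { evaluate(th); -cache$grad }
  opt <- stats::optim(th0, obj, grd, method = "L-BFGS-B",
                      lower = bounds$lower[seq_len(nbl)],
                      upper = bounds$upper[seq_len(nbl)],
                      control = list(maxit = config$m_step_maxit))
  pbl <- unpack_bl(opt$par, params, info)
  gamma <- params$gamma
  if (info$X > 1) {
    Wx <- sapply(seq_len(info$X), function(x) {
      cols <- (x - 1L) * length(grid$weights) + seq_along(grid$weights)
      rowSums(W[, cols, drop = FALSE])
    })
    g0 <- as.numeric(t(params$gamma))
    gobj <- function(v) {
      gm <- matrix(v, info$X - 1, 1 + info$n_cov, byrow = TRUE)
      -gamma_obj_grad(gm, prep$C, Wx)$value
    }
    ggrd <- function(v) {
      gm <- matrix(v, info$X - 1, 1 + info$n_cov, byrow = TRUE)
      -as.numeric(t(gamma_obj_grad(gm, prep$C, Wx)$grad))
    }
    gopt <- stats::optim(g0, gobj, ggrd, method = "BFGS",
                         control = list(maxit = 50))
    gamma <- matrix(gopt$par, info$X - 1, 1 + info$n_cov, byrow = TRUE)
  }
  list(params = relcl_params(params$scheme, pbl$beta, pbl$lambda, gamma),
       loglik = mp$loglik)
}

unpack_bl <- function(th_bl, params, info) {
  beta <- matrix(th_bl[seq_len(info$n_beta)], info$X, info$P, byrow = TRUE)
  lambda <- matrix(0, info$P, info$D)
  off <- info$n_beta
  for (d in seq_len(info$D)) {
    cols <- info$lam_cols[[d]]
    lambda[cols, d] <- th_bl[off + seq_along(cols)]
    off <- off + length(cols)
  }
  list(beta = beta, lambda = lambda)
}

#' Single EM step
#'
#' Runs one expectation step (joint posteriors over class x quadrature
#' node) and one maximization step (weighted exploded-logit update of the
#' utility weights and loadings; weighted multinomial-logit update of the
#' membership coefficients). The marginal log-likelihood is non-decreasing
#' across calls.
#'
#' @param params current `relcl_params`
#' @param dataset a `ranking_dataset`
#' @param grid integration grid; defaults to `gh_grid(params$D)`
#' @param config a [fit_config()]
#' @return updated `relcl_params`
#' @export
em_step <- function(params, dataset, grid = NULL, config = fit_config()) {
  if (is.null(grid)) grid <- gh_grid(params$D, config$n_nodes)
  prep <- prepare_choice_data(dataset, params$scheme)
  info <- pack_info(params$scheme, params$X, params$D, ncol(prep$C))
  bounds <- order_bounds(params$scheme, info, config$order_constraint)
  em_iterate(params, prep, grid, info, bounds, config)$params
}

# full-likelihood objective/gradient on the packed parameter vector,
# sharing one evaluation between fn and gr via a small cache
make_marginal_objective <- function(prep, scheme, info, grid) {
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  evaluate <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) return()
    params <- unpack_params(theta, scheme, info)
    mp <- marginal_parts(prep, params, grid)
    g <- weighted_cll_grad(prep, params$beta, params$lambda, grid$nodes,
                           mp$W, info)
    grad <- c(as.numeric(t(g$gbeta)), unlist(g$glam, use.names = FALSE))
    if (info$X > 1) {
      Q <- length(grid$weights)
      Wx <- sapply(seq_len(info$X), function(x)
        rowSums(mp$W[, (x - 1L) * Q + seq_len(Q), drop = FALSE]))
      gg <- gamma_obj_grad(params$gamma, prep$C, Wx)$grad
      grad <- c(grad, as.numeric(t(gg)))
    }
    cache$theta <- theta
    cache$value <- mp$loglik
    cache$grad <- grad
  }
  list(
    fn = function(theta) { evaluate(theta); -cache$value },
    gr = function(theta) { evaluate(theta); -cache$grad }
  )
}

#' Fit a RELCL model by maximum likelihood
#'
#' Multi-start estimation: each start runs an EM phase (monotone in the
#' marginal log-likelihood) followed by quasi-Newton (L-BFGS-B) refinement
#' of the full marginal likelihood with analytic scores obtained from the
#' posterior weights (Fisher's identity). The best start is kept and
#' canonicalized: classes ordered by decreasing posterior share, loading
#' signs fixed per domain.
#'
#' @param dataset a `ranking_dataset`
#' @param scheme an `attribute_scheme`
#' @param X number of latent classes
#' @param D number of random effects (0..3 for the default scheme)
#' @param config a [fit_config()]
#' @return a `relcl_fit`: list with `params`, `loglik`, `n_params`, `bic`,
#'   `converged`, `best_start`, `start_logliks`, `se` (optional), plus the
#'   grid and config used.
#' @export
fit_relcl <- function(dataset, scheme, X, D, config = fit_config()) {
  if (nrow(dataset$choices) == 0) stop("empty dataset")
  prep <- prepare_choice_data(dataset, scheme)
  info <- pack_info(scheme, X, D, ncol(prep$C))
  grid <- make_grid(D, config)
  bounds <- order_bounds(scheme, info, config$order_constraint)
  objective <- make_marginal_objective(prep, scheme, info, grid)

  best <- NULL
  start_ll <- numeric(config$n_starts)
  converged <- logical(config$n_starts)
  for (s in seq_len(config$n_starts)) {
    set.seed(config$seed + s)
    params <- init_params(scheme, X, D, n_cov = ncol(prep$C))
    ll_prev <- -Inf
    ok <- FALSE
    res <- try({
      for (it in seq_len(config$em_iterations)) {
        step <- em_iterate(params, prep, grid, info, bounds, config)
        params <- step$params
        if (is.finite(ll_prev) && step$loglik - ll_prev < config$tol) {
          ok <- TRUE
          break
        }
        ll_prev <- step$loglik
      }
      theta <- pack_params(params, info)
      if (config$newton_iterations > 0) {
        opt <- stats::optim(theta, objective$fn, objective$gr,
                            method = "L-BFGS-B",
                            lower = bounds$lower, upper = bounds$upper,
                            control = list(maxit = config$newton_iterations))
        theta <- opt$par
        ok <- ok || opt$convergence == 0
      }
      list(theta = theta, loglik = -objective$fn(theta))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      start_ll[s] <- -Inf
      converged[s] <- FALSE
      next
    }
    start_ll[s] <- res$loglik
    converged[s] <- ok
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best$start <- s
    }
  }
  if (is.null(best)) stop("all starts failed")

  params <- unpack_params(best$theta, scheme, info)
  # canonical order by posterior shares
  mp <- marginal_parts(prep, params, grid)
  Q <- length(grid$weights)
  shares <- vapply(seq_len(X), function(x)
    mean(rowSums(mp$W[, (x - 1L) * Q + seq_len(Q), drop = FALSE])), numeric(1))
  params <- canonicalize_params(params, shares)

  n_par <- n_free_params(scheme, X, D, n_cov = ncol(prep$C))
  N <- if (config$bic_n == "participants") prep$n else 2L * prep$n_task
  se <- NULL
  if (config$compute_se) {
    se <- tryCatch(relcl_se(params, prep, scheme, info, grid),
                   error = function(e) NULL)
  }
  structure(list(
    params = params, loglik = best$loglik, n_params = n_par,
    bic = -2 * best$loglik + n_par * log(N),
    converged = any(converged), best_start = best$start,
    start_logliks = start_ll, se = se,
    X = X, D = D, grid = grid, config = config, scheme = scheme
  ), class = "relcl_fit")
}

#' @export
print.relcl_fit <- function(x, ...) {
  cat(sprintf("RELCL fit: X = %d classes, D = %d random effects\n", x$X, x$D))
  cat(sprintf("  loglik %.2f, %d parameters, BIC %.2f, best start %d%s\n",
              x$loglik, x$n_params, x$bic, x$best_start,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# observed-information standard errors by central-difference Hessian of
# the marginal log-likelihood on the packed vector
relcl_se <- function(params, prep, scheme, info, grid, h = 1e-4) {
  theta <- pack_params(params, info)
  k <- length(theta)
  f <- function(th) marginal_parts(prep, unpack_params(th, scheme, info), grid)$loglik
  H <- matrix(0, k, k)
  f0 <- f(theta)
  fp <- numeric(k); fm <- numeric(k)
  for (j in seq_len(k)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    fp[j] <- f(tp); fm[j] <- f(tm)
    H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / h^2
  }
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      tpp <- theta; tpp[c(j, l)] <- tpp[c(j, l)] + h
      tmm <- theta; tmm[c(j, l)] <- tmm[c(j, l)] - h
      H[j, l] <- H[l, j] <-
        (f(tpp) - fp[j] - fp[l] + 2 * f0 - fm[j] - fm[l] + f(tmm)) / (2 * h^2)
    }
  }
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  se <- sqrt(pmax(diag(V), 0))
  unpack_params(se, scheme, info)  # same shapes as the parameters
}

#' BIC model-selection grid
#'
#' Fits every combination of class count and random-effect count and
#' tabulates log-likelihood, parameter count and BIC; the BIC-minimizing
#' row is flagged. Individual cell failures are recorded and the grid
#' continues.
#'
#' @param dataset a `ranking_dataset`
#' @param scheme an `attribute_scheme`
#' @param classes integer vector of class counts (e.g. `1:10`)
#' @param effects integer vector of random-effect counts (e.g. `0:3`)
#' @param config a [fit_config()]
#' @return data frame with columns `X`, `D`, `loglik`, `n_params`, `bic`,
#'   `converged`, `best` (logical flag on the BIC minimum), with the
#'   fitted objects attached as attribute `"fits"`.
#' @export
fit_grid <- function(dataset, scheme, classes = 1:10, effects = 0:3,
                     config = fit_config()) {
  stopifnot(length(classes) >= 1, length(effects) >= 1)
  cells <- expand.grid(X = classes, D = effects, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  fits <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    X <- cells$X[k]; D <- cells$D[k]
    res <- tryCatch(fit_relcl(dataset, scheme, X, D, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[k]] <- data.frame(X = X, D = D, loglik = NA_real_,
                              n_params = NA_integer_, bic = NA_real_,
                              converged = FALSE)
    } else {
      fits[[k]] <- res
      rows[[k]] <- data.frame(X = X, D = D, loglik = res$loglik,
                              n_params = res$n_params, bic = res$bic,
                              converged = res$converged)
    }
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  if (any(!is.na(out$bic))) out$best[which.min(out$bic)] <- TRUE
  attr(out, "fits") <- fits
  out
}
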