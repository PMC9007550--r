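#' Posterior class membership and empirical-Bayes random-effect scores
#'
#' For each participant: posterior class probabilities
#' `post_x(i) \propto pi_x(i) * sum_q w_q exp(cll(i, x, f_q))`, the modal
#' class (ties to the lower index), and posterior-mean random-effect
#' scores `E[F_d | data_i]` computed as posterior-weighted quadrature-node
#' means. Also returns the classification error matrix (average posterior
#' probability of each class among participants modally assigned to each
#' class) and the classification probabilities `P(assigned = j | true = x)`
#' used by the bias-adjusted three-step estimator.
#'
#' The full posterior (`post`, `modal`) conditions on the membership
#' model's covariates. For the three-step analyses a second, measurement-only
#' assignment is computed in which the covariate-specific prior is replaced
#' by the marginal class shares: classification error is then independent
#' of the covariates, which the bias adjustment requires (`assigned`,
#' `assign_probs`).
#'
#' @param fit a `relcl_fit`
#' @param dataset the `ranking_dataset` the model was fitted to
#' @return a `relcl_posteriors` list: `post` (n x X), `modal` (length n),
#'   `F_hat` (n x D), `F_sd` (n x D posterior standard deviations),
#'   `class_error` (X x X, rows = modal class, row-stochastic),
#'   `class_probs` (X x X, `P(modal = j | true = x)`), `assigned` /
#'   `assign_probs` (measurement-only analogues used by
#'   [three_step_membership()]), `shares` (posterior mean class shares),
#'   `entropy` (normalized classification entropy).
#' @export
class_posteriors <- function(fit, dataset) {
  params <- fit$params
  prep <- prepare_choice_data(dataset, params$scheme)
  grid <- fit$grid
  mp <- marginal_parts(prep, params, grid)
  X <- params$X; D <- params$D; Q <- length(grid$weights)
  cll <- mp$cll
  post <- sapply(seq_len(X), function(x)
    rowSums(mp$W[, (x - 1L) * Q + seq_len(Q), drop = FALSE]))
  post <- matrix(post, prep$n, X)
  modal <- max.col(post, ties.method = "first")
  F_hat <- matrix(0, prep$n, D)
  F_sd <- matrix(0, prep$n, D)
  if (D > 0) {
    for (d in seq_len(D)) {
      nd <- rep(grid$nodes[, d], X)
      F_hat[, d] <- as.vector(mp$W %*% nd)
      F_sd[, d] <- sqrt(pmax(as.vector(mp$W %*% nd^2) - F_hat[, d]^2, 0))
    }
  }
  class_error <- matrix(0, X, X)
  for (j in seq_len(X)) {
    idx <- modal == j
    if (any(idx))
      class_error[j, ] <- colMeans(post[idx, , drop = FALSE])
  }
  class_probs <- assignment_probs(post, modal, X)

  # measurement-only assignment: marginal shares replace the
  # covariate-specific prior
  lw <- log(grid$weights)
  llm <- sapply(seq_len(X), function(x) {
    B <- cll[, (x - 1L) * Q + seq_len(Q), drop = FALSE] +
      matrix(lw, prep$n, Q, byrow = TRUE)
    m <- apply(B, 1, max)
    m + log(rowSums(exp(B - m)))
  })
  llm <- matrix(llm, prep$n, X)
  prior_shares <- colMeans(exp(mp$log_pi))
  Am <- sweep(llm, 2, log(prior_shares), "+")
  post_m <- exp(Am - apply(Am, 1, max))
  post_m <- post_m / rowSums(post_m)
  assigned <- max.col(post_m, ties.method = "first")
  assign_probs <- assignment_probs(post_m, assigned, X)
  ent <- 0
  if (X > 1) {
    p <- pmax(post, 1e-12)
    ent <- 1 + sum(p * log(p)) / (prep$n * log(X))
  }
  structure(list(
    post = post, modal = modal, F_hat = F_hat, F_sd = F_sd,
    class_error = class_error, class_probs = class_probs,
    assigned = assigned, assign_probs = assign_probs,
    shares = colMeans(post), entropy = ent, X = X, D = D
  ), class = "relcl_posteriors")
}

# P(assigned = j | true = x) estimated from posterior weights
assignment_probs <- function(post, assigned, X) {
  M <- matrix(0, X, X)
  for (x in seq_len(X)) {
    denom <- sum(post[, x])
    for (j in seq_len(X))
      M[x, j] <- sum(post[assigned == j, x]) / denom
  }
  M
}

#' @export
print.relcl_posteriors <- function(x, ...) {
  cat(sprintf("Posterior summary: %d participants, %d classes, %d random effects\n",
              nrow(x$post), x$X, x$D))
  cat("  shares:", paste(sprintf("%.3f", x$shares), collapse = " "), "\n")
  invisible(x)
}

#' Individual-level preference estimates
#'
#' The per-participant preference value for each expanded attribute level:
#' the modal class's expanded utility weight plus the loading-weighted
#' posterior random-effect scores,
#' `value(i, p) = beta*_{modal(i), p} + sum_d lambda*_{dp} Fhat_{id}`
#' (starred quantities are expanded per-level coefficients). These are the
#' quantities whose within-class kernel densities visualize between- and
#' within-class preference heterogeneity.
#'
#' @param fit a `relcl_fit`
#' @param posteriors output of [class_posteriors()]
#' @return list with `values` (n x total_levels matrix, named columns) and
#'   `long` (data frame `id`, `class`, `attribute`, `level_label`,
#'   `value`) ready for density plotting with class-size weights.
#' @export
individual_preferences <- function(fit, posteriors) {
  ex <- expand_params(fit$params)
  n <- nrow(posteriors$post)
  vals <- ex$beta[posteriors$modal, , drop = FALSE]
  if (fit$params$D > 0)
    vals <- vals + posteriors$F_hat %*% t(ex$lambda)
  ei <- expanded_index(fit$params$scheme)
  long <- data.frame(
    id = rep(seq_len(n), times = ncol(vals)),
    class = rep(posteriors$modal, times = ncol(vals)),
    attribute = rep(ei$attribute, each = n),
    level_label = rep(ei$label, each = n),
    value = as.vector(vals)
  )
  list(values = vals, long = long)
}
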