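#' Log-probability of a ranked (best, second-best) response
#'
#' The ranking of three alternatives is modeled as sequential logit
#' choices: the best alternative is chosen from all three with softmax
#' probabilities, then the second-best from the remaining two using the
#' same utilities (the exploded / rank-ordered logit).
#'
#' @param utilities numeric vector of 3 alternative utilities
#' @param first index (1..3) of the best alternative
#' @param second index (1..3) of the second-best; must differ from `first`
#' @return log probability of the ranking
#' @examples
#' exp(ranking_logprob(c(0, 0, 0), 1, 2))  # 1/6
#' @export
ranking_logprob <- function(utilities, first, second) {
  if (length(utilities) != 3 || any(!is.finite(utilities)))
    stop("utilities must be 3 finite values")
  if (!first %in% 1:3 || !second %in% 1:3 || first == second)
    stop("first and second must be distinct indices in 1..3")
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  rest <- setdiff(1:3, first)
  (utilities[first] - lse(utilities)) +
    (utilities[second] - lse(utilities[rest]))
}

# --- data preparation ---------------------------------------------------

# Precomputes everything the likelihood engine needs from a ranking
# dataset: the effects-coded matrix Z (rows sorted by participant, task,
# alt), per-task chosen positions, task -> participant index, and the
# membership-model covariate matrix.
prepare_choice_data <- function(dataset, scheme) {
  ch <- dataset$choices
  parts <- dataset$participants
  attrs <- names(scheme$attributes)
  pid <- match(ch$participant, parts$id)
  if (anyNA(pid)) stop("choices reference unknown participant ids")
  ord <- order(pid, ch$task, ch$alt)
  ch <- ch[ord, , drop = FALSE]
  pid <- pid[ord]
  n_alts <- 3L
  if (nrow(ch) %% n_alts != 0) stop("rows are not complete 3-alternative tasks")
  n_task <- nrow(ch) / n_alts
  tpos <- rep(seq_len(n_alts), n_task)
  f <- which(ch$chosen_first == 1)
  s <- which(ch$chosen_second == 1)
  if (length(f) != n_task || length(s) != n_task)
    stop("each task needs exactly one chosen_first and one chosen_second")
  first_pos <- tpos[f]
  second_pos <- tpos[s]
  if (any(first_pos == second_pos)) stop("chosen_first equals chosen_second in some task")
  Z <- code_matrix(scheme, ch[, attrs, drop = FALSE])
  C <- membership_covariates(parts)
  list(
    Z = Z, n = nrow(parts), n_task = n_task,
    part_of_task = pid[seq(1, nrow(ch), by = n_alts)],
    first_pos = first_pos, second_pos = second_pos,
    third_pos = 6L - first_pos - second_pos,
    C = C, scheme = scheme
  )
}

# cohort indicator: 1 for porters (or for the last factor level)
membership_covariates <- function(parts) {
  if (!"cohort" %in% names(parts)) return(matrix(0, nrow(parts), 0))
  if (all(parts$cohort %in% c("barworker", "porter"))) {
    m <- matrix(as.numeric(parts$cohort == "porter"), ncol = 1)
  } else {
    lv <- levels(factor(parts$cohort))
    m <- matrix(as.numeric(parts$cohort == lv[length(lv)]), ncol = 1)
  }
  colnames(m) <- "cohort"
  m
}

# class-membership log-probabilities, n x X, reference class X
log_membership <- function(gamma, C, X, n) {
  if (X == 1) return(matrix(0, n, 1))
  eta <- cbind(cbind(1, C) %*% t(gamma), 0)
  eta - apply(eta, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
}

# per-task ranking log-likelihood for one utility vector (length n_rows)
task_loglik <- function(u, prep) {
  U <- matrix(u, ncol = 3, byrow = TRUE)
  i <- seq_len(prep$n_task)
  m3 <- pmax(U[, 1], U[, 2], U[, 3])
  lse3 <- m3 + log(exp(U[, 1] - m3) + exp(U[, 2] - m3) + exp(U[, 3] - m3))
  u1 <- U[cbind(i, prep$first_pos)]
  u2 <- U[cbind(i, prep$second_pos)]
  u3 <- rowSums(U) - u1 - u2
  lse2 <- pmax(u2, u3) + log1p(exp(-abs(u2 - u3)))
  u1 - lse3 + u2 - lse2
}

# residual d(task loglik)/dU as a task x 3 matrix, flattened back to rows
task_residual <- function(u, prep) {
  U <- matrix(u, ncol = 3, byrow = TRUE)
  i <- seq_len(prep$n_task)
  m3 <- pmax(U[, 1], U[, 2], U[, 3])
  lse3 <- m3 + log(exp(U[, 1] - m3) + exp(U[, 2] - m3) + exp(U[, 3] - m3))
  u1 <- U[cbind(i, prep$first_pos)]
  u2 <- U[cbind(i, prep$second_pos)]
  u3 <- rowSums(U) - u1 - u2
  lse2 <- pmax(u2, u3) + log1p(exp(-abs(u2 - u3)))
  R <- -exp(U - lse3)
  R[cbind(i, prep$first_pos)] <- R[cbind(i, prep$first_pos)] + 1
  R[cbind(i, prep$second_pos)] <- R[cbind(i, prep$second_pos)] + 1 - exp(u2 - lse2)
  R[cbind(i, prep$third_pos)] <- R[cbind(i, prep$third_pos)] - exp(u3 - lse2)
  as.vector(t(R))
}

# conditional per-participant log-likelihoods for every (class, node)
# combination; returns n x (X * Q) matrix, column k = (x - 1) * Q + q
cll_all <- function(prep, beta, lambda, nodes) {
  X <- nrow(beta); Q <- nrow(nodes); D <- ncol(nodes)
  ZB <- prep$Z %*% t(beta)
  ZL <- if (D > 0) prep$Z %*% lambda else NULL
  out <- matrix(0, prep$n, X * Q)
  grp <- factor(prep$part_of_task, levels = seq_len(prep$n))
  for (x in seq_len(X)) {
    for (q in seq_len(Q)) {
      u <- ZB[, x]
      if (D > 0) u <- u + as.vector(ZL %*% nodes[q, ])
      tll <- task_loglik(u, prep)
      out[, (x - 1L) * Q + q] <- rowsum(tll, grp, reorder = FALSE)
    }
  }
  out
}

# marginal log-likelihood pieces: total loglik, per-participant loglik,
# and the posterior weights over (class, node) used by EM and by the
# Fisher-identity gradient
marginal_parts <- function(prep, params, grid) {
  X <- params$X; Q <- length(grid$weights)
  cll <- cll_all(prep, params$beta, params$lambda, grid$nodes)
  lp <- log_membership(params$gamma, prep$C, X, prep$n)
  lw <- log(grid$weights)
  A <- cll +
    lp[, rep(seq_len(X), each = Q), drop = FALSE] +
    matrix(rep(lw, X), prep$n, X * Q, byrow = TRUE)
  m <- apply(A, 1, max)
  ll_i <- m + log(rowSums(exp(A - m)))
  W <- exp(A - ll_i)
  list(loglik = sum(ll_i), ll_i = ll_i, W = W, cll = cll, log_pi = lp)
}

# gradient of sum_{i,x,q} W[i,(x,q)] * cll_i(x,q) with respect to the
# packed (beta, lambda) block, holding W fixed; also returns the value.
# By Fisher's identity this is the marginal-likelihood score when W is the
# posterior weight matrix.
weighted_cll_grad <- function(prep, beta, lambda, nodes, W, info) {
  X <- nrow(beta); Q <- nrow(nodes); D <- ncol(nodes)
  ZB <- prep$Z %*% t(beta)
  ZL <- if (D > 0) prep$Z %*% lambda else NULL
  gbeta <- matrix(0, X, info$P)
  glam <- vector("list", D)
  for (d in seq_len(D)) glam[[d]] <- numeric(length(info$lam_cols[[d]]))
  value <- 0
  grp <- factor(prep$part_of_task, levels = seq_len(prep$n))
  for (x in seq_len(X)) {
    for (q in seq_len(Q)) {
      k <- (x - 1L) * Q + q
      wi <- W[, k]
      if (all(wi == 0)) next
      u <- ZB[, x]
      if (D > 0) u <- u + as.vector(ZL %*% nodes[q, ])
      tll <- task_loglik(u, prep)
      wtask <- wi[prep$part_of_task]
      value <- value + sum(wtask * tll)
      r <- task_residual(u, prep)
      wrow <- rep(wtask, each = 3L)
      Acc <- crossprod(prep$Z, r * wrow)
      gbeta[x, ] <- gbeta[x, ] + Acc
      for (d in seq_len(D)) {
        glam[[d]] <- glam[[d]] + nodes[q, d] * Acc[info$lam_cols[[d]], 1]
      }
    }
  }
  list(value = value, gbeta = gbeta, glam = glam)
}

# gradient of sum_i sum_x w_ix log pi_x(c_i) in gamma (class X reference)
gamma_obj_grad <- function(gamma, C, Wx) {
  X <- ncol(Wx); n <- nrow(Wx)
  lp <- log_membership(gamma, C, X, n)
  Cmat <- cbind(1, C)
  resid <- Wx - exp(lp)
  g <- crossprod(resid[, -X, drop = FALSE], Cmat)  # (X-1) x (1 + n_cov)
  list(value = sum(Wx * lp), grad = g)
}

#' Conditional ranking log-likelihood for one participant
#'
#' Log-likelihood of a participant's rankings given class membership and
#' random-effect scores, with utilities
#' `eta_m = sum_p beta_xp z_mp + sum_d sum_p lambda_dp F_d z_mp`.
#'
#' @param params a `relcl_params`
#' @param dataset a `ranking_dataset`
#' @param participant a participant id present in the dataset
#' @param x class index in `1..X`
#' @param F numeric vector of `D` random-effect scores
#' @return log-likelihood (sum over the participant's tasks)
#' @export
conditional_loglik <- function(params, dataset, participant, x, F = numeric(0)) {
  if (length(F) != params$D) stop("F must have length D = ", params$D)
  if (!x %in% seq_len(params$X)) stop("class index out of range")
  ch <- dataset$choices
  ch <- ch[ch$participant == participant, , drop = FALSE]
  if (nrow(ch) == 0) stop("unknown participant: ", participant)
  ch <- ch[order(ch$task, ch$alt), , drop = FALSE]
  attrs <- names(params$scheme$attributes)
  Z <- code_matrix(params$scheme, ch[, attrs, drop = FALSE])
  coefs <- params$beta[x, ]
  if (params$D > 0) coefs <- coefs + as.vector(params$lambda %*% F)
  u <- as.vector(Z %*% coefs)
  total <- 0
  for (t0 in seq(1, nrow(ch), by = 3)) {
    rows <- t0:(t0 + 2)
    fpos <- which(ch$chosen_first[rows] == 1)
    spos <- which(ch$chosen_second[rows] == 1)
    total <- total + ranking_logprob(u[rows], fpos, spos)
  }
  total
}

#' Marginal log-likelihood of a ranking dataset
#'
#' Sums, over participants, the log of the class-membership-weighted
#' mixture of conditional ranking likelihoods, integrating the `D`
#' independent standard-normal random effects over the supplied grid
#' (Gauss-Hermite quadrature by default). All accumulation is done in log
#' space with log-sum-exp stabilization.
#'
#' @param params a `relcl_params`
#' @param dataset a `ranking_dataset`
#' @param grid integration grid from [gh_grid()] or [halton_grid()];
#'   defaults to `gh_grid(params$D)`
#' @return total log-likelihood (numeric scalar)
#' @export
marginal_loglik <- function(params, dataset, grid = NULL) {
  if (is.null(grid)) grid <- gh_grid(params$D)
  if (ncol(grid$nodes) != params$D) stop("grid dimension must equal D")
  prep <- prepare_choice_data(dataset, params$scheme)
  if (params$X > 1 && !is.null(params$gamma) &&
      ncol(params$gamma) != 1 + ncol(prep$C))
    stop("gamma has wrong number of covariate columns for this dataset")
  marginal_parts(prep, params, grid)$loglik
}
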