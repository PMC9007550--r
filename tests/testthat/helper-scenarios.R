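# Shared fixtures, built in code. Small sizes keep unit tests fast; the
# acceptance tests use the full study-scale conditions.

test_scheme <- function() default_scheme()

test_design <- function(scheme = test_scheme(), n_tasks = 12, n_blocks = 1,
                        seed = 42) {
  set.seed(seed)
  generate_design(scheme, n_tasks, n_blocks, 3)
}

test_dataset <- function(n = 50, X = 2, D = 1, seed = 7, separation = 1,
                         scheme = test_scheme(), design = NULL) {
  if (is.null(design)) design <- test_design(scheme, 12, 1, seed = seed + 1000)
  truth <- example_params(scheme, X = X, D = D, separation = separation)
  set.seed(seed)
  simulate_dataset(scheme, design, truth, n = n)
}

quick_config <- function(seed = 1, ...) {
  fit_config(em_iterations = 4, m_step_maxit = 10, newton_iterations = 80,
             n_starts = 2, tol = 1e-4, seed = seed, ...)
}

# Independent brute-force oracle for the conditional ranking
# log-likelihood: works on expanded per-level coefficients and explicit
# double summation, never touching the package's coding or engine code.
oracle_participant_loglik <- function(scheme, choices_i, beta_expanded,
                                      lambda_expanded, F) {
  L <- vapply(scheme$attributes, length, integer(1))
  offs <- c(0L, cumsum(L))
  attrs <- names(scheme$attributes)
  ch <- choices_i[order(choices_i$task, choices_i$alt), , drop = FALSE]
  total <- 0
  for (tk in unique(ch$task)) {
    rows <- ch[ch$task == tk, , drop = FALSE]
    u <- numeric(3)
    for (m in 1:3) {
      for (a in seq_along(attrs)) {
        p <- offs[a] + rows[[attrs[a]]][m]
        u[m] <- u[m] + beta_expanded[p]
        if (length(F) > 0) {
          for (d in seq_along(F)) {
            u[m] <- u[m] + lambda_expanded[p, d] * F[d]
          }
        }
      }
    }
    f <- which(rows$chosen_first == 1)
    s <- which(rows$chosen_second == 1)
    rest <- setdiff(1:3, f)
    pr <- exp(u[f]) / sum(exp(u)) * exp(u[s]) / sum(exp(u[rest]))
    total <- total + log(pr)
  }
  total
}

# align a fitted 2-class parameter set with the truth by best class
# permutation (on expanded beta) and per-domain loading sign
align_to_truth <- function(fit_params, truth) {
  exf <- expand_params(fit_params)
  ext <- expand_params(truth)
  X <- nrow(ext$beta)
  perms <- relcl:::all_permutations(X)
  err <- function(p) sum(abs(exf$beta[p, , drop = FALSE] - ext$beta))
  best <- perms[[which.min(vapply(perms, err, numeric(1)))]]
  beta <- exf$beta[best, , drop = FALSE]
  lambda <- exf$lambda
  for (d in seq_len(ncol(lambda))) {
    if (sum(abs(lambda[, d] - ext$lambda[, d])) >
        sum(abs(-lambda[, d] - ext$lambda[, d])))
      lambda[, d] <- -lambda[, d]
  }
  list(beta = beta, lambda = lambda, perm = unlist(best))
}
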