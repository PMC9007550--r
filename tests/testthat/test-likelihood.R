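test_that("ranking log-probabilities normalize and match direct arithmetic", {
  expect_equal(ranking_logprob(c(0, 0, 0), 1, 2), log(1 / 6))
  expect_equal(ranking_logprob(c(0, 0, 0), 3, 1), log(1 / 6))

  # direct-arithmetic oracle
  u <- c(1.0, 0.5, -0.2)
  expected <- exp(1) / (exp(1) + exp(0.5) + exp(-0.2)) *
    exp(0.5) / (exp(0.5) + exp(-0.2))
  expect_equal(ranking_logprob(u, 1, 2), log(expected), tolerance = 1e-12)

  # exp of the 6 ranking log-probabilities sums to 1
  set.seed(41)
  for (r in 1:100) {
    u <- rnorm(3, 0, 2)
    total <- 0
    for (f in 1:3) for (s in setdiff(1:3, f))
      total <- total + exp(ranking_logprob(u, f, s))
    expect_equal(total, 1, tolerance = 1e-10)
  }
  expect_error(ranking_logprob(c(0, 0, 0), 2, 2), "distinct")
  expect_error(ranking_logprob(c(0, 0), 1, 2), "3 finite")
})

test_that("conditional log-likelihood matches a brute-force oracle", {
  sch <- test_scheme()
  ds <- test_dataset(n = 4, X = 2, D = 2, seed = 43)
  truth <- ds$truth$params
  ex <- expand_params(truth)
  set.seed(44)
  for (i in c(1, 3)) {
    for (x in 1:2) {
      F <- rnorm(2)
      got <- conditional_loglik(truth, ds, i, x, F)
      want <- oracle_participant_loglik(
        sch, ds$choices[ds$choices$participant == i, ],
        ex$beta[x, ], ex$lambda, F)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("zero loadings make the conditional likelihood F-free", {
  sch <- test_scheme()
  ds <- test_dataset(n = 3, X = 2, D = 1, seed = 45)
  p0 <- relcl_params(sch, ds$truth$params$beta,
                     matrix(0, 11, 1), ds$truth$params$gamma)
  a <- conditional_loglik(p0, ds, 1, 1, 0.7)
  b <- conditional_loglik(p0, ds, 1, 1, -2.1)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("marginal likelihood nests the simpler models", {
  sch <- test_scheme()
  ds <- test_dataset(n = 10, X = 1, D = 0, seed = 46)
  beta <- example_params(sch, 1, 0)$beta

  # single class, no effects: marginal = sum of conditional logliks
  p1 <- relcl_params(sch, beta)
  direct <- sum(vapply(ds$participants$id, function(i)
    conditional_loglik(p1, ds, i, 1), numeric(1)))
  expect_equal(marginal_loglik(p1, ds, gh_grid(0)), direct, tolerance = 1e-10)

  # D = 0 with classes: plain latent class logit mixture
  p2 <- example_params(sch, 2, 0)
  prep <- relcl:::prepare_choice_data(ds, sch)
  lp <- relcl:::log_membership(p2$gamma, prep$C, 2, prep$n)
  cll <- sapply(1:2, function(x) vapply(ds$participants$id, function(i)
    conditional_loglik(p2, ds, i, x), numeric(1)))
  byhand <- sum(log(rowSums(exp(lp) * exp(cll))))
  expect_equal(marginal_loglik(p2, ds, gh_grid(0)), byhand, tolerance = 1e-8)
})

test_that("quadrature agrees with Monte-Carlo integration at D = 1", {
  sch <- test_scheme()
  ds <- test_dataset(n = 12, X = 1, D = 1, seed = 47)
  truth <- ds$truth$params
  ll_gh <- marginal_loglik(truth, ds, gh_grid(1, 15))
  set.seed(48)
  R <- 20000
  mc <- list(nodes = matrix(rnorm(R), R, 1), weights = rep(1 / R, R))
  ll_mc <- marginal_loglik(truth, ds, mc)
  expect_equal(ll_gh, ll_mc, tolerance = 0.05)
})

test_that("likelihood error decreases with quadrature precision", {
  # convergence oscillates at small node counts; along a refining
  # subsequence the error against a dense reference decreases weakly
  ds <- test_dataset(n = 8, X = 1, D = 1, seed = 49)
  truth <- ds$truth$params
  ref <- marginal_loglik(truth, ds, gh_grid(1, 101))
  errs <- vapply(c(5, 25, 51), function(k)
    abs(marginal_loglik(truth, ds, gh_grid(1, k)) - ref), numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
  expect_lt(errs[3], 0.01)
})

test_that("likelihood is invariant to class relabeling and loading signs", {
  sch <- test_scheme()
  ds <- test_dataset(n = 10, X = 2, D = 2, seed = 50)
  truth <- ds$truth$params
  grid <- gh_grid(2, 7)
  ll <- marginal_loglik(truth, ds, grid)

  # permute classes in (beta, gamma): gamma re-referenced exactly
  beta_p <- truth$beta[2:1, ]
  gamma_p <- -truth$gamma
  perm <- relcl_params(sch, beta_p, truth$lambda, gamma_p)
  expect_equal(marginal_loglik(perm, ds, grid), ll, tolerance = 1e-9)

  # negate one loading column: symmetric standard normal
  lam_f <- truth$lambda; lam_f[, 1] <- -lam_f[, 1]
  flip <- relcl_params(sch, truth$beta, lam_f, truth$gamma)
  expect_equal(marginal_loglik(flip, ds, grid), ll, tolerance = 1e-9)

  # conditional level: negate (lambda_d, F_d) jointly
  set.seed(51)
  F <- rnorm(2)
  a <- conditional_loglik(truth, ds, 1, 1, F)
  b <- conditional_loglik(flip, ds, 1, 1, c(-F[1], F[2]))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("parameter counts follow the free-parameter formula", {
  sch <- test_scheme()
  expect_equal(n_free_params(sch, 1, 0, 0), 11)
  expect_equal(n_free_params(sch, 8, 3, 1), 113)
  expect_equal(n_free_params(sch, 1, 2, 5), 11 + 6 + 2)
  # X = 1: no membership parameters regardless of covariates
  expect_equal(n_free_params(sch, 1, 0, 4), 11)
})

test_that("quadrature grids integrate standard-normal moments", {
  g <- gh_grid(2, 7)
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_equal(colSums(g$nodes * g$weights), c(0, 0), tolerance = 1e-10)
  expect_equal(colSums(g$nodes^2 * g$weights), c(1, 1), tolerance = 1e-8)
  h <- halton_grid(2, 5000)
  expect_equal(colMeans(h$nodes), c(0, 0), tolerance = 0.02)
  expect_equal(apply(h$nodes, 2, var), c(1, 1), tolerance = 0.05)
})
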