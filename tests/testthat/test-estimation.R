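test_that("random starts are reproducible and distinct", {
  sch <- test_scheme()
  set.seed(61); a <- init_params(sch, 2, 1)
  set.seed(61); b <- init_params(sch, 2, 1)
  expect_identical(a$beta, b$beta)
  thetas <- sapply(1:16, function(s) {
    set.seed(s)
    p <- init_params(sch, 2, 1)
    c(p$beta, p$lambda)
  })
  expect_equal(nrow(unique(t(thetas))), 16)
  p1 <- init_params(sch, 1, 0)
  expect_null(p1$gamma)
})

test_that("EM steps never decrease the marginal log-likelihood", {
  sch <- test_scheme()
  ds <- test_dataset(n = 60, X = 2, D = 1, seed = 62)
  grid <- gh_grid(1, 7)
  cfg <- fit_config(m_step_maxit = 5, seed = 1)
  set.seed(63)
  params <- init_params(sch, 2, 1)
  ll <- marginal_loglik(params, ds, grid)
  for (it in 1:15) {
    params <- em_step(params, ds, grid, cfg)
    ll_new <- marginal_loglik(params, ds, grid)
    expect_gte(ll_new, ll - 1e-8)
    ll <- ll_new
  }
  # near the optimum a step barely moves the log-likelihood
  f <- fit_relcl(ds, sch, 2, 1, quick_config(seed = 64))
  at_opt <- marginal_loglik(f$params, ds, grid)
  after <- marginal_loglik(em_step(f$params, ds, grid, cfg), ds, grid)
  expect_lt(after - at_opt, 0.05)
  expect_gte(after, at_opt - 1e-8)
})

test_that("single-class fit matches the conditional-logit oracle", {
  sch <- test_scheme()
  ds <- test_dataset(n = 80, X = 1, D = 0, seed = 65)
  cfg <- fit_config(em_iterations = 2, newton_iterations = 400, n_starts = 1,
                    seed = 66, order_constraint = FALSE, tol = 1e-9)
  f <- fit_relcl(ds, sch, 1, 0, cfg)

  # independent oracle: exploded strata + survival::clogit
  withr::local_package("survival")
  ch <- ds$choices[order(ds$choices$participant, ds$choices$task,
                         ds$choices$alt), ]
  Z <- code_matrix(sch, ch[, names(sch$attributes)])
  n_task <- nrow(ch) / 3
  rows1 <- seq_len(nrow(ch))
  keep2 <- ch$chosen_first == 0
  expl <- data.frame(
    event = c(ch$chosen_first, ch$chosen_second[keep2]),
    sid = c(rep(seq_len(n_task), each = 3),
            n_task + rep(seq_len(n_task), each = 3)[keep2])
  )
  Zx <- rbind(Z, Z[keep2, ])
  colnames(Zx) <- paste0("z", seq_len(ncol(Zx)))
  dat <- cbind(expl, Zx)
  fml <- stats::as.formula(paste(
    "event ~", paste(colnames(Zx), collapse = " + "), "+ strata(sid)"))
  or <- survival::clogit(fml, data = dat)
  expect_equal(unname(f$params$beta[1, ]), unname(coef(or)), tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(logLik(or)), tolerance = 1e-4)
})

test_that("canonicalization is idempotent and orients loadings", {
  sch <- test_scheme()
  p <- example_params(sch, 3, 2)
  # scramble: permute classes, flip a loading
  scr <- relcl_params(sch, p$beta[c(3, 1, 2), ], {
    l <- p$lambda; l[, 1] <- -l[, 1]; l
  }, matrix(c(0.5, -1, 0.2, 0.3), 2, 2))
  c1 <- canonicalize_params(scr, shares = c(0.2, 0.5, 0.3))
  c2 <- canonicalize_params(c1, shares = c(0.5, 0.3, 0.2))
  expect_equal(c1$beta, c2$beta, tolerance = 1e-12)
  expect_equal(c1$lambda, c2$lambda, tolerance = 1e-12)
  expect_equal(c1$gamma, c2$gamma, tolerance = 1e-12)
  ex <- expand_params(c1)
  for (d in 1:2) {
    top <- which.max(abs(ex$lambda[, d]))
    expect_gte(ex$lambda[top, d], 0)
  }
  # permuting classes leaves the membership probabilities intact
  pr0 <- exp(relcl:::log_membership(scr$gamma, matrix(0.5, 1, 1), 3, 1))
  pr1 <- exp(relcl:::log_membership(c1$gamma, matrix(0.5, 1, 1), 3, 1))
  expect_equal(sort(as.numeric(pr0)), sort(as.numeric(pr1)), tolerance = 1e-9)
})

test_that("degenerate inputs are handled", {
  sch <- test_scheme()
  ds <- test_dataset(n = 1, X = 1, D = 0, seed = 67)
  cfg <- fit_config(em_iterations = 2, newton_iterations = 30, n_starts = 1,
                    seed = 68)
  f <- fit_relcl(ds, sch, 1, 0, cfg)
  expect_s3_class(f, "relcl_fit")
  expect_true(is.finite(f$loglik))
})

test_that("the BIC grid covers all cells and flags the minimum", {
  sch <- test_scheme()
  ds <- test_dataset(n = 100, X = 2, D = 0, seed = 69)
  cfg <- fit_config(em_iterations = 3, newton_iterations = 40, n_starts = 1,
                    seed = 70)
  gr <- fit_grid(ds, sch, classes = 1:2, effects = 0, cfg)
  expect_equal(nrow(gr), 2)
  expect_equal(sum(gr$best), 1L)
  # nested models: loglik non-decreasing in X (up to optimizer noise)
  expect_gte(gr$loglik[gr$X == 2], gr$loglik[gr$X == 1] - 0.5)
  # BIC recomputes from its parts
  expect_equal(gr$bic, -2 * gr$loglik + gr$n_params * log(100), tolerance = 1e-8)

  # D = 0 cell equals a direct latent-class fit
  f2 <- fit_relcl(ds, sch, 2, 0, cfg)
  expect_equal(gr$loglik[gr$X == 2], f2$loglik, tolerance = 1e-6)
})

test_that("standard errors have plausible scale and coverage", {
  sch <- test_scheme()
  cfg <- fit_config(em_iterations = 2, newton_iterations = 300, n_starts = 1,
                    seed = 71, order_constraint = FALSE, tol = 1e-8,
                    compute_se = TRUE)
  truth <- example_params(sch, 1, 0)
  d <- test_design(sch, 12, 1, seed = 72)
  covered <- 0L; total <- 0L
  for (r in 1:5) {
    set.seed(100 + r)
    ds <- simulate_dataset(sch, d, truth, n = 150)
    f <- fit_relcl(ds, sch, 1, 0, cfg)
    expect_false(is.null(f$se))
    expect_true(all(f$se$beta > 0))
    hit <- abs(f$params$beta - truth$beta) <= 2 * f$se$beta
    covered <- covered + sum(hit); total <- total + length(hit)
  }
  expect_gte(covered / total, 0.85)
})
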