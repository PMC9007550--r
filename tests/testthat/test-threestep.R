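as_fit3 <- function(params, n_nodes = 7) {
  structure(list(params = params, X = params$X, D = params$D,
                 grid = gh_grid(params$D, n_nodes)),
            class = "relcl_fit")
}

test_that("with perfect classification the correction is a no-op", {
  set.seed(91)
  n <- 300
  cls <- sample(1:2, n, replace = TRUE)
  post <- structure(list(
    post = cbind(cls == 1, cls == 2) * 1,
    modal = cls, assigned = cls,
    class_error = diag(2), class_probs = diag(2), assign_probs = diag(2),
    F_hat = matrix(0, n, 0), F_sd = matrix(0, n, 0),
    shares = c(mean(cls == 1), mean(cls == 2)),
    X = 2, D = 0
  ), class = "relcl_posteriors")
  cov <- data.frame(z = rnorm(n))
  fitstub <- NULL  # fit object is not consulted by the step-3 regression
  corrected <- three_step_membership(fitstub, post, cov, correction = "ml")
  naive <- three_step_membership(fitstub, post, cov, correction = "none")
  expect_equal(corrected$coef, naive$coef, tolerance = 1e-6)
})

test_that("naive step-3 estimates match an off-the-shelf multinomial logit", {
  set.seed(92)
  n <- 500
  z <- rnorm(n)
  pr <- 1 / (1 + exp(-(0.2 + 0.8 * z)))
  cls <- 1L + rbinom(n, 1, pr)
  post <- structure(list(
    post = cbind(cls == 1, cls == 2) * 1, modal = cls, assigned = cls,
    class_error = diag(2), class_probs = diag(2), assign_probs = diag(2),
    F_hat = matrix(0, n, 0), F_sd = matrix(0, n, 0),
    shares = tabulate(cls, 2) / n, X = 2, D = 0
  ), class = "relcl_posteriors")
  cov <- data.frame(z = z)
  ours <- three_step_membership(NULL, post, cov, correction = "none")
  ref <- nnet::multinom(factor(cls) ~ z, trace = FALSE)
  expect_equal(unname(ours$coef["class2", ]), unname(coef(ref)),
               tolerance = 1e-3)
})

test_that("the bias adjustment undoes modal-assignment attenuation", {
  # weakly separated classes so that classification error is material
  sch <- test_scheme()
  d <- test_design(sch, 12, 1, seed = 93)
  base <- example_params(sch, 2, 0, separation = 0.3)
  truth <- relcl_params(sch, base$beta, NULL, matrix(c(0.2, 1.0), 1, 2))
  set.seed(94)
  ds <- simulate_dataset(sch, d, truth, n = 1200)
  post <- class_posteriors(as_fit3(truth), ds)
  expect_lt(mean(apply(post$post, 1, max)), 0.98)  # imperfect classification
  cov <- data.frame(cohort = as.numeric(ds$participants$cohort == "porter"))
  corrected <- three_step_membership(NULL, post, cov, correction = "ml")
  naive <- three_step_membership(NULL, post, cov, correction = "none")
  # membership model has reference class X (=2); step 3 reports against
  # class 1, so the simulated slope +1.0 for class 1 appears as -1.0
  slope_c <- -corrected$coef["class2", "cohort"]
  slope_n <- -naive$coef["class2", "cohort"]
  expect_lt(abs(slope_n), abs(slope_c))   # attenuation of the naive fit
  expect_equal(slope_c, 1.0, tolerance = 0.35)
})

test_that("no covariate effect yields corrected slopes near zero", {
  sch <- test_scheme()
  d <- test_design(sch, 12, 1, seed = 95)
  base <- example_params(sch, 2, 0, separation = 0.35)
  truth <- relcl_params(sch, base$beta, NULL, matrix(c(0.2, 0.0), 1, 2))
  inside <- 0L
  for (r in 1:10) {
    set.seed(200 + r)
    ds <- simulate_dataset(sch, d, truth, n = 300)
    post <- class_posteriors(as_fit3(truth), ds)
    cov <- data.frame(cohort = as.numeric(ds$participants$cohort == "porter"))
    ts <- three_step_membership(NULL, post, cov, correction = "ml")
    est <- ts$coef["class2", "cohort"]; se <- ts$se["class2", "cohort"]
    if (is.finite(se) && abs(est) <= 2 * se) inside <- inside + 1L
  }
  expect_gte(inside, 8L)
})

test_that("factor-score regressions behave as least squares", {
  set.seed(96)
  n <- 2000
  z <- rnorm(n)
  Fh <- cbind(0.5 * z + rnorm(n, 0, 0.3))
  post <- structure(list(
    post = matrix(1, n, 1), modal = rep(1L, n),
    class_error = diag(1), class_probs = diag(1),
    F_hat = Fh, F_sd = Fh * 0, shares = 1, X = 1, D = 1
  ), class = "relcl_posteriors")
  cov <- data.frame(z = z)
  out <- regress_factor_scores(post, cov)
  ct <- out$F1$coef_table
  expect_equal(unname(ct["z", "Estimate"]), 0.5, tolerance = 0.1)
  # residuals orthogonal to covariates
  expect_lt(abs(sum(resid(out$F1$model) * z)), 1e-8)

  # identically zero scores give zero coefficients
  post$F_hat <- Fh * 0
  out0 <- regress_factor_scores(post, cov)
  expect_equal(unname(out0$F1$coef_table[, "Estimate"]), c(0, 0),
               tolerance = 1e-12)
})
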