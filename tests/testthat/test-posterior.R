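# a fit-shaped wrapper around known parameters, for posterior analyses
# that only need (params, grid)
as_fit <- function(params, n_nodes = 7) {
  structure(list(params = params, X = params$X, D = params$D,
                 grid = gh_grid(params$D, n_nodes)),
            class = "relcl_fit")
}

test_that("posteriors normalize and degenerate cases behave", {
  sch <- test_scheme()
  ds <- test_dataset(n = 30, X = 2, D = 1, seed = 81)

  # X = 1: all posterior mass on the single class
  p1 <- example_params(sch, 1, 0)
  post1 <- class_posteriors(as_fit(p1), ds)
  expect_true(all(post1$post == 1))
  expect_true(all(post1$modal == 1))
  expect_equal(post1$class_error, matrix(1, 1, 1))

  # lambda = 0: posterior F scores collapse to the prior mean 0
  p0 <- relcl_params(sch, ds$truth$params$beta, matrix(0, 11, 1),
                     ds$truth$params$gamma)
  post0 <- class_posteriors(as_fit(p0), ds)
  expect_true(all(abs(post0$F_hat) < 1e-8))

  # general case: rows of posteriors and of the classification matrix sum to 1
  post <- class_posteriors(as_fit(ds$truth$params), ds)
  expect_equal(rowSums(post$post), rep(1, 30), tolerance = 1e-10)
  expect_equal(rowSums(post$class_error), rep(1, 2), tolerance = 1e-10)
  expect_equal(rowSums(post$class_probs), rep(1, 2), tolerance = 1e-10)
})

test_that("modal assignment recovers well-separated true classes", {
  ds <- test_dataset(n = 200, X = 2, D = 1, seed = 82)
  post <- class_posteriors(as_fit(ds$truth$params), ds)
  acc <- max(mean(post$modal == ds$truth$class),
             mean(3 - post$modal == ds$truth$class))
  expect_gte(acc, 0.9)
})

test_that("individual preference values respect the model structure", {
  sch <- test_scheme()
  ds <- test_dataset(n = 150, X = 2, D = 1, seed = 83)
  fit <- as_fit(ds$truth$params)
  post <- class_posteriors(fit, ds)
  prefs <- individual_preferences(fit, post)

  # per participant and attribute, expanded values sum to zero
  L <- scheme_n_levels(sch)
  offs <- c(0, cumsum(L))
  for (a in seq_along(L)) {
    block <- prefs$values[, (offs[a] + 1):offs[a + 1], drop = FALSE]
    expect_true(all(abs(rowSums(block)) < 1e-10))
  }

  # lambda = 0: every member of a class shares the class profile
  p0 <- relcl_params(sch, ds$truth$params$beta, matrix(0, 11, 1),
                     ds$truth$params$gamma)
  fit0 <- as_fit(p0)
  post0 <- class_posteriors(fit0, ds)
  prefs0 <- individual_preferences(fit0, post0)
  for (x in 1:2) {
    rows <- prefs0$values[post0$modal == x, , drop = FALSE]
    expect_lt(max(apply(rows, 2, stats::sd)), 1e-10)
  }

  # within-class spread ordered by |expanded loading| within each domain
  ex <- expand_params(ds$truth$params)
  sd_by_level <- apply(prefs$values[post$modal == 1, , drop = FALSE], 2, stats::sd)
  lam <- abs(ex$lambda[, 1])
  dom1 <- which(rep(unname(sch$domains), L) == 1)
  widest <- dom1[which.max(lam[dom1])]
  expect_equal(unname(which.max(sd_by_level[dom1])), which(dom1 == widest))
  expect_gt(stats::cor(sd_by_level[dom1], lam[dom1]), 0.9)
})

test_that("concordance matching recovers agreement structure", {
  # a labeling compared with itself is in perfect agreement
  set.seed(84)
  a <- sample(1:4, 2000, replace = TRUE)
  self <- class_concordance(a, a, 4)
  expect_equal(self$agreement, 1)
  expect_equal(self$permutation, 1:4)

  # independent labelings: chance-level agreement after matching
  b <- sample(1:4, 2000, replace = TRUE)
  indep <- class_concordance(a, b, 4)
  expect_lt(abs(indep$agreement - 0.25), 0.05)

  # margins equal each labeling's class sizes
  expect_equal(as.integer(rowSums(indep$tab)), as.integer(table(factor(a, 1:4))))
  expect_equal(as.integer(colSums(indep$tab)), as.integer(table(factor(b, 1:4))))

  # matching undoes a deliberate relabeling
  perm <- c(3, 1, 4, 2)
  expect_equal(class_concordance(a, perm[a], 4)$agreement, 1)
})

test_that("aggregate vs cohort-specific fits agree on separated classes", {
  sch <- test_scheme()
  ds <- test_dataset(n = 120, X = 2, D = 0, seed = 85)
  truth <- ds$truth$params
  fit_all <- as_fit(truth)
  # cohort-specific "fits" share the measurement model here; the test
  # targets the matching/cross-tab machinery
  group <- ds$participants$cohort
  fits_by <- list(barworker = fit_all, porter = fit_all)
  cc <- concordance(fit_all, fits_by, ds, group)
  expect_equal(cc$agreement, 1)
  expect_equal(sum(cc$by_group$barworker$tab),
               sum(group == "barworker"))
})
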