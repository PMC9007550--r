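test_that("participant tables follow the configured marginals", {
  set.seed(21)
  p <- draw_participants(740)
  expect_equal(nrow(p), 740)
  expect_equal(as.integer(table(p$cohort)), c(300L, 440L))
  expect_true(all(p$age >= 18 & p$age <= 49))
  expect_true(all(!is.na(p$testing)))
  expect_equal(as.integer(table(p$block)), rep(74L, 10))

  p1 <- draw_participants(1)
  expect_equal(nrow(p1), 1)
  expect_false(anyNA(p1))
})

test_that("class assignment follows the multinomial-logit membership model", {
  set.seed(22)
  p <- draw_participants(10000)
  # zero coefficients: uniform shares
  cls <- assign_classes(p, matrix(0, 3, 2))
  shares <- table(cls) / 10000
  expect_true(all(abs(shares - 0.25) <= 0.02))

  # a huge intercept concentrates membership
  g <- matrix(c(20, 0, 0, 0, 0, 0), 3, 2)
  cls2 <- assign_classes(p, g)
  expect_true(mean(cls2 == 1) > 0.999)

  # nonzero cohort slope: cohort-specific shares match the closed form
  g3 <- matrix(c(0.4, -0.8), 1, 2)
  cls3 <- assign_classes(p, g3)
  for (co in c("barworker", "porter")) {
    z <- as.numeric(co == "porter")
    expected <- exp(0.4 - 0.8 * z) / (1 + exp(0.4 - 0.8 * z))
    got <- mean(cls3[p$cohort == co] == 1)
    expect_equal(got, expected, tolerance = 0.03)
  }
})

test_that("simulated rankings follow the exploded-logit distribution", {
  set.seed(23)
  draws <- replicate(10000, simulate_ranking(c(0, 0, 0)))
  freq <- table(paste(draws[1, ], draws[2, ])) / 10000
  expect_equal(length(freq), 6)
  expect_true(all(abs(freq - 1 / 6) <= 0.02))

  # dominance limit
  set.seed(24)
  dom <- replicate(200, simulate_ranking(c(10, 0, -10)))
  expect_true(mean(dom[1, ] == 1 & dom[2, ] == 2) > 0.99)

  # arbitrary utilities: empirical frequencies match the closed form
  u <- c(0.8, -0.3, 0.1)
  set.seed(25)
  draws <- replicate(20000, simulate_ranking(u))
  for (f in 1:3) {
    for (s in setdiff(1:3, f)) {
      rest <- setdiff(1:3, f)
      p_exp <- exp(u[f]) / sum(exp(u)) * exp(u[s]) / sum(exp(u[rest]))
      p_obs <- mean(draws[1, ] == f & draws[2, ] == s)
      expect_lt(abs(p_obs - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / 20000) + 1e-4)
    }
  }
  expect_error(simulate_ranking(c(1, NA, 0)), "finite")
})

test_that("simulated datasets have exact exploded counts and are reproducible", {
  sch <- test_scheme()
  d <- test_design(sch, 12, 1)
  truth <- example_params(sch, 2, 1)
  set.seed(26); ds1 <- simulate_dataset(sch, d, truth, n = 40)
  expect_equal(n_rankings(ds1), 40 * 12)
  expect_equal(n_choice_records(ds1), 2 * 40 * 12)
  expect_true(all(ds1$choices$chosen_first + ds1$choices$chosen_second <= 1))
  set.seed(26); ds2 <- simulate_dataset(sch, d, truth, n = 40)
  expect_identical(ds1$choices, ds2$choices)
  expect_identical(ds1$truth$F, ds2$truth$F)
})

test_that("random-effect scores are independent standard normals", {
  sch <- test_scheme()
  d <- test_design(sch, 2, 1, seed = 30)  # minimal design; F draws are the target
  truth <- example_params(sch, 1, 3)
  set.seed(31)
  ds <- simulate_dataset(sch, d, truth, n = 10000)
  Fm <- ds$truth$F
  expect_true(all(abs(colMeans(Fm)) <= 0.03))
  expect_true(all(abs(apply(Fm, 2, var) - 1) <= 0.05))
  cc <- cor(Fm)
  expect_true(all(abs(cc[upper.tri(cc)]) <= 0.03))
})

test_that("true parameters beat perturbed parameters in likelihood", {
  sch <- test_scheme()
  d <- test_design(sch, 12, 1, seed = 33)
  truth <- example_params(sch, 2, 1)
  grid <- gh_grid(1, 7)
  wins <- 0L
  set.seed(34)
  for (r in 1:20) {
    ds <- simulate_dataset(sch, d, truth, n = 60)
    pert <- relcl_params(
      sch,
      truth$beta + matrix(rnorm(length(truth$beta), 0, 0.5), nrow = 2),
      truth$lambda, truth$gamma
    )
    if (marginal_loglik(truth, ds, grid) > marginal_loglik(pert, ds, grid))
      wins <- wins + 1L
  }
  expect_gte(wins, 19)
})
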