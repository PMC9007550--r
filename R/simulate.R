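#' Default covariate configuration for the synthetic cohort
#'
#' Marginal distributions for the simulated participants, patterned on the
#' two study populations (female barworkers and male mountain porters):
#' cohort counts 300/440, cohort-specific age means/SDs (truncated to
#' 18-49), marriage and secondary-education proportions, and HIV-testing
#' history (never / once / more than once). Covariates are drawn
#' independently from their cohort-specific marginals.
#'
#' @return a list understood by [draw_participants()]
#' @export
default_covariate_config <- function() {
  list(
    cohort_counts = c(barworker = 300, porter = 440),
    age = list(barworker = c(mean = 29.7, sd = 7.61),
               porter = c(mean = 31.4, sd = 6.71)),
    age_range = c(18, 49),
    married = c(barworker = 0.318, porter = 0.656),
    secondary = c(barworker = 0.579, porter = 0.446),
    # never / once / more than once, per cohort
    testing = list(barworker = c(never = 0.053, once = 0.137, more = 0.810),
                   porter = c(never = 0.200, once = 0.200, more = 0.600)),
    block_assignment = "round_robin"
  )
}

#' Draw a synthetic participant table
#'
#' @param n number of participants; if `n` equals the sum of
#'   `config$cohort_counts` the cohort sizes are exact, otherwise cohorts
#'   are drawn with the configured proportions.
#' @param config covariate configuration, see [default_covariate_config()]
#' @param n_blocks number of design blocks to assign participants to
#' @return data frame with columns `id`, `cohort`, `age`, `secondary`,
#'   `married`, `testing`, `block`
#' @export
draw_participants <- function(n, config = default_covariate_config(),
                              n_blocks = 10) {
  stopifnot(n >= 1)
  cc <- config$cohort_counts
  if (is.null(cc) || length(cc) != 2)
    stop("config$cohort_counts must give two cohort counts")
  if (sum(cc) == n) {
    cohort <- sample(rep(names(cc), cc))
  } else {
    cohort <- sample(names(cc), n, replace = TRUE, prob = cc / sum(cc))
  }
  rng_trunc_norm <- function(k, mean, sd, lo, hi) {
    x <- stats::rnorm(k, mean, sd)
    bad <- x < lo | x > hi
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- x < lo | x > hi
    }
    x
  }
  age <- numeric(n); married <- integer(n); secondary <- integer(n)
  testing <- character(n)
  for (co in names(cc)) {
    idx <- which(cohort == co)
    if (!length(idx)) next
    a <- config$age[[co]]
    age[idx] <- round(rng_trunc_norm(length(idx), a["mean"], a["sd"],
                                     config$age_range[1], config$age_range[2]))
    married[idx] <- stats::rbinom(length(idx), 1, config$married[[co]])
    secondary[idx] <- stats::rbinom(length(idx), 1, config$secondary[[co]])
    p <- config$testing[[co]]
    testing[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
  }
  block <- switch(config$block_assignment %||% "round_robin",
    round_robin = rep(seq_len(n_blocks), length.out = n),
    uniform = sample.int(n_blocks, n, replace = TRUE),
    stop("unknown block_assignment: ", config$block_assignment)
  )
  data.frame(
    id = seq_len(n), cohort = cohort, age = age,
    secondary = secondary, married = married,
    testing = factor(testing, levels = c("never", "once", "more")),
    block = block, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign latent classes from the membership model
#'
#' Draws each participant's latent class from the multinomial-logit
#' membership probabilities given the cohort indicator, with class `X` as
#' the reference (zero coefficients).
#'
#' @param participants participant table with a `cohort` column
#' @param gamma `(X - 1) x 2` matrix of (intercept, cohort slope)
#'   membership coefficients; a single class results from a 0-row matrix
#' @return integer vector of class labels in `1..X`
#' @export
assign_classes <- function(participants, gamma) {
  gamma <- as.matrix(gamma)
  X <- nrow(gamma) + 1L
  if (X == 1) return(rep(1L, nrow(participants)))
  C <- membership_covariates(participants)
  if (ncol(gamma) != 1 + ncol(C))
    stop("gamma must have 1 + n_cov columns")
  lp <- log_membership(gamma, C, X, nrow(participants))
  pr <- exp(lp)
  vapply(seq_len(nrow(pr)),
         function(i) sample.int(X, 1, prob = pr[i, ]), integer(1))
}

#' Simulate a ranked (best, second-best) response
#'
#' The best of three alternatives is drawn with logit probabilities over
#' the three utilities; the second-best is drawn with logit probabilities
#' over the two remaining alternatives using the same utilities. Gumbel
#' errors are never drawn explicitly; the noise is implicit in the logit
#' draws, matching the exploded-logit likelihood.
#'
#' @param utilities numeric vector of 3 finite utilities
#' @return integer vector `c(first, second)`
#' @export
simulate_ranking <- function(utilities) {
  if (length(utilities) != 3 || any(!is.finite(utilities)))
    stop("utilities must be 3 finite values")
  p3 <- exp(utilities - max(utilities)); p3 <- p3 / sum(p3)
  first <- sample.int(3, 1, prob = p3)
  rest <- setdiff(1:3, first)
  u2 <- utilities[rest]
  p2 <- exp(u2 - max(u2)); p2 <- p2 / sum(p2)
  second <- rest[sample.int(2, 1, prob = p2)]
  c(first = first, second = second)
}

#' Simulate a full ranking dataset from a RELCL model
#'
#' For each participant: a latent class is drawn from the membership model
#' given cohort; `D` independent standard-normal random-effect scores are
#' drawn; the participant's design block is task- and alternative-order
#' randomized; utilities are computed from the effects-coded alternatives
#' via the class coefficients and loadings; and each task's ranking is
#' simulated sequentially.
#'
#' @param scheme an `attribute_scheme`
#' @param design a `choice_design` covering the participants' blocks
#' @param params generating `relcl_params`
#' @param participants participant table from [draw_participants()]; or
#'   `NULL` to draw `n` participants with `covariate_config`
#' @param n number of participants when `participants` is `NULL`
#' @param covariate_config see [default_covariate_config()]
#' @return a `ranking_dataset`: list with `choices` (long data frame, one
#'   row per participant x task x alternative with `chosen_first` /
#'   `chosen_second` flags), `participants`, and `truth` (per-participant
#'   class and random-effect scores plus the generating parameters)
#' @export
simulate_dataset <- function(scheme, design, params, participants = NULL,
                             n = NULL, covariate_config = default_covariate_config()) {
  if (is.null(participants)) {
    if (is.null(n)) stop("give either participants or n")
    participants <- draw_participants(n, covariate_config,
                                      n_blocks = attr(design, "n_blocks") %||%
                                        length(unique(design$block)))
  }
  n <- nrow(participants)
  X <- params$X; D <- params$D
  gamma <- if (X > 1) params$gamma else matrix(0, 0, 2)
  cls <- assign_classes(participants, gamma)
  Fm <- matrix(stats::rnorm(n * D), n, D)
  attrs <- names(scheme$attributes)
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    pres <- randomize_for_participant(design, participants$block[i])
    Z <- code_matrix(scheme, pres[, attrs, drop = FALSE])
    coefs <- params$beta[cls[i], ]
    if (D > 0) coefs <- coefs + as.vector(params$lambda %*% Fm[i, ])
    u <- as.vector(Z %*% coefs)
    n_task <- nrow(pres) / 3L
    cf <- integer(nrow(pres)); cs <- integer(nrow(pres))
    for (t in seq_len(n_task)) {
      rows <- (t - 1L) * 3L + 1:3
      r <- simulate_ranking(u[rows])
      cf[rows[r[1]]] <- 1L
      cs[rows[r[2]]] <- 1L
    }
    pieces[[i]] <- data.frame(
      participant = participants$id[i],
      block = pres$block,
      task = rep(seq_len(n_task), each = 3L),
      design_task = pres$task,
      alt = pres$alt,
      pres[, attrs, drop = FALSE],
      chosen_first = cf, chosen_second = cs,
      row.names = NULL
    )
  }
  choices <- do.call(rbind, pieces)
  structure(
    list(choices = choices, participants = participants,
         truth = list(class = cls, F = Fm, params = params)),
    class = "ranking_dataset"
  )
}

#' @export
print.ranking_dataset <- function(x, ...) {
  cat(sprintf("Ranking dataset: %d participants, %d rankings, %d exploded choices\n",
              nrow(x$participants), n_rankings(x), n_choice_records(x)))
  invisible(x)
}

#' Counting helpers for ranking datasets
#'
#' A ranking of 3 alternatives contributes one best choice (from 3) and
#' one second-best choice (from 2), so the exploded data contain exactly
#' two choice records per ranking.
#'
#' @param dataset a `ranking_dataset`
#' @return integer count
#' @export
n_rankings <- function(dataset) nrow(dataset$choices) / 3L

#' @rdname n_rankings
#' @export
n_choice_records <- function(dataset) 2L * n_rankings(dataset)

#' Deterministic example parameters for simulation studies
#'
#' Fixed, well-separated class profiles on the default attribute scheme
#' (up to 3 classes), with domain-masked loadings whose largest-magnitude
#' expanded entries are positive (the canonical orientation). `separation`
#' scales the class-specific utility weights; loadings and membership
#' coefficients are fixed.
#'
#' @param scheme the default scheme (other schemes are not supported here)
#' @param X number of classes (1..3)
#' @param D number of random effects (0..3)
#' @param separation multiplier on the class utility weights (default 1)
#' @return a `relcl_params`
#' @export
example_params <- function(scheme = default_scheme(), X = 2, D = 1,
                           separation = 1) {
  if (scheme_n_contrasts(scheme) != 11)
    stop("example_params is defined for the default 11-contrast scheme")
  if (!X %in% 1:3) stop("X must be 1..3 for example_params")
  base <- rbind(
    c(-1.0, 1.2,  -0.4,  0.8, -0.2,  -0.8, 0.5,   0.3, -0.3, -0.2, -0.5),
    c( 1.0, -0.8, -0.1, -0.7, 0.9,   -0.2, -0.3, -0.6, 0.4,  0.3,  0.4),
    c( 0.0, -1.0, -0.8,  0.1, -0.9,   0.9, -0.4,  0.8, -0.7, 0.5, -0.1)
  )
  beta <- separation * base[seq_len(X), , drop = FALSE]
  lambda <- NULL
  if (D > 0) {
    lambda <- matrix(0, 11, D)
    lam_full <- cbind(
      c(0.2, -0.1, 0, 0, 0, 0, 0, -0.7, -0.2, -0.8, -0.1),  # domain 1
      c(0, 0, 0, -0.9, -0.1, 0, 0, 0, 0, 0, 0),             # domain 2
      c(0, 0, 0.4, 0, 0, 0.0, 0.4, 0, 0, 0, 0)              # domain 3
    )
    lambda <- lam_full[, seq_len(D), drop = FALSE]
  }
  gamma <- NULL
  if (X > 1) {
    gam_full <- rbind(c(0.3, 0.5), c(-0.2, 0.4))
    gamma <- gam_full[seq_len(X - 1), , drop = FALSE]
  }
  relcl_params(scheme, beta, lambda, gamma)
}
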