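#' Bias-adjusted three-step covariate analysis of class membership
#'
#' Step 1 is the fitted measurement model (the RELCL fit), step 2 assigns
#' each participant to the modal posterior class, and step 3 regresses the
#' assigned class on covariates while treating the assignment as an
#' error-prone indicator of the true class with known misclassification
#' rates (the maximum-likelihood variant of the bias-adjusted three-step
#' approach). The step-3 likelihood is
#' `sum_i log sum_x pi_x(c_i; gamma) P(assigned_i | true = x)`,
#' with the `P(assigned | true)` matrix estimated from the posteriors.
#' Ignoring the correction (`correction = "none"`) gives the naive
#' multinomial logit on the modal assignment, which is attenuated toward
#' zero when classification is imperfect.
#'
#' Class assignment and misclassification rates come from the
#' measurement-only posterior (marginal class shares as prior), so the
#' classification error is covariate-independent; see [class_posteriors()].
#'
#' @param fit a `relcl_fit`
#' @param posteriors output of [class_posteriors()]
#' @param covariates data frame of numeric covariates (one row per
#'   participant, no intercept column)
#' @param correction `"ml"` (bias-adjusted, default) or `"none"` (naive)
#' @return a `threestep_fit`: `coef` and `se` matrices ((X - 1) x (1 +
#'   n_cov), class 1 is the reference), `vcov`, `loglik`, `converged`,
#'   `correction`.
#' @export
three_step_membership <- function(fit, posteriors, covariates,
                                  correction = c("ml", "none")) {
  correction <- match.arg(correction)
  X <- posteriors$X
  if (X < 2) stop("three-step analysis needs at least 2 classes")
  W <- posteriors$assigned
  M <- posteriors$assign_probs          # P(assigned = j | true = x)
  if (correction == "none") {
    M <- diag(X)
  } else if (abs(det(M)) < 1e-10) {
    warning("classification matrix is singular; falling back to the uncorrected logit")
    M <- diag(X)
    correction <- "none"
  }
  Cmat <- cbind(`(intercept)` = 1, as.matrix(covariates))
  k <- ncol(Cmat)
  n <- nrow(Cmat)
  stopifnot(n == length(W))

  # reference class 1: gamma rows for classes 2..X
  negll <- function(v) {
    g <- matrix(v, X - 1, k, byrow = TRUE)
    eta <- cbind(0, Cmat %*% t(g))              # n x X
    m <- apply(eta, 1, max)
    lpi <- eta - (m + log(rowSums(exp(eta - m))))
    # P(W_i) = sum_x pi_x M[x, W_i]
    -sum(log(rowSums(exp(lpi) * t(M)[W, , drop = FALSE])))
  }
  grad <- function(v) {
    g <- matrix(v, X - 1, k, byrow = TRUE)
    eta <- cbind(0, Cmat %*% t(g))
    m <- apply(eta, 1, max)
    pi_ <- exp(eta - (m + log(rowSums(exp(eta - m)))))
    num <- pi_ * t(M)[W, , drop = FALSE]        # pi_x * P(W_i | x)
    u <- num / rowSums(num)                     # posterior of true class
    resid <- u - pi_
    -as.numeric(t(crossprod(resid[, -1, drop = FALSE], Cmat)))
  }
  v0 <- numeric((X - 1) * k)
  opt <- stats::optim(v0, negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  coef <- matrix(opt$par, X - 1, k, byrow = TRUE,
                 dimnames = list(paste0("class", 2:X), colnames(Cmat)))
  H <- pracma::hessian(negll, opt$par)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(v0), length(v0)))
  se <- matrix(sqrt(pmax(diag(V), 0)), X - 1, k, byrow = TRUE,
               dimnames = dimnames(coef))
  structure(list(coef = coef, se = se, vcov = V, loglik = -opt$value,
                 converged = opt$convergence == 0, correction = correction),
            class = "threestep_fit")
}

#' @export
print.threestep_fit <- function(x, ...) {
  cat("Three-step class-membership model (",
      if (x$correction == "ml") "bias-adjusted" else "naive", ")\n", sep = "")
  print(round(x$coef, 3))
  invisible(x)
}

#' Linear regression of posterior random-effect scores on covariates
#'
#' One least-squares fit per random effect: posterior-mean score on the
#' covariate set, with coefficients and standard errors.
#'
#' @param posteriors output of [class_posteriors()]
#' @param covariates data frame of numeric covariates
#' @return list of per-effect coefficient tables (estimate, se, t, p);
#'   collinear covariates are dropped by `lm` and reported as `NA`.
#' @export
regress_factor_scores <- function(posteriors, covariates) {
  D <- posteriors$D
  if (D == 0) return(list())
  out <- vector("list", D)
  for (d in seq_len(D)) {
    df <- data.frame(score = posteriors$F_hat[, d], covariates)
    fit <- stats::lm(score ~ ., data = df)
    ct <- summary(fit)$coefficients
    al <- stats::coef(fit)
    if (anyNA(al)) {
      dropped <- names(al)[is.na(al)]
      warning("collinear covariates dropped for effect ", d, ": ",
              paste(dropped, collapse = ", "))
    }
    out[[d]] <- list(coef_table = ct, model = fit)
  }
  names(out) <- paste0("F", seq_len(D))
  out
}
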