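#' RELCL parameter container
#'
#' Holds the parameters of a random effects latent class logit model in the
#' free-contrast parameterization:
#' * `beta`: `X x P` matrix of class-specific utility weights, one column
#'   per free effects-coded contrast (`P = scheme_n_contrasts(scheme)`);
#' * `lambda`: `P x D` matrix of loadings relating each of `D` independent
#'   standard-normal individual random effects to the contrasts. Loadings
#'   are domain-masked: `lambda[p, d]` is fixed at 0 unless contrast `p`
#'   belongs to an attribute assigned to domain `d`;
#' * `gamma`: `(X - 1) x (1 + n_cov)` matrix of multinomial-logit class
#'   membership coefficients (intercept plus covariate slopes), with class
#'   `X` as the reference (its coefficients are identically zero). `NULL`
#'   when `X = 1`.
#'
#' @param scheme an `attribute_scheme`
#' @param beta numeric `X x P` matrix
#' @param lambda numeric `P x D` matrix (or `NULL` for `D = 0`); entries
#'   outside the domain mask must be zero
#' @param gamma numeric `(X - 1) x (1 + n_cov)` matrix or `NULL`
#' @return an object of class `relcl_params`
#' @export
relcl_params <- function(scheme, beta, lambda = NULL, gamma = NULL) {
  P <- scheme_n_contrasts(scheme)
  beta <- as.matrix(beta)
  if (ncol(beta) != P) stop("beta must have ", P, " columns")
  X <- nrow(beta)
  if (is.null(lambda)) lambda <- matrix(0, P, 0)
  lambda <- as.matrix(lambda)
  if (nrow(lambda) != P) stop("lambda must have ", P, " rows")
  D <- ncol(lambda)
  for (d in seq_len(D)) {
    mask <- domain_cols(scheme, d)
    off <- setdiff(seq_len(P), mask)
    if (any(lambda[off, d] != 0))
      stop("lambda has nonzero loadings outside domain ", d, "'s attributes")
  }
  if (X > 1) {
    if (is.null(gamma)) stop("gamma required when X > 1")
    gamma <- as.matrix(gamma)
    if (nrow(gamma) != X - 1) stop("gamma must have X - 1 rows")
  } else {
    gamma <- NULL
  }
  structure(list(beta = beta, lambda = lambda, gamma = gamma,
                 X = X, D = D, scheme = scheme),
            class = "relcl_params")
}

#' @export
print.relcl_params <- function(x, ...) {
  cat(sprintf("RELCL parameters: %d class(es), %d random effect(s), %d contrasts\n",
              x$X, x$D, ncol(x$beta)))
  invisible(x)
}

#' Expanded per-level coefficients
#'
#' Expands the free-contrast `beta` (per class) or `lambda` (per domain) to
#' the full per-level coefficient vectors, which sum to zero within each
#' attribute.
#'
#' @param params a `relcl_params`
#' @return `expand_params` returns a list with `beta` (`X x total_levels`)
#'   and `lambda` (`total_levels x D`), with named columns/rows.
#' @export
expand_params <- function(params) {
  E <- expansion_matrix(params$scheme)
  nm <- expanded_names(params$scheme)
  eb <- params$beta %*% t(E)
  colnames(eb) <- nm
  el <- E %*% params$lambda
  rownames(el) <- nm
  list(beta = eb, lambda = el)
}

# --- packing for optimization ------------------------------------------

# The packed vector is c(vec(beta) by class-major rows, free lambda entries
# domain by domain, vec(gamma) by class-major rows). The index map is
# recomputed cheaply from (scheme, X, D, n_cov).
pack_info <- function(scheme, X, D, n_cov) {
  P <- scheme_n_contrasts(scheme)
  lam_cols <- lapply(seq_len(D), function(d) domain_cols(scheme, d))
  n_lam <- sum(lengths(lam_cols))
  n_gam <- if (X > 1) (X - 1L) * (1L + n_cov) else 0L
  list(P = P, X = X, D = D, n_cov = n_cov, lam_cols = lam_cols,
       n_beta = X * P, n_lam = n_lam, n_gam = n_gam,
       n_total = X * P + n_lam + n_gam)
}

pack_params <- function(params, info) {
  th <- as.numeric(t(params$beta))
  for (d in seq_len(info$D)) th <- c(th, params$lambda[info$lam_cols[[d]], d])
  if (info$X > 1) th <- c(th, as.numeric(t(params$gamma)))
  th
}

unpack_params <- function(theta, scheme, info) {
  P <- info$P
  beta <- matrix(theta[seq_len(info$n_beta)], info$X, P, byrow = TRUE)
  lambda <- matrix(0, P, info$D)
  off <- info$n_beta
  for (d in seq_len(info$D)) {
    cols <- info$lam_cols[[d]]
    lambda[cols, d] <- theta[off + seq_along(cols)]
    off <- off + length(cols)
  }
  gamma <- NULL
  if (info$X > 1) {
    gamma <- matrix(theta[off + seq_len(info$n_gam)], info$X - 1L,
                    1L + info$n_cov, byrow = TRUE)
  }
  relcl_params(scheme, beta, lambda, gamma)
}

# Box bounds implementing the monotone constraint on ordered two-level
# attributes: the first level's contrast (the less preferred level) is
# kept <= 0 in every class. Loadings and gamma are unconstrained.
order_bounds <- function(scheme, info, order_constraint = TRUE) {
  lo <- rep(-Inf, info$n_total)
  hi <- rep(Inf, info$n_total)
  if (order_constraint) {
    cc <- contrast_cols(scheme)
    L <- scheme_n_levels(scheme)
    for (a in seq_along(cc)) {
      if (scheme$ordered[[a]] && L[a] == 2L) {
        for (x in seq_len(info$X)) {
          hi[(x - 1L) * info$P + cc[[a]][1]] <- 0
        }
      }
    }
  }
  list(lower = lo, upper = hi)
}

#' Count the free parameters of a RELCL specification
#'
#' `X * sum(L_a - 1)` class-specific utility weights, plus the free
#' loadings of the first `D` domains (`sum(L_a - 1)` over the attributes in
#' each used domain), plus `(X - 1) * (1 + n_cov)` class-membership
#' coefficients.
#'
#' @param scheme an `attribute_scheme`
#' @param X number of latent classes
#' @param D number of random effects (domains used, in index order)
#' @param n_cov number of covariates in the class-membership model
#' @return integer parameter count
#' @examples
#' n_free_params(default_scheme(), X = 8, D = 3, n_cov = 1)  # 113
#' @export
n_free_params <- function(scheme, X, D, n_cov = 0) {
  P <- scheme_n_contrasts(scheme)
  n_lam <- if (D > 0) sum(lengths(lapply(seq_len(D), function(d) domain_cols(scheme, d)))) else 0L
  X * P + n_lam + if (X > 1) (X - 1L) * (1L + n_cov) else 0L
}

#' Canonicalize a parameter set
#'
#' Fixes the label-switching and sign indeterminacies of the RELCL model:
#' classes are reordered by decreasing share (ties broken by the first beta
#' contrast), and each random effect's loading vector is negated if its
#' largest-magnitude expanded loading is negative (the random effect's sign
#' is arbitrary because its distribution is symmetric). `gamma` is
#' re-expressed against the new reference class; this is exact because
#' multinomial-logit coefficients transform by subtraction.
#'
#' @param params a `relcl_params`
#' @param shares numeric vector of class shares used for ordering (e.g.,
#'   mean posterior class probabilities); defaults to prior shares at the
#'   covariate value 0.
#' @return a canonicalized `relcl_params`
#' @export
canonicalize_params <- function(params, shares = NULL) {
  X <- params$X
  if (is.null(shares)) {
    eta <- c(if (X > 1) params$gamma[, 1] else numeric(0), 0)
    shares <- exp(eta - max(eta)); shares <- shares / sum(shares)
  }
  ord <- order(-shares, params$beta[, 1])
  beta <- params$beta[ord, , drop = FALSE]
  gamma <- params$gamma
  if (X > 1) {
    # per-class linear predictors (rows 1..X, reference X = 0), permute,
    # then re-reference against the new last class
    full <- rbind(gamma, 0)[ord, , drop = FALSE]
    gamma <- sweep(full, 2, full[X, ], "-")[-X, , drop = FALSE]
  }
  lambda <- params$lambda
  if (params$D > 0) {
    E <- expansion_matrix(params$scheme)
    el <- E %*% lambda
    for (d in seq_len(params$D)) {
      top <- which.max(abs(el[, d]))
      if (el[top, d] < 0) lambda[, d] <- -lambda[, d]
    }
  }
  relcl_params(params$scheme, beta, lambda, gamma)
}

#' Serialize parameters to JSON
#'
#' Writes the expanded per-level coefficients (beta per class, lambda per
#' domain), the membership coefficients, and a scheme fingerprint used to
#' check consistency on read.
#'
#' @param params a `relcl_params`
#' @param path file path
#' @return invisibly, the JSON-ready list
#' @export
write_params_json <- function(params, path) {
  ex <- expand_params(params)
  obj <- list(
    X = params$X, D = params$D,
    scheme_hash = scheme_hash(params$scheme),
    beta_free = unname(params$beta),
    lambda_free = unname(params$lambda),
    gamma = if (is.null(params$gamma)) NULL else unname(params$gamma),
    beta_expanded = ex$beta,
    lambda_expanded = ex$lambda
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(obj)
}

scheme_hash <- function(scheme) {
  s <- paste(names(scheme$attributes),
             vapply(scheme$attributes, paste, character(1), collapse = "|"),
             scheme$domains, scheme$ordered, collapse = ";")
  # small stable rolling hash; no digest dependency needed
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  format(h)
}
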