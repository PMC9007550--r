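#' Gauss-Hermite quadrature grid for standard-normal random effects
#'
#' Tensor product of one-dimensional Gauss-Hermite rules, transformed so
#' that the grid integrates functions against the D-dimensional standard
#' normal density: nodes are scaled by sqrt(2) and weights normalized to
#' sum to one.
#'
#' @param D dimension (number of random effects); `D = 0` returns the
#'   trivial grid with one node and weight 1.
#' @param n_nodes nodes per dimension (default 7)
#' @return list with `nodes` (`Q x D` matrix) and `weights` (length `Q`,
#'   summing to 1)
#' @examples
#' g <- gh_grid(2, 5)
#' sum(g$weights)  # 1
#' colSums(g$nodes^2 * g$weights)  # ~ c(1, 1): E[F^2] = 1
#' @export
gh_grid <- function(D, n_nodes = 7) {
  if (D == 0) return(list(nodes = matrix(0, 1, 0), weights = 1))
  gh <- pracma::gaussHermite(n_nodes)
  x <- gh$x * sqrt(2)
  w <- gh$w / sqrt(pi)
  grids <- rep(list(x), D)
  nodes <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  wgrids <- rep(list(w), D)
  weights <- apply(as.matrix(expand.grid(wgrids, KEEP.OUT.ATTRS = FALSE)), 1, prod)
  weights <- weights / sum(weights)
  list(nodes = nodes, weights = weights)
}

#' Quasi Monte-Carlo grid of standard-normal draws (Halton sequence)
#'
#' Alternative to [gh_grid()] for simulated maximum likelihood: `R` Halton
#' draws mapped through the normal quantile function, with equal weights.
#'
#' @param D dimension
#' @param R number of draws (default 200)
#' @param skip leading sequence elements to drop (burn-in)
#' @return list with `nodes` (`R x D`) and `weights` (length `R`)
#' @export
halton_grid <- function(D, R = 200, skip = 20) {
  if (D == 0) return(list(nodes = matrix(0, 1, 0), weights = 1))
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  if (D > length(bases)) stop("Halton grid supports up to ", length(bases), " dimensions")
  H <- vapply(bases[seq_len(D)], function(b) halton_1d(R, b, skip), numeric(R))
  H <- matrix(H, R, D)
  list(nodes = stats::qnorm(H), weights = rep(1 / R, R))
}

# radical-inverse (van der Corput) sequence in the given prime base
halton_1d <- function(n, base, skip = 0) {
  idx <- seq_len(n) + skip
  out <- numeric(n)
  f <- 1 / base
  while (any(idx > 0)) {
    out <- out + f * (idx %% base)
    idx <- idx %/% base
    f <- f / base
  }
  out
}
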