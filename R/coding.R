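#' Effects coding of a single attribute level
#'
#' Level `l` of an `L`-level attribute is coded as a contrast vector of
#' length `L - 1`: levels `1..L-1` map to unit indicator vectors and the
#' last level maps to the all-minus-one vector, so that any coefficient
#' vector's expansion over the `L` levels sums to zero.
#'
#' @param level integer level index in `1..n_levels`
#' @param n_levels number of levels `L >= 2`
#' @return numeric contrast vector of length `L - 1`
#' @examples
#' effects_code(1, 3)  # c(1, 0)
#' effects_code(3, 3)  # c(-1, -1)
#' @export
effects_code <- function(level, n_levels) {
  if (n_levels < 2) stop("n_levels must be >= 2")
  if (length(level) != 1 || is.na(level) || level < 1 || level > n_levels)
    stop("level out of range 1..", n_levels)
  if (level < n_levels) {
    v <- numeric(n_levels - 1L)
    v[level] <- 1
    v
  } else {
    rep(-1, n_levels - 1L)
  }
}

#' Expand free effects-coded contrasts to per-level coefficients
#'
#' The omitted level's coefficient is the negative sum of the free
#' contrasts, so the expanded coefficients sum to zero.
#'
#' @param contrasts numeric vector of `L - 1` free coefficients
#' @return numeric vector of `L` per-level coefficients
#' @examples
#' expand_effects(c(-1.34, 1.65))  # third coefficient is -0.31
#' @export
expand_effects <- function(contrasts) {
  c(contrasts, -sum(contrasts))
}

# Block-diagonal expansion matrix E (total_levels x n_contrasts) such that
# expanded = E %*% free for any free-contrast vector over the whole scheme.
expansion_matrix <- function(scheme) {
  L <- scheme_n_levels(scheme)
  blocks <- lapply(L, function(l) rbind(diag(l - 1L), rep(-1, l - 1L)))
  total <- sum(L); P <- sum(L - 1L)
  E <- matrix(0, total, P)
  r0 <- 0L; c0 <- 0L
  for (b in blocks) {
    E[r0 + seq_len(nrow(b)), c0 + seq_len(ncol(b))] <- b
    r0 <- r0 + nrow(b); c0 <- c0 + ncol(b)
  }
  E
}

#' Effects-code one alternative
#'
#' @param scheme an `attribute_scheme`
#' @param levels integer vector of level indices, one per attribute, in
#'   scheme order
#' @return numeric row of length `scheme_n_contrasts(scheme)`
#' @export
effects_code_row <- function(scheme, levels) {
  L <- scheme_n_levels(scheme)
  stopifnot(length(levels) == length(L))
  unlist(Map(effects_code, levels, L), use.names = FALSE)
}

#' Effects-code a design or choice table
#'
#' Builds the coded matrix `Z` with one row per alternative and one column
#' per free contrast (`L_a - 1` per attribute `a`).
#'
#' @param scheme an `attribute_scheme`
#' @param levels_df data frame (or matrix) with one column per attribute, in
#'   scheme order, holding 1-based level indices; one row per alternative.
#' @return numeric matrix, `nrow(levels_df)` x `scheme_n_contrasts(scheme)`
#' @export
code_matrix <- function(scheme, levels_df) {
  L <- scheme_n_levels(scheme)
  A <- length(L)
  lv <- as.matrix(levels_df)
  stopifnot(ncol(lv) == A)
  for (a in seq_len(A)) {
    if (any(lv[, a] < 1 | lv[, a] > L[a]))
      stop("level index out of range for attribute ", names(scheme$attributes)[a])
  }
  P <- sum(L - 1L)
  Z <- matrix(0, nrow(lv), P)
  cc <- contrast_cols(scheme)
  for (a in seq_len(A)) {
    cols <- cc[[a]]
    la <- L[a]
    x <- lv[, a]
    last <- x == la
    if (any(!last)) {
      Z[cbind(which(!last), cols[x[!last]])] <- 1
    }
    if (any(last)) Z[last, cols] <- -1
  }
  colnames(Z) <- contrast_names(scheme)
  Z
}

contrast_names <- function(scheme) {
  L <- scheme_n_levels(scheme)
  unlist(Map(function(a, l) paste0(a, "_c", seq_len(l - 1L)),
             names(scheme$attributes), L), use.names = FALSE)
}

expanded_names <- function(scheme) {
  ei <- expanded_index(scheme)
  paste0(ei$attribute, ":", ei$label)
}
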