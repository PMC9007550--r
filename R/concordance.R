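# enumerate all permutations of 1..k (k <= 8 is instantaneous)
all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Concordance of two class assignments
#'
#' Cross-tabulates two modal class assignments over the same participants
#' and finds the class relabeling of the second assignment that maximizes
#' agreement (exhaustive assignment matching over permutations), reporting
#' the agreement proportion after relabeling.
#'
#' @param labels_a integer class labels in `1..X`
#' @param labels_b integer class labels (same length); relabeled to match
#' @param X number of classes (defaults to the max label observed)
#' @return list with `tab` (X x X cross-tabulation, rows = `labels_a`),
#'   `permutation` (optimal relabeling of b's classes), `agreement`
#'   (proportion agreeing after relabeling).
#' @export
class_concordance <- function(labels_a, labels_b, X = max(labels_a, labels_b)) {
  stopifnot(length(labels_a) == length(labels_b))
  fa <- factor(labels_a, levels = seq_len(X))
  fb <- factor(labels_b, levels = seq_len(X))
  tab <- table(a = fa, b = fb)
  best_perm <- seq_len(X); best <- -1
  for (p in all_permutations(X)) {
    agree <- sum(diag(tab[, p, drop = FALSE]))
    if (agree > best) { best <- agree; best_perm <- p }
  }
  list(tab = unclass(tab), permutation = unlist(best_perm),
       agreement = best / length(labels_a))
}

#' Aggregate versus group-specific class-membership concordance
#'
#' Compares modal class assignments from a model fitted to all
#' participants against assignments from models fitted separately within
#' groups (e.g., cohorts). Each group fit's classes are relabeled to best
#' match the aggregate fit's classes before computing agreement. When the
#' numbers of classes differ, the cross-tabulation is reported without an
#' agreement proportion.
#'
#' @param fit_aggregate `relcl_fit` on the full dataset
#' @param fits_by_group named list of `relcl_fit`s, one per group
#' @param dataset the full `ranking_dataset`
#' @param group character/factor vector over participants naming each
#'   participant's group (names must match `fits_by_group`)
#' @return list with per-group concordance results and the pooled
#'   `agreement` proportion (NA if class counts differ).
#' @export
concordance <- function(fit_aggregate, fits_by_group, dataset, group) {
  post_agg <- class_posteriors(fit_aggregate, dataset)
  parts <- dataset$participants
  stopifnot(length(group) == nrow(parts))
  by_group <- list()
  n_agree <- 0; n_tot <- 0; comparable <- TRUE
  for (g in names(fits_by_group)) {
    ids <- parts$id[group == g]
    sub <- subset_dataset(dataset, ids)
    post_g <- class_posteriors(fits_by_group[[g]], sub)
    agg_labels <- post_agg$modal[match(ids, parts$id)]
    if (fits_by_group[[g]]$X != fit_aggregate$X) {
      comparable <- FALSE
      X <- max(fit_aggregate$X, fits_by_group[[g]]$X)
      tab <- table(a = factor(agg_labels, levels = seq_len(X)),
                   b = factor(post_g$modal, levels = seq_len(X)))
      by_group[[g]] <- list(tab = unclass(tab), permutation = NULL,
                            agreement = NA_real_)
    } else {
      cc <- class_concordance(agg_labels, post_g$modal, fit_aggregate$X)
      by_group[[g]] <- cc
      n_agree <- n_agree + cc$agreement * length(ids)
      n_tot <- n_tot + length(ids)
    }
  }
  list(by_group = by_group,
       agreement = if (comparable && n_tot > 0) n_agree / n_tot else NA_real_)
}

#' Subset a ranking dataset to selected participants
#'
#' @param dataset a `ranking_dataset`
#' @param ids participant ids to keep
#' @return a `ranking_dataset` restricted to `ids`
#' @export
subset_dataset <- function(dataset, ids) {
  keep <- dataset$participants$id %in% ids
  idx <- which(keep)
  truth <- dataset$truth
  if (!is.null(truth)) {
    truth <- list(class = truth$class[idx],
                  F = truth$F[idx, , drop = FALSE],
                  params = truth$params)
  }
  structure(list(
    choices = dataset$choices[dataset$choices$participant %in% ids, , drop = FALSE],
    participants = dataset$participants[keep, , drop = FALSE],
    truth = truth
  ), class = "ranking_dataset")
}
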