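#' Generate a blocked, level-balanced choice design
#'
#' Builds `n_tasks` choice tasks of `n_alts` alternatives each, partitioned
#' into `n_blocks` equal blocks. Each attribute's levels are allocated in
#' (near-)exactly balanced proportions across the `n_tasks * n_alts`
#' alternatives and then randomly permuted; duplicate alternatives within a
#' task are repaired by swapping single attribute levels between tasks,
#' which preserves the balance exactly. Feasibility of counseling x
#' notification combinations is guaranteed by construction because the
#' infeasible pairs are excluded from the compound attribute's levels.
#'
#' A D-efficiency-optimized design requires priors and a dedicated
#' optimizer; level-balanced random designs keep all coefficients estimable
#' and are sufficient for simulation and estimation studies.
#'
#' @param scheme an `attribute_scheme`
#' @param n_tasks total number of tasks (divisible by `n_blocks`)
#' @param n_blocks number of blocks
#' @param n_alts alternatives per task
#' @param max_sweeps internal cap on duplicate-repair sweeps
#' @return a `choice_design`: data frame with columns `block`, `task`,
#'   `alt`, then one 1-based level-index column per attribute.
#' @examples
#' set.seed(1)
#' d <- generate_design(default_scheme(), n_tasks = 12, n_blocks = 1)
#' nrow(d)  # 12 tasks x 3 alternatives
#' @export
generate_design <- function(scheme, n_tasks = 120, n_blocks = 10, n_alts = 3,
                            max_sweeps = 1000) {
  if (n_tasks %% n_blocks != 0) stop("n_tasks must be divisible by n_blocks")
  L <- scheme_n_levels(scheme)
  if (prod(L) < n_alts)
    stop("scheme admits fewer than n_alts distinct alternatives")
  n_rows <- n_tasks * n_alts
  A <- length(L)
  lev <- matrix(0L, n_rows, A)
  for (a in seq_len(A)) {
    # balanced allocation: each level appears floor/ceil(n_rows / L) times
    pool <- rep(seq_len(L[a]), length.out = n_rows)
    lev[, a] <- sample(pool)
  }
  task_of <- rep(seq_len(n_tasks), each = n_alts)

  dup_tasks <- function(lv) {
    key <- apply(lv, 1, paste, collapse = ",")
    km <- matrix(key, nrow = n_alts)
    which(apply(km, 2, anyDuplicated) > 0)
  }
  for (sweep in seq_len(max_sweeps)) {
    bad <- dup_tasks(lev)
    if (length(bad) == 0) break
    for (tk in bad) {
      rows <- which(task_of == tk)
      key <- apply(lev[rows, , drop = FALSE], 1, paste, collapse = ",")
      r <- rows[which(duplicated(key))[1]]
      a <- sample.int(A, 1)
      other <- sample(setdiff(seq_len(n_rows), rows), 1)
      tmp <- lev[r, a]; lev[r, a] <- lev[other, a]; lev[other, a] <- tmp
    }
  }
  if (length(dup_tasks(lev)) > 0)
    stop("could not repair duplicate alternatives; scheme too small for n_alts")

  out <- data.frame(
    block = rep(seq_len(n_blocks), each = n_alts * n_tasks / n_blocks),
    task = task_of,
    alt = rep(seq_len(n_alts), n_tasks)
  )
  lev <- as.data.frame(lev)
  names(lev) <- names(scheme$attributes)
  out <- cbind(out, lev)
  class(out) <- c("choice_design", "data.frame")
  attr(out, "n_blocks") <- n_blocks
  attr(out, "n_alts") <- n_alts
  out
}

#' Level frequencies of a design
#'
#' @param scheme an `attribute_scheme`
#' @param design a `choice_design`
#' @return named list, per attribute, of level counts over all alternatives
#' @export
design_level_counts <- function(scheme, design) {
  lapply(stats::setNames(names(scheme$attributes), names(scheme$attributes)),
         function(a) tabulate(design[[a]], nbins = length(scheme$attributes[[a]])))
}

#' Per-participant randomization of a design block
#'
#' Returns the tasks of one block in randomized order, with the
#' alternatives within each task presented in randomized order. Task and
#' alternative content is unchanged; presentation columns `task_order` and
#' `alt` are re-assigned.
#'
#' @param design a `choice_design`
#' @param block block id to draw from
#' @return data frame like `design` restricted to `block`, with a
#'   `task_order` column (1..tasks-per-block) giving presentation order and
#'   `alt` renumbered to presentation position.
#' @export
randomize_for_participant <- function(design, block) {
  db <- design[design$block == block, , drop = FALSE]
  if (nrow(db) == 0) stop("unknown block id: ", block)
  tasks <- unique(db$task)
  ord <- sample(tasks)
  pieces <- lapply(seq_along(ord), function(k) {
    dt <- db[db$task == ord[k], , drop = FALSE]
    dt <- dt[sample.int(nrow(dt)), , drop = FALSE]
    dt$task_order <- k
    dt$alt <- seq_len(nrow(dt))
    dt
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write / read a choice design as CSV
#' @param design a `choice_design`
#' @param path file path
#' @param scheme an `attribute_scheme` used to re-attach structure on read
#' @return `read_design` returns a `choice_design`
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, scheme) {
  df <- utils::read.csv(path)
  need <- c("block", "task", "alt", names(scheme$attributes))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design file missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  class(df) <- c("choice_design", "data.frame")
  attr(df, "n_blocks") <- length(unique(df$block))
  attr(df, "n_alts") <- max(df$alt)
  df
}
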