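#' Write a ranking dataset to CSV (plus ground truth as JSON)
#'
#' The interchange format is a UTF-8, comma-separated, headered long table
#' with one row per participant x task x alternative: `participant`,
#' `block`, `task`, `alt`, one 1-based level-index column per attribute,
#' and the `chosen_first` / `chosen_second` flags. Participant covariates
#' go to a second CSV; simulated ground truth (true classes and
#' random-effect scores) to JSON.
#'
#' @param dataset a `ranking_dataset`
#' @param choices_path CSV path for the long choice table
#' @param participants_path CSV path for the covariate table
#' @param truth_path optional JSON path for simulation ground truth
#' @param scheme the `attribute_scheme` (to order the level columns)
#' @return invisibly, the choices path
#' @export
write_choice_data <- function(dataset, choices_path, participants_path = NULL,
                              truth_path = NULL,
                              scheme = dataset$truth$params$scheme) {
  attrs <- names(scheme$attributes)
  cols <- c("participant", "block", "task", "alt", attrs,
            "chosen_first", "chosen_second")
  utils::write.csv(dataset$choices[, cols], choices_path, row.names = FALSE)
  if (!is.null(participants_path))
    utils::write.csv(dataset$participants, participants_path, row.names = FALSE)
  if (!is.null(truth_path) && !is.null(dataset$truth)) {
    tr <- dataset$truth
    jsonlite::write_json(
      list(class = tr$class, F = tr$F,
           beta = unname(tr$params$beta), lambda = unname(tr$params$lambda),
           gamma = if (is.null(tr$params$gamma)) NULL else unname(tr$params$gamma)),
      truth_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(choices_path)
}

#' Read and validate a ranking dataset from CSV
#'
#' Validates structure strictly: required columns present, level indices
#' in range, exactly three alternatives per (participant, task), no
#' duplicate (participant, task, alt), and exactly one `chosen_first` and
#' one distinct `chosen_second` per task. Violations are reported with the
#' offending row numbers.
#'
#' @param choices_path CSV of the long choice table
#' @param scheme an `attribute_scheme`
#' @param participants_path optional covariate CSV; when absent, a minimal
#'   participant table is derived from the choice table
#' @return a `ranking_dataset`
#' @export
read_choice_data <- function(choices_path, scheme, participants_path = NULL) {
  ch <- utils::read.csv(choices_path)
  attrs <- names(scheme$attributes)
  need <- c("participant", "block", "task", "alt", attrs,
            "chosen_first", "chosen_second")
  miss <- setdiff(need, names(ch))
  if (length(miss))
    stop("choice file missing columns: ", paste(miss, collapse = ", "))
  L <- scheme_n_levels(scheme)
  for (a in seq_along(attrs)) {
    bad <- which(ch[[attrs[a]]] < 1 | ch[[attrs[a]]] > L[a])
    if (length(bad))
      stop("level index out of range for attribute '", attrs[a], "' at rows ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(ch$participant, ch$task, ch$alt)
  if (anyDuplicated(key))
    stop("duplicate (participant, task, alt) at rows ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  tkey <- paste(ch$participant, ch$task)
  tsize <- table(tkey)
  if (any(tsize != 3)) {
    bad <- names(tsize)[tsize != 3][1]
    stop("task ", bad, " does not have exactly 3 alternatives (rows ",
         paste(utils::head(which(tkey == bad), 5), collapse = ", "), ")")
  }
  agg_f <- tapply(ch$chosen_first, tkey, sum)
  agg_s <- tapply(ch$chosen_second, tkey, sum)
  if (any(agg_f != 1) || any(agg_s != 1)) {
    bad <- c(names(agg_f)[agg_f != 1], names(agg_s)[agg_s != 1])[1]
    stop("task ", bad, " must have exactly one chosen_first and one chosen_second")
  }
  both <- ch$chosen_first == 1 & ch$chosen_second == 1
  if (any(both))
    stop("chosen_first equals chosen_second in task (participant task) ",
         paste(utils::head(unique(tkey[both]), 5), collapse = "; "),
         " at rows ", paste(utils::head(which(both), 5), collapse = ", "))
  if (!is.null(participants_path)) {
    parts <- utils::read.csv(participants_path)
    if (!"id" %in% names(parts)) stop("participant file needs an 'id' column")
    if ("testing" %in% names(parts))
      parts$testing <- factor(parts$testing, levels = c("never", "once", "more"))
    missing_ids <- setdiff(unique(ch$participant), parts$id)
    if (length(missing_ids))
      stop("participants missing from covariate file: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
  } else {
    ids <- unique(ch$participant)
    parts <- data.frame(id = ids,
                        block = ch$block[match(ids, ch$participant)])
  }
  structure(list(choices = ch, participants = parts, truth = NULL),
            class = "ranking_dataset")
}

#' Coefficient table in reporting layout
#'
#' One row per expanded attribute level with the class-specific expanded
#' utility weights, the expanded loadings with their domain index, plus a
#' class-share table overall and by cohort.
#'
#' @param fit a `relcl_fit`
#' @param posteriors output of [class_posteriors()]
#' @param participants participant table (for cohort-specific shares)
#' @return list with `coefficients` and `shares` data frames
#' @export
coefficient_table <- function(fit, posteriors, participants = NULL) {
  ex <- expand_params(fit$params)
  sch <- fit$params$scheme
  ei <- expanded_index(sch)
  co <- data.frame(attribute = ei$attribute, level = ei$label,
                   t(ex$beta), check.names = FALSE)
  names(co)[-(1:2)] <- paste0("class", seq_len(fit$X))
  if (fit$D > 0) {
    for (d in seq_len(fit$D)) co[[paste0("lambda", d)]] <- ex$lambda[, d]
    co$domain <- sch$domains[match(ei$attribute, names(sch$attributes))]
  }
  shares <- data.frame(class = seq_len(fit$X), all = posteriors$shares)
  if (!is.null(participants) && "cohort" %in% names(participants)) {
    for (co_name in unique(participants$cohort)) {
      idx <- participants$cohort == co_name
      shares[[co_name]] <- colMeans(posteriors$post[idx, , drop = FALSE])
    }
  }
  list(coefficients = co, shares = shares)
}

#' Run the full simulation-to-report pipeline
#'
#' Stages: build the design, simulate a dataset, fit the model (or a BIC
#' grid), compute posteriors, three-step covariate models, and write all
#' report tables plus a manifest (seeds, sizes, per-stage wall time) under
#' `out_dir`. Re-running with the same config reproduces the outputs
#' bit-for-bit.
#'
#' @param config list with elements `seed`, `out_dir`, and optional
#'   overrides: `design` (n_tasks, n_blocks, n_alts), `sim` (n, X, D,
#'   separation), `fit` (a [fit_config()]), `grid` (classes, effects; NULL
#'   skips the grid stage), `threestep` (logical)
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config) {
  stopifnot(!is.null(config$seed), !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  tic <- function() proc.time()[["elapsed"]]
  stamp <- function(name, t0) {
    manifest$stages[[name]] <<- list(seconds = round(tic() - t0, 2))
  }
  scheme <- config$scheme %||% default_scheme()
  dcfg <- config$design %||% list(n_tasks = 120, n_blocks = 10, n_alts = 3)
  scfg <- config$sim %||% list(n = 300, X = 2, D = 1, separation = 1)
  fcfg <- config$fit %||% fit_config(em_iterations = 30, newton_iterations = 40,
                                     n_starts = 2, seed = config$seed)

  t0 <- tic(); set.seed(config$seed)
  design <- generate_design(scheme, dcfg$n_tasks, dcfg$n_blocks, dcfg$n_alts)
  write_design(design, file.path(config$out_dir, "design.csv"))
  stamp("design", t0)

  t0 <- tic(); set.seed(config$seed + 1)
  truth <- example_params(scheme, X = scfg$X, D = scfg$D,
                          separation = scfg$separation %||% 1)
  dataset <- simulate_dataset(scheme, design, truth, n = scfg$n)
  write_choice_data(dataset,
                    file.path(config$out_dir, "choices.csv"),
                    file.path(config$out_dir, "participants.csv"),
                    file.path(config$out_dir, "truth.json"), scheme)
  stamp("simulate", t0)

  t0 <- tic()
  fit <- fit_relcl(dataset, scheme, scfg$X, scfg$D, fcfg)
  write_params_json(fit$params, file.path(config$out_dir, "fit_params.json"))
  jsonlite::write_json(
    list(loglik = fit$loglik, n_params = fit$n_params, bic = fit$bic,
         converged = fit$converged, best_start = fit$best_start,
         start_logliks = fit$start_logliks),
    file.path(config$out_dir, "fit_summary.json"), digits = NA, auto_unbox = TRUE)
  stamp("fit", t0)

  if (!is.null(config$grid)) {
    t0 <- tic()
    gr <- fit_grid(dataset, scheme, config$grid$classes, config$grid$effects, fcfg)
    utils::write.csv(gr, file.path(config$out_dir, "grid.csv"), row.names = FALSE)
    stamp("grid", t0)
  }

  t0 <- tic()
  post <- class_posteriors(fit, dataset)
  pdf_ <- data.frame(id = dataset$participants$id, post$post,
                     modal = post$modal, check.names = FALSE)
  names(pdf_)[1 + seq_len(fit$X)] <- paste0("p_class", seq_len(fit$X))
  if (fit$D > 0) {
    Fh <- post$F_hat; colnames(Fh) <- paste0("F", seq_len(fit$D))
    pdf_ <- cbind(pdf_, Fh)
  }
  utils::write.csv(pdf_, file.path(config$out_dir, "posteriors.csv"),
                   row.names = FALSE)
  ct <- coefficient_table(fit, post, dataset$participants)
  utils::write.csv(ct$coefficients, file.path(config$out_dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(ct$shares, file.path(config$out_dir, "class_shares.csv"),
                   row.names = FALSE)
  prefs <- individual_preferences(fit, post)
  utils::write.csv(prefs$long, file.path(config$out_dir, "preferences.csv"),
                   row.names = FALSE)
  stamp("posteriors", t0)

  if (isTRUE(config$threestep %||% TRUE) && fit$X > 1) {
    t0 <- tic()
    cov <- threestep_covariates(dataset$participants)
    ts <- three_step_membership(fit, post, cov)
    tdf <- data.frame(class = rownames(ts$coef), ts$coef, check.names = FALSE)
    utils::write.csv(tdf, file.path(config$out_dir, "threestep_membership.csv"),
                     row.names = FALSE)
    if (fit$D > 0) {
      fs <- regress_factor_scores(post, cov)
      rows <- do.call(rbind, lapply(names(fs), function(nm) {
        ct <- fs[[nm]]$coef_table
        data.frame(effect = nm, term = rownames(ct), ct,
                   row.names = NULL, check.names = FALSE)
      }))
      utils::write.csv(rows, file.path(config$out_dir, "threestep_scores.csv"),
                       row.names = FALSE)
    }
    stamp("threestep", t0)
  }

  manifest$n_participants <- nrow(dataset$participants)
  manifest$n_rankings <- n_rankings(dataset)
  manifest$n_choice_records <- n_choice_records(dataset)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}

#' Standard covariate set for the three-step analyses
#'
#' Age, secondary education, married, testing once, testing more than
#' once, and the cohort indicator, as numeric columns.
#'
#' @param participants participant table from [draw_participants()]
#' @return data frame of numeric covariates
#' @export
threestep_covariates <- function(participants) {
  data.frame(
    age = participants$age,
    secondary = as.numeric(participants$secondary),
    married = as.numeric(participants$married),
    tested_once = as.numeric(participants$testing == "once"),
    tested_more = as.numeric(participants$testing == "more"),
    cohort = as.numeric(participants$cohort == "porter")
  )
}
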