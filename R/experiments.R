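# Monte-Carlo study grids: replicate a condition (generate -> fit -> adjust
# -> score), run the three factorial studies, and aggregate marginals.

# Deterministic, collision-free replicate seeds: unique within a study as
# long as condition_id <= 21473 and r <= 99999. Master seeds should be kept
# below 2^30.
replicate_seed <- function(master_seed, condition_id, r) {
  as.integer((master_seed + condition_id * 100000 + r) %% .Machine$integer.max)
}

#' Run one simulation condition with replication
#'
#' For each replicate: simulate an OSCE dataset, fit the three-facet Rasch
#' model, back-transform fair-average adjusted scores and compute
#' per-student accuracy; then pool everything into one
#' [summarize_condition()] row. Each replicate runs on its own seed derived
#' deterministically from `(master_seed, condition_id, replicate)`, so
#' results do not depend on execution order.
#'
#' @param params A [simulation_params()] object.
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param master_seed Master seed of the study.
#' @param condition_id Integer id of this condition inside its study grid
#'   (keeps replicate seeds distinct between conditions).
#' @param control An [mfrm_control()].
#' @param keep_students Keep the pooled per-student accuracy rows (needed
#'   for the adjustment-size tabulation) in the result.
#' @return A list of class `condition_result`: `summary` (a
#'   `condition_summary` row), `accuracy` (pooled per-student rows with a
#'   `replicate` column, or `NULL`), `n_nonconverged`, `seeds`.
#' @examples
#' \donttest{
#' res <- run_condition(simulation_params(), n_replicates = 5, master_seed = 1)
#' res$summary
#' }
#' @export
run_condition <- function(params, n_replicates = 200L, master_seed = 1L,
                          condition_id = 1L, control = mfrm_control(),
                          keep_students = TRUE) {
  validate_params(params)
  stopifnot(n_replicates >= 1L)
  seeds <- vapply(seq_len(n_replicates), function(r)
    replicate_seed(master_seed, condition_id, r), 1L)
  acc <- vector("list", n_replicates)
  nonconv <- 0L
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    out <- tryCatch({
      sim <- simulate_osce(params, replicate = r, seed = seeds[r])
      fit <- fit_jmle(sim$dataset, control)
      if (!fit$converged) nonconv <- nonconv + 1L
      a <- score_student_accuracy(sim$perf, sim$dataset, adjusted_scores(fit))
      a$replicate <- r
      a
    }, error = function(e) e)
    if (inherits(out, "error")) failures <- failures + 1L else acc[[r]] <- out
  }
  acc <- acc[!vapply(acc, is.null, TRUE)]
  if (length(acc) == 0L)
    stop("condition error: all ", n_replicates, " replicates failed",
         call. = FALSE)
  structure(list(summary = summarize_condition(acc, params),
                 accuracy = if (keep_students) do.call(rbind, acc) else NULL,
                 n_nonconverged = nonconv,
                 n_failed = failures,
                 seeds = seeds),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  print(x$summary)
  if (x$n_nonconverged > 0 || x$n_failed > 0)
    cat(sprintf("  (%d non-converged fits, %d failed replicates)\n",
                x$n_nonconverged, x$n_failed))
  invisible(x)
}

#' Build one of the three study grids
#'
#' Study 1 crosses linking videos (0, 2, 4, 6, 8) with examiner
#' participation (50%, 65%, 80%, 100%) at no baseline difference: 20
#' conditions. Study 2 crosses the between-school baseline difference (0%,
#' 5%, 10%, 20% of scale) with the number of stations (6, 12, 18): 12
#' conditions, the examiner count scaling with stations (4 per station).
#' Study 3 divides the residual error SD by 2, 4 and 8 at otherwise default
#' parameters: 3 conditions. All non-varied fields sit at their defaults.
#'
#' @param study 1, 2 or 3.
#' @param n_replicates Replicates per condition. The presets of
#'   [replicate_preset()] give the conventional choices.
#' @param master_seed Master seed for the whole study.
#' @return A list of class `study_grid` with `study`, `conditions` (named
#'   list of [simulation_params()]), `n_replicates`, `master_seed`.
#' @export
study_grid <- function(study, n_replicates = 200L, master_seed = 1L) {
  stopifnot(study %in% 1:3)
  conditions <- switch(as.character(study),
    "1" = {
      g <- expand.grid(n_videos = c(0L, 2L, 4L, 6L, 8L),
                       participation = c(0.50, 0.65, 0.80, 1.00))
      stats::setNames(
        lapply(seq_len(nrow(g)), function(k)
          simulation_params(n_videos = g$n_videos[k],
                            participation = g$participation[k])),
        sprintf("videos%d_part%d", g$n_videos, round(100 * g$participation)))
    },
    "2" = {
      g <- expand.grid(baseline_diff = c(0, 0.05, 0.10, 0.20),
                       n_stations = c(6L, 12L, 18L))
      stats::setNames(
        lapply(seq_len(nrow(g)), function(k)
          simulation_params(baseline_diff = g$baseline_diff[k],
                            n_stations = g$n_stations[k])),
        sprintf("base%d_stations%d", round(100 * g$baseline_diff),
                g$n_stations))
    },
    "3" = {
      stats::setNames(
        lapply(c(2, 4, 8), function(d) simulation_params(error_divisor = d)),
        sprintf("errdiv%d", c(2, 4, 8)))
    })
  structure(list(study = study, conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed)),
            class = "study_grid")
}

#' Conventional replicate counts
#'
#' `"full"` is the 1000-replicate setting used for publication-stable
#' estimates; `"desk"` is a 200-replicate setting whose Monte-Carlo error on
#' the pooled error ratio and pAcc is already below about 0.01.
#'
#' @param preset `"full"` or `"desk"`.
#' @return Integer replicate count.
#' @export
replicate_preset <- function(preset = c("desk", "full")) {
  switch(match.arg(preset), desk = 200L, full = 1000L)
}

#' Run a whole study grid
#'
#' Executes every condition of the grid on independent seed substreams and
#' collects the per-condition summaries. Optionally writes the summary
#' table, the pooled per-student accuracy rows and a reproducibility
#' manifest (grid, seeds, package version) to `out_dir`.
#'
#' @param grid A [study_grid()].
#' @param control An [mfrm_control()].
#' @param keep_students Keep pooled per-student rows per condition.
#' @param out_dir Optional output directory.
#' @param verbose Print one line per finished condition.
#' @return A list of class `study_result`: `grid`, `results` (named list of
#'   `condition_result`), `summary` (stacked `condition_summary` rows).
#' @export
run_study <- function(grid, control = mfrm_control(), keep_students = FALSE,
                      out_dir = NULL, verbose = interactive()) {
  stopifnot(inherits(grid, "study_grid"))
  results <- vector("list", length(grid$conditions))
  names(results) <- names(grid$conditions)
  for (k in seq_along(grid$conditions)) {
    results[[k]] <- run_condition(grid$conditions[[k]],
                                  n_replicates = grid$n_replicates,
                                  master_seed = grid$master_seed,
                                  condition_id = k,
                                  control = control,
                                  keep_students = keep_students)
    if (verbose) {
      s <- results[[k]]$summary
      cat(sprintf("[study %d] %-22s ErR %.3f pAcc %.3f\n", grid$study,
                  names(results)[k], s$error_ratio, s$p_acc))
    }
  }
  summary <- do.call(rbind, lapply(results, `[[`, "summary"))
  rownames(summary) <- names(results)
  out <- structure(list(grid = grid, results = results, summary = summary),
                   class = "study_result")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Study %d: %d conditions x %d replicates (master seed %d)\n",
              x$grid$study, length(x$results), x$grid$n_replicates,
              x$grid$master_seed))
  print(as.data.frame(x$summary)[c("n_videos", "participation",
                                   "baseline_diff", "n_stations",
                                   "error_divisor", "error_ratio", "p_acc")])
  invisible(x)
}

#' Marginal error ratios and pAcc over one grid factor
#'
#' Averages the condition-level error ratio and pAcc over the levels of the
#' *other* factor of a two-factor study grid (simple mean of condition
#' values), e.g. the per-videos margin of study 1 averaged across all
#' participation levels. Requires a complete factorial grid.
#'
#' @param summary The stacked `summary` data frame of a `study_result` (or
#'   any data frame with the condition columns plus `error_ratio`, `p_acc`).
#' @param factor_name Column to keep as the margin (e.g. `"n_videos"`,
#'   `"participation"`, `"baseline_diff"`, `"n_stations"`).
#' @param across Column averaged over; inferred for the standard study-1 and
#'   study-2 pairs.
#' @return A data frame: `factor`, `level`, `n_conditions`, `error_ratio`,
#'   `p_acc`.
#' @export
marginal_summaries <- function(summary, factor_name,
                               across = NULL) {
  pairs <- c(n_videos = "participation", participation = "n_videos",
             baseline_diff = "n_stations", n_stations = "baseline_diff")
  if (is.null(across)) {
    if (!factor_name %in% names(pairs))
      stop("cannot infer the crossed factor for ", factor_name, call. = FALSE)
    across <- pairs[[factor_name]]
  }
  if (!all(c(factor_name, across, "error_ratio", "p_acc") %in% names(summary)))
    stop("summary lacks required columns", call. = FALSE)
  tab <- table(summary[[factor_name]], summary[[across]])
  if (any(tab != 1L))
    stop("incomplete factorial grid: each (", factor_name, ", ", across,
         ") pair must appear exactly once", call. = FALSE)
  lv <- sort(unique(summary[[factor_name]]))
  out <- data.frame(
    factor = factor_name,
    level = lv,
    n_conditions = as.vector(table(summary[[factor_name]])[as.character(lv)]),
    error_ratio = vapply(lv, function(v)
      mean(summary$error_ratio[summary[[factor_name]] == v]), 1),
    p_acc = vapply(lv, function(v)
      mean(summary$p_acc[summary[[factor_name]] == v]), 1)
  )
  rownames(out) <- NULL
  out
}
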