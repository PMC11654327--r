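# CSV interchange, configuration files, manifests and test fixtures.

dataset_columns <- c("replicate", "student_id", "station_id", "examiner_id",
                     "cohort_id", "is_video", "performance_id", "score")

#' Write / read a long-format score dataset as CSV
#'
#' Columns: `replicate,student_id,station_id,examiner_id,cohort_id,is_video,
#' performance_id,score`, header required, UTF-8. Reading restores an
#' `osce_dataset`; parameters must be re-supplied because the CSV carries
#' only the records.
#'
#' @param dataset An `osce_dataset`.
#' @param path Output CSV path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` an
#'   `osce_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  d <- as.data.frame(dataset)
  d$replicate <- attr(dataset, "replicate")
  utils::write.csv(d[dataset_columns], path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param params The [simulation_params()] the records were generated under.
#' @export
read_dataset <- function(path, params) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing <- setdiff(dataset_columns, names(d))
  if (length(missing) > 0)
    stop("parse error: missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  d$is_video <- as.logical(d$is_video)
  rep_idx <- unique(d$replicate)
  new_osce_dataset(d[setdiff(dataset_columns, "replicate")], params,
                   replicate = rep_idx[1])
}

summary_columns <- c("n_videos", "participation", "baseline_diff",
                     "n_stations", "error_divisor", "mean_obs_err",
                     "sd_obs_err", "mean_adj_err", "sd_adj_err",
                     "error_ratio", "p_acc")

#' Write / read condition summaries as CSV
#'
#' Lossless round-trip of pooled condition summaries; numbers are written at
#' full double precision with a C locale decimal point.
#'
#' @param summary One or more stacked `condition_summary` rows.
#' @param path CSV path.
#' @export
write_summary <- function(summary, path) {
  d <- as.data.frame(summary)[summary_columns]
  for (cl in summary_columns)
    d[[cl]] <- vapply(d[[cl]], function(v)
      format(v, digits = 17, scientific = FALSE, decimal.mark = "."), "")
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8", dec = ".")
  missing <- setdiff(summary_columns, names(d))
  if (length(missing) > 0)
    stop("parse error: missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  d[summary_columns]
}

#' Export fitted facet measures / adjusted scores as CSV
#'
#' `write_estimates` emits `facet,element_id,measure,se` rows for the three
#' facets and the thresholds; `write_adjusted` emits
#' `student_id,measure,adjusted_score`.
#'
#' @param fit An `mfrm_fit`.
#' @param path CSV path.
#' @export
write_estimates <- function(fit, path) {
  d <- rbind(
    data.frame(facet = "student", element_id = as.character(fit$student_ids),
               measure = unname(fit$student_measures),
               se = unname(fit$student_se)),
    data.frame(facet = "station", element_id = as.character(fit$station_ids),
               measure = unname(fit$station_difficulties), se = NA_real_),
    data.frame(facet = "cohort", element_id = as.character(fit$cohort_ids),
               measure = unname(fit$cohort_severities), se = NA_real_),
    data.frame(facet = "threshold",
               element_id = as.character(fit$category_values[-1]),
               measure = fit$thresholds, se = NA_real_)
  )
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @param adj An [adjusted_scores()] frame.
#' @export
write_adjusted <- function(adj, path) {
  utils::write.csv(adj[c("student_id", "measure", "adjusted_score")], path,
                   row.names = FALSE, fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a flat YAML key-value file whose keys mirror [simulation_params()]
#' and [mfrm_control()] argument names, plus `n_replicates` and
#' `master_seed`. Unknown keys are rejected by name; every value records its
#' provenance (`default`, `file` or `override`). Calling without a path (or
#' with overrides only) resolves the full default configuration.
#'
#' @param path Optional YAML file.
#' @param overrides Named list applied on top of the file (highest
#'   precedence).
#' @return A list of class `run_config` with `params`
#'   ([simulation_params()]), `control` ([mfrm_control()]), `n_replicates`,
#'   `master_seed` and `provenance` (named character vector).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  param_keys <- names(formals(simulation_params))
  control_keys <- setdiff(names(formals(mfrm_control)), "anchor_policy")
  run_keys <- c("n_replicates", "master_seed", "anchor_policy")
  known <- c(param_keys, control_keys, run_keys)

  values <- list(n_replicates = replicate_preset("desk"), master_seed = 1L)
  prov <- c(n_replicates = "default", master_seed = "default")
  for (k in c(param_keys, control_keys)) prov[k] <- "default"
  prov["anchor_policy"] <- "default"

  absorb <- function(vals, lst, origin) {
    unknown <- setdiff(names(lst), known)
    if (length(unknown) > 0)
      stop("configuration error: unknown key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (k in names(lst)) { vals[[k]] <- lst[[k]]; prov[k] <<- origin }
    vals
  }
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("configuration error: no such file: ", path, call. = FALSE)
    values <- absorb(values, yaml::read_yaml(path), "file")
  }
  values <- absorb(values, overrides, "override")

  params <- do.call(simulation_params,
                    values[intersect(names(values), param_keys)])
  ctrl_args <- values[intersect(names(values),
                                c(control_keys, "anchor_policy"))]
  control <- do.call(mfrm_control, ctrl_args)
  nrep <- as.integer(values$n_replicates)
  if (is.na(nrep) || nrep < 1L)
    stop("configuration error: n_replicates must be a positive count",
         call. = FALSE)
  structure(list(params = params, control = control,
                 n_replicates = nrep,
                 master_seed = as.integer(values$master_seed),
                 provenance = prov),
            class = "run_config")
}

#' Deterministic datasets for unit testing
#'
#' @param kind One of `"tiny-connected"` (8 students, 4 cohorts, 2 stations,
#'   2 videos, full participation), `"tiny-disconnected"` (same but 0
#'   videos, leaving the 4 cohorts unlinked), `"two-cohort-shift"` (a
#'   constructed two-cohort instance in which cohort 2 scores the identical
#'   video performances exactly 2 raw points lower than cohort 1, giving a
#'   known severity gap) or `"paper-defaults"` (one full default replicate).
#' @param seed RNG seed for the generated kinds.
#' @return An `osce_dataset`; for `"two-cohort-shift"` the attribute
#'   `"shift"` records the built-in 2-point gap.
#' @export
make_fixture <- function(kind = c("tiny-connected", "tiny-disconnected",
                                  "two-cohort-shift", "paper-defaults"),
                         seed = 1L) {
  kind <- match.arg(kind)
  if (kind %in% c("tiny-connected", "tiny-disconnected")) {
    p <- simulation_params(n_students = 8, n_stations = 2, n_cohorts = 4,
                           n_videos = if (kind == "tiny-connected") 2L else 0L,
                           participation = 1)
    return(simulate_osce(p, seed = seed)$dataset)
  }
  if (kind == "paper-defaults") {
    return(simulate_osce(simulation_params(), seed = seed)$dataset)
  }
  # two-cohort-shift: 6 students in 2 cohorts, 2 stations; every examiner of
  # cohort 2 scores the shared videos exactly `shift` points lower
  shift <- 2L
  p <- simulation_params(n_students = 6, n_stations = 2, n_cohorts = 2,
                         n_videos = 3, participation = 1,
                         examiner_sd = 0, residual_sd = 0)
  set.seed(seed)
  perf <- generate_true_scores(p)
  roster <- build_roster(p)
  live <- generate_live_scores(perf, roster, p)
  video <- generate_video_scores(perf, roster, p)
  sel <- video$cohort_id == 2
  video$score[sel] <- pmax(video$score[sel] - shift, p$scale_min)
  live_sel <- live$cohort_id == 2
  live$score[live_sel] <- pmax(live$score[live_sel] - shift, p$scale_min)
  d <- assemble_dataset(live, video, p, seed = seed)
  attr(d, "shift") <- shift
  d
}

#' Write the outputs and manifest of a study run
#'
#' Writes `summary.csv` (condition summaries), per-condition accuracy rows
#' (`accuracy.csv`, when kept) and `manifest.yaml` holding the grid,
#' replicate seeds, and package version -- enough to reproduce the run
#' bitwise.
#'
#' @param study_result A `study_result` from [run_study()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study_result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_summary(study_result$summary, file.path(out_dir, "summary.csv"))
  acc <- lapply(names(study_result$results), function(nm) {
    a <- study_result$results[[nm]]$accuracy
    if (is.null(a)) return(NULL)
    a$condition <- nm
    a
  })
  acc <- acc[!vapply(acc, is.null, TRUE)]
  if (length(acc) > 0)
    utils::write.csv(do.call(rbind, acc), file.path(out_dir, "accuracy.csv"),
                     row.names = FALSE)
  grid <- study_result$grid
  manifest <- list(
    package = "vescasim",
    version = as.character(utils::packageVersion("vescasim")),
    study = grid$study,
    master_seed = grid$master_seed,
    n_replicates = grid$n_replicates,
    conditions = lapply(grid$conditions, function(p) unclass(p)),
    replicate_seeds = lapply(study_result$results, `[[`, "seeds"),
    n_nonconverged = lapply(study_result$results, `[[`, "n_nonconverged")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
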