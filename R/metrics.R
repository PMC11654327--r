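# Accuracy metrics: per-student observed/adjusted score errors, the pooled
# error ratio (ErR) and improvement proportion (pAcc), and the
# adjustment-size threshold tabulation.

#' Per-student score accuracy for one replicate
#'
#' For each student computes the true mean (mean of the continuous,
#' unrounded true station scores), the observed mean (mean of live scores;
#' video records are excluded), the fair-average adjusted score, and three
#' absolute errors: observed error |observed - true|, adjusted error
#' |adjusted - true| and the adjustment size |adjusted - observed|. A
#' student counts as improved only when the adjusted error is *strictly*
#' smaller than the observed error; exact ties are not improvements.
#'
#' @param perf The `true_performance` behind the replicate (post baseline
#'   shift).
#' @param dataset The `osce_dataset` of the same replicate.
#' @param adj The [adjusted_scores()] fitted on that dataset.
#' @return A data frame with one row per student: `student_id`, `true_mean`,
#'   `observed_mean`, `adjusted`, `observed_error`, `adjusted_error`,
#'   `adjustment`, `improved`.
#' @export
score_student_accuracy <- function(perf, dataset, adj) {
  live <- dataset[!dataset$is_video, ]
  obs <- tapply(live$score, live$student_id, mean)
  ids <- as.integer(names(obs))
  true_mean <- rowMeans(perf$true_scores)[ids]
  k <- match(ids, adj$student_id)
  if (anyNA(k))
    stop("data error: missing adjusted score for some student", call. = FALSE)
  out <- data.frame(
    student_id = ids,
    true_mean = unname(true_mean),
    observed_mean = unname(as.vector(obs)),
    adjusted = adj$adjusted_score[k]
  )
  out$observed_error <- abs(out$observed_mean - out$true_mean)
  out$adjusted_error <- abs(out$adjusted - out$true_mean)
  out$adjustment <- abs(out$adjusted - out$observed_mean)
  out$improved <- out$adjusted_error < out$observed_error
  out
}

#' Pool per-replicate accuracies into a condition summary
#'
#' Students are pooled across replicates: the error ratio is the ratio of the
#' pooled mean adjusted error to the pooled mean observed error (a ratio of
#' means, not a mean of per-replicate ratios), and pAcc is the pooled
#' fraction of student-replicates whose adjusted score is strictly more
#' accurate.
#'
#' @param accuracy_list List of data frames from [score_student_accuracy()],
#'   one per replicate (a single data frame is accepted).
#' @param params The condition's [simulation_params()].
#' @return A one-row data frame of class `condition_summary`:
#'   `n_videos`, `participation`, `baseline_diff`, `n_stations`,
#'   `error_divisor`, `n_replicates`, `n_students_pooled`, `mean_obs_err`,
#'   `sd_obs_err`, `mean_adj_err`, `sd_adj_err`, `error_ratio`, `p_acc`.
#' @export
summarize_condition <- function(accuracy_list, params) {
  if (is.data.frame(accuracy_list)) accuracy_list <- list(accuracy_list)
  if (length(accuracy_list) < 1L)
    stop("need at least one replicate", call. = FALSE)
  pooled <- do.call(rbind, accuracy_list)
  mo <- mean(pooled$observed_error)
  ma <- mean(pooled$adjusted_error)
  if (mo == 0)
    warning("pooled observed error is zero; error ratio undefined")
  out <- data.frame(
    n_videos = params$n_videos,
    participation = params$participation,
    baseline_diff = params$baseline_diff,
    n_stations = params$n_stations,
    error_divisor = params$error_divisor,
    n_replicates = length(accuracy_list),
    n_students_pooled = nrow(pooled),
    mean_obs_err = mo,
    sd_obs_err = stats::sd(pooled$observed_error),
    mean_adj_err = ma,
    sd_adj_err = stats::sd(pooled$adjusted_error),
    error_ratio = if (mo == 0) NA_real_ else ma / mo,
    p_acc = mean(pooled$improved)
  )
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("Condition: %d videos, %.0f%% participation, %.0f%% baseline, %d stations, error/%g\n",
              x$n_videos, 100 * x$participation, 100 * x$baseline_diff,
              x$n_stations, x$error_divisor))
  cat(sprintf("  %d replicates, %d pooled students\n", x$n_replicates,
              x$n_students_pooled))
  cat(sprintf("  mean observed error %.3f (SD %.2f), mean adjusted error %.3f (SD %.2f)\n",
              x$mean_obs_err, x$sd_obs_err, x$mean_adj_err, x$sd_adj_err))
  cat(sprintf("  error ratio %.2f, pAcc %.2f\n", x$error_ratio, x$p_acc))
  invisible(x)
}

adjustment_bin_labels <- c(sprintf("[%d-%d%%)", 0:8, 1:9), ">9%")
accuracy_bin_labels <- c("<-6%", "(-6,-4%]", "(-4,-2%]", "(-2,0%]",
                         "[0,2%)", "[2,4%)", "[4,6%)", ">6%")

#' Adjustment-size threshold tabulation
#'
#' Expresses each student-replicate's adjustment size and accuracy change as
#' percentages of the scale range, cross-tabulates them in the fixed bins
#' ([0-1%), [1-2%), ..., [8-9%), >9% for adjustment size; <-6% up to >6% in
#' 2% steps for accuracy change, where positive change means the adjusted
#' score became more accurate), computes pAcc per adjustment bin, and
#' searches for the smallest *observed* adjustment bin at and above which
#' the cumulative pAcc reaches the 0.8 target (bins holding no students
#' cannot anchor a threshold).
#'
#' @param accuracy Data frame of pooled rows from [score_student_accuracy()]
#'   (or a list of them).
#' @param scale_range Raw scale range `scale_max - scale_min` used to express
#'   percentages.
#' @param target Cumulative pAcc target defining the threshold (default 0.8).
#' @return A list of class `adjustment_bin_table`: `table` (counts,
#'   adjustment bins x accuracy bins), `bin_n`, `bin_p_acc`,
#'   `cumulative_p_acc` (from each bin upward), `threshold_bin` (label, or
#'   `NA` when the target is never reached) and `threshold_pct` (lower edge
#'   of that bin, in % of scale).
#' @export
rq4_tabulate <- function(accuracy, scale_range, target = 0.8) {
  if (!is.data.frame(accuracy)) accuracy <- do.call(rbind, accuracy)
  if (nrow(accuracy) == 0L) stop("empty accuracy input", call. = FALSE)
  stopifnot(scale_range > 0)

  adj_pct <- 100 * accuracy$adjustment / scale_range
  chg_pct <- 100 * (accuracy$observed_error - accuracy$adjusted_error) /
    scale_range

  a_bin <- pmin(floor(adj_pct), 9) + 1L           # 1..10
  # negative changes bin right-closed, non-negative left-closed, so that an
  # exact zero change sits in [0,2%)
  c_bin <- ifelse(chg_pct >= 0,
                  pmin(floor(chg_pct / 2), 3) + 5L,
                  pmax(ceiling(chg_pct / 2), -4L) + 4L)
  tab <- table(factor(a_bin, levels = 1:10, labels = adjustment_bin_labels),
               factor(c_bin, levels = 1:8, labels = accuracy_bin_labels))

  bin_n <- as.vector(tapply(rep(1, nrow(accuracy)),
                            factor(a_bin, levels = 1:10), sum))
  bin_n[is.na(bin_n)] <- 0
  bin_imp <- as.vector(tapply(accuracy$improved,
                              factor(a_bin, levels = 1:10), sum))
  bin_imp[is.na(bin_imp)] <- 0
  bin_p <- ifelse(bin_n > 0, bin_imp / bin_n, NA_real_)

  cum_n <- rev(cumsum(rev(bin_n)))
  cum_imp <- rev(cumsum(rev(bin_imp)))
  cum_p <- ifelse(cum_n > 0, cum_imp / cum_n, NA_real_)

  # a threshold must be anchored at an observed adjustment size: empty
  # leading bins cannot define one
  hit <- which(!is.na(cum_p) & cum_p >= target & cum_n > 0 & bin_n > 0)
  threshold_bin <- if (length(hit)) adjustment_bin_labels[min(hit)]
                   else NA_character_
  threshold_pct <- if (length(hit)) min(hit) - 1 else NA_real_

  structure(list(table = tab,
                 bin_n = stats::setNames(bin_n, adjustment_bin_labels),
                 bin_p_acc = stats::setNames(bin_p, adjustment_bin_labels),
                 cumulative_p_acc = stats::setNames(cum_p,
                                                    adjustment_bin_labels),
                 target = target,
                 threshold_bin = threshold_bin,
                 threshold_pct = threshold_pct),
            class = "adjustment_bin_table")
}

#' @export
print.adjustment_bin_table <- function(x, ...) {
  cat("Score-adjustment size vs accuracy change (% of scale)\n")
  print(x$table)
  cat("\nper-bin pAcc:\n")
  print(round(x$bin_p_acc, 3))
  if (is.na(x$threshold_bin)) {
    cat(sprintf("\nno adjustment threshold reaches cumulative pAcc >= %.2f\n",
                x$target))
  } else {
    cat(sprintf("\nthreshold: adjustments >= %s reach cumulative pAcc >= %.2f\n",
                x$threshold_bin, x$target))
  }
  invisible(x)
}
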