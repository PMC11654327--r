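#' Simulation parameters for one OSCE condition
#'
#' Bundles every generating-model constant and design size needed to simulate
#' one distributed-OSCE condition. Defaults reproduce the reference condition:
#' 60 students rotating through 12 stations, 4 examiner cohorts with one
#' examiner per station per cohort (48 examiners), a 6--27 integer marksheet,
#' 4 linking videos per station and an expected 80% examiner participation in
#' video scoring. Variance components are in raw score points.
#'
#' @param n_students Number of students.
#' @param n_stations Number of OSCE stations.
#' @param n_cohorts Number of examiner cohorts. Must be even: schools are
#'   formed from the two cohort halves when a baseline difference is applied.
#' @param examiners_per_station_per_cohort Examiners covering each
#'   (station, cohort) cell. The default 1 yields
#'   `n_stations * n_cohorts` examiners.
#' @param scale_min,scale_max Integer bounds of the rating scale.
#' @param grand_mean Intercept of the generating model: the average student
#'   score on the raw scale.
#' @param student_sd SD of student overall ability (score points).
#' @param station_sd SD of station difficulty.
#' @param interaction_sd SD of the idiosyncratic student-by-station
#'   interaction.
#' @param examiner_sd SD of examiner leniency/stringency.
#' @param residual_sd SD of the residual rating error added to every score.
#' @param error_divisor Positive factor the residual SD is divided by
#'   (1, 2, 4 or 8 in the study grids).
#' @param n_videos Number of filmed performances per station used as linking
#'   videos.
#' @param participation Probability that an examiner takes part in video
#'   scoring.
#' @param baseline_diff Between-school difference in examiner stringency (and,
#'   with opposite sign, student ability) as a fraction of the scale range.
#'   Each school is shifted by half the difference.
#'
#' @return An object of class `simulation_params` (a validated named list).
#' @examples
#' p <- simulation_params()
#' p$n_students
#' simulation_params(n_stations = 6, baseline_diff = 0.2)
#' @export
simulation_params <- function(n_students = 60,
                              n_stations = 12,
                              n_cohorts = 4,
                              examiners_per_station_per_cohort = 1,
                              scale_min = 6,
                              scale_max = 27,
                              grand_mean = 19.47,
                              student_sd = 1.13,
                              station_sd = 1.52,
                              interaction_sd = 1.71,
                              examiner_sd = 1.40,
                              residual_sd = 2.35,
                              error_divisor = 1,
                              n_videos = 4,
                              participation = 0.80,
                              baseline_diff = 0) {
  p <- list(
    n_students = as.integer(n_students),
    n_stations = as.integer(n_stations),
    n_cohorts = as.integer(n_cohorts),
    examiners_per_station_per_cohort =
      as.integer(examiners_per_station_per_cohort),
    scale_min = as.integer(scale_min),
    scale_max = as.integer(scale_max),
    grand_mean = as.numeric(grand_mean),
    student_sd = as.numeric(student_sd),
    station_sd = as.numeric(station_sd),
    interaction_sd = as.numeric(interaction_sd),
    examiner_sd = as.numeric(examiner_sd),
    residual_sd = as.numeric(residual_sd),
    error_divisor = as.numeric(error_divisor),
    n_videos = as.integer(n_videos),
    participation = as.numeric(participation),
    baseline_diff = as.numeric(baseline_diff)
  )
  class(p) <- "simulation_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "simulation_params"))
  err <- function(msg) stop("invalid simulation parameters: ", msg,
                            call. = FALSE)
  counts <- c("n_students", "n_stations", "n_cohorts",
              "examiners_per_station_per_cohort")
  for (f in counts)
    if (is.na(p[[f]]) || p[[f]] < 1L) err(paste(f, "must be a positive count"))
  if (p$n_videos < 0L) err("n_videos must be a non-negative count")
  if (p$n_videos > p$n_students)
    err("n_videos cannot exceed the number of students per station")
  if (p$scale_max <= p$scale_min) err("scale_max must exceed scale_min")
  sds <- c("student_sd", "station_sd", "interaction_sd", "examiner_sd",
           "residual_sd")
  for (f in sds)
    if (is.na(p[[f]]) || p[[f]] < 0) err(paste(f, "must be >= 0"))
  if (p$error_divisor <= 0) err("error_divisor must be positive")
  if (is.na(p$participation) || p$participation < 0 || p$participation > 1)
    err("participation must lie in [0, 1]")
  if (is.na(p$baseline_diff) || p$baseline_diff < 0 || p$baseline_diff >= 1)
    err("baseline_diff must lie in [0, 1)")
  if (p$baseline_diff > 0 && p$n_cohorts %% 2L != 0L)
    err("n_cohorts must be even so cohorts split into two schools")
  invisible(p)
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("OSCE simulation parameters\n")
  cat(sprintf("  design : %d students x %d stations, %d cohorts, %d examiners\n",
              x$n_students, x$n_stations, x$n_cohorts,
              x$n_stations * x$n_cohorts * x$examiners_per_station_per_cohort))
  cat(sprintf("  scale  : %d..%d, grand mean %.2f\n",
              x$scale_min, x$scale_max, x$grand_mean))
  cat(sprintf("  SDs    : student %.2f, station %.2f, interaction %.2f, examiner %.2f, residual %.2f/%g\n",
              x$student_sd, x$station_sd, x$interaction_sd, x$examiner_sd,
              x$residual_sd, x$error_divisor))
  cat(sprintf("  linking: %d videos/station, participation %.0f%%, baseline diff %.0f%% of scale\n",
              x$n_videos, 100 * x$participation, 100 * x$baseline_diff))
  invisible(x)
}

# number of distinct scale categories
n_categories <- function(p) p$scale_max - p$scale_min + 1L

# even block assignment of students to cohorts (students are exchangeable)
cohort_assignment <- function(p) {
  rep_len(rep(seq_len(p$n_cohorts),
              each = ceiling(p$n_students / p$n_cohorts)), p$n_students)
}

# cohorts 1..n/2 form school A, the rest school B
school_of_cohort <- function(p) {
  ifelse(seq_len(p$n_cohorts) <= p$n_cohorts %/% 2L, "A", "B")
}
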