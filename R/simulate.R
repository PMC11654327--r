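# Synthetic OSCE data generation: true performance, examiner roster,
# live scores, and crossed video (linking) scores.

# nearest-integer rounding with ties going up, then clamp to the marksheet
round_score <- function(x, p) {
  as.integer(pmin(pmax(floor(x + 0.5), p$scale_min), p$scale_max))
}

#' Generate true student performance on every station
#'
#' Draws student abilities, station difficulties and student-by-station
#' interactions and combines them additively with the grand mean into a
#' continuous (unrounded, unclamped) matrix of true scores. These are the
#' scores a perfectly accurate, perfectly neutral examiner would report
#' before any rating noise.
#'
#' Uses the current RNG state; call [set.seed()] beforehand for
#' reproducibility.
#'
#' @param params A [simulation_params()] object.
#' @return An object of class `true_performance`: a list with `abilities`
#'   (per-student deviation from the grand mean), `station_difficulties`,
#'   `interactions` (students x stations), `true_scores` (students x
#'   stations, continuous) and `cohort_of_student`.
#' @examples
#' set.seed(1)
#' perf <- generate_true_scores(simulation_params())
#' dim(perf$true_scores)
#' @export
generate_true_scores <- function(params) {
  validate_params(params)
  S <- params$n_students
  I <- params$n_stations
  abilities <- stats::rnorm(S, 0, params$student_sd)
  station_difficulties <- stats::rnorm(I, 0, params$station_sd)
  interactions <- matrix(stats::rnorm(S * I, 0, params$interaction_sd), S, I)
  perf <- list(
    abilities = abilities,
    station_difficulties = station_difficulties,
    interactions = interactions,
    true_scores = params$grand_mean + outer(abilities, station_difficulties,
                                            `+`) + interactions,
    cohort_of_student = cohort_assignment(params)
  )
  class(perf) <- "true_performance"
  perf
}

#' Build the examiner roster
#'
#' Creates one examiner (or `examiners_per_station_per_cohort`) for every
#' (station, cohort) pair, draws each examiner's leniency from
#' Normal(0, `examiner_sd`) and flags video-scoring participation with
#' independent Bernoulli(`participation`) draws. Positive leniency adds to
#' the scores an examiner gives; stringency is negative leniency.
#'
#' @param params A [simulation_params()] object.
#' @return A data frame of class `examiner_roster` with columns
#'   `examiner_id`, `station_id`, `cohort_id`, `leniency`, `participates`.
#' @examples
#' set.seed(1)
#' r <- build_roster(simulation_params())
#' nrow(r)  # 48 at defaults
#' @export
build_roster <- function(params) {
  validate_params(params)
  grid <- expand.grid(slot = seq_len(params$examiners_per_station_per_cohort),
                      cohort_id = seq_len(params$n_cohorts),
                      station_id = seq_len(params$n_stations))
  n <- nrow(grid)
  roster <- data.frame(
    examiner_id = seq_len(n),
    station_id = grid$station_id,
    cohort_id = grid$cohort_id,
    leniency = stats::rnorm(n, 0, params$examiner_sd),
    participates = stats::runif(n) < params$participation
  )
  class(roster) <- c("examiner_roster", "data.frame")
  roster
}

#' Apply a between-school baseline difference
#'
#' Splits the cohorts into school A (first half) and school B (second half)
#' and shifts student abilities up and examiner leniencies down by half of
#' `baseline_diff * (scale_max - scale_min)` in school A, with opposite signs
#' in school B. Ability and stringency are thereby perfectly negatively
#' correlated between schools, so the *expected observed* score means stay
#' equal across schools while true ability and examiner severity both differ
#' by the full `baseline_diff` fraction of the scale range.
#'
#' @param perf A `true_performance` object.
#' @param roster An `examiner_roster`.
#' @param params The [simulation_params()] that produced both.
#' @return A list with elements `perf` and `roster`, shifted. With
#'   `baseline_diff = 0` the inputs are returned unchanged.
#' @export
apply_baseline_difference <- function(perf, roster, params) {
  validate_params(params)
  if (params$baseline_diff == 0) return(list(perf = perf, roster = roster))
  if (params$n_cohorts %% 2L != 0L)
    stop("baseline differences need an even number of cohorts", call. = FALSE)
  shift <- params$baseline_diff * (params$scale_max - params$scale_min) / 2
  school <- school_of_cohort(params)
  stu_sign <- ifelse(school[perf$cohort_of_student] == "A", 1, -1)
  exa_sign <- ifelse(school[roster$cohort_id] == "A", 1, -1)
  perf$abilities <- perf$abilities + stu_sign * shift
  perf$true_scores <- perf$true_scores + stu_sign * shift
  roster$leniency <- roster$leniency - exa_sign * shift
  list(perf = perf, roster = roster)
}

# examiner lookup: one row index per (station, cohort) record; when several
# examiners share a cell one is sampled uniformly per record
match_examiner <- function(station, cohort, roster) {
  key <- paste(station, cohort)
  rkey <- paste(roster$station_id, roster$cohort_id)
  if (!all(key %in% rkey))
    stop("no examiner covers some (station, cohort) cell", call. = FALSE)
  if (anyDuplicated(rkey)) {
    idx <- split(seq_len(nrow(roster)), rkey)[key]
    vapply(idx, function(i) if (length(i) == 1L) i else sample(i, 1L), 1L)
  } else {
    match(key, rkey)
  }
}

#' Generate live examination scores
#'
#' Every student is scored once per station by the roster examiner of their
#' own cohort: raw score = true score + examiner leniency + a residual draw
#' from Normal(0, `residual_sd / error_divisor`), rounded to the nearest
#' integer and clamped to the scale.
#'
#' @inheritParams apply_baseline_difference
#' @return A data frame of score records (`student_id`, `station_id`,
#'   `examiner_id`, `cohort_id`, `score`, `is_video = FALSE`,
#'   `performance_id`, `residual_draw`).
#' @export
generate_live_scores <- function(perf, roster, params) {
  validate_params(params)
  S <- params$n_students
  I <- params$n_stations
  grid <- expand.grid(student_id = seq_len(S), station_id = seq_len(I))
  cohort <- perf$cohort_of_student[grid$student_id]
  ex <- match_examiner(grid$station_id, cohort, roster)
  eps <- stats::rnorm(nrow(grid), 0, params$residual_sd / params$error_divisor)
  raw <- perf$true_scores[cbind(grid$student_id, grid$station_id)] +
    roster$leniency[ex] + eps
  data.frame(
    student_id = grid$student_id,
    station_id = grid$station_id,
    examiner_id = roster$examiner_id[ex],
    cohort_id = roster$cohort_id[ex],
    score = round_score(raw, params),
    is_video = FALSE,
    performance_id = performance_label(grid$student_id, grid$station_id),
    residual_draw = eps
  )
}

performance_label <- function(student, station) {
  sprintf("s%d.st%d", student, station)
}

#' Generate crossed video (linking) scores
#'
#' Per station, `n_videos` distinct student performances are drawn uniformly
#' (from all students, any cohort) and nominated as linking videos. Every
#' *participating* examiner assigned to that station then scores every
#' selected video: the filmed student's true score on that station plus the
#' examiner's own leniency plus a fresh residual draw, rounded and clamped.
#' Because examiners from all cohorts score the same filmed performances,
#' these records partially cross the otherwise fully nested design and make
#' cohort severities estimable.
#'
#' @inheritParams apply_baseline_difference
#' @return A data frame of video score records (`is_video = TRUE`); empty
#'   when `n_videos = 0` or no examiner participates.
#' @export
generate_video_scores <- function(perf, roster, params) {
  validate_params(params)
  empty <- generate_live_scores_template()
  if (params$n_videos == 0L) return(empty)
  pieces <- vector("list", params$n_stations)
  for (st in seq_len(params$n_stations)) {
    vids <- sample.int(params$n_students, params$n_videos)
    judges <- which(roster$station_id == st & roster$participates)
    if (length(judges) == 0L) next
    g <- expand.grid(v = vids, j = judges)
    eps <- stats::rnorm(nrow(g), 0,
                        params$residual_sd / params$error_divisor)
    raw <- perf$true_scores[cbind(g$v, st)] + roster$leniency[g$j] + eps
    pieces[[st]] <- data.frame(
      student_id = g$v,
      station_id = st,
      examiner_id = roster$examiner_id[g$j],
      cohort_id = roster$cohort_id[g$j],
      score = round_score(raw, params),
      is_video = TRUE,
      performance_id = performance_label(g$v, st),
      residual_draw = eps
    )
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0L) return(empty)
  do.call(rbind, pieces)
}

generate_live_scores_template <- function() {
  data.frame(student_id = integer(), station_id = integer(),
             examiner_id = integer(), cohort_id = integer(),
             score = integer(), is_video = logical(),
             performance_id = character(), residual_draw = numeric())
}

#' Assemble and validate a complete OSCE dataset
#'
#' Concatenates live and video records into one long-format table, checks the
#' dataset invariants (record counts, scale bounds, uniqueness of live
#' scores) and attaches provenance.
#'
#' @param live,video Data frames from [generate_live_scores()] /
#'   [generate_video_scores()] built from the same performance and roster.
#' @param params The [simulation_params()] used.
#' @param replicate Replicate index recorded as provenance.
#' @param seed Seed recorded as provenance (not consumed).
#' @return An `osce_dataset`: the combined data frame with attributes
#'   `params`, `replicate` and `seed`.
#' @export
assemble_dataset <- function(live, video, params, replicate = 1L,
                             seed = NA_integer_) {
  validate_params(params)
  records <- rbind(live, video)
  d <- new_osce_dataset(records, params, replicate, seed)
  lv <- d[!d$is_video, ]
  if (nrow(lv) != params$n_students * params$n_stations)
    stop("assembly error: expected ",
         params$n_students * params$n_stations, " live records, got ",
         nrow(lv), call. = FALSE)
  if (anyDuplicated(lv[c("student_id", "station_id", "examiner_id")]))
    stop("assembly error: duplicate live score records", call. = FALSE)
  vd <- d[d$is_video, ]
  if (nrow(vd) > 0) {
    per_ex <- table(vd$examiner_id)
    if (any(per_ex != params$n_videos))
      stop("assembly error: a participating examiner does not have exactly ",
           params$n_videos, " video records", call. = FALSE)
  }
  d
}

# low-level constructor: bounds/typing checks only, used by fixtures too
new_osce_dataset <- function(records, params, replicate = 1L,
                             seed = NA_integer_) {
  needed <- c("student_id", "station_id", "examiner_id", "cohort_id",
              "score", "is_video", "performance_id")
  if (!all(needed %in% names(records)))
    stop("assembly error: missing columns: ",
         paste(setdiff(needed, names(records)), collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L)
    stop("assembly error: empty dataset", call. = FALSE)
  bad <- records$score < params$scale_min | records$score > params$scale_max |
    records$score != floor(records$score)
  if (any(bad))
    stop("assembly error: scores outside the integer scale bounds",
         call. = FALSE)
  structure(records,
            params = params, replicate = as.integer(replicate),
            seed = seed,
            class = c("osce_dataset", "data.frame"))
}

#' Simulate one complete OSCE replicate
#'
#' Convenience wrapper running the full generation pipeline: true scores,
#' roster, baseline shift, live scores, video scores, assembly.
#'
#' @param params A [simulation_params()] object.
#' @param replicate Replicate index stored as provenance.
#' @param seed Optional seed; when given, `set.seed(seed)` is called first
#'   and the seed is recorded in the dataset.
#' @return A list with `dataset` (an `osce_dataset`), `perf`
#'   (`true_performance`, post baseline shift) and `roster`.
#' @examples
#' sim <- simulate_osce(simulation_params(), seed = 42)
#' nrow(sim$dataset)
#' @export
simulate_osce <- function(params = simulation_params(), replicate = 1L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  perf <- generate_true_scores(params)
  roster <- build_roster(params)
  shifted <- apply_baseline_difference(perf, roster, params)
  live <- generate_live_scores(shifted$perf, shifted$roster, params)
  video <- generate_video_scores(shifted$perf, shifted$roster, params)
  dataset <- assemble_dataset(live, video, params, replicate,
                              if (is.null(seed)) NA_integer_ else seed)
  list(dataset = dataset, perf = shifted$perf, roster = shifted$roster)
}

#' @export
print.osce_dataset <- function(x, ...) {
  p <- attr(x, "params")
  nv <- sum(x$is_video)
  cat(sprintf("OSCE dataset: %d records (%d live, %d video, %.1f%% video)\n",
              nrow(x), nrow(x) - nv, nv, 100 * nv / nrow(x)))
  cat(sprintf("  %d students x %d stations, %d cohorts; scale %d..%d\n",
              p$n_students, p$n_stations, p$n_cohorts, p$scale_min,
              p$scale_max))
  invisible(x)
}
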