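test_that("category probabilities follow the adjacent-category model", {
  # two categories, net logit zero at the single threshold: even odds
  expect_equal(category_probabilities(1.5, 1.0, 0.5, thresholds = 0),
               c(0.5, 0.5))
  # three categories, net logit 0, thresholds (-1, +1): (1, e, 1)/(2 + e)
  expect_equal(category_probabilities(0, 0, 0, c(-1, 1)),
               c(1, exp(1), 1) / (2 + exp(1)), tolerance = 1e-12)
  expect_error(category_probabilities(0, 0, 0, numeric(0)), "2 categories")
  expect_error(category_probabilities(0, 0, 0, c(0, Inf)), "finite")
})

test_that("probabilities match the independent oracle and sum to one", {
  set.seed(1)
  for (k in 1:50) {
    m <- sample(2:22, 1)
    th <- sort(rnorm(m - 1, 0, 2))
    eta <- rnorm(3)
    p <- category_probabilities(eta[1], eta[2], eta[3], th)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, oracle_category_probs(eta[1] - eta[2] - eta[3], th),
                 tolerance = 1e-12)
  }
})

test_that("expected score interpolates the category values monotonically", {
  th <- seq(-2, 2, length.out = 21)
  # symmetric thresholds and net logit 0: exactly the scale midpoint
  expect_equal(expected_score(0, 0, 0, th, 6:27), 16.5, tolerance = 1e-9)
  # extreme measures pin the extreme categories
  expect_equal(expected_score(40, 0, 0, th, 6:27), 27, tolerance = 1e-6)
  expect_equal(expected_score(-40, 0, 0, th, 6:27), 6, tolerance = 1e-6)
  # the worked 3-category case
  expect_equal(expected_score(0, 0, 0, c(-1, 1), 1:3), 2, tolerance = 1e-12)
  # strict monotonicity in the measure
  es <- vapply(seq(-4, 4, by = 0.25), function(b)
    expected_score(b, 0, 0, th, 6:27), 1)
  expect_true(all(diff(es) > 0))
  expect_error(expected_score(0, 0, 0, th, c(6, 6, 7)), "increasing")
})

test_that("connectivity reflects the video linking structure", {
  expect_true(check_connectivity(make_fixture("tiny-connected"))$connected)
  disc <- check_connectivity(make_fixture("tiny-disconnected"))
  expect_false(disc$connected)
  expect_equal(disc$n_subsets, 4L)
  # participation zero severs the links no matter how many videos
  p <- simulation_params(participation = 0)
  expect_false(check_connectivity(simulate_osce(p, seed = 2)$dataset)$connected)
  expect_true(check_connectivity(simulate_osce(simulation_params(),
                                               seed = 2)$dataset)$connected)
})

test_that("joint estimates agree with direct likelihood maximisation", {
  sim <- simulate_osce(tiny_mfrm_params(), seed = 37)
  d <- sim$dataset
  vals <- sort(unique(d$score))
  m <- length(vals)
  expect_gte(m, 3)  # thresholds identifiable on this frozen instance
  x <- match(d$score, vals) - 1L
  s <- match(d$student_id, sort(unique(d$student_id)))
  i <- match(d$station_id, sort(unique(d$station_id)))
  j <- match(d$cohort_id, sort(unique(d$cohort_id)))
  nS <- max(s); nI <- max(i); nJ <- max(j)
  # no extreme student totals, so the JMLE and the plain likelihood agree
  tot <- rowsum(x, s)
  expect_true(all(tot > 0 & tot < tabulate(s) * (m - 1L)))

  fit <- fit_jmle(d, mfrm_control(convergence_tol = 1e-9,
                                  max_iterations = 5000))
  expect_true(fit$converged)

  theta0 <- rep(0, nS + nI + nJ + m - 4L)
  opt <- optim(theta0, oracle_negll, x = x, s = s, i = i, j = j,
               nS = nS, nI = nI, nJ = nJ, m = m, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  B <- opt$par[seq_len(nS)]
  D <- c(opt$par[nS + 1L], -opt$par[nS + 1L])
  C <- c(opt$par[nS + 2L], -opt$par[nS + 2L])
  Ff <- opt$par[nS + 2L + seq_len(m - 2L)]
  F_ <- c(Ff, -sum(Ff))
  expect_equal(unname(fit$student_measures), B, tolerance = 1e-3)
  expect_equal(unname(fit$station_difficulties), D, tolerance = 1e-3)
  expect_equal(unname(fit$cohort_severities), C, tolerance = 1e-3)
  expect_equal(fit$thresholds, F_, tolerance = 1e-3)
})

test_that("identification constraints hold after fitting", {
  fit <- fit_jmle(simulate_osce(simulation_params(), seed = 19)$dataset)
  expect_equal(mean(fit$station_difficulties), 0, tolerance = 1e-9)
  expect_equal(mean(fit$cohort_severities), 0, tolerance = 1e-9)
  expect_equal(mean(fit$thresholds), 0, tolerance = 1e-9)
  # shifting measure and severity together leaves probabilities unchanged
  p1 <- category_probabilities(0.7, 0.2, -0.3, fit$thresholds)
  p2 <- category_probabilities(0.7 + 5, 0.2, -0.3 + 5, fit$thresholds)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("a constant cross-cohort scoring gap is recovered as severity", {
  d <- make_fixture("two-cohort-shift", seed = 4)
  fit <- fit_jmle(d, mfrm_control(convergence_tol = 1e-6,
                                  max_iterations = 2000))
  expect_true(fit$connected)
  sev <- fit$cohort_severities
  expect_gt(sev[["2"]], sev[["1"]])  # cohort 2 scored lower, so is severer
  # back-transformed, the severity gap matches the built-in 2-point shift
  mb <- mean(fit$student_measures)
  raw <- vapply(sev, function(C)
    expected_score(mb, 0, C, fit$thresholds, fit$category_values), 1)
  expect_equal(unname(raw[1] - raw[2]), attr(d, "shift"), tolerance = 0.35)
})

test_that("disconnected cohorts are anchored and adjustment collapses to round-trip", {
  d0 <- simulate_osce(simulation_params(n_videos = 0), seed = 23)
  fit <- fit_jmle(d0$dataset)
  expect_false(fit$connected)
  expect_true(fit$anchored)
  expect_true(all(fit$cohort_severities == 0))
  res <- run_condition(simulation_params(n_videos = 0), n_replicates = 10,
                       master_seed = 23)
  expect_lt(mean(res$accuracy$adjustment), 0.2)
})

test_that("fair averages reproduce observed means in the identity configuration", {
  p <- simulation_params(examiner_sd = 0, residual_sd = 0, n_videos = 0)
  sim <- simulate_osce(p, seed = 3)
  adj <- adjusted_scores(fit_jmle(sim$dataset))
  obs <- tapply(sim$dataset$score, sim$dataset$student_id, mean)
  expect_lt(max(abs(adj$adjusted_score - obs)), 0.25)
  # increasing in the measure, strictly so between distinct measures
  o <- order(adj$measure)
  dm <- diff(adj$measure[o])
  da <- diff(adj$adjusted_score[o])
  expect_true(all(da[dm > 1e-12] > 0))
  expect_true(all(abs(da[dm <= 1e-12]) < 1e-9))
})

test_that("equal raw means from a severer cohort earn the higher adjusted score", {
  # two cohorts, two stations; cohort-2's examiners score every shared video
  # exactly 2 points lower, and students 5..8 mirror students 1..4's raw
  # scores under those severer examiners
  p <- simulation_params(n_students = 8, n_stations = 2, n_cohorts = 2,
                         n_videos = 2, participation = 1)
  base <- 13 + (0:3)
  live <- data.frame(
    student_id = rep(1:8, each = 2),
    station_id = rep(1:2, 8),
    examiner_id = 0L,
    cohort_id = rep(c(1L, 2L), each = 8),
    score = as.integer(rep(c(base, base), each = 2) + rep(0:1, 8)),
    is_video = FALSE,
    performance_id = sprintf("s%d.st%d", rep(1:8, each = 2), rep(1:2, 8)),
    residual_draw = 0)
  live$examiner_id <- ifelse(live$cohort_id == 1,
                             ifelse(live$station_id == 1, 1L, 2L),
                             ifelse(live$station_id == 1, 3L, 4L))
  vid_perf <- data.frame(student_id = c(1L, 5L, 2L, 6L),
                         station_id = c(1L, 1L, 2L, 2L))
  video <- do.call(rbind, lapply(seq_len(4), function(k) {
    v <- vid_perf[k, ]
    sc <- live$score[live$student_id == v$student_id &
                       live$station_id == v$station_id]
    neutral <- sc + ifelse(v$student_id > 4, 2L, 0L)  # undo cohort-2 severity
    data.frame(student_id = v$student_id, station_id = v$station_id,
               examiner_id = c(ifelse(v$station_id == 1, 1L, 2L),
                               ifelse(v$station_id == 1, 3L, 4L)),
               cohort_id = c(1L, 2L),
               score = as.integer(c(neutral, neutral - 2L)),
               is_video = TRUE,
               performance_id = sprintf("s%d.st%d", v$student_id,
                                        v$station_id),
               residual_draw = 0)
  }))
  d <- assemble_dataset(live, video, p)
  adj <- adjusted_scores(fit_jmle(d, mfrm_control(convergence_tol = 1e-6,
                                                  max_iterations = 2000)))
  # mirrored students share raw means but cohort 2 is severer by 2 points
  for (k in 1:4)
    expect_gt(adj$adjusted_score[k + 4], adj$adjusted_score[k] + 0.8)
})

test_that("cohort severities track realized cohort leniency on large data", {
  # strong examiner signal relative to rating noise so that the four
  # cohort-level contrasts are well separated
  p <- simulation_params(n_students = 500, examiner_sd = 3, residual_sd = 0.5,
                         participation = 1, n_videos = 8)
  for (seed in c(1, 2)) {
    sim <- simulate_osce(p, seed = seed)
    fit <- fit_jmle(sim$dataset)
    Lbar <- tapply(sim$roster$leniency, sim$roster$cohort_id, mean)
    expect_gt(cor(-unname(fit$cohort_severities), as.vector(Lbar)), 0.95)
  }
})

test_that("non-convergence is flagged but estimates are still returned", {
  d <- simulate_osce(simulation_params(), seed = 29)$dataset
  fit <- fit_jmle(d, mfrm_control(max_iterations = 2))
  expect_false(fit$converged)
  expect_equal(fit$iterations, 2L)
  expect_length(fit$student_measures, 60L)
  expect_error(fit_jmle(d[0, ]), "empty")
})
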