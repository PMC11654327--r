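# Three-facet many-facet Rasch rating-scale model (student - station -
# cohort), estimated by joint maximum likelihood with alternating
# Newton-Raphson updates, plus the fair-average back-transformation that
# turns a student measure into an adjusted raw-scale score.
#
# Adjacent-category formulation: for ordered categories k = 0..m-1 with a
# shared threshold set F_2..F_m,
#   log(P_k / P_{k-1}) = B_student - D_station - C_cohort - F_k
# so log P_k = k * eta - cumsum(F)_k - log Z with eta the net logit.

#' Estimation controls for the facet Rasch fit
#'
#' @param max_iterations Maximum number of alternating Newton sweeps.
#' @param convergence_tol Convergence is declared when the largest absolute
#'   parameter change in a sweep (logits) falls below this.
#' @param extreme_score_adjustment Score-point shrinkage applied to
#'   all-minimum / all-maximum student totals so their measures stay finite
#'   (the usual rater-package convention of 0.3).
#' @param anchor_policy `"auto"` anchors all cohort severities at zero when
#'   the linking graph leaves cohorts disconnected (e.g. zero videos);
#'   `"cohorts_at_zero"` forces that anchoring always.
#' @return A list of class `mfrm_control`.
#' @export
mfrm_control <- function(max_iterations = 100L,
                         convergence_tol = 1e-3,
                         extreme_score_adjustment = 0.3,
                         anchor_policy = c("auto", "cohorts_at_zero")) {
  anchor_policy <- match.arg(anchor_policy)
  stopifnot(max_iterations >= 1L, convergence_tol > 0,
            extreme_score_adjustment > 0, extreme_score_adjustment < 0.5)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 extreme_score_adjustment = extreme_score_adjustment,
                 anchor_policy = anchor_policy),
            class = "mfrm_control")
}

#' Rating-scale category probabilities
#'
#' Probability of each ordered category under the rating-scale Rasch model,
#' given a net logit `measure - difficulty - severity` and the shared step
#' thresholds. With m categories there are m - 1 thresholds (the step into
#' the lowest category is fixed at 0).
#'
#' @param measure Person measure (logits).
#' @param difficulty Station difficulty (logits).
#' @param severity Cohort/rater severity (logits).
#' @param thresholds Numeric vector of m - 1 step thresholds.
#' @return Numeric probability vector over the m categories; sums to 1.
#' @examples
#' category_probabilities(0, 0, 0, thresholds = c(-1, 1))
#' @export
category_probabilities <- function(measure, difficulty, severity, thresholds) {
  if (length(thresholds) < 1L)
    stop("model error: need at least 2 categories", call. = FALSE)
  if (any(!is.finite(thresholds)))
    stop("model error: thresholds must be finite", call. = FALSE)
  eta <- measure - difficulty - severity
  cl <- cumsum(c(0, eta - thresholds))   # cumulative step logits
  p <- exp(cl - max(cl))
  p / sum(p)
}

#' Model-expected raw score (fair average when facets are at reference)
#'
#' Probability-weighted mean of the category values; strictly increasing in
#' the person measure. Called with `difficulty = 0` and `severity = 0` this
#' is the fair average: the raw-scale score expected from a perfectly
#' average station and a perfectly neutral examiner cohort.
#'
#' @inheritParams category_probabilities
#' @param category_values Strictly increasing raw values of the categories.
#' @return A single numeric score on the raw scale.
#' @export
expected_score <- function(measure, difficulty, severity, thresholds,
                           category_values) {
  if (is.unsorted(category_values, strictly = TRUE))
    stop("category_values must be strictly increasing", call. = FALSE)
  if (length(category_values) != length(thresholds) + 1L)
    stop("need one more category value than thresholds", call. = FALSE)
  p <- category_probabilities(measure, difficulty, severity, thresholds)
  sum(p * category_values)
}

#' Check linking connectivity between examiner cohorts
#'
#' Cohorts are fully nested with students in a conventional OSCE; only video
#' records in which examiners from different cohorts score the same filmed
#' performance connect them. Builds the cohort graph with an edge whenever a
#' performance is scored by two cohorts and returns its connected components.
#' Disconnected cohorts cannot be separated from student ability and must be
#' group-anchored during estimation.
#'
#' @param dataset An `osce_dataset` (or any data frame with `cohort_id`,
#'   `performance_id`, `is_video` columns).
#' @return A list with `connected` (flag), `n_subsets` and `subset`
#'   (integer subset label per cohort, named by cohort id).
#' @export
check_connectivity <- function(dataset) {
  if (nrow(dataset) == 0L) stop("empty dataset", call. = FALSE)
  cohorts <- sort(unique(dataset$cohort_id))
  parent <- seq_along(cohorts)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  vids <- dataset[dataset$is_video, c("performance_id", "cohort_id")]
  if (nrow(vids) > 0) {
    for (grp in split(match(vids$cohort_id, cohorts), vids$performance_id)) {
      grp <- unique(grp)
      r <- find(grp[1])
      for (g in grp[-1]) { rg <- find(g); if (rg != r) parent[rg] <- r }
    }
  }
  # live records also tie a performance to the student's own cohort: a video
  # of student k scored by cohort j links cohort(k) with j as well
  if (nrow(vids) > 0) {
    live <- dataset[!dataset$is_video, c("performance_id", "cohort_id")]
    shared <- intersect(vids$performance_id, live$performance_id)
    if (length(shared) > 0) {
      own <- live$cohort_id[match(shared, live$performance_id)]
      oth <- vids$cohort_id[match(shared, vids$performance_id)]
      for (i in seq_along(shared)) {
        a <- find(match(own[i], cohorts)); b <- find(match(oth[i], cohorts))
        if (a != b) parent[a] <- b
      }
    }
  }
  roots <- vapply(seq_along(cohorts), find, 1L)
  subset <- match(roots, unique(roots))
  names(subset) <- cohorts
  list(connected = length(unique(subset)) == 1L,
       n_subsets = length(unique(subset)),
       subset = subset)
}

#' Fit the three-facet Rasch model by joint maximum likelihood
#'
#' Alternating Newton-Raphson: student measures, station difficulties,
#' cohort severities and the shared rating-scale thresholds are each updated
#' in turn from the current expected scores until the largest absolute logit
#' change falls below `convergence_tol`. Identification: station
#' difficulties, cohort severities (within each connected subset) and
#' thresholds are centred at zero; the student facet is free and absorbs the
#' overall location. Categories never observed in the data are dropped and
#' estimation runs on the observed ordered category values, so fair averages
#' return to the raw 6--27 scale. Students with all-minimum or all-maximum
#' totals have their totals shrunk by `extreme_score_adjustment` points to
#' keep their measures finite. When the cohort graph is disconnected (no
#' cross-cohort video links) all cohort severities are anchored at zero
#' under the default `anchor_policy = "auto"`.
#'
#' @param dataset An `osce_dataset`.
#' @param control An [mfrm_control()] list.
#' @return An object of class `mfrm_fit` with elements `student_measures`
#'   (joint-likelihood measures), `reporting_measures` (measures
#'   re-estimated from live observations only -- video scores link the
#'   cohorts but do not contribute to any student's own score; these feed
#'   [adjusted_scores()]), the corresponding standard errors,
#'   `station_difficulties`, `cohort_severities`, `thresholds`,
#'   `category_values`, `converged`, `iterations`, `connected`, `subsets`,
#'   and the ids of each facet's elements.
#' @examples
#' sim <- simulate_osce(simulation_params(), seed = 7)
#' fit <- fit_jmle(sim$dataset)
#' fit
#' @export
fit_jmle <- function(dataset, control = mfrm_control()) {
  if (nrow(dataset) == 0L) stop("model error: empty dataset", call. = FALSE)
  stopifnot(inherits(control, "mfrm_control"))

  students <- sort(unique(dataset$student_id))
  stations <- sort(unique(dataset$station_id))
  cohorts <- sort(unique(dataset$cohort_id))
  s <- match(dataset$student_id, students)
  i <- match(dataset$station_id, stations)
  j <- match(dataset$cohort_id, cohorts)

  vals <- sort(unique(dataset$score))     # observed category values
  conn0 <- check_connectivity(dataset)
  if (length(vals) < 2L) {
    # degenerate: every score identical, nothing to estimate
    z <- function(ids) stats::setNames(numeric(length(ids)), ids)
    return(structure(list(
      student_ids = students, station_ids = stations, cohort_ids = cohorts,
      student_measures = z(students), student_se = z(students) + Inf,
      reporting_measures = z(students), reporting_se = z(students) + Inf,
      station_difficulties = z(stations), cohort_severities = z(cohorts),
      thresholds = numeric(0), category_values = vals,
      converged = TRUE, iterations = 0L,
      connected = conn0$connected, subsets = conn0$subset,
      anchored = TRUE), class = "mfrm_fit"))
  }
  x <- match(dataset$score, vals) - 1L    # category index 0..m-1
  m <- length(vals)
  K <- 0:(m - 1L)

  conn <- conn0
  anchor_cohorts <- control$anchor_policy == "cohorts_at_zero" ||
    (!conn$connected && control$anchor_policy == "auto")

  nS <- length(students); nI <- length(stations); nJ <- length(cohorts)
  B <- numeric(nS); D <- numeric(nI); C <- numeric(nJ)
  F_ <- rep(0, m - 1L)

  # per-element observed totals; shrink extreme student totals
  tot_s <- as.vector(rowsum(x, s))
  nobs_s <- tabulate(s, nS)
  adj <- control$extreme_score_adjustment
  tot_s[tot_s == 0] <- adj
  at_max <- tot_s == nobs_s * (m - 1L)
  tot_s[at_max] <- tot_s[at_max] - adj
  tot_i <- as.vector(rowsum(x, i))
  tot_j <- as.vector(rowsum(x, j))
  tab <- tabulate(x + 1L, m)
  n_ge <- rev(cumsum(rev(tab)))[-1L]      # observed counts in category >= k

  # upper-triangular collector: P %*% U gives P(X >= k), k = 1..m-1
  U <- outer(K, seq_len(m - 1L), `>=`) * 1
  mx <- outer(seq_len(m - 1L), seq_len(m - 1L), pmax)

  cap <- function(step, lim = 1) pmin(pmax(step, -lim), lim)

  expectations <- function() {
    eta <- B[s] - D[i] - C[j]
    L <- outer(eta, K) -
      matrix(cumsum(c(0, F_)), length(eta), m, byrow = TRUE)
    Lmax <- L[, 1L]
    for (k in 2:m) Lmax <- pmax(Lmax, L[, k])
    P <- exp(L - Lmax)
    P / rowSums(P)
  }

  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(control$max_iterations)) {
    delta <- 0

    # students
    P <- expectations()
    E <- as.vector(P %*% K); V <- as.vector(P %*% K^2) - E^2
    step <- cap((tot_s - as.vector(rowsum(E, s))) /
                  pmax(as.vector(rowsum(V, s)), 1e-10))
    B <- B + step
    delta <- max(delta, max(abs(step)))

    # stations (sign reversed: larger D lowers expected scores)
    P <- expectations()
    E <- as.vector(P %*% K); V <- as.vector(P %*% K^2) - E^2
    step <- cap((tot_i - as.vector(rowsum(E, i))) /
                  pmax(as.vector(rowsum(V, i)), 1e-10))
    D <- D - step
    dbar <- mean(D); D <- D - dbar; B <- B - dbar
    delta <- max(delta, max(abs(step)))

    # cohorts
    if (!anchor_cohorts && nJ > 1L) {
      P <- expectations()
      E <- as.vector(P %*% K); V <- as.vector(P %*% K^2) - E^2
      step <- cap((tot_j - as.vector(rowsum(E, j))) /
                    pmax(as.vector(rowsum(V, j)), 1e-10))
      C <- C - step
      cbar <- mean(C); C <- C - cbar; B <- B - cbar
      delta <- max(delta, max(abs(step)))
    }

    # shared thresholds: one multivariate Newton step (the cross-derivatives
    # between steps are large, so the full Hessian is needed for stability)
    if (m > 2L) {
      P <- expectations()
      Sge <- P %*% U
      grad <- colSums(Sge) - n_ge
      colS <- colSums(Sge)
      H <- crossprod(Sge) - matrix(colS[mx], m - 1L, m - 1L)
      step <- tryCatch(-solve(H - diag(1e-8, m - 1L), grad),
                       error = function(e) -grad /
                         pmax(colSums(Sge * (1 - Sge)), 1e-10))
      step <- cap(step)
      F_ <- F_ + step
      fbar <- mean(F_); F_ <- F_ - fbar; B <- B - fbar
      delta <- max(delta, max(abs(step)))
    }

    if (delta < control$convergence_tol) { converged <- TRUE; break }
  }

  # student standard errors from the final information
  P <- expectations()
  V <- as.vector(P %*% K^2) - as.vector(P %*% K)^2
  se <- 1 / sqrt(pmax(as.vector(rowsum(V, s)), 1e-10))

  # reporting measures: video scores link the cohorts but do not contribute
  # to any student's own score, so each student's reported measure is
  # re-estimated from their live observations alone, holding the station,
  # cohort and threshold estimates of the joint linked fit fixed
  live <- !dataset$is_video
  rep_est <- estimate_measures_conditional(
    x[live], s[live], offset = -D[i[live]] - C[j[live]],
    n_elements = nS, m = m, F_ = F_, start = B,
    extreme_adjustment = control$extreme_score_adjustment)

  structure(list(
    student_ids = students, station_ids = stations, cohort_ids = cohorts,
    student_measures = stats::setNames(B, students),
    student_se = stats::setNames(se, students),
    reporting_measures = stats::setNames(rep_est$measure, students),
    reporting_se = stats::setNames(rep_est$se, students),
    station_difficulties = stats::setNames(D, stations),
    cohort_severities = stats::setNames(C, cohorts),
    thresholds = F_,
    category_values = vals,
    converged = converged,
    iterations = iter,
    connected = conn$connected,
    subsets = conn$subset,
    anchored = anchor_cohorts
  ), class = "mfrm_fit")
}

# Newton estimation of person measures with all other facets fixed: used to
# read student measures off the live records at the linked frame of
# reference. `offset` carries -difficulty - severity per observation.
estimate_measures_conditional <- function(x, s, offset, n_elements, m, F_,
                                          start, extreme_adjustment) {
  K <- 0:(m - 1L)
  cumF <- cumsum(c(0, F_))
  tot <- as.vector(rowsum(x, s))
  nobs <- tabulate(s, n_elements)
  tot[tot == 0] <- extreme_adjustment
  hi <- tot == nobs * (m - 1L)
  tot[hi] <- tot[hi] - extreme_adjustment
  B <- start
  V_s <- NULL
  for (it in seq_len(200L)) {
    L <- outer(B[s] + offset, K) -
      matrix(cumF, length(s), m, byrow = TRUE)
    Lmax <- L[, 1L]
    for (k in 2:m) Lmax <- pmax(Lmax, L[, k])
    P <- exp(L - Lmax)
    P <- P / rowSums(P)
    E <- as.vector(P %*% K)
    V <- as.vector(P %*% K^2) - E^2
    V_s <- pmax(as.vector(rowsum(V, s)), 1e-10)
    step <- pmin(pmax((tot - as.vector(rowsum(E, s))) / V_s, -1), 1)
    B <- B + step
    if (max(abs(step)) < 1e-4) break
  }
  list(measure = B, se = 1 / sqrt(V_s))
}

#' @export
print.mfrm_fit <- function(x, ...) {
  cat(sprintf("Three-facet Rasch fit: %d students, %d stations, %d cohorts, %d categories\n",
              length(x$student_measures), length(x$station_difficulties),
              length(x$cohort_severities), length(x$category_values)))
  cat(sprintf("  %s after %d iterations; cohorts %s%s\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations,
              if (x$connected) "linked" else "disconnected",
              if (x$anchored) " (severities anchored at 0)" else ""))
  cat("  cohort severities (logits): ",
      paste(sprintf("%s=%.3f", names(x$cohort_severities),
                    x$cohort_severities), collapse = ", "), "\n")
  invisible(x)
}

#' Fair-average adjusted scores
#'
#' Back-transforms each student's logit measure to the raw scale with the
#' station and cohort facets at their reference value zero: the score an
#' average station and a neutral examiner cohort would be expected to give.
#' Cohort severity and station effects are removed by construction.
#'
#' @param fit An `mfrm_fit` from [fit_jmle()].
#' @return A data frame of class `adjusted_scores` with columns
#'   `student_id`, `measure`, `se`, `adjusted_score`.
#' @export
adjusted_scores <- function(fit) {
  stopifnot(inherits(fit, "mfrm_fit"))
  adj <- if (length(fit$category_values) == 1L) {
    rep(fit$category_values, length(fit$reporting_measures))
  } else {
    vapply(fit$reporting_measures, function(b)
      expected_score(b, 0, 0, fit$thresholds, fit$category_values), 1)
  }
  out <- data.frame(student_id = fit$student_ids,
                    measure = unname(fit$reporting_measures),
                    se = unname(fit$reporting_se),
                    adjusted_score = unname(adj))
  class(out) <- c("adjusted_scores", "data.frame")
  out
}
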