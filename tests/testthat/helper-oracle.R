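# Independent likelihood machinery for cross-checking the alternating-Newton
# fit against direct numerical maximisation. Written from the adjacent-
# category definition only; shares no code path with the package internals.

# probability of category k (0-based) via explicit products of adjacent odds
oracle_category_probs <- function(eta, thresholds) {
  m <- length(thresholds) + 1L
  logw <- numeric(m)
  for (k in seq_len(m - 1L))
    logw[k + 1L] <- logw[k] + eta - thresholds[k]
  w <- exp(logw - max(logw))
  w / sum(w)
}

# negative joint log-likelihood over a score table, parameterised with
# sum-to-zero constraints absorbed (last station/cohort/threshold implied)
oracle_negll <- function(theta, x, s, i, j, nS, nI, nJ, m) {
  B <- theta[seq_len(nS)]
  Dfree <- theta[nS + seq_len(nI - 1L)]
  D <- c(Dfree, -sum(Dfree))
  Cfree <- theta[nS + nI - 1L + seq_len(nJ - 1L)]
  C <- c(Cfree, -sum(Cfree))
  Ffree <- theta[nS + nI + nJ - 2L + seq_len(m - 2L)]
  F_ <- c(Ffree, -sum(Ffree))
  ll <- 0
  for (r in seq_along(x)) {
    p <- oracle_category_probs(B[s[r]] - D[i[r]] - C[j[r]], F_)
    ll <- ll + log(p[x[r] + 1L])
  }
  -ll
}

# tiny instance on a 1..4 scale with full participation and cross-cohort
# videos; seed chosen so that all categories are observed and no student
# holds an extreme (all-minimum / all-maximum) total
tiny_mfrm_params <- function() {
  simulation_params(n_students = 6, n_stations = 2, n_cohorts = 2,
                    scale_min = 1, scale_max = 4, grand_mean = 2.5,
                    student_sd = 0.7, station_sd = 0.4, interaction_sd = 0.3,
                    examiner_sd = 0.5, residual_sd = 0.4,
                    n_videos = 2, participation = 1)
}

# pooled accuracy rows from a quick run of one condition
pooled_accuracy <- function(params, n_replicates, master_seed,
                            condition_id = 1L) {
  run_condition(params, n_replicates = n_replicates,
                master_seed = master_seed, condition_id = condition_id,
                keep_students = TRUE)
}
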