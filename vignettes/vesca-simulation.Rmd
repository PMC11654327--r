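---
title: "Simulating video-linked examiner adjustment in distributed OSCEs"
author: "vescasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating video-linked examiner adjustment in distributed OSCEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vescasim)
```

## What the package models

A distributed OSCE sends cohorts of students through parallel tracks of the
same exam, each track staffed by its own examiners. Because every student is
scored only by their cohort's examiners, systematic differences in examiner
stringency between tracks (or between collaborating schools) are confounded
with real ability differences. Video linking breaks the confound: a handful
of station performances are filmed, examiners from every cohort score the
same videos, and the shared ratings identify cohort-level severity. A
many-facet Rasch model then produces a severity-adjusted ("fair average")
score per student.

Whether those adjusted scores are *more accurate* than the raw scores is an
empirical question about the interplay of systematic severity differences,
random rating error, and the strength of the linking. `vescasim` answers it
by Monte-Carlo simulation with known truth: generate scores from an explicit
model, adjust them, and measure both errors against the generating truth.

## The generating model

Each replicate draws, in raw score points on a bounded integer marksheet
(`scale_min = 6` to `scale_max = 27`, a 21-point range):

* student ability: Normal(0, 1.13) around a grand mean of 19.47;
* station difficulty: Normal(0, 1.52);
* a student-by-station interaction: Normal(0, 1.71) — the irreducible
  occasion-specific component of a performance;
* examiner leniency: Normal(0, 1.40), one examiner per (station, cohort);
* residual rating error: Normal(0, 2.35 / `error_divisor`) per rating,
  covering halo, contrast, time-of-day and other unmodelled influences.

The continuous sum `grand mean + ability + station + interaction` is the
student's *true score* for a station. A live rating adds the examiner's
leniency and a residual draw, then rounds to the nearest integer (ties up)
and clamps to the scale — a bounded marksheet records whole points, and the
categorical Rasch model needs ordered categories. The default design is 60
students in 4 cohorts, 12 stations, 48 examiners.

Video linking is mimicked by drawing `n_videos` (default 4) distinct
performances per station, uniformly across all cohorts, and having every
*participating* examiner of that station score each of them with their own
leniency and a fresh residual draw. Participation is an independent
Bernoulli(`participation`, default 0.80) flag per examiner — the expected,
not exact, participation rate. An examiner may be allocated a video of a
student they also scored live; the residuals are independent. At the
defaults this yields about 154 video ratings next to the 720 live ones
(roughly 18% of records), matching the volume a real video-linked OSCE
produces.

A between-school *baseline difference* of fraction `b` of the scale range
splits the cohorts into school A (first half, a fixed convention — cohort
labels are exchangeable) and school B: student abilities shift by
`+b * 21 / 2` in school A and `-b * 21 / 2` in school B, while examiner
leniencies shift by the same amounts in the *opposite* direction. Ability
and stringency are thus perfectly negatively correlated, the expected
observed means of the two schools are equal, and the true ability gap (and
severity gap) between schools is exactly `b * 21` points — the scenario in
which raw scores hide a real inter-school difference. The stated percentage
is the *between*-school difference; each school moves by half. This
convention makes the per-student observed error under a 20% baseline
difference come out at about the 2.1-point per-school shift, which is the
scale of what adjustment can recover there.

## The measurement model

Ratings are modelled with a three-facet rating-scale Rasch model on
adjacent-category logits,

$$\log\frac{P_{nijk}}{P_{nij(k-1)}} = B_n - D_i - C_j - F_k,$$

with one shared threshold set $F_k$ across stations (a rating-scale rather
than partial-credit structure: all stations use the same marksheet).
`category_probabilities()` and `expected_score()` expose the model
primitives.

### Estimation

`fit_jmle()` maximises the joint likelihood by alternating Newton–Raphson
sweeps over the four parameter blocks. Students, stations and cohorts use
per-element Newton steps (score residual over information, capped at 1
logit per sweep). The thresholds are updated with a full multivariate
Newton step on the $(m-1)$-vector: on 20-odd categories the
cross-derivatives between adjacent steps are large and a per-threshold
update limit-cycles, whereas the full-Hessian step converges in 15–40
sweeps. Convergence is declared when the largest absolute parameter change
in a sweep drops below `convergence_tol` (default 1e-3 logits; the
estimates themselves move by far less at that point).

Identification: station difficulties, cohort severities and thresholds are
centred at zero after every sweep (with the compensating constant absorbed
into the student measures), so the student facet carries the location.

Numerical and degenerate-input policies:

* *Null categories.* Categories never observed in a replicate are dropped
  and estimation runs on the observed ordered category values; fair
  averages are computed over those raw values, so they return to the 6–27
  scale. With ~875 ratings on 22 categories some empty cells are certain,
  and an unobserved category's threshold has no maximum-likelihood
  estimate.
* *Extreme totals.* A student scoring the minimum (or maximum) category
  everywhere has an infinite measure; their total is shrunk by
  `extreme_score_adjustment` (default 0.3 score points, the convention of
  the established rater-measurement programs) to keep it estimable.
* *Disconnection.* `check_connectivity()` builds the cohort graph through
  shared video performances. With no videos (or no participants) the
  cohorts fall into separate subsets and severity is not identified; under
  `anchor_policy = "auto"` all cohort severities are then anchored at 0,
  which makes the zero-video condition well-defined and turns adjustment
  into a pure Rasch round-trip (empirically below 0.05 points of change on
  average).
* *Constant data.* If every score is identical the fit returns a degenerate
  solution whose fair average is that constant.

### What the adjusted score is

Video ratings exist to link the cohorts; they are comparisons of examiners,
not extra evidence about the filmed student, and must not move that
student's own result. The fit therefore reports, alongside the
joint-likelihood measures, a *reporting measure* per student: their measure
re-estimated from live observations only, holding stations, cohorts and
thresholds at the jointly linked values. `adjusted_scores()` back-transforms
the reporting measure to the raw scale with the other facets at their
reference zero — the fair average. Two alternatives were considered and
rejected: letting video ratings feed the students' own measures leaks the
video raters' leniencies and residuals into the scores of filmed students
(visibly degrading adjustment precisely when residual error is small), and
modelling each filmed performance as a separate person element makes the
severity estimates substantially noisier when linking is sparse (two raters
per video leave such pseudo-persons barely estimable). The reporting-measure
construction keeps the linking strength of the joint fit and the cleanliness
of live-only student scores.

## Accuracy metrics

Per student and replicate: the *true mean* (mean of the continuous true
station scores), the *observed mean* (mean of live ratings; videos are
excluded), and the fair average. Observed error and adjusted error are the
absolute differences from the true mean; the adjustment is
|adjusted − observed|. A student improves only if the adjusted error is
*strictly* smaller — ties do not count. Note the errors compare per-student
*means*, not per-station ratings: the adjusted score is one number per
student, and its natural raw-scale rival is the student's mean observed
score.

A condition pools all students across replicates: the error ratio `ErR` is
the ratio of pooled means (not a mean of per-replicate ratios, which would
weight small denominators erratically), and `pAcc` is the pooled improved
fraction. `rq4_tabulate()` expresses adjustment sizes and accuracy changes
as percentages of the scale range, bins them ([0–1%) … [8–9%), >9%; ±6% in
2% steps), and looks for the smallest *observed* bin from which the
cumulative (upper-tail) pAcc reaches 0.8. Empty leading bins cannot anchor
a threshold: when every adjustment exceeds 3% of scale — the typical
situation under a 20% baseline difference — the threshold lands at the
first bin that actually holds students. An exact zero accuracy change is
binned on the non-negative side.

## Study grids, replication, determinism

`study_grid()` builds three factorial designs: linking videos {0,2,4,6,8} ×
participation {50,65,80,100}% (20 conditions); baseline difference
{0,5,10,20}% × stations {6,12,18} (12 conditions, examiners scaling as 4
per station); and residual error divided by {2,4,8} (3 conditions).
Non-varied parameters stay at the defaults. `marginal_summaries()` averages
condition-level `ErR`/`pAcc` over the crossed factor as a simple mean of
condition values, matching the factorial framing.

Each replicate's seed is `master_seed + condition_id * 100000 + replicate`,
so streams never collide within a study, results are independent of
execution order, and a master seed reproduces every number bitwise
(`write_study()` records the manifest). Two replicate presets are provided:
`"full"` (1000, publication-stable) and `"desk"` (200). At 200 replicates
the Monte-Carlo standard error of a pooled error ratio at the defaults is
under 0.01, comfortably inside the ±0.05 resolution at which the headline
quantities are read; the package's own acceptance checks run at 100–200
replicates per condition for that reason.

```{r quick-run, eval = FALSE}
res <- run_condition(simulation_params(baseline_diff = 0.2),
                     n_replicates = 200, master_seed = 1)
res$summary
tab <- rq4_tabulate(run_condition(simulation_params(baseline_diff = 0.2),
                                  n_replicates = 100, master_seed = 1,
                                  keep_students = TRUE)$accuracy,
                    scale_range = 21)
tab$threshold_bin
```

## What the generator does and does not emulate

It emulates: bounded integer marksheets; fully nested live scoring; sparse,
possibly incomplete video linking; perfectly anti-correlated inter-school
ability/stringency differences; and tunable residual rating noise. It does
**not** emulate examiner-by-station interactions (examiners never change
station, so such effects are inestimable in this design and are folded into
the residual), rater drift, contrast or halo structure (all residual),
multidimensional performance constructs, item-level domain scoring (the
marksheet is a collapsed sum score), or non-random participation. Passing
tests therefore certify the adjustment machinery under these idealised
conditions; on real data, multidimensionality, drift and informative
non-participation can only degrade adjustment further.

## Known limitations

* Joint maximum likelihood is inconsistent in the number of observations
  per element; with 12–13 ratings per student, measures are slightly
  stretched. Since observed and adjusted scores are compared on the raw
  scale after a fair-average round-trip, the stretch largely cancels, but
  severity estimates inherit a few percent of it.
* Cohort severity can only be estimated as precisely as the video block
  allows. With Bernoulli participation the participating subset's mean
  leniency differs from the whole cohort's by ~0.2 points at the defaults;
  that sampling gap is a floor on adjustment accuracy no estimator can
  beat, and it is the main reason weakly-linked conditions show error
  ratios above 1.
* The rating-scale structure shares thresholds across stations. If real
  stations used different marksheets a partial-credit structure would be
  needed; the fit does not provide one.
* Standard errors are information-based diagnostics, not used by the
  accuracy metrics.
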