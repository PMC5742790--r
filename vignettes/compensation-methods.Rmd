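---
title: "Methods: lameness scoring, expert acceptability and compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lameness scoring, expert acceptability and compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wqlame)
```

`wqlame` studies a failure mode of hierarchical animal-welfare aggregation:
*compensation*, where a severe problem on one measure (here, dairy-cow
lameness) is masked by good scores elsewhere as measures are rolled up into
criteria, principles and one overall farm category.  The package implements
three pieces — herd lameness scoring, an ordinal model of expert
acceptability, and the comparison between the two — plus seeded generators
that stand in for the farm and questionnaire data, which were never
deposited.

## 1. Herd lameness scoring

Each cow carries a gait score: 0 (non-lame), 1 (mildly lame, imperfect
stride rhythm), 2 (severely lame, reluctance to bear weight).  Herd
prevalence $(p_m, p_s)$, in percent, is collapsed into a 0–100 index with
severity weights $w_m = 2$ and $w_s = 7$ (one severely lame cow counts as
3.5 mildly lame ones), normalized by the maximum weight:

$$I = 100 - \frac{w_m p_m + w_s p_s}{w_s}.$$

The normalization by $w_s$ is the only formula consistent with all the
published worked values (index 100 at no lameness, 90 at 10% severe, 50 at
50% severe, 0 at 100% severe); the source describes the index only through
those examples.

The index is then transformed into a *welfare score* that penalizes low
prevalences disproportionately.  The protocol's exact spline is not public;
the transform here is a monotone shape-preserving piecewise-cubic (Hyman)
interpolation through the five published anchor pairs $(0,0)$, $(70,21)$,
$(80,29)$, $(90,48)$, $(100,100)$.  It is exact at every anchor, strictly
increasing, and never exceeds the index below 90.  Anchors are configurable
(`score_anchors()`), so a protocol-exact curve can be swapped in; whether
the true curve changes curvature between the anchors is unknowable from the
published points.

Scores are banded into Not classified / Acceptable / Enhanced / Excellent
at 20/55/80 (configurable, half-open on the left so a boundary score falls
in the better category).  `wq_aggregate()` provides a configurable
*skeleton* of the measures-to-criteria-to-principles-to-overall chain with
weighted-mean combiners and a threshold-predicate overall rule.  This is
deliberately not the protocol's I-spline/Choquet machinery (which lives in
the protocol reference, not the source for this package); it preserves the
0–100 scale at every level, which is all the compensation analysis needs.
The overall rule treats its thresholds as "at least" comparisons so that
boundary scores behave like the category bands.

Farms are assigned to nine lameness *profiles* crossing mild bins 5–15,
15–40, 40–70, >70% with severe bins <5, 5–15, >15% — the nine combinations
that occur in the case study and match the questionnaire scenarios.  Bins
are half-open on the left and closed at 100; combinations outside the nine
(including mild below 5%) are reported as `Unprofiled`, never dropped.
Whether "severe 0%" in the published profile labels means exactly zero or
below 5% is ambiguous; the `[0, 5)` reading is used.

## 2. Expert acceptability: cumulative-link mixed model

Experts rate scenarios $(p_m, p_s)$ on a 0–10 acceptability scale.  Ratings
are modelled with a cumulative-logit model with *equidistant thresholds*
$\theta_j = \alpha + (j-1)\delta$, $j = 1..10$, a respondent random
intercept $u_i \sim N(0, \sigma^2)$, and fixed effects in the prevalences
(as proportions):

$$P(Y_{io} \le j - 1 \mid u_i) = \operatorname{logit}^{-1}
  (\theta_j - x_{io}'\beta - u_i).$$

Four nested fixed-effect structures are considered: linear in both
prevalences; plus their interaction (non-additive); plus quadratic terms
(non-linear); or both.  The marginal likelihood integrates $u_i$ out by
non-adaptive Gauss–Hermite quadrature; fits are compared by
$\mathrm{AIC} = -2\ell + 2k$, where $k$ counts $\alpha$, $\delta$, all
$\beta$ and $\sigma$, with ties broken toward the smaller model.
Predictions for the "average expert" set $u = 0$ and are binned into
clearly unacceptable (0–2), unacceptable (3–4), acceptable (5–7), clearly
acceptable (8–10), with "acceptable" summarized as $P(Y \ge 6)$.

Numerical choices:

* **Quadrature order** defaults to 61.  At the originally intended order 31
  the marginal likelihood differs from brute-force integration by about
  $4\times10^{-5}$ at $\sigma = 1.5$, which breaks the package's own
  1e-6 agreement requirement; order 61 achieves ~1e-9 on the reference
  instances at negligible cost (cluster size is only 5, so adaptive
  centering is unnecessary).
* **Parameterization**: $(\alpha, \log\delta, \beta, \log\sigma)$, so the
  spacing and SD constraints hold by construction.  Design columns are
  rescaled to unit maximum inside the optimizer (the quadratic and
  interaction columns span tiny ranges on the proportion scale, which
  otherwise cripples BFGS conditioning) and estimates are mapped back.
* **Optimization**: BFGS with analytic gradients of the marginal
  likelihood (posterior-node-weight form), warm-started from a fixed
  effects fit whose thresholds come from regressing empirical cumulative
  logits on the category index; up to five deterministic starts spread
  over $\sigma$.  Line-search excursions are guarded (log-scale parameters
  clamped, non-finite objectives mapped to a large value).  A fit is
  flagged converged when the gradient max-norm falls below a tolerance
  scaled to the likelihood magnitude.
* **Boundary**: fitted $\sigma$ below `sigma_floor` (default $10^{-3}$) is
  reported as exactly 0 with the likelihood recomputed there — a
  degenerate fit, not an error.  Note that under a true $\sigma = 0$ the
  boundary MLE converges at the $n^{1/4}$ rate, so small positive
  estimates at realistic sizes are expected sampling behavior.

**Panel cleaning.**  A respondent's scenario pair is *ordered* when one
scenario dominates the other componentwise; a *violation* is a strictly
higher rating for the strictly worse scenario.  Respondents with two or
more violations over all ordered pairs are removed as nonsensical (the
published rule says "two or more nonsensical scores" without defining pair
enumeration; counting all ordered pairs is this package's reading), and
respondents missing any of their allocated ratings are removed as
incomplete.  Cleaning is idempotent.  One consequence found during
development: under a monotone truth with respondent noise, the rule also
removes honest-but-noisy respondents, and that truncation measurably biases
the linear prevalence coefficients.  The recovery and selection experiments
therefore fit uncleaned panels; cleaning is exercised on contaminated
panels, which it catches at high rates.

**Per-measure agreement.**  For each welfare measure, an intercept-only
cumulative-link model with a respondent random intercept is fitted to the
0–10 validity ratings; $\sigma$ is read as systematic disagreement beyond
multinomial noise.  With a single rating per respondent and measure,
$\sigma$ is identified only through the shape difference between a logistic
and a logistic-normal convolution; the profile likelihood is nearly flat,
so estimates are usable for rank ordering across measures (given thousands
of respondents) but not for precise recovery — consistent with the original
analysis declining to attach confidence intervals to these estimates.

## 3. Synthetic data: the stated world

The generators emulate the two study designs so the pipeline is testable
end to end:

* **Herds** (`generate_herds()`): 44 farms of 101–452 cows.  Sizes are
  drawn from a clamped log-normal (median ≈ 175 cows, log-SD 0.28, mean ≈
  184, matching the reported mean within the reported range); the source
  gives only min/mean/max, so the shape is this package's choice of a
  realistic right-skewed herd-size distribution.  Per-profile farm counts
  default to the case study's (2, 6, 14, 4, 2, 7, 2, 4, 3); each farm's
  target prevalence is uniform inside its profile bin (open-ended bins
  capped at 90% mild / 35% severe to stay feasible), and per-cow gait
  scores are i.i.d. multinomial at the target — no within-farm correlation,
  the simplest model consistent with prevalence-only reporting.
* **Expert panel** (`generate_expert_ratings()`): 181 respondents, each
  allocated 5 of the 9 scenarios uniformly without replacement, rating from
  the cumulative-logit model above.  The default truth is a least-squares
  calibration of $(\alpha, \delta, \beta)$ to the published average-expert
  bin probabilities: $\alpha = -7.25$, $\delta = 1.68$,
  $\beta = (-9.6, -61.5, +1.3, +102, +31.5)$ for (mild, severe, mild²,
  severe², mild×severe); $\sigma = 1.5$ is a moderate-disagreement choice,
  unrecoverable from published numbers.  A configurable fraction of
  contaminants rates i.i.d. uniformly — a fixture for the cleaning rule,
  not a feature of the published analysis.
* **Measure panel** (`generate_measure_scores()`): 159 respondents × 10
  measures, one rating each, intercept-only truths positioned by a
  per-measure median with per-measure $\sigma$; defaults give somatic cell
  count, access to brush and avoidance distance real disagreement and
  lameness a high median with none, mirroring the qualitative published
  pattern.  The measure list itself is configuration: only four of the ten
  measures are named in the source.

Seeding: every config carries one seed; a small integer mix fans it out to
independent sub-streams per generator, and identical configs are
byte-identical after serialization.

What a green test does *not* establish: real farms have within-herd
correlation, assessor effects and seasonal structure; real experts have
covariates, non-logistic tails and informative non-response.  None of that
is modelled, so passing tests certify the *machinery* (formulas, estimation,
bookkeeping, direction-level conclusions), not empirical claims about real
herds or expert panels.

**The well-separated truth.**  `selection_truth()`
($\alpha = -16$, $\delta = 1.8$, $\beta = (-5, -15, -15, -120, -40)$,
$\sigma = 1.2$) exists because the Table-calibrated default has a weak
quadratic block on the nine-scenario design (three mild levels leave little
room for curvature after the linear term), making "AIC recovers the
generating structure" a test of the design rather than of the selector.
Its coefficients were chosen, before running the selection study, to give
the quadratic block and the interaction orthogonalized signals of roughly
0.4–0.7 logit RMS across the scenarios (tens of expected AIC points per
omitted group at 181 respondents), to keep the surface monotone in both
prevalences, to stay inside the dynamic range of the 0–10 ladder, and to
keep every coefficient away from zero so relative bias at $n = 2000$ is
well defined.

## 4. Compensation comparison

`build_crosstab()` tabulates farms by profile with row-percent category
distributions at criterion, principle and overall level; totals are always
recomputed from counts, never from rounded percentages, and rounding to one
decimal happens only at render time.  `validate_crosstab()` checks internal
consistency and *surfaces* discrepancies rather than correcting them — the
published case-study table itself contains one (a criterion-level row
summing to 50%, without which its printed 11.4% Not-classified total cannot
be rebuilt), and `casestudy_profiles()` transcribes it verbatim, defect
included.

`predict_profile_acceptability()` maps each profile to its questionnaire
scenario (bin lower bounds 5/15/40/>70% mild → shown 10/40/70/70%; <5/5–15/
>15% severe → 0/5/15%) and tabulates average-expert bin probabilities.
`compensation_report()` then contrasts, for configured profile sets
(defaults: 1, 2, 5 "tolerated" and 6–9 "rejected"), the share of farms in
the set — with a Wilson score interval; the original's CI method is
unstated and its printed interval matches no standard method to the third
decimal, so Wilson is declared in the output metadata — against the
predicted clearly-unacceptable probability.  Compensation is flagged when
profiles experts overwhelmingly reject still largely escape the worst
overall category.

## 5. Known limitations

* The aggregation skeleton is a stand-in: criterion/principle/overall
  categories from `wq_aggregate()` reproduce the *shape* of protocol
  output, not protocol-exact values, so cross-tab comparisons against real
  protocol output are direction-level only.
* The equidistant-threshold constraint is global; flexible thresholds,
  non-logit links and crossed random effects are out of scope.
* Published AIC values, predicted probability tables and disagreement SDs
  are not reproducible without the undeposited raw data; the package
  reproduces the printed worked examples, the arithmetic consistency of the
  published tables, and the qualitative conclusions.
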