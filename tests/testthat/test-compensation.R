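make_farms <- function(profiles, crit, prin, over) {
  labs <- wq_categories()
  data.frame(farm_id = seq_along(profiles), profile = profiles,
             criterion_category = factor(crit, levels = labs, ordered = TRUE),
             principle_category = factor(prin, levels = labs, ordered = TRUE),
             overall_category = factor(over, levels = labs, ordered = TRUE))
}

test_that("crosstab rows and totals are counted from the data", {
  farms <- make_farms(c(1L, 1L, 3L),
                      c("Enhanced", "Enhanced", "Acceptable"),
                      c("Enhanced", "Enhanced", "Acceptable"),
                      c("Enhanced", "Acceptable", "Acceptable"))
  ct <- build_crosstab(farms)
  r1 <- ct[ct$profile == "Profile 1", ]
  expect_equal(r1$n, 2L)
  expect_equal(r1$criterion.enhanced, 100)
  tot <- ct[ct$profile == "Total", ]
  expect_equal(tot$n, 3L)
  expect_equal(tot$overall.acceptable, 200 / 3)
  expect_equal(nrow(validate_crosstab(ct)), 0L)
})

test_that("crosstab conservation holds for seeded pipeline runs", {
  for (seed in c(3L, 17L)) {
    herds <- generate_herds(herd_config(seed = seed))
    farms <- aggregate_farms(score_farms(herds))
    ct <- build_crosstab(farms)
    expect_equal(nrow(validate_crosstab(ct)), 0L)
    body <- ct[ct$profile != "Total", ]
    expect_equal(sum(body$n), ct$n[ct$profile == "Total"])
    # totals equal count-weighted means of the body rows
    expect_equal(crosstab_totals(body)$overall.not_classified,
                 ct[ct$profile == "Total", "overall.not_classified"])
  }
})

test_that("unprofiled farms appear as an explicit row", {
  farms <- make_farms(c(2L, NA), c("Enhanced", "Enhanced"),
                      c("Enhanced", "Enhanced"), c("Enhanced", "Enhanced"))
  ct <- build_crosstab(farms)
  expect_true("Unprofiled" %in% ct$profile)
  expect_equal(ct$n[ct$profile == "Unprofiled"], 1L)
})

test_that("published case-study table reconstructs its own totals", {
  ct <- casestudy_profiles()
  tot <- crosstab_totals(ct)
  expect_equal(round(tot$criterion.enhanced, 1), 15.9)
  expect_equal(round(tot$criterion.acceptable, 1), 72.7)
  expect_equal(round(tot$overall.not_classified, 1), 2.3)
  expect_equal(round(tot$principle.acceptable, 1), 86.4)
  # the known internal inconsistency is surfaced, not corrected: the
  # Profile 7 criterion row sums to 50 and the published criterion-level
  # Not-classified total (11.4) cannot be rebuilt from the body (9.1)
  issues <- validate_crosstab(ct)
  expect_true(any(issues$row == "Profile 7" &
                    grepl("criterion", issues$check)))
  expect_equal(round(tot$criterion.not_classified, 1), 9.1)
})

test_that("wilson interval matches the score formula and its bounds", {
  expect_equal(wilson_ci(0, 44)[["lower"]], 0)
  expect_equal(wilson_ci(44, 44)[["upper"]], 1)
  ci <- wilson_ci(10, 44, 0.95)
  expect_equal(unname(round(ci, 3)), c(0.128, 0.370))
  # independent oracle: prop.test without continuity correction is Wilson
  pt <- prop.test(10, 44, correct = FALSE)$conf.int
  expect_equal(unname(ci), as.numeric(pt), tolerance = 1e-10)
  expect_error(wilson_ci(5, 0), "n > 0")
  expect_error(wilson_ci(-1, 10), "successes")
})

test_that("compensation report computes shares, CIs and the verdict", {
  ct <- casestudy_profiles()
  acc <- predict_profile_acceptability(clmm_params())
  rep <- compensation_report(ct, acc)
  sets <- rep$sets
  expect_equal(round(sets$share_pct[sets$set == "tolerated"], 1), 22.7)
  expect_equal(round(sets$share_pct[sets$set == "rejected"], 1), 36.4)
  expect_true(all(sets$ci_lower_pct <= sets$share_pct &
                    sets$share_pct <= sets$ci_upper_pct))
  expect_equal(rep$overall_not_classified_pct, 2.3)
  expect_true(rep$compensated)
  expect_error(compensation_report(ct, acc, list(bad = c(1L, 12L))),
               "unknown profile")
  # empty profile set: zero share with a zero lower bound
  r0 <- compensation_report(ct, acc, list(none = integer(0)))
  expect_equal(r0$sets$share_pct, 0)
  expect_equal(r0$sets$ci_lower_pct, 0)
})

test_that("profile acceptability rows are proper percent distributions", {
  acc <- predict_profile_acceptability(clmm_params())
  bins <- c("clearly_unacceptable", "unacceptable", "acceptable",
            "clearly_acceptable")
  expect_equal(unname(rowSums(acc[, bins])), rep(100, 9), tolerance = 1e-9)
  # clearly-unacceptable rises down the severe gradient at fixed mild
  # (evaluate on the unique scenario grid; profiles 3/4 and 6/7 share one)
  uq <- unique(acc[, c("mild_pct", "severe_pct", "clearly_unacceptable")])
  for (m in c(10, 40, 70)) {
    rows <- uq[uq$mild_pct == m, ]
    cu <- rows$clearly_unacceptable[order(rows$severe_pct)]
    expect_true(all(diff(cu) > 0))
  }
})
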