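test_that("prevalence is computed by direct counting", {
  p <- compute_prevalence(c(0, 0, 0, 0))
  expect_equal(c(p$mild_pct, p$severe_pct), c(0, 0))
  p <- compute_prevalence(c(2, 2, 0, 0))
  expect_equal(c(p$mild_pct, p$severe_pct), c(0, 50))
  p <- compute_prevalence(c(1, 1, 1, 1, 1, 1, 1, 0, 2, 2))
  expect_equal(c(p$mild_pct, p$severe_pct), c(70, 20))
  expect_error(compute_prevalence(integer(0)), "empty")
  expect_error(compute_prevalence(c(0, 3)), "0, 1 or 2")
})

test_that("lameness index reproduces the worked examples", {
  expect_equal(lameness_index(prevalence(0, 10)), 90)
  expect_equal(lameness_index(prevalence(0, 50)), 50)
  expect_equal(lameness_index(prevalence(0, 0)), 100)
  expect_equal(lameness_index(prevalence(0, 100)), 0)
  expect_equal(lameness_index(prevalence(100, 0)), 100 - 200 / 7,
               tolerance = 1e-12)
})

test_that("index is strictly decreasing in each prevalence component", {
  for (m in seq(0, 60, by = 10)) {
    i1 <- lameness_index(prevalence(m, 10))
    i2 <- lameness_index(prevalence(m + 5, 10))
    i3 <- lameness_index(prevalence(m, 15))
    expect_lt(i2, i1)
    expect_lt(i3, i1)
  }
})

test_that("welfare-score transform hits the anchors and is monotone", {
  expect_equal(index_to_welfare_score(c(0, 70, 80, 90, 100)),
               c(0, 21, 29, 48, 100))
  grid <- seq(0, 100, by = 0.25)
  s <- index_to_welfare_score(grid)
  expect_true(all(diff(s) > 0))
  # score falls faster than the index over the non-trivial range
  sub <- grid <= 90
  expect_true(all(s[sub] <= grid[sub] + 1e-9))
  expect_error(index_to_welfare_score(101), "\\[0, 100\\]")
  expect_error(index_to_welfare_score(-0.1), "\\[0, 100\\]")
})

test_that("index + transform composition maps the printed pairs", {
  for (case in list(c(10, 48), c(20, 29), c(30, 21))) {
    idx <- lameness_index(prevalence(0, case[1L]))
    expect_equal(index_to_welfare_score(idx), case[2L])
  }
})

test_that("custom anchors are validated and respected", {
  expect_error(score_anchors(cbind(c(0, 50, 100), c(0, 60, 50))),
               "strictly increasing")
  expect_error(score_anchors(cbind(c(10, 100), c(10, 100))), "endpoints")
  lin <- score_anchors(cbind(c(0, 50, 100), c(0, 50, 100)))
  expect_equal(index_to_welfare_score(25, lin), 25)
})

test_that("categorization uses half-open bands", {
  expect_equal(as.character(categorize(48)), "Acceptable")
  expect_equal(as.character(categorize(0)), "Not classified")
  expect_equal(as.character(categorize(100)), "Excellent")
  expect_equal(as.character(categorize(c(20, 55, 80))),
               c("Acceptable", "Enhanced", "Excellent"))
})

test_that("profile assignment matches the published bins and partitions them", {
  expect_equal(assign_profile(prevalence(50, 0)), 3L)
  expect_equal(assign_profile(prevalence(20, 10)), 5L)
  expect_true(is.na(assign_profile(prevalence(3, 0))))
  expect_true(is.na(assign_profile(prevalence(10, 7))))   # mild 5-15, severe >5
  expect_true(is.na(assign_profile(prevalence(75, 20))))  # mild >70, severe >15
  # partition property: every in-bin point maps to exactly one profile
  set.seed(1)
  for (i in 1:200) {
    m <- runif(1, 0, 85)
    s <- runif(1, 0, min(30, 100 - m))
    g <- wqlame:::profile_grid()
    hits <- sum(m >= g$mild_lo & m < g$mild_hi &
                  s >= g$severe_lo & s < g$severe_hi)
    expect_lte(hits, 1L)
    pr <- assign_profile(prevalence(m, s))
    expect_equal(is.na(pr), hits == 0L)
  }
})

test_that("aggregation skeleton combines and classifies", {
  all100 <- setNames(rep(100, 7), c("lameness", "integument", "disease",
                                    "pain_management", "feeding", "housing",
                                    "behaviour"))
  agg <- wq_aggregate(all100)
  expect_equal(agg$criteria$score, rep(100, 6))
  expect_equal(agg$principles$score, rep(100, 4))
  expect_equal(agg$overall, "Excellent")
  agg0 <- wq_aggregate(all100 * 0)
  expect_equal(agg0$overall, "Not classified")
  # equal-weights combiner: mean of (48, 72) is 60
  agg2 <- wq_aggregate(`[<-`(all100, c("lameness", "integument"), c(48, 72)))
  expect_equal(agg2$criteria$score[agg2$criteria$criterion ==
                                     "absence_of_injuries"], 60)
  expect_error(wq_aggregate(all100[-1L]), "lameness")
})

test_that("score_farms runs the whole per-farm chain", {
  herds <- data.frame(farm_id = rep(1:2, c(10, 4)),
                      cow_id = c(1:10, 1:4),
                      gait_score = c(rep(1, 6), 0, 0, 2, 2, rep(0, 4)))
  sc <- score_farms(herds)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$mild_pct, c(60, 0))
  expect_equal(sc$severe_pct, c(20, 0))
  expect_equal(sc$index[2L], 100)
  expect_equal(sc$welfare_score[2L], 100)
  expect_equal(sc$profile, c(9L, NA))
})
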