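test_that("single-record likelihood matches the closed form", {
  rec <- data.frame(respondent_id = "a", mild = 0, severe = 0, rating = 0L)
  pars <- clmm_params(alpha = 0, delta = 1, beta = numeric(0), sigma = 0)
  expect_equal(clmm_loglik(pars, rec), log(plogis(0)), tolerance = 1e-12)
})

test_that("sigma = 0 reduces exactly to the fixed-effects likelihood", {
  recs <- tiny_panel()
  pars <- clmm_params(alpha = -2, delta = 0.6,
                      beta = c(mild = -3, severe = -10), sigma = 0)
  expect_equal(clmm_loglik(pars, recs), brute_loglik(pars, recs),
               tolerance = 1e-12)
})

test_that("quadrature matches brute-force integration to 1e-6", {
  recs <- tiny_panel()
  for (sigma in c(0.4, 1.5)) {
    pars <- clmm_params(alpha = -2, delta = 0.6,
                        beta = c(mild = -3, severe = -10), sigma = sigma)
    expect_equal(clmm_loglik(pars, recs), brute_loglik(pars, recs),
                 tolerance = 1e-6)
  }
  # full five-term structure too
  pars <- clmm_params(sigma = 1.2)
  expect_equal(clmm_loglik(pars, recs), brute_loglik(pars, recs),
               tolerance = 1e-6)
})

test_that("invalid parameters are rejected", {
  expect_error(clmm_params(delta = 0), "delta")
  expect_error(clmm_params(sigma = -1), "sigma")
  expect_error(clmm_params(beta = c(bogus = 1)), "named")
})

test_that("analytic gradient agrees with numerical differentiation", {
  skip_if_not_installed("numDeriv")
  recs <- tiny_panel()
  X <- wqlame:::clmm_model_matrix(model_spec("linear"), recs$mild,
                                  recs$severe)
  resp <- as.integer(factor(recs$respondent_id))
  f <- function(th) wqlame:::clmm_loglik_core(
    th[1L], exp(th[2L]), drop(X %*% th[3:4]), recs$rating, resp,
    exp(th[5L]), 31L)$loglik
  th <- c(-2, log(0.6), -3, -10, log(1.5))
  ga <- wqlame:::clmm_grad_core(-2, 0.6, drop(X %*% c(-3, -10)), X,
                                recs$rating, resp, 1.5, 31L)
  expect_equal(ga, numDeriv::grad(f, th), tolerance = 1e-6)
})

test_that("fit recovers a known truth on a moderate panel", {
  tr <- selection_truth()
  pan <- generate_expert_ratings(panel_config(n_respondents = 400L,
                                              truth = tr, seed = 31L))
  f <- clmm_fit(pan, model_spec("linear_quadratic_interaction"), fast_ctrl())
  expect_true(f$converged)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$n_params)
  expect_equal(f$n_params, 8L)
  expect_lt(abs(f$alpha - tr$alpha) / abs(tr$alpha), 0.15)
  expect_lt(abs(f$delta - tr$delta) / tr$delta, 0.15)
  expect_lt(abs(f$sigma - tr$sigma), 0.4)
})

test_that("sigma = 0 truths give boundary-consistent fits", {
  # Boundary variance components converge at the n^(1/4) rate, so the
  # point estimate stays noticeably above zero at practical sizes; the
  # meaningful checks are that it is small and that the likelihood gain
  # over sigma = 0 is insignificant against the half-chi-square(1) null.
  truth <- clmm_params(alpha = -5.5, delta = 1.1,
                       beta = c(mild = -4, severe = -20), sigma = 0)
  pan <- generate_expert_ratings(panel_config(n_respondents = 250L,
                                              truth = truth, seed = 12L))
  f <- clmm_fit(pan, model_spec("linear"), fast_ctrl(n_starts = 2L))
  expect_lt(f$sigma, 0.6)
  p0 <- clmm_params(f$alpha, f$delta, f$beta, sigma = 0)
  lrt <- 2 * (f$loglik - clmm_loglik(p0, pan, model_spec("linear")))
  expect_gte(lrt, -1e-6)
  expect_lt(lrt, qchisq(0.95, 1))
  # the reporting floor maps tiny fitted SDs to exactly zero
  f0 <- clmm_fit(pan, model_spec("linear"),
                 fast_ctrl(n_starts = 1L, sigma_floor = 0.5))
  expect_identical(f0$sigma, 0)
})

test_that("rank-deficient designs are refused", {
  recs <- data.frame(respondent_id = rep(1:40, each = 2),
                     mild = 0.4, severe = 0.05,
                     rating = rep(c(2L, 5L), 40))
  expect_error(clmm_fit(recs, model_spec("linear")), "rank-deficient")
})

test_that("AIC selection follows the arithmetic and the tie rule", {
  mk <- function(terms, loglik, n_params) {
    structure(list(spec = model_spec(terms), loglik = loglik,
                   n_params = n_params, aic = -2 * loglik + 2 * n_params,
                   converged = TRUE, n_obs = 905L, n_respondents = 181L),
              class = "clmm_fit")
  }
  f1 <- mk("linear_quadratic_interaction", -1197.3, 5L)
  f2 <- mk("linear", -1183.9, 4L)
  sel <- select_by_aic(list(f1, f2))
  expect_equal(sort(sel$table$aic), c(2375.8, 2404.6))
  expect_equal(sel$best$spec$terms, "linear")
  # exact tie goes to the smaller model
  f3 <- mk("linear_interaction", -1000, 4L)
  f4 <- mk("linear", -1001, 3L)   # same AIC = 2008
  sel2 <- select_by_aic(list(f3, f4))
  expect_equal(sel2$best$spec$terms, "linear")
  # differing data are rejected
  f5 <- mk("linear", -900, 4L); f5$n_obs <- 500L
  expect_error(select_by_aic(list(f1, f5)), "identical data")
})

test_that("average-respondent predictions are proper distributions", {
  set.seed(77)
  for (i in 1:20) {
    pars <- clmm_params(alpha = runif(1, -10, 0), delta = runif(1, 0.3, 2),
                        beta = c(mild = runif(1, -20, 0),
                                 severe = runif(1, -60, 0)),
                        sigma = runif(1, 0, 2))
    p <- predict_probs(pars, c(runif(1), runif(1) * 0.3))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(predict_probs(clmm_params(), c(1.2, 0)), "\\[0, 1\\]")
})

test_that("negative prevalence effects give monotone acceptability", {
  pars <- clmm_params(alpha = -4, delta = 0.8,
                      beta = c(mild = -5, severe = -25), sigma = 1)
  pa <- sapply(seq(0, 0.3, by = 0.05), function(s)
    prob_acceptable(predict_probs(pars, c(0.1, s))))
  expect_true(all(diff(pa) < 0))
})

test_that("probability binning matches direct sums", {
  u <- rep(1 / 11, 11)
  expect_equal(unname(bin_probs(u)), c(3, 2, 3, 3) / 11)
  expect_equal(prob_acceptable(u), 5 / 11)
  point <- c(1, rep(0, 10))
  expect_equal(unname(bin_probs(point)), c(1, 0, 0, 0))
  expect_equal(prob_acceptable(point), 0)
  expect_error(bin_probs(rep(0.2, 11)), "summing to 1")
  expect_error(category_bins(bins = list(a = 0:3, b = 3:10,
                                         c = integer(0), d = integer(0))),
               "partition")
})

test_that("agreement model ranks respondent SDs correctly", {
  # With a single rating per respondent and measure, sigma is identified
  # only by the shape difference between a logistic and a logistic-normal
  # convolution, so the recovery experiment needs a large panel to have
  # power (see the methods vignette).
  cfg <- measure_panel_config(
    measures = data.frame(measure = c("low_dis", "high_dis"),
                          median = c(6, 6), sigma = c(0.5, 3)),
    n_respondents = 3000L, seed = 21L)
  ms <- generate_measure_scores(cfg)
  ag <- fit_agreement(ms, fast_ctrl())
  expect_false(any(ag$degenerate))
  expect_lt(ag$sigma[ag$measure == "low_dis"],
            ag$sigma[ag$measure == "high_dis"])
  # zero-SD measure stays near the boundary (weak identification keeps the
  # sampling distribution of the estimate wide even at this size)
  cfg0 <- measure_panel_config(
    measures = data.frame(measure = "flat", median = 5, sigma = 0),
    n_respondents = 3000L, seed = 22L)
  ag0 <- fit_agreement(generate_measure_scores(cfg0), fast_ctrl())
  expect_lt(ag0$sigma, 0.5)
})

test_that("agreement estimate is invariant to respondent relabelling", {
  cfg <- measure_panel_config(
    measures = data.frame(measure = "m", median = 6, sigma = 1.5),
    n_respondents = 120L, seed = 23L)
  ms <- generate_measure_scores(cfg)
  ag1 <- fit_agreement(ms, fast_ctrl())
  ms2 <- ms
  ms2$respondent_id <- rev(ms2$respondent_id)
  ag2 <- fit_agreement(ms2, fast_ctrl())
  expect_equal(ag1$sigma, ag2$sigma, tolerance = 1e-4)
})
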