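#' The nine questionnaire scenarios
#'
#' Cross of mild lameness prevalence 10/40/70% with severe prevalence
#' 0/5/15%, as shown to the expert panel.
#'
#' @return Data frame with `mild`, `severe` (proportions) and `mild_pct`,
#'   `severe_pct`.
#' @export
default_scenarios <- function() {
  g <- expand.grid(severe_pct = c(0, 5, 15), mild_pct = c(10, 40, 70))
  data.frame(mild = g$mild_pct / 100, severe = g$severe_pct / 100,
             mild_pct = g$mild_pct, severe_pct = g$severe_pct)
}

#' A well-separated generative truth for recovery and selection experiments
#'
#' The default [clmm_params()] truth mirrors the published acceptability
#' surface, whose quadratic components are weak on the nine-scenario design;
#' power experiments on model selection and parameter recovery instead need
#' a truth whose quadratic and interaction components each carry a clearly
#' detectable signal at the study size, and whose coefficients are all
#' bounded away from zero so relative bias is meaningful.  This parameter
#' set keeps the acceptability surface monotone in both prevalences and
#' inside the dynamic range of the 0-10 scale while giving the quadratic
#' block and the interaction orthogonalized signals of roughly 0.4-0.7 logit
#' RMS across the scenarios, so omitting either term group costs tens of
#' expected AIC points at 181 respondents.
#'
#' @return A [clmm_params()] object.
#' @export
selection_truth <- function() {
  clmm_params(alpha = -16, delta = 1.8,
              beta = c(mild = -5, severe = -15, mild_sq = -15,
                       severe_sq = -120, mild_x_severe = -40),
              sigma = 1.2)
}

#' Configuration for the synthetic expert panel
#'
#' Defaults emulate the questionnaire design: 181 analyzable respondents,
#' each randomly allocated 5 of the 9 scenarios (uniformly over subsets,
#' without replacement) and rating them 0 (completely unacceptable) to 10
#' (highly acceptable).  Ratings are drawn from the cumulative-logit model
#' in `truth` with a per-respondent latent intercept; a configurable
#' fraction of contaminant "random responders" instead rates i.i.d.
#' uniformly on 0-10 (a fixture for the cleaning rule, default 0).
#'
#' @param n_respondents panel size.
#' @param scenarios data frame of scenarios with `mild`, `severe`
#'   proportions.
#' @param per_respondent scenarios allocated to each respondent (must not
#'   exceed the number of scenarios).
#' @param truth a [clmm_params()] generative parameter set.
#' @param contamination_rate fraction of random responders in \[0, 1\].
#' @param seed integer master seed.
#' @return Class `panel_config`.
#' @export
panel_config <- function(n_respondents = 181L,
                         scenarios = default_scenarios(),
                         per_respondent = 5L,
                         truth = clmm_params(),
                         contamination_rate = 0,
                         seed = 1L) {
  stopifnot(n_respondents >= 1L, inherits(truth, "clmm_params"))
  if (per_respondent > nrow(scenarios))
    stop("per_respondent cannot exceed the number of scenarios",
         call. = FALSE)
  if (contamination_rate < 0 || contamination_rate > 1)
    stop("contamination_rate must lie in [0, 1]", call. = FALSE)
  structure(list(n_respondents = as.integer(n_respondents),
                 scenarios = scenarios,
                 per_respondent = as.integer(per_respondent),
                 truth = truth,
                 contamination_rate = contamination_rate,
                 seed = as.integer(seed)),
            class = "panel_config")
}

# One rating from the cumulative-logit model at linear predictor eta + u.
draw_ratings <- function(alpha, delta, eta) {
  cum <- stats::plogis(outer(alpha + (0:9) * delta, eta, function(t, e) t - e))
  # cum: 10 x n matrix of P(Y <= j-1); invert by uniform draw
  uu <- stats::runif(length(eta))
  colSums(cum < rep(uu, each = 10L))
}

#' Generate a synthetic expert rating panel
#'
#' @param config a [panel_config()].
#' @return Data frame of rating records (`respondent_id`, `mild`, `severe`,
#'   `rating`, plus `mild_pct`, `severe_pct`, `contaminant`), class
#'   `wq_panel`.
#' @export
generate_expert_ratings <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  tr <- config$truth
  sc <- config$scenarios
  with_seed(derive_seed(config$seed, 2L), {
    n <- config$n_respondents
    m <- config$per_respondent
    contam <- stats::runif(n) < config$contamination_rate
    u <- stats::rnorm(n, 0, tr$sigma)
    recs <- lapply(seq_len(n), function(i) {
      rows <- sort(sample.int(nrow(sc), m))
      s <- sc[rows, , drop = FALSE]
      if (contam[i]) {
        rating <- sample(0:10, m, replace = TRUE)
      } else {
        X <- clmm_model_matrix(spec_from_beta(tr$beta), s$mild, s$severe)
        eta <- drop(X %*% tr$beta) + u[i]
        rating <- draw_ratings(tr$alpha, tr$delta, eta)
      }
      data.frame(respondent_id = sprintf("R%03d", i),
                 mild = s$mild, severe = s$severe,
                 mild_pct = s$mild * 100, severe_pct = s$severe * 100,
                 rating = as.integer(rating), contaminant = contam[i])
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    structure(out, class = c("wq_panel", "data.frame"))
  })
}

#' Configuration for the per-measure validity-rating generator
#'
#' Emulates the face-validity section of the questionnaire: each respondent
#' rates every welfare measure 0 (very poor indicator) to 10 (very good).
#' Ratings come from an intercept-only cumulative-logit model per measure;
#' `median` positions the measure's typical rating (via the threshold base)
#' and `sigma` is the respondent random-intercept SD, i.e. systematic
#' disagreement.
#'
#' @param measures data frame with columns `measure`, `median` (0-10) and
#'   `sigma` (>= 0).  The default is a 10-measure panel in which somatic
#'   cell count, access to brush and avoidance distance show real
#'   disagreement and lameness scores high with none.
#' @param n_respondents panel size (default 159, the complete-case panel).
#' @param delta threshold spacing of the generative model.
#' @param seed integer master seed.
#' @return Class `measure_panel_config`.
#' @export
measure_panel_config <- function(
    measures = data.frame(
      measure = c("somatic cell count", "access to brush",
                  "avoidance distance", "lameness", "body condition",
                  "cleanliness", "integument alterations", "lying comfort",
                  "social behaviour", "water access"),
      median = c(5, 5, 6, 9, 7, 7, 8, 7, 7, 8),
      sigma = c(3, 2.5, 2.9, 0, 0, 0, 0, 0, 0, 0)),
    n_respondents = 159L, delta = 0.8, seed = 1L) {
  stopifnot(all(c("measure", "median", "sigma") %in% names(measures)),
            n_respondents >= 2L)
  if (any(measures$median < 0 | measures$median > 10))
    stop("measure medians must lie in [0, 10]", call. = FALSE)
  if (any(measures$sigma < 0))
    stop("measure SDs must be >= 0", call. = FALSE)
  structure(list(measures = measures,
                 n_respondents = as.integer(n_respondents),
                 delta = delta, seed = as.integer(seed)),
            class = "measure_panel_config")
}

#' Generate per-measure validity ratings
#'
#' One 0-10 rating per respondent per measure.  The threshold base is placed
#' so the median rating of an average respondent sits at the configured
#' median level.
#'
#' @param config a [measure_panel_config()].
#' @return Data frame with `respondent_id`, `measure`, `rating`, class
#'   `wq_measure_panel`.
#' @export
generate_measure_scores <- function(config = measure_panel_config()) {
  stopifnot(inherits(config, "measure_panel_config"))
  with_seed(derive_seed(config$seed, 3L), {
    n <- config$n_respondents
    out <- lapply(seq_len(nrow(config$measures)), function(k) {
      med <- config$measures$median[k]
      sg <- config$measures$sigma[k]
      # median at level `med`: cut below med sits at 0 on the latent scale
      alpha <- -(med - 0.5) * config$delta
      u <- stats::rnorm(n, 0, sg)
      data.frame(respondent_id = sprintf("R%03d", seq_len(n)),
                 measure = config$measures$measure[k],
                 rating = as.integer(draw_ratings(alpha, config$delta, u)))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    structure(out, class = c("wq_measure_panel", "data.frame"))
  })
}
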