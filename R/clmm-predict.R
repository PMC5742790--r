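#' Predicted ordinal probabilities for the average respondent
#'
#' Sets the respondent random intercept to zero (the "average" expert) and
#' evaluates the cumulative-logit cell probabilities for all 11 rating
#' levels at one scenario.
#'
#' @param fit a [clmm_fit()] result or a [clmm_params()] object.
#' @param scenario `c(mild, severe)` prevalences as proportions in \[0, 1\].
#' @param spec optional [model_spec()] (required when `fit` is a bare
#'   parameter set whose beta names do not identify a candidate structure).
#' @return Named numeric vector of 11 probabilities (levels `"0"`-`"10"`),
#'   summing to 1.
#' @export
predict_probs <- function(fit, scenario, spec = NULL) {
  if (inherits(fit, "clmm_fit")) {
    params <- clmm_params(fit$alpha, fit$delta, fit$beta, fit$sigma)
    spec <- spec %||% fit$spec
  } else if (inherits(fit, "clmm_params")) {
    params <- fit
    spec <- spec %||% spec_from_beta(params$beta)
  } else stop("fit must be a clmm_fit or clmm_params object", call. = FALSE)
  stopifnot(length(scenario) == 2L)
  if (any(scenario < 0 | scenario > 1))
    stop("scenario prevalences must be proportions in [0, 1]", call. = FALSE)
  X <- clmm_model_matrix(spec, scenario[1L], scenario[2L])
  eta <- if (ncol(X)) drop(X %*% params$beta[colnames(X)]) else 0
  cum <- stats::plogis(params$alpha + (0:9) * params$delta - eta)
  p <- diff(c(0, cum, 1))
  stats::setNames(p, as.character(0:10))
}

#' Acceptability bins over the 0-10 rating scale
#'
#' @param bins list mapping bin label to the rating levels it contains;
#'   default: clearly unacceptable 0-2, unacceptable 3-4, acceptable 5-7,
#'   clearly acceptable 8-10.
#' @param acceptable_from rating level from which a scenario counts as
#'   "acceptable" for the threshold summary (default 6).
#' @return Class `wq_bins`.
#' @export
category_bins <- function(bins = list(
                            "clearly unacceptable" = 0:2,
                            "unacceptable" = 3:4,
                            "acceptable" = 5:7,
                            "clearly acceptable" = 8:10),
                          acceptable_from = 6L) {
  lv <- sort(unlist(bins))
  if (!identical(as.integer(lv), 0:10))
    stop("bins must partition the rating levels 0..10", call. = FALSE)
  structure(list(bins = bins, acceptable_from = as.integer(acceptable_from)),
            class = "wq_bins")
}

check_prob_vector <- function(probs) {
  if (length(probs) != 11L || any(!is.finite(probs)) || any(probs < -1e-12) ||
      abs(sum(probs) - 1) > 1e-6)
    stop("probs must be 11 non-negative probabilities summing to 1",
         call. = FALSE)
  invisible(probs)
}

#' Collapse 11 ordinal probabilities into the four acceptability bins
#'
#' @param probs 11 probabilities over rating levels 0-10 (summing to 1).
#' @param bins a [category_bins()] object.
#' @return Named numeric vector of 4 bin probabilities.
#' @export
bin_probs <- function(probs, bins = category_bins()) {
  check_prob_vector(probs)
  vapply(bins$bins, function(lv) sum(probs[lv + 1L]), numeric(1))
}

#' Probability of an acceptable rating
#'
#' `P(rating >= threshold)` with the threshold defaulting to 6.
#'
#' @param probs 11 probabilities over rating levels 0-10.
#' @param bins a [category_bins()] (supplies the threshold).
#' @return Scalar probability.
#' @export
prob_acceptable <- function(probs, bins = category_bins()) {
  check_prob_vector(probs)
  sum(probs[(bins$acceptable_from + 1L):11L])
}

#' AIC model selection over candidate fits
#'
#' @param fits list of [clmm_fit()] objects fitted to the same data (same
#'   number of observations and respondents; fits on differing data are
#'   rejected).
#' @param tie_tol AIC difference below which fits count as tied; ties go to
#'   the fit with fewer parameters.
#' @return List with `best` (the selected fit) and `table` (data frame of
#'   terms, n_params, logLik, AIC, dAIC ordered by AIC).
#' @export
select_by_aic <- function(fits, tie_tol = 1e-8) {
  stopifnot(is.list(fits), length(fits) >= 2L,
            all(vapply(fits, inherits, TRUE, "clmm_fit")))
  n_obs <- vapply(fits, `[[`, 0, "n_obs")
  n_resp <- vapply(fits, `[[`, 0, "n_respondents")
  if (length(unique(n_obs)) != 1L || length(unique(n_resp)) != 1L)
    stop("fits were not computed on identical data", call. = FALSE)
  tab <- data.frame(
    terms = vapply(fits, function(f) f$spec$terms, ""),
    n_params = vapply(fits, `[[`, 0L, "n_params"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = vapply(fits, `[[`, 0, "aic"),
    converged = vapply(fits, `[[`, TRUE, "converged"))
  # order by AIC, ties toward fewer parameters
  ord <- order(round(tab$aic / tie_tol) * tie_tol, tab$n_params)
  tab <- tab[ord, , drop = FALSE]
  tab$dAIC <- tab$aic - tab$aic[1L]
  rownames(tab) <- NULL
  list(best = fits[[ord[1L]]], table = tab)
}

#' Per-measure expert-agreement model
#'
#' For each welfare measure, fits an intercept-only cumulative-link model
#' (equidistant thresholds, respondent random intercept, no fixed effects)
#' to the 0-10 validity ratings.  The fitted respondent SD measures how much
#' experts disagree systematically beyond multinomial sampling noise.
#'
#' @param measure_scores data frame with `respondent_id`, `measure`,
#'   `rating` (0-10).
#' @param control a [clmm_control()].
#' @return Data frame with one row per measure: `measure`, `sigma`,
#'   `loglik`, `aic`, `converged`, `degenerate` (TRUE when the measure's
#'   ratings are constant and no model can be fit).
#' @export
fit_agreement <- function(measure_scores, control = clmm_control()) {
  need <- c("respondent_id", "measure", "rating")
  if (!all(need %in% names(measure_scores)))
    stop("need columns: ", paste(need, collapse = ", "), call. = FALSE)
  out <- lapply(split(measure_scores, measure_scores$measure), function(d) {
    if (length(unique(d$respondent_id)) < 2L)
      stop("need >= 2 respondents per measure", call. = FALSE)
    if (length(unique(d$rating)) < 2L)
      return(data.frame(measure = d$measure[1L], sigma = NA_real_,
                        loglik = NA_real_, aic = NA_real_,
                        converged = FALSE, degenerate = TRUE))
    rec <- data.frame(respondent_id = d$respondent_id, mild = 0, severe = 0,
                      rating = d$rating)
    spec <- structure(list(terms = "intercept_only",
                           coef_names = character(0)), class = "clmm_spec")
    f <- clmm_fit(rec, spec, control)
    data.frame(measure = d$measure[1L], sigma = f$sigma, loglik = f$loglik,
               aic = f$aic, converged = f$converged, degenerate = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
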