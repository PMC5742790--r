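#' Aggregation configuration: measures -> criteria -> principles -> overall
#'
#' A configurable skeleton of the three-step aggregation used for dairy
#' cattle: named measures combine into criteria, criteria into principles,
#' and the four principle scores into one overall category.  The exact
#' protocol combiners (I-splines, Choquet integrals) live in the protocol
#' reference and are not reproduced here; the default combiner at each step
#' is a weighted mean, which preserves the \[0, 100\] scale and lets
#' compensation between inputs be studied directly.
#'
#' The default layout carries the lameness pathway explicitly (criterion
#' "absence of injuries" combines lameness with integument alterations, and
#' feeds the principle "good health" together with absence of disease and
#' absence of procedural pain) plus single-measure placeholders for the other
#' three principles.
#'
#' @param criteria named list; each element is a named numeric vector of
#'   measure weights defining one criterion.
#' @param principles named list; each element is a named numeric vector of
#'   criterion weights defining one principle.
#' @param overall_rule function mapping the named vector of principle scores
#'   to one of the four categories; default [wq_overall_rule()].
#' @param bands [category_bands()] used to categorize criterion and principle
#'   scores.
#' @return Class `wq_aggregation`.
#' @export
aggregation_config <- function(
    criteria = list(
      absence_of_injuries = c(lameness = 0.5, integument = 0.5),
      absence_of_disease  = c(disease = 1),
      absence_of_pain     = c(pain_management = 1),
      feeding             = c(feeding = 1),
      housing             = c(housing = 1),
      behaviour           = c(behaviour = 1)
    ),
    principles = list(
      good_health = c(absence_of_injuries = 1 / 3, absence_of_disease = 1 / 3,
                      absence_of_pain = 1 / 3),
      good_feeding = c(feeding = 1),
      good_housing = c(housing = 1),
      appropriate_behaviour = c(behaviour = 1)
    ),
    overall_rule = wq_overall_rule(),
    bands = category_bands()) {
  stopifnot(is.list(criteria), is.list(principles), is.function(overall_rule))
  for (w in c(criteria, principles)) {
    if (is.null(names(w)) || any(!is.finite(w)) || any(w < 0) || sum(w) <= 0)
      stop("combiner weights must be named, non-negative and not all zero",
           call. = FALSE)
  }
  crit_needed <- unique(unlist(lapply(principles, names)))
  missing <- setdiff(crit_needed, names(criteria))
  if (length(missing))
    stop("principles reference undefined criteria: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(criteria = criteria, principles = principles,
                 overall_rule = overall_rule, bands = bands),
            class = "wq_aggregation")
}

#' Default overall categorization rule
#'
#' Threshold predicate over the four principle scores in the style of the
#' 2009 dairy-cattle protocol: Excellent if all principles exceed 55 and at
#' least two exceed 80; Enhanced if all exceed 20 and at least two exceed 55;
#' Acceptable if all exceed 10 and at least three exceed 20; otherwise Not
#' classified.  Boundary scores count as meeting the target (`>=`), so a farm
#' with every measure at 100 is Excellent.
#'
#' @param excellent,enhanced,acceptable,minimum threshold levels.
#' @return A function `(named numeric principle scores) -> category` string.
#' @export
wq_overall_rule <- function(excellent = 80, enhanced = 55, acceptable = 20,
                            minimum = 10) {
  force(excellent); force(enhanced); force(acceptable); force(minimum)
  function(principles) {
    p <- as.numeric(principles)
    if (all(p >= enhanced) && sum(p >= excellent) >= 2L) return("Excellent")
    if (all(p >= acceptable) && sum(p >= enhanced) >= 2L) return("Enhanced")
    if (all(p >= minimum) && sum(p >= acceptable) >= 3L) return("Acceptable")
    "Not classified"
  }
}

combine_scores <- function(scores, weights, what) {
  missing <- setdiff(names(weights), names(scores))
  if (length(missing))
    stop("missing required ", what, " score(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- scores[names(weights)]
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100))
    stop(what, " scores must lie in [0, 100]", call. = FALSE)
  sum(weights * x) / sum(weights)
}

#' Aggregate measure scores to criterion, principle and overall level
#'
#' @param measure_scores named numeric vector of measure scores in
#'   \[0, 100\]; must cover every measure referenced by the configuration.
#' @param config an [aggregation_config()].
#' @return List with `criteria` and `principles` (each a data frame of
#'   `score` and `category`) and `overall` (single category string).
#' @examples
#' agg <- wq_aggregate(c(lameness = 48, integument = 72, disease = 80,
#'                       pain_management = 100, feeding = 80, housing = 80,
#'                       behaviour = 80))
#' agg$overall
#' @export
wq_aggregate <- function(measure_scores, config = aggregation_config()) {
  stopifnot(inherits(config, "wq_aggregation"))
  crit <- vapply(config$criteria, combine_scores, numeric(1),
                 scores = measure_scores, what = "measure")
  prin <- vapply(config$principles, combine_scores, numeric(1),
                 scores = crit, what = "criterion")
  overall <- config$overall_rule(prin)
  if (!overall %in% wq_categories())
    stop("overall rule returned an unknown category: ", overall,
         call. = FALSE)
  list(
    criteria = data.frame(criterion = names(crit), score = unname(crit),
                          category = categorize(unname(crit), config$bands)),
    principles = data.frame(principle = names(prin), score = unname(prin),
                            category = categorize(unname(prin), config$bands)),
    overall = overall
  )
}

#' Aggregate every farm given its lameness score and companion measures
#'
#' Convenience wrapper running [wq_aggregate()] per farm, substituting each
#' farm's lameness welfare score into the companion measure profile.  Used by
#' the compensation pipeline to ask: if a farm does well on everything except
#' lameness, where does it end up?
#'
#' @param scored data frame from [score_farms()].
#' @param companion_scores named numeric vector of the non-lameness measure
#'   scores shared by all farms (default: 70 for every companion measure in
#'   the configuration, i.e. farms doing well elsewhere).
#' @param config an [aggregation_config()].
#' @param criterion,principle which rows of the aggregation output to report
#'   as the farm's criterion/principle category (defaults follow the lameness
#'   pathway).
#' @return `scored` with added columns `criterion_category`,
#'   `principle_category`, `overall_category`.
#' @export
aggregate_farms <- function(scored, companion_scores = NULL,
                            config = aggregation_config(),
                            criterion = "absence_of_injuries",
                            principle = "good_health") {
  measures <- unique(unlist(lapply(config$criteria, names)))
  if (is.null(companion_scores)) {
    companion <- setdiff(measures, "lameness")
    companion_scores <- stats::setNames(rep(70, length(companion)), companion)
  }
  res <- lapply(scored$welfare_score, function(s) {
    agg <- wq_aggregate(c(companion_scores, lameness = s), config)
    c(crit = as.character(agg$criteria$category[
        agg$criteria$criterion == criterion]),
      prin = as.character(agg$principles$category[
        agg$principles$principle == principle]),
      over = agg$overall)
  })
  labs <- wq_categories()
  scored$criterion_category <- factor(vapply(res, `[[`, "", "crit"),
                                      levels = labs, ordered = TRUE)
  scored$principle_category <- factor(vapply(res, `[[`, "", "prin"),
                                      levels = labs, ordered = TRUE)
  scored$overall_category <- factor(vapply(res, `[[`, "", "over"),
                                    levels = labs, ordered = TRUE)
  scored
}
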