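#' Measure weights for the lameness index
#'
#' Severity weights attached to mildly and severely lame cows when the herd
#' prevalence is collapsed into a single 0-100 index.  The protocol-derived
#' defaults are 2 (mild) and 7 (severe), i.e. one severely lame cow weighs as
#' much as 3.5 mildly lame cows.
#'
#' @param w_mild positive weight for mild lameness (gait score 1).
#' @param w_severe positive weight for severe lameness (gait score 2); must be
#'   at least `w_mild`.
#' @return An object of class `wq_weights`.
#' @export
measure_weights <- function(w_mild = 2, w_severe = 7) {
  stopifnot(is.numeric(w_mild), is.numeric(w_severe),
            length(w_mild) == 1L, length(w_severe) == 1L)
  if (!(w_mild > 0) || !(w_severe >= w_mild))
    stop("weights must satisfy w_severe >= w_mild > 0", call. = FALSE)
  structure(list(w_mild = w_mild, w_severe = w_severe),
            class = "wq_weights")
}

#' Lameness prevalence of a herd
#'
#' Percent of mildly and severely lame cows computed from per-cow gait scores
#' (0 = non-lame, 1 = mildly lame, 2 = severely lame).
#'
#' @param gait_scores integer vector of per-cow gait scores in `{0, 1, 2}`,
#'   or a data frame with a `gait_score` column (a single herd).
#' @return A list with `mild_pct` and `severe_pct`, class `wq_prevalence`.
#' @examples
#' compute_prevalence(c(1, 1, 1, 1, 1, 1, 1, 0, 2, 2))  # 70% mild, 20% severe
#' @export
compute_prevalence <- function(gait_scores) {
  if (is.data.frame(gait_scores)) {
    if (!"gait_score" %in% names(gait_scores))
      stop("data frame input must have a 'gait_score' column", call. = FALSE)
    gait_scores <- gait_scores$gait_score
  }
  if (length(gait_scores) == 0L)
    stop("empty herd: no gait scores", call. = FALSE)
  if (!all(gait_scores %in% c(0L, 1L, 2L)))
    stop("gait scores must all be 0, 1 or 2", call. = FALSE)
  n <- length(gait_scores)
  prevalence(100 * sum(gait_scores == 1L) / n,
             100 * sum(gait_scores == 2L) / n)
}

#' Construct a lameness prevalence pair
#'
#' @param mild_pct,severe_pct percent of mildly / severely lame cows; must be
#'   non-negative and sum to at most 100.
#' @return A list with `mild_pct` and `severe_pct`, class `wq_prevalence`.
#' @export
prevalence <- function(mild_pct, severe_pct) {
  stopifnot(is.numeric(mild_pct), is.numeric(severe_pct),
            length(mild_pct) == 1L, length(severe_pct) == 1L)
  if (mild_pct < 0 || severe_pct < 0 || mild_pct + severe_pct > 100 + 1e-9)
    stop("prevalences must be non-negative and mild + severe <= 100%",
         call. = FALSE)
  structure(list(mild_pct = mild_pct, severe_pct = severe_pct),
            class = "wq_prevalence")
}

#' Weighted lameness index
#'
#' Collapses herd lameness prevalence into a linear 0-100 index.  The weighted
#' count of lame cows is normalized by the maximum weight so that a fully
#' healthy herd scores 100 and a herd where every cow is severely lame scores
#' 0:
#'
#' \deqn{I = 100 - (w_m \cdot p_m + w_s \cdot p_s) / w_s}
#'
#' where \eqn{p_m}, \eqn{p_s} are percent mild and severe lameness.  With the
#' default weights (2, 7) a herd with 10% severely lame cows scores 90, and a
#' herd with 50% severely lame cows scores 50.
#'
#' @param prev a [prevalence()] object (or anything coercible via
#'   `prevalence(mild, severe)`).
#' @param weights a [measure_weights()] object.
#' @return Index value in \[0, 100\].
#' @export
lameness_index <- function(prev, weights = measure_weights()) {
  prev <- as_prevalence(prev)
  idx <- 100 - (weights$w_mild * prev$mild_pct +
                  weights$w_severe * prev$severe_pct) / weights$w_severe
  unname(idx)
}

as_prevalence <- function(x) {
  if (inherits(x, "wq_prevalence")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(prevalence(x[[1]], x[[2]]))
  if (is.list(x) && all(c("mild_pct", "severe_pct") %in% names(x)))
    return(prevalence(x$mild_pct, x$severe_pct))
  stop("cannot interpret input as a lameness prevalence", call. = FALSE)
}

#' Anchor points of the index-to-welfare-score transform
#'
#' The non-linear transform from index to welfare score is pinned down by
#' published worked examples: both scales agree at 0 and 100, and index values
#' 70, 80 and 90 map to welfare scores 21, 29 and 48.  Between anchors the
#' curve is a monotone shape-preserving cubic spline; alternative anchor sets
#' (for example a protocol-exact curve) can be supplied.
#'
#' @param anchors two-column matrix or data frame of `(index, score)` pairs.
#'   Must contain `(0, 0)` and `(100, 100)` and be strictly increasing in both
#'   coordinates.
#' @return Class `wq_anchors`: the sorted anchor matrix.
#' @export
score_anchors <- function(anchors = cbind(index = c(0, 70, 80, 90, 100),
                                          score = c(0, 21, 29, 48, 100))) {
  anchors <- as.matrix(anchors)
  stopifnot(ncol(anchors) == 2L, nrow(anchors) >= 2L)
  anchors <- anchors[order(anchors[, 1L]), , drop = FALSE]
  colnames(anchors) <- c("index", "score")
  if (any(diff(anchors[, 1L]) <= 0) || any(diff(anchors[, 2L]) <= 0))
    stop("anchors must be strictly increasing in both coordinates",
         call. = FALSE)
  ends <- anchors[c(1L, nrow(anchors)), ]
  if (!isTRUE(all.equal(unname(ends),
                        matrix(c(0, 100, 0, 100), 2L), tolerance = 1e-9)))
    stop("anchors must include the endpoints (0, 0) and (100, 100)",
         call. = FALSE)
  structure(anchors, class = c("wq_anchors", class(anchors)))
}

#' Transform a lameness index into a welfare score
#'
#' Monotone shape-preserving piecewise-cubic (Hyman-filtered) interpolation
#' through the anchor points.  The transform is exact at every anchor and
#' strictly increasing on \[0, 100\]; below 100 the welfare score drops
#' faster than the index, so low prevalences of lameness are penalized
#' disproportionately.
#'
#' @param index numeric vector of index values in \[0, 100\].
#' @param anchors a [score_anchors()] object.
#' @return Welfare score(s) in \[0, 100\].
#' @examples
#' index_to_welfare_score(c(90, 80, 70))  # 48, 29, 21
#' @export
index_to_welfare_score <- function(index, anchors = score_anchors()) {
  if (!inherits(anchors, "wq_anchors")) anchors <- score_anchors(anchors)
  if (any(!is.finite(index)) || any(index < 0) || any(index > 100))
    stop("index must lie in [0, 100]", call. = FALSE)
  f <- stats::splinefun(anchors[, 1L], anchors[, 2L], method = "hyman")
  f(index)
}

#' Category bands for a 0-100 welfare score
#'
#' Thresholds partitioning \[0, 100\] into the four ordered categories
#' Not classified / Acceptable / Enhanced / Excellent.  Banding is half-open
#' on the left: a score equal to a threshold falls in the better category.
#'
#' @param thresholds strictly increasing vector of three cut points
#'   (defaults 20, 55, 80, the aspiration levels of the dairy-cattle
#'   protocol).
#' @return Class `wq_bands`.
#' @export
category_bands <- function(thresholds = c(20, 55, 80)) {
  stopifnot(is.numeric(thresholds), length(thresholds) == 3L)
  if (any(diff(thresholds) <= 0) || thresholds[1L] <= 0 || thresholds[3L] >= 100)
    stop("thresholds must be strictly increasing and inside (0, 100)",
         call. = FALSE)
  structure(list(thresholds = thresholds, labels = wq_categories()),
            class = "wq_bands")
}

#' The four ordered category labels, worst to best
#' @return Character vector of length 4.
#' @export
wq_categories <- function() {
  c("Not classified", "Acceptable", "Enhanced", "Excellent")
}

#' Categorize a welfare score
#'
#' @param score numeric vector of scores in \[0, 100\].
#' @param bands a [category_bands()] object.
#' @return Ordered factor over the four categories.
#' @export
categorize <- function(score, bands = category_bands()) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 100))
    stop("score must lie in [0, 100]", call. = FALSE)
  labs <- bands$labels
  idx <- findInterval(score, bands$thresholds) + 1L
  factor(labs[idx], levels = labs, ordered = TRUE)
}

# Lameness profile bins.  Mild bins are [5,15), [15,40), [40,70), [70,100];
# severe bins [0,5), [5,15), [15,100].  Only the nine observed combinations
# carry a profile id; everything else (including mild < 5%) is "Unprofiled".
profile_grid <- function() {
  data.frame(
    profile    = 1:9,
    mild_lo    = c(5, 15, 40, 70, 15, 40, 70, 15, 40),
    mild_hi    = c(15, 40, 70, 100, 40, 70, 100, 40, 70),
    severe_lo  = c(0, 0, 0, 0, 5, 5, 5, 15, 15),
    severe_hi  = c(5, 5, 5, 5, 15, 15, 15, 100, 100)
  )
}

#' Assign a herd to a lameness profile
#'
#' Profiles 1-9 cross bins of mild prevalence (5-15, 15-40, 40-70, >70%) with
#' bins of severe prevalence (<5, 5-15, >15%), matching the nine scenario
#' combinations experts were asked about.  Combinations outside the nine
#' observed cells (mild below 5%, or mild 5-15% with any severe lameness, or
#' mild above 70% with severe above 15%) return `"Unprofiled"`.
#' Bins are half-open on the left bound and closed at 100.
#'
#' @param prev a [prevalence()] object or `c(mild, severe)` pair in percent.
#' @return Integer profile id 1-9, or `NA` with the value labelled via
#'   [format_profile()]; scalar character `"Unprofiled"` is encoded as `NA`.
#' @export
assign_profile <- function(prev) {
  prev <- as_prevalence(prev)
  g <- profile_grid()
  hit <- prev$mild_pct >= g$mild_lo &
    (prev$mild_pct < g$mild_hi | (g$mild_hi == 100 & prev$mild_pct == 100)) &
    prev$severe_pct >= g$severe_lo &
    (prev$severe_pct < g$severe_hi |
       (g$severe_hi == 100 & prev$severe_pct == 100))
  if (!any(hit)) return(NA_integer_)
  g$profile[which(hit)]
}

#' Human-readable profile label
#' @param profile integer profile id (or `NA` for unprofiled herds).
#' @return Character label such as `"Profile 3"` or `"Unprofiled"`.
#' @export
format_profile <- function(profile) {
  ifelse(is.na(profile), "Unprofiled", paste("Profile", profile))
}

#' Score every farm in a herd table
#'
#' Runs prevalence, index, welfare score, category and profile assignment for
#' each farm in a per-cow gait-score table.
#'
#' @param herds data frame with columns `farm_id`, `cow_id`, `gait_score`
#'   (as produced by [generate_herds()] or [read_herds_csv()]).
#' @param weights,anchors,bands scoring configuration.
#' @return Data frame with one row per farm: `farm_id`, `n_cows`,
#'   `mild_pct`, `severe_pct`, `index`, `welfare_score`, `category`,
#'   `profile`.
#' @export
score_farms <- function(herds, weights = measure_weights(),
                        anchors = score_anchors(), bands = category_bands()) {
  stopifnot(all(c("farm_id", "gait_score") %in% names(herds)))
  out <- do.call(rbind, lapply(split(herds, herds$farm_id), function(h) {
    p <- compute_prevalence(h$gait_score)
    data.frame(farm_id = h$farm_id[1L], n_cows = nrow(h),
               mild_pct = p$mild_pct, severe_pct = p$severe_pct,
               profile = assign_profile(p))
  }))
  out <- out[order(out$farm_id), , drop = FALSE]
  out$index <- 100 - (weights$w_mild * out$mild_pct +
                        weights$w_severe * out$severe_pct) / weights$w_severe
  out$welfare_score <- index_to_welfare_score(out$index, anchors)
  out$category <- categorize(out$welfare_score, bands)
  rownames(out) <- NULL
  out[, c("farm_id", "n_cows", "mild_pct", "severe_pct", "index",
          "welfare_score", "category", "profile")]
}
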