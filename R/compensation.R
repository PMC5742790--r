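#' Cross-tabulate farm categories by lameness profile
#'
#' Builds the profile-by-category table at the three aggregation levels
#' (criterion, principle, overall): per profile the farm count, percent of
#' farms, and the row-percent distribution over the four categories, plus a
#' totals row computed from counts (never from rounded percentages).
#' Unprofiled farms get their own explicit row.
#'
#' @param farms data frame from [aggregate_farms()]: needs `profile`,
#'   `criterion_category`, `principle_category`, `overall_category`.
#' @return Class `wq_crosstab`: data frame with one row per profile (plus
#'   `Unprofiled` when present and a `Total` row); row percents are kept at
#'   full precision, rounding happens at render time.
#' @export
build_crosstab <- function(farms) {
  need <- c("profile", "criterion_category", "principle_category",
            "overall_category")
  if (!all(need %in% names(farms)))
    stop("farms need columns: ", paste(need, collapse = ", "), call. = FALSE)
  labs <- wq_categories()
  lvl_cols <- c(criterion = "criterion_category",
                principle = "principle_category",
                overall = "overall_category")
  prof <- format_profile(farms$profile)
  present <- c(paste("Profile", 1:9), "Unprofiled")
  present <- present[present %in% prof]
  n_total <- nrow(farms)
  one_row <- function(sel, label) {
    row <- data.frame(profile = label, n = sum(sel),
                      pct = 100 * sum(sel) / n_total)
    for (lv in names(lvl_cols)) {
      counts <- table(factor(farms[[lvl_cols[lv]]][sel], levels = labs))
      share <- if (sum(sel)) 100 * as.numeric(counts) / sum(sel) else
        rep(NA_real_, 4L)
      names(share) <- paste(lv, gsub(" ", "_", tolower(labs)), sep = ".")
      row <- cbind(row, as.data.frame(as.list(share)))
    }
    row
  }
  rows <- lapply(present, function(pl) one_row(prof == pl, pl))
  rows <- c(rows, list(one_row(rep(TRUE, n_total), "Total")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("wq_crosstab", "data.frame"))
}

#' Validate a cross-tab (including externally supplied ones)
#'
#' Checks that farm counts sum to the total and that every row-percent block
#' sums to 100 within `tol`.  Discrepancies are reported, never silently
#' corrected — printed tables sometimes contain internal inconsistencies and
#' these must surface.
#'
#' @param crosstab a [build_crosstab()]-shaped data frame.
#' @param tol allowed deviation of a row-percent block from 100.
#' @return Data frame of issues (zero rows when the table is consistent).
#' @export
validate_crosstab <- function(crosstab, tol = 0.5) {
  issues <- list()
  tot <- crosstab[crosstab$profile == "Total", , drop = FALSE]
  body <- crosstab[crosstab$profile != "Total", , drop = FALSE]
  if (nrow(tot) == 1L && sum(body$n) != tot$n)
    issues[[length(issues) + 1L]] <- data.frame(
      row = "Total", check = "counts",
      detail = sprintf("profile counts sum to %d, total says %d",
                       sum(body$n), tot$n))
  for (lv in c("criterion", "principle", "overall")) {
    cols <- grep(paste0("^", lv, "\\."), names(crosstab), value = TRUE)
    s <- rowSums(crosstab[, cols, drop = FALSE])
    bad <- which(is.finite(s) & abs(s - 100) > tol)
    for (b in bad)
      issues[[length(issues) + 1L]] <- data.frame(
        row = crosstab$profile[b], check = paste(lv, "row percent"),
        detail = sprintf("row sums to %.1f, not 100", s[b]))
  }
  if (!length(issues))
    return(data.frame(row = character(0), check = character(0),
                      detail = character(0)))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

#' Published per-profile category shares of the 44-farm case study
#'
#' The cross-tab of the 44 Danish dairy farms as published: per lameness
#' profile the farm count, percent of farms and the row-percent category
#' distribution at criterion ("absence of injuries"), principle ("good
#' health") and overall level, including the published totals row.
#' Transcribed verbatim, internal inconsistencies included — notably the
#' Profile 7 criterion-level row, which sums to 50%, not 100%
#' ([validate_crosstab()] surfaces this; it is never silently corrected).
#'
#' @return A `wq_crosstab`-shaped data frame (10 rows: 9 profiles + Total).
#' @export
casestudy_profiles <- function() {
  path <- system.file("extdata", "casestudy_profiles.csv", package = "wqlame",
                      mustWork = TRUE)
  ct <- utils::read.csv(path, check.names = TRUE)
  structure(ct, class = c("wq_crosstab", "data.frame"))
}

#' Recompute a cross-tab totals row from its per-profile rows
#'
#' Count-weighted aggregation of the body rows: total row percent for each
#' category is `sum(n_i * pct_i) / sum(n_i)`.  Used to check a published
#' totals row against its own body.
#'
#' @param crosstab a `wq_crosstab` data frame; any `Total` row is ignored.
#' @return One-row data frame in the same column layout.
#' @export
crosstab_totals <- function(crosstab) {
  body <- crosstab[crosstab$profile != "Total", , drop = FALSE]
  n <- body$n
  out <- data.frame(profile = "Total", n = sum(n), pct = 100)
  pc_cols <- setdiff(names(crosstab), c("profile", "n", "pct"))
  for (col in pc_cols) out[[col]] <- sum(n * body[[col]]) / sum(n)
  out
}

# Representative questionnaire scenario for each profile bin: mild bins
# 5-15 / 15-40 / 40-70 / >70 % map to the shown 10 / 40 / 70 / 70 %, severe
# bins <5 / 5-15 / >15 % to 0 / 5 / 15 %.
profile_scenarios <- function() {
  g <- profile_grid()
  mild_map <- c(`5` = 10, `15` = 40, `40` = 70, `70` = 70)
  severe_map <- c(`0` = 0, `5` = 5, `15` = 15)
  data.frame(profile = g$profile,
             mild_pct = unname(mild_map[as.character(g$mild_lo)]),
             severe_pct = unname(severe_map[as.character(g$severe_lo)]))
}

#' Predicted acceptability of each lameness profile
#'
#' Evaluates the fitted acceptability model at one representative scenario
#' per profile (the questionnaire scenario whose prevalences fall in the
#' profile's bins) and bins the average-respondent probabilities into the
#' four acceptability categories, as percentages.
#'
#' @param fit a converged [clmm_fit()].
#' @param scenarios data frame with `profile`, `mild_pct`, `severe_pct`
#'   (default [profile_scenarios()]).
#' @param bins a [category_bins()].
#' @return Class `wq_acceptability`: data frame with `profile`, `mild_pct`,
#'   `severe_pct`, the four bin percentages and `p_acceptable`
#'   (`P(rating >= 6)`, percent).  Full precision; round when rendering.
#' @export
predict_profile_acceptability <- function(fit,
                                          scenarios = profile_scenarios(),
                                          bins = category_bins()) {
  stopifnot(all(c("mild_pct", "severe_pct") %in% names(scenarios)))
  if (inherits(fit, "clmm_fit") && !fit$converged)
    warning("predicting from a fit flagged as not converged")
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    pr <- predict_probs(fit, c(scenarios$mild_pct[i] / 100,
                               scenarios$severe_pct[i] / 100))
    bp <- 100 * bin_probs(pr, bins)
    cbind(scenarios[i, , drop = FALSE],
          as.data.frame(as.list(stats::setNames(
            bp, gsub(" ", "_", names(bp))))),
          p_acceptable = 100 * prob_acceptable(pr, bins))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("wq_acceptability", "data.frame"))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,n counts with `0 <= successes <= n`, `n > 0`.
#' @param level confidence level in (0, 1).
#' @return Named vector `c(lower, upper)` on the proportion scale.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  stopifnot(length(successes) == 1L, length(n) == 1L)
  if (n <= 0 || successes < 0 || successes > n)
    stop("need 0 <= successes <= n with n > 0", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("level must lie in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Summarize compensation: WQ categories versus expert acceptability
#'
#' For each configured set of lameness profiles, reports the share of farms
#' in the set (with a binomial confidence interval) alongside the range of
#' predicted probabilities that an average expert would call those profiles
#' clearly unacceptable; contrasts this with the share of farms landing in
#' the worst overall category.  Compensation is flagged when profiles that
#' experts would overwhelmingly reject still largely escape the worst
#' overall category.
#'
#' @param crosstab a [build_crosstab()] result.
#' @param acceptability a [predict_profile_acceptability()] result.
#' @param profile_sets named list of profile-id vectors (defaults:
#'   `tolerated` = profiles 1, 2, 5; `rejected` = profiles 6-9).
#' @param ci_level confidence level for the farm-share intervals.
#' @param ci_method currently `"wilson"` (recorded in the output).
#' @return Class `wq_compensation`: list with `sets` (one row per profile
#'   set: farm count, share %, CI bounds %, min/max clearly-unacceptable %),
#'   `overall_not_classified_pct`, `verdict`, `ci_method`, `ci_level`.
#' @export
compensation_report <- function(crosstab, acceptability,
                                profile_sets = list(tolerated = c(1L, 2L, 5L),
                                                    rejected = c(6L, 7L, 8L,
                                                                 9L)),
                                ci_level = 0.95, ci_method = "wilson") {
  ci_method <- match.arg(ci_method, "wilson")
  tot <- crosstab[crosstab$profile == "Total", , drop = FALSE]
  stopifnot(nrow(tot) == 1L)
  n_total <- tot$n
  cu_col <- "clearly_unacceptable"
  if (!cu_col %in% names(acceptability))
    stop("acceptability table lacks a clearly_unacceptable column",
         call. = FALSE)
  sets <- lapply(names(profile_sets), function(nm) {
    ids <- profile_sets[[nm]]
    if (!all(ids %in% 1:9))
      stop("unknown profile id(s) in set '", nm, "': ",
           paste(setdiff(ids, 1:9), collapse = ", "), call. = FALSE)
    rows <- crosstab$profile %in% paste("Profile", ids)
    k <- sum(crosstab$n[rows])
    ci <- wilson_ci(k, n_total, ci_level)
    acc <- acceptability[acceptability$profile %in% ids, cu_col]
    data.frame(set = nm, profiles = paste(ids, collapse = ","),
               n_farms = k, share_pct = 100 * k / n_total,
               ci_lower_pct = 100 * ci[["lower"]],
               ci_upper_pct = 100 * ci[["upper"]],
               min_clearly_unacceptable_pct = if (length(acc)) min(acc) else NA_real_,
               max_clearly_unacceptable_pct = if (length(acc)) max(acc) else NA_real_)
  })
  sets <- do.call(rbind, sets)
  rownames(sets) <- NULL
  overall_nc <- tot[["overall.not_classified"]]
  finite <- is.finite(sets$min_clearly_unacceptable_pct)
  worst <- sets[finite, ][which.max(sets$min_clearly_unacceptable_pct[finite]), ]
  compensated <- nrow(worst) == 1L &&
    worst$min_clearly_unacceptable_pct > overall_nc
  verdict <- if (compensated) {
    sprintf(paste0(
      "Compensation detected: an average expert rates profiles %s clearly ",
      "unacceptable with probability %.1f-%.1f%%, yet only %.1f%% of farms ",
      "fall in the worst overall category."),
      worst$profiles, worst$min_clearly_unacceptable_pct,
      worst$max_clearly_unacceptable_pct, overall_nc)
  } else {
    "No compensation detected at the overall level for the configured profile sets."
  }
  structure(list(sets = sets, overall_not_classified_pct = overall_nc,
                 compensated = compensated, verdict = verdict,
                 ci_method = ci_method, ci_level = ci_level),
            class = "wq_compensation")
}

#' @export
print.wq_compensation <- function(x, ...) {
  cat("Compensation report (CI:", x$ci_method, "at",
      sprintf("%.0f%%)\n", 100 * x$ci_level))
  df <- x$sets
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 1)
  print(df, row.names = FALSE)
  cat(sprintf("Overall 'Not classified' share: %.1f%%\n",
              x$overall_not_classified_pct))
  cat(x$verdict, "\n")
  invisible(x)
}
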