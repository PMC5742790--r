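#' Remove nonsensical and incomplete respondents from a rating panel
#'
#' A respondent's pair of scenarios is *ordered* when one dominates the other
#' componentwise (mild and severe prevalence both no larger, at least one
#' strictly smaller).  A *violation* is a strictly higher acceptability
#' rating for the strictly worse scenario of an ordered pair.  Respondents
#' with two or more violations across all their ordered pairs are removed as
#' nonsensical; a single violation is tolerated.  Respondents who did not
#' rate all their allocated scenarios (`n_required`) are removed as
#' incomplete.
#'
#' Cleaning is idempotent: applying it to an already-cleaned panel removes
#' nobody.
#'
#' @param records rating records (`respondent_id`, `mild`, `severe`,
#'   `rating`); duplicate (respondent, scenario) pairs are an error.
#' @param n_required number of ratings a complete respondent must have
#'   (default 5, the per-respondent allocation).
#' @return List with `kept` (records of surviving respondents, original
#'   order), `removed` (data frame of `respondent_id`, `reason`,
#'   `n_violations`), and `n_kept`.
#' @export
clean_panel <- function(records, n_required = 5L) {
  check_records(records)
  key <- paste(records$respondent_id, records$mild, records$severe)
  if (anyDuplicated(key))
    stop("duplicate (respondent, scenario) pairs in panel", call. = FALSE)
  by_resp <- split(records, records$respondent_id)
  removed <- list()
  for (id in names(by_resp)) {
    d <- by_resp[[id]]
    nv <- count_violations(d)
    if (nv >= 2L) {
      removed[[id]] <- data.frame(respondent_id = d$respondent_id[1L],
                                  reason = "nonsensical", n_violations = nv)
    } else if (nrow(d) < n_required) {
      removed[[id]] <- data.frame(respondent_id = d$respondent_id[1L],
                                  reason = "incomplete", n_violations = nv)
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(respondent_id = character(0), reason = character(0),
               n_violations = integer(0))
  rownames(removed) <- NULL
  drop_ids <- removed$respondent_id
  kept <- records[!records$respondent_id %in% drop_ids, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed, n_kept = length(unique(kept$respondent_id)))
}

# Number of ordered scenario pairs where the strictly worse scenario got a
# strictly higher rating.  All ordered pairs are counted.
count_violations <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0L)
  nv <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cmp <- dominance(d$mild[i], d$severe[i], d$mild[j], d$severe[j])
      if (cmp == 0L) next
      # cmp = +1: scenario i better (less lameness) than j
      better <- if (cmp > 0L) i else j
      worse <- if (cmp > 0L) j else i
      if (d$rating[worse] > d$rating[better]) nv <- nv + 1L
    }
  }
  nv
}

dominance <- function(m1, s1, m2, s2) {
  if (m1 <= m2 && s1 <= s2 && (m1 < m2 || s1 < s2)) return(1L)
  if (m2 <= m1 && s2 <= s1 && (m2 < m1 || s2 < s1)) return(-1L)
  0L
}
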