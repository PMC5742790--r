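# CSV artifacts: header row, UTF-8, '.' decimal separator. Readers validate
# column names and value domains and report file/line/column on failure.

read_checked_csv <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(names(columns), names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in names(columns)) {
    check <- columns[[col]]
    bad <- which(!check(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: invalid value in column '%s' at data line %d",
                   path, col, bad[1L]), call. = FALSE)
  }
  df
}

is_gait <- function(x) !is.na(x) & x %in% c(0, 1, 2)
is_rating <- function(x) !is.na(x) & x %in% 0:10
is_pct <- function(x) !is.na(x) & x >= 0 & x <= 100
not_na <- function(x) !is.na(x)

#' Read / write per-cow gait score tables
#'
#' `herds.csv` columns: `farm_id`, `cow_id`, `gait_score` (0/1/2).
#'
#' @param path file path.
#' @return Data frame of per-cow records.
#' @export
read_herds_csv <- function(path) {
  read_checked_csv(path, list(farm_id = not_na, cow_id = not_na,
                              gait_score = is_gait))
}

#' @rdname read_herds_csv
#' @param herds data frame with `farm_id`, `cow_id`, `gait_score`.
#' @export
write_herds_csv <- function(herds, path) {
  utils::write.csv(herds[, c("farm_id", "cow_id", "gait_score")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write expert rating tables
#'
#' `ratings.csv` columns: `respondent_id`, `mild_pct`, `severe_pct`,
#' `rating` (0-10).  On read, prevalences are also exposed as proportions
#' (`mild`, `severe`) for the modelling layer.
#'
#' @param path file path.
#' @return Data frame of rating records.
#' @export
read_ratings_csv <- function(path) {
  df <- read_checked_csv(path, list(respondent_id = not_na,
                                    mild_pct = is_pct, severe_pct = is_pct,
                                    rating = is_rating))
  df$mild <- df$mild_pct / 100
  df$severe <- df$severe_pct / 100
  df
}

#' @rdname read_ratings_csv
#' @param ratings data frame with `respondent_id`, `mild_pct`,
#'   `severe_pct`, `rating`.
#' @export
write_ratings_csv <- function(ratings, path) {
  utils::write.csv(ratings[, c("respondent_id", "mild_pct", "severe_pct",
                               "rating")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-measure validity rating tables
#'
#' `measures.csv` columns: `respondent_id`, `measure`, `rating` (0-10).
#'
#' @param path file path.
#' @return Data frame of per-measure records.
#' @export
read_measures_csv <- function(path) {
  read_checked_csv(path, list(respondent_id = not_na, measure = not_na,
                              rating = is_rating))
}

#' @rdname read_measures_csv
#' @param measures data frame with `respondent_id`, `measure`, `rating`.
#' @export
write_measures_csv <- function(measures, path) {
  utils::write.csv(measures[, c("respondent_id", "measure", "rating")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-farm scores
#' @param scored data frame from [score_farms()] (optionally with the
#'   aggregated category columns).
#' @param path file path.
#' @export
write_scores_csv <- function(scored, path) {
  utils::write.csv(scored, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize fitted models and the AIC table to JSON
#'
#' @param fits named list of [clmm_fit()] objects.
#' @param selection result of [select_by_aic()] over `fits`.
#' @param path output path (`fits.json`).
#' @export
write_fits_json <- function(fits, selection, path) {
  payload <- list(
    models = lapply(fits, function(f) list(
      terms = f$spec$terms, alpha = f$alpha, delta = f$delta,
      beta = as.list(f$beta), sigma = f$sigma, loglik = f$loglik,
      n_params = f$n_params, aic = f$aic, converged = f$converged,
      n_obs = f$n_obs, n_respondents = f$n_respondents)),
    aic_table = selection$table,
    selected = selection$best$spec$terms)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration (JSON, or YAML when available)
#'
#' Unknown top-level keys are rejected so typos cannot silently disable a
#' setting.
#'
#' @param path path to a `.json` (or `.yaml`/`.yml`, if the yaml package is
#'   installed) configuration file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("seed", "n_farms", "herd_size_range", "profile_counts",
             "n_respondents", "per_respondent", "contamination_rate",
             "truth", "companion_scores", "profile_sets", "ci_level",
             "out_dir", "quad_order", "n_starts")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}
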