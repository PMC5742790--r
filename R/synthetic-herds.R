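#' Configuration for the synthetic herd generator
#'
#' The defaults emulate the case-study design the pipeline is meant to
#' exercise: 44 loose-housed dairy farms with 101-452 cows (mean about 184),
#' whose mild/severe lameness prevalences are spread over the nine observed
#' lameness profiles with the case study's per-profile farm counts
#' (2, 6, 14, 4, 2, 7, 2, 4, 3 farms in profiles 1-9).
#'
#' @param n_farms number of farms.
#' @param herd_size_range integer interval `c(min, max)` of cows per farm.
#' @param prevalence_scheme either a data frame / two-column matrix of
#'   per-farm `(mild_pct, severe_pct)` targets (recycled or truncated to
#'   `n_farms` is an error: must have `n_farms` rows), or a length-9 integer
#'   vector of per-profile farm counts summing to `n_farms`, in which case
#'   each farm's target is drawn uniformly inside its profile's prevalence
#'   bin.
#' @param seed integer master seed.
#' @return Class `herd_config`.
#' @export
herd_config <- function(n_farms = 44L,
                        herd_size_range = c(101L, 452L),
                        prevalence_scheme = c(2L, 6L, 14L, 4L, 2L, 7L, 2L,
                                              4L, 3L),
                        seed = 1L) {
  stopifnot(n_farms >= 1L, length(herd_size_range) == 2L,
            herd_size_range[1L] >= 1L,
            herd_size_range[2L] >= herd_size_range[1L])
  if (is.data.frame(prevalence_scheme) || is.matrix(prevalence_scheme)) {
    tgt <- as.matrix(prevalence_scheme)
    stopifnot(ncol(tgt) == 2L)
    if (nrow(tgt) != n_farms)
      stop("prevalence target table must have one row per farm",
           call. = FALSE)
    bad <- tgt[, 1L] < 0 | tgt[, 2L] < 0 | rowSums(tgt) > 100
    if (any(bad))
      stop("infeasible prevalence target (mild + severe > 100%) in row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
  } else {
    stopifnot(length(prevalence_scheme) == 9L,
              all(prevalence_scheme >= 0))
    if (sum(prevalence_scheme) != n_farms)
      stop("per-profile farm counts must sum to n_farms", call. = FALSE)
  }
  structure(list(n_farms = as.integer(n_farms),
                 herd_size_range = as.integer(herd_size_range),
                 prevalence_scheme = prevalence_scheme,
                 seed = as.integer(seed)),
            class = "herd_config")
}

# Uniform draw of a (mild, severe) target inside one profile's bin.  The
# open-ended bins are capped (mild <= 90%, severe <= 35%) so targets stay
# jointly feasible.
draw_profile_target <- function(profile) {
  g <- profile_grid()
  row <- g[g$profile == profile, ]
  mild_hi <- min(row$mild_hi, 90)
  severe_hi <- min(row$severe_hi, 35)
  mild <- stats::runif(1L, row$mild_lo, mild_hi)
  severe <- stats::runif(1L, row$severe_lo, min(severe_hi, 100 - mild))
  c(mild, severe)
}

#' Generate per-cow gait scores for a set of farms
#'
#' Herd sizes are drawn from a clamped log-normal (median about 175 cows, log
#' SD 0.28) inside `herd_size_range`; each cow's gait score is an independent
#' multinomial draw from the farm's target `(mild, severe)` prevalence (no
#' within-farm correlation structure beyond the shared prevalence).
#'
#' @param config a [herd_config()].
#' @return Data frame with `farm_id`, `cow_id`, `gait_score`, of class
#'   `wq_herds`; the per-farm targets are attached as attribute `targets`.
#' @export
generate_herds <- function(config = herd_config()) {
  stopifnot(inherits(config, "herd_config"))
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_farms
    rng <- config$herd_size_range
    sizes <- pmin(pmax(round(exp(stats::rnorm(n, log(175), 0.28))),
                       rng[1L]), rng[2L])
    if (is.data.frame(config$prevalence_scheme) ||
        is.matrix(config$prevalence_scheme)) {
      targets <- as.matrix(config$prevalence_scheme)
    } else {
      profiles <- rep(1:9, times = config$prevalence_scheme)
      profiles <- profiles[sample.int(n)]
      targets <- t(vapply(profiles, draw_profile_target, numeric(2L)))
    }
    colnames(targets) <- c("mild_pct", "severe_pct")
    herds <- do.call(rbind, lapply(seq_len(n), function(i) {
      p <- c(1 - sum(targets[i, ]) / 100, targets[i, 1L] / 100,
             targets[i, 2L] / 100)
      data.frame(farm_id = i, cow_id = seq_len(sizes[i]),
                 gait_score = sample(0:2, sizes[i], replace = TRUE, prob = p))
    }))
    rownames(herds) <- NULL
    structure(herds, targets = cbind(farm_id = seq_len(n), targets),
              class = c("wq_herds", "data.frame"))
  })
}
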