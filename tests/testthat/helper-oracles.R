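# Independent oracles used to check the package's likelihood machinery.
# These deliberately avoid the package's Gauss-Hermite code path.

# Brute-force marginal log-likelihood: trapezoid rule over the random
# intercept on a wide fixed grid, record-wise logistic interval
# probabilities.
brute_loglik <- function(params, records, grid_n = 20001L, lim = 12) {
  th <- c(-Inf, params$alpha + (0:9) * params$delta, Inf)
  eta <- rep(0, nrow(records))
  if (length(params$beta)) {
    cols <- cbind(mild = records$mild, severe = records$severe,
                  mild_sq = records$mild^2, severe_sq = records$severe^2,
                  mild_x_severe = records$mild * records$severe)
    eta <- drop(cols[, names(params$beta), drop = FALSE] %*% params$beta)
  }
  u <- seq(-lim, lim, length.out = grid_n)
  du <- u[2L] - u[1L]
  total <- 0
  for (id in unique(records$respondent_id)) {
    rows <- which(records$respondent_id == id)
    if (params$sigma == 0) {
      for (o in rows)
        total <- total + log(plogis(th[records$rating[o] + 2L] - eta[o]) -
                               plogis(th[records$rating[o] + 1L] - eta[o]))
    } else {
      lik_u <- rep(1, grid_n)
      for (o in rows)
        lik_u <- lik_u *
          (plogis(th[records$rating[o] + 2L] - eta[o] - u) -
             plogis(th[records$rating[o] + 1L] - eta[o] - u))
      total <- total + log(sum(lik_u * dnorm(u, 0, params$sigma)) * du)
    }
  }
  total
}

# Small deterministic rating panel for likelihood tests.
tiny_panel <- function(seed = 42L, n_resp = 3L, per = 5L) {
  set.seed(seed)
  data.frame(
    respondent_id = rep(letters[seq_len(n_resp)], each = per),
    mild = round(runif(n_resp * per, 0, 0.7), 3),
    severe = round(runif(n_resp * per, 0, 0.15), 3),
    rating = sample(0:10, n_resp * per, replace = TRUE))
}

# Build rating records for one respondent from (mild%, severe%, rating)
# triples; used by the cleaning-rule fixtures.
resp_records <- function(id, triples) {
  do.call(rbind, lapply(triples, function(tr)
    data.frame(respondent_id = id, mild = tr[1L] / 100,
               severe = tr[2L] / 100, rating = as.integer(tr[3L]))))
}

fast_ctrl <- function(n_starts = 1L, quad_order = 31L, ...)
  clmm_control(n_starts = n_starts, quad_order = quad_order, ...)
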