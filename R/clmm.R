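#' Candidate fixed-effect structures for the acceptability model
#'
#' Four nested structures over the (mild, severe) lameness prevalences:
#' both linear effects; plus their interaction (non-additive); plus quadratic
#' terms (non-linear); or both (non-additive and non-linear, interaction
#' between the linear effects only).  All models share a logit link,
#' equidistant thresholds and a respondent random intercept.
#'
#' @param terms one of `"linear"`, `"linear_interaction"`,
#'   `"linear_quadratic"`, `"linear_quadratic_interaction"`.
#' @return Class `clmm_spec`.
#' @export
model_spec <- function(terms = c("linear", "linear_interaction",
                                 "linear_quadratic",
                                 "linear_quadratic_interaction")) {
  terms <- match.arg(terms)
  cols <- switch(terms,
    linear = c("mild", "severe"),
    linear_interaction = c("mild", "severe", "mild_x_severe"),
    linear_quadratic = c("mild", "severe", "mild_sq", "severe_sq"),
    linear_quadratic_interaction = c("mild", "severe", "mild_sq",
                                     "severe_sq", "mild_x_severe"))
  structure(list(terms = terms, coef_names = cols), class = "clmm_spec")
}

#' All four candidate structures
#' @return Named list of [model_spec()] objects.
#' @export
candidate_specs <- function() {
  nm <- c("linear", "linear_interaction", "linear_quadratic",
          "linear_quadratic_interaction")
  stats::setNames(lapply(nm, model_spec), nm)
}

# Design matrix on the internal proportion scale (mild, severe in [0, 1]).
clmm_model_matrix <- function(spec, mild, severe) {
  stopifnot(inherits(spec, "clmm_spec"))
  all_cols <- cbind(mild = mild, severe = severe,
                    mild_sq = mild^2, severe_sq = severe^2,
                    mild_x_severe = mild * severe)
  all_cols[, spec$coef_names, drop = FALSE]
}

#' Generative / fitted parameter set for the cumulative-link mixed model
#'
#' Thresholds are equidistant on the latent logit scale:
#' \eqn{\theta_j = \alpha + (j - 1)\delta}, `j = 1..10`, giving
#' \eqn{P(Y \le j - 1 \mid u) = \mathrm{logit}^{-1}(\theta_j - x'\beta - u)}
#' for ratings `Y` in 0-10, with respondent intercept
#' \eqn{u \sim N(0, \sigma^2)}.  Positive \eqn{x'\beta} pushes ratings up
#' (more acceptable); lameness effects are therefore negative.
#'
#' The defaults are the package's calibrated "true" expert process: a least
#' squares fit of the cumulative-logit surface implied by the published
#' average-expert acceptability table over the nine questionnaire scenarios
#' (clearly-unacceptable probability about 5% at 10% mild / 0% severe,
#' rising past 99% at 70% mild / 15% severe, with the mild-prevalence effect
#' attenuating as severe prevalence grows — a positive interaction).  The
#' respondent SD is not recoverable from published numbers and defaults to
#' 1.5 on the latent logit scale (moderate systematic disagreement).
#'
#' @param alpha threshold base (location of the first cut point).
#' @param delta threshold spacing, > 0.
#' @param beta named coefficients on the proportion scale; names must be a
#'   subset of `mild`, `severe`, `mild_sq`, `severe_sq`, `mild_x_severe`.
#' @param sigma respondent random-intercept SD, >= 0 (latent logit scale).
#' @return Class `clmm_params`.
#' @export
clmm_params <- function(alpha = -7.25, delta = 1.68,
                        beta = c(mild = -9.6, severe = -61.5, mild_sq = 1.3,
                                 severe_sq = 102, mild_x_severe = 31.5),
                        sigma = 1.5) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(delta), length(delta) == 1L,
            is.numeric(sigma), length(sigma) == 1L)
  if (delta <= 0) stop("threshold spacing delta must be > 0", call. = FALSE)
  if (sigma < 0) stop("respondent SD sigma must be >= 0", call. = FALSE)
  known <- c("mild", "severe", "mild_sq", "severe_sq", "mild_x_severe")
  if (length(beta) && (is.null(names(beta)) || !all(names(beta) %in% known)))
    stop("beta must be named with terms among: ",
         paste(known, collapse = ", "), call. = FALSE)
  structure(list(alpha = alpha, delta = delta, beta = beta, sigma = sigma),
            class = "clmm_params")
}

# Gauss-Hermite nodes/weights for weight exp(-x^2) via Golub-Welsch.
gauss_hermite <- function(order) {
  stopifnot(order >= 1L)
  if (order == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(order - 1L)
  J <- matrix(0, order, order)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

# Interval probabilities P(a < Z <= b) on the logistic scale, computed from
# the tail nearer the interval to avoid cancellation far out in either tail.
logistic_interval <- function(A, B) {
  up <- !is.na(A + B) & (A + B) > 0
  p <- stats::plogis(A) - stats::plogis(B)
  if (any(up)) {
    p[up] <- stats::plogis(-B[up]) - stats::plogis(-A[up])
  }
  p
}

# Upper/lower cut points for each rating: extended threshold ladder with
# -Inf below rating 0 and +Inf above rating 10.
rating_cuts <- function(rating, alpha, delta) {
  theta_ext <- c(-Inf, alpha + (0:9) * delta, Inf)
  list(upper = theta_ext[rating + 2L], lower = theta_ext[rating + 1L])
}

check_records <- function(records) {
  need <- c("respondent_id", "mild", "severe", "rating")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(records$rating %in% 0:10))
    stop("ratings must be integers in 0..10", call. = FALSE)
  if (any(records$mild < 0 | records$mild > 1 |
            records$severe < 0 | records$severe > 1))
    stop("mild/severe must be proportions in [0, 1]", call. = FALSE)
  invisible(records)
}

#' Marginal log-likelihood of the cumulative-link mixed model
#'
#' Integrates the respondent random intercept out of the cumulative-logit
#' likelihood by (non-adaptive) Gauss-Hermite quadrature:
#' \deqn{\ell = \sum_r \log \int \prod_{o \in r} P(y_o \mid u)\,
#'   \phi(u; 0, \sigma^2)\, du .}
#' With `sigma = 0` this reduces exactly to the fixed-effects
#' cumulative-logit log-likelihood.
#'
#' @param params a [clmm_params()] object (beta names must match `spec`).
#' @param records data frame with `respondent_id`, `mild`, `severe`
#'   (proportions in \[0, 1\]) and `rating` (0-10).
#' @param spec a [model_spec()]; defaults to the structure implied by
#'   `names(params$beta)`.
#' @param quad_order number of quadrature nodes (>= 1).
#' @return Log-likelihood (scalar).
#' @export
clmm_loglik <- function(params, records, spec = NULL, quad_order = 61L) {
  stopifnot(inherits(params, "clmm_params"), quad_order >= 1L)
  check_records(records)
  spec <- spec %||% spec_from_beta(params$beta)
  X <- clmm_model_matrix(spec, records$mild, records$severe)
  if (!identical(colnames(X), names(params$beta) %||% character(0)) &&
      length(params$beta))
    params$beta <- params$beta[colnames(X)]
  eta <- if (ncol(X)) drop(X %*% params$beta) else rep(0, nrow(records))
  clmm_loglik_core(params$alpha, params$delta, eta, records$rating,
                   as.integer(factor(records$respondent_id)),
                   params$sigma, quad_order)$loglik
}

spec_from_beta <- function(beta) {
  nm <- names(beta) %||% character(0)
  for (s in candidate_specs()) if (setequal(s$coef_names, nm)) return(s)
  # fall back to a bare spec carrying exactly these columns
  structure(list(terms = "custom", coef_names = nm), class = "clmm_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Core marginal likelihood. Returns loglik plus the pieces the gradient
# needs (posterior node weights, interval densities).
clmm_loglik_core <- function(alpha, delta, eta, rating, resp, sigma,
                             quad_order, keep = FALSE) {
  cuts <- rating_cuts(rating, alpha, delta)
  a0 <- cuts$upper - eta
  b0 <- cuts$lower - eta
  if (sigma == 0) {
    p <- pmax(logistic_interval(a0, b0), 1e-312)
    lp <- log(p)
    ll_by_resp <- rowsum(lp, resp)
    out <- list(loglik = sum(lp))
    if (keep) {
      out$A <- matrix(a0); out$B <- matrix(b0); out$P <- matrix(p)
      out$PW <- matrix(1, nrow = nrow(ll_by_resp)); out$u_nodes <- 0
      out$z_nodes <- 0
    }
    return(out)
  }
  gh <- gauss_hermite(quad_order)
  u <- sqrt(2) * sigma * gh$nodes              # latent intercepts at nodes
  logW <- log(gh$weights) - 0.5 * log(pi)      # normalized N(0,1) weights
  K <- length(u)
  A <- outer(a0, rep(1, K)) - rep(u, each = length(a0))
  B <- outer(b0, rep(1, K)) - rep(u, each = length(b0))
  P <- pmax(logistic_interval(A, B), 1e-312)
  L <- rowsum(log(P), resp)                    # respondents x nodes
  M <- sweep(L, 2L, logW, `+`)
  mmax <- apply(M, 1L, max)
  lse <- mmax + log(rowSums(exp(M - mmax)))
  out <- list(loglik = sum(lse))
  if (keep) {
    out$A <- A; out$B <- B; out$P <- P
    out$PW <- exp(M - lse)                     # posterior node weights
    out$u_nodes <- u; out$z_nodes <- gh$nodes
  }
  out
}

# Analytic gradient of the marginal log-likelihood w.r.t. the optimizer
# parameterization (alpha, log delta, beta, log sigma).
clmm_grad_core <- function(alpha, delta, eta, X, rating, resp, sigma,
                           quad_order) {
  core <- clmm_loglik_core(alpha, delta, eta, rating, resp, sigma,
                           quad_order, keep = TRUE)
  FA <- stats::dlogis(core$A)
  FB <- stats::dlogis(core$B)
  D <- (FA - FB) / core$P
  # multipliers of delta inside each cut: theta_j = alpha + (j-1) delta
  m_up <- rating          # j_up - 1 (value irrelevant where cut infinite)
  m_lo <- pmax(rating - 1L, 0L)
  Ddelta <- (FA * m_up - FB * m_lo) / core$P
  PW <- core$PW
  g_alpha <- sum(PW * rowsum(D, resp))
  g_delta <- sum(PW * rowsum(Ddelta, resp)) * delta       # d/d log delta
  g_beta <- if (ncol(X)) {
    vapply(seq_len(ncol(X)), function(j)
      -sum(PW * rowsum(D * X[, j], resp)), numeric(1))
  } else numeric(0)
  if (sigma == 0) {
    g_sigma <- 0
  } else {
    SD <- rowsum(D, resp)                                  # resp x nodes
    g_sigma <- -sqrt(2) * sum(colSums(PW * SD) * core$z_nodes) * sigma
  }
  c(g_alpha, g_delta, g_beta, g_sigma)
}

#' Fitting control for [clmm_fit()]
#'
#' @param quad_order Gauss-Hermite order (default 61, at which the
#'   non-adaptive marginal likelihood matches brute-force integration to
#'   better than 1e-6 for respondent SDs up to about 2 with 5 observations
#'   per respondent).
#' @param n_starts number of deterministic multistarts (default 5).
#' @param maxit BFGS iteration cap per start.
#' @param grad_tol max-norm gradient tolerance below which a fit is flagged
#'   converged.
#' @param sigma_floor fitted SDs below this are reported as exactly 0 (the
#'   boundary of the parameter space), with the likelihood recomputed at
#'   `sigma = 0`.
#' @return Class `clmm_control`.
#' @export
clmm_control <- function(quad_order = 61L, n_starts = 5L, maxit = 400L,
                         grad_tol = 1e-3, sigma_floor = 1e-3) {
  structure(list(quad_order = as.integer(quad_order),
                 n_starts = as.integer(n_starts),
                 maxit = as.integer(maxit),
                 grad_tol = grad_tol, sigma_floor = sigma_floor),
            class = "clmm_control")
}

# Data-driven threshold start: regress empirical cumulative logits on the
# category index.
threshold_start <- function(rating) {
  cf <- cumsum(tabulate(rating + 1L, 11L)) / length(rating)
  cf <- pmin(pmax(cf[1:10], 0.01), 0.99)
  j <- 0:9
  fit <- stats::lm.fit(cbind(1, j), stats::qlogis(cf))
  alpha <- fit$coefficients[1L]
  delta <- max(fit$coefficients[2L], 0.05)
  c(alpha = unname(alpha), ldelta = log(unname(delta)))
}

#' Maximum-likelihood fit of the cumulative-link mixed model
#'
#' BFGS on the marginal likelihood with analytic gradients, parameterized as
#' (alpha, log delta, beta, log sigma) so the spacing and SD constraints hold
#' by construction.  A fixed-effects (sigma = 0) fit provides the warm start;
#' up to `n_starts` deterministic starting points spread over sigma are then
#' tried and the best optimum kept.  Fits whose SD collapses below
#' `sigma_floor` are returned at the sigma = 0 boundary (not an error).
#'
#' @param records rating records (see [clmm_loglik()]).
#' @param spec a [model_spec()].
#' @param control a [clmm_control()].
#' @return Class `clmm_fit`: estimates, log-likelihood, AIC (with
#'   `n_params` counting alpha, delta, all beta and sigma), convergence flag
#'   and gradient norm.
#' @export
clmm_fit <- function(records, spec = model_spec("linear"),
                     control = clmm_control()) {
  check_records(records)
  if (length(unique(records$rating)) < 2L)
    stop("need at least two distinct rating levels to fit", call. = FALSE)
  X <- clmm_model_matrix(spec, records$mild, records$severe)
  if (ncol(X) && qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("design is rank-deficient for spec '", spec$terms,
         "' (too few distinct scenarios)", call. = FALSE)
  resp <- as.integer(factor(records$respondent_id))
  rating <- as.integer(records$rating)
  nbeta <- ncol(X)
  # scale columns to unit max for optimizer conditioning (quadratic and
  # interaction terms span tiny ranges on the proportion scale); estimates
  # are reported back on the original scale
  scl <- if (nbeta) pmax(apply(abs(X), 2L, max), 1e-12) else numeric(0)
  if (nbeta) X <- sweep(X, 2L, scl, `/`)

  # line searches can propose wild parameters; keep the log-scale pieces
  # finite and make the objective defensively large instead of NaN
  guard <- function(th) {
    th[!is.finite(th)] <- 50
    th[2L] <- min(max(th[2L], -50), 50)
    if (length(th) == 3L + nbeta) th[3L + nbeta] <- min(th[3L + nbeta], 50)
    th
  }
  finite_or_big <- function(v) if (is.finite(v)) v else 1e10

  nll_fe <- function(th) {  # fixed-effects stage (sigma = 0)
    th <- guard(th)
    eta <- if (nbeta) drop(X %*% th[3:(2 + nbeta)]) else rep(0, length(rating))
    finite_or_big(
      -clmm_loglik_core(th[1L], exp(th[2L]), eta, rating, resp, 0, 1L)$loglik)
  }
  gr_fe <- function(th) {
    th <- guard(th)
    eta <- if (nbeta) drop(X %*% th[3:(2 + nbeta)]) else rep(0, length(rating))
    g <- -clmm_grad_core(th[1L], exp(th[2L]), eta, X, rating, resp, 0,
                         1L)[seq_len(2L + nbeta)]
    g[!is.finite(g)] <- 0
    g
  }
  ts <- threshold_start(rating)
  fe_start <- c(ts[1L], ts[2L], rep(0, nbeta))
  fe <- stats::optim(fe_start, nll_fe, gr_fe, method = "BFGS",
                     control = list(maxit = control$maxit, reltol = 1e-12))

  nll <- function(th) {
    th <- guard(th)
    eta <- if (nbeta) drop(X %*% th[3:(2 + nbeta)]) else rep(0, length(rating))
    finite_or_big(
      -clmm_loglik_core(th[1L], exp(th[2L]), eta, rating, resp,
                        exp(th[3L + nbeta]), control$quad_order)$loglik)
  }
  gr <- function(th) {
    th <- guard(th)
    eta <- if (nbeta) drop(X %*% th[3:(2 + nbeta)]) else rep(0, length(rating))
    g <- -clmm_grad_core(th[1L], exp(th[2L]), eta, X, rating, resp,
                         exp(th[3L + nbeta]), control$quad_order)
    g[!is.finite(g)] <- 0
    g
  }
  start_sigmas <- c(0.5, 1.5, 0.1, 3, 0.02)[seq_len(control$n_starts)]
  starts <- lapply(start_sigmas, function(s) c(fe$par, log(s)))
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, nll, gr, method = "BFGS",
                   control = list(maxit = control$maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best))
    stop("all optimizer starts failed", call. = FALSE)

  th <- guard(best$par)
  gnorm <- max(abs(gr(th)))
  sigma <- exp(th[3L + nbeta])
  alpha <- th[1L]; delta <- exp(th[2L])
  beta <- if (nbeta) stats::setNames(th[3:(2 + nbeta)] / scl, colnames(X)) else numeric(0)
  loglik <- -best$value
  if (sigma < control$sigma_floor) {
    sigma <- 0
    eta <- if (nbeta) drop(X %*% th[3:(2 + nbeta)]) else rep(0, length(rating))
    loglik <- clmm_loglik_core(alpha, delta, eta, rating, resp, 0, 1L)$loglik
  }
  n_params <- 2L + nbeta + 1L
  structure(list(
    spec = spec, alpha = alpha, delta = delta, beta = beta, sigma = sigma,
    loglik = loglik, n_params = n_params,
    aic = -2 * loglik + 2 * n_params,
    converged = best$convergence == 0L && gnorm < max(control$grad_tol,
                                                      1e-6 * abs(loglik)),
    grad_norm = gnorm, n_obs = length(rating),
    n_respondents = length(unique(resp)),
    quad_order = control$quad_order
  ), class = "clmm_fit")
}

#' @export
print.clmm_fit <- function(x, ...) {
  cat("Cumulative-link mixed model (logit, equidistant thresholds)\n")
  cat(sprintf("  terms: %s | n = %d obs, %d respondents\n",
              x$spec$terms, x$n_obs, x$n_respondents))
  cat(sprintf("  alpha = %.3f, delta = %.3f, sigma = %.3f\n",
              x$alpha, x$delta, x$sigma))
  if (length(x$beta)) {
    cat("  beta:\n")
    for (nm in names(x$beta))
      cat(sprintf("    %-14s %8.3f\n", nm, x$beta[[nm]]))
  }
  cat(sprintf("  logLik = %.2f, AIC = %.1f (k = %d), converged: %s\n",
              x$loglik, x$aic, x$n_params, x$converged))
  invisible(x)
}
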