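# One-way random-intercept variance decomposition.
#
# Model: y_ij = mu + a_i + e_ij, a_i ~ N(0, sigma2_b), e_ij ~ N(0, sigma2_w),
# for individual i and biopsy j. The likelihood is profiled over the variance
# ratio lambda = sigma2_b / sigma2_w: given lambda, the GLS mean and the
# within variance have closed forms, leaving a 1-D bounded optimization.
#
# For group i with n_i observations, group mean m_i and within sum of
# squares SS_i, and w_i = n_i / (1 + lambda * n_i):
#   mu(lambda)  = sum(w_i m_i) / sum(w_i)
#   Q(lambda)   = sum(SS_i) + sum(w_i (m_i - mu)^2)
#   ML:   sigma2_w = Q/N,       logLik = -N/2 (log 2pi + 1 + log(Q/N))
#                                        - 1/2 sum(log(1 + lambda n_i))
#   REML: sigma2_w = Q/(N-1),   logLik adds -1/2 log(sum w_i) and replaces
#                                N by N-1 in the first term (up to constants
#                                this is the Patterson-Thompson restricted
#                                likelihood for the intercept-only design).

group_stats <- function(values, groups) {
  groups <- as.character(groups)
  n_i <- tapply(values, groups, length)
  m_i <- tapply(values, groups, mean)
  ss_i <- tapply(values, groups, function(x) sum((x - mean(x))^2))
  list(n_i = as.numeric(n_i), m_i = as.numeric(m_i),
       ss_i = as.numeric(ss_i), N = length(values), G = length(n_i))
}

profile_loglik <- function(lambda, gs, method) {
  w <- gs$n_i / (1 + lambda * gs$n_i)
  mu <- sum(w * gs$m_i) / sum(w)
  Q <- sum(gs$ss_i) + sum(w * (gs$m_i - mu)^2)
  if (method == "ML") {
    s2w <- Q / gs$N
    ll <- -gs$N / 2 * (log(2 * pi) + 1 + log(s2w)) -
      0.5 * sum(log1p(lambda * gs$n_i))
  } else {
    s2w <- Q / (gs$N - 1)
    ll <- -(gs$N - 1) / 2 * (log(2 * pi) + 1 + log(s2w)) -
      0.5 * sum(log1p(lambda * gs$n_i)) - 0.5 * log(sum(w))
  }
  list(loglik = ll, mu = mu, sigma2_within = s2w)
}

#' Fit the one-way random-intercept model by profile likelihood
#'
#' Estimates the between-individual and within-individual variance
#' components of `y_ij = mu + a_i + e_ij` by maximizing the (restricted)
#' Gaussian likelihood, profiled over the variance ratio
#' `lambda = sigma2_between / sigma2_within` with the mean and the within
#' variance concentrated out. The search is bounded (`lambda` in
#' `[0, 1e6]`): a coarse log-spaced scan brackets the optimum, which is then
#' refined by Brent's method ([stats::optimize()]) to a relative tolerance
#' below 1e-8. The boundary `lambda = 0` is always considered.
#'
#' @param values Numeric response (component content, g/gDW), finite.
#' @param groups Grouping labels (individual sponge ids); at least 2 groups.
#' @param method `"REML"` (default, standard for variance components) or
#'   `"ML"` (used for likelihood-ratio model comparison).
#' @return An object of class `varcomp_fit`: list with `sigma2_between`,
#'   `sigma2_within`, `pct_between`, `mu`, `lambda`, `loglik`, `method`,
#'   `n`, `n_groups`.
#' @seealso [lrt_random_effect()], [pct_between()]
#' @export
#' @examples
#' set.seed(1)
#' y <- rep(rnorm(4, sd = 1), each = 5) + rnorm(20, sd = 0.5)
#' fit_random_intercept(y, rep(1:4, each = 5))
fit_random_intercept <- function(values, groups, method = c("REML", "ML")) {
  method <- match.arg(method)
  stop_if_not_number(values, "values")
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  gs <- group_stats(values, groups)
  if (gs$G < 2L) stop("at least 2 groups are required", call. = FALSE)
  if (gs$N < 2L) stop("at least 2 observations are required", call. = FALSE)

  if (stats::var(values) == 0) {
    # constant response: no variance to partition
    warning("all observations equal; variance components are zero",
            call. = FALSE)
    return(structure(
      list(sigma2_between = 0, sigma2_within = .Machine$double.eps,
           pct_between = 0, mu = values[1L], lambda = 0,
           loglik = NA_real_, method = method, n = gs$N, n_groups = gs$G),
      class = "varcomp_fit"))
  }

  degenerate_within <- sum(gs$ss_i) <= 0 && stats::var(gs$m_i) > 0
  obj <- function(lambda) profile_loglik(lambda, gs, method)$loglik

  upper <- 1e6
  grid <- c(0, 10^seq(-8, log10(upper), length.out = 120L))
  ll_grid <- vapply(grid, obj, numeric(1))
  best <- which.max(ll_grid)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  if (hi > lo) {
    opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-12)
    lambda <- if (opt$objective >= ll_grid[best]) opt$maximum else grid[best]
  } else {
    lambda <- grid[best]
  }
  # boundary check: never report an interior optimum worse than lambda = 0
  if (obj(0) >= obj(lambda)) lambda <- 0

  prof <- profile_loglik(lambda, gs, method)
  s2w <- prof$sigma2_within
  if (degenerate_within) {
    warning("no within-group variability; within variance at its floor",
            call. = FALSE)
    s2w <- max(s2w, .Machine$double.eps)
  }
  s2b <- lambda * s2w
  structure(
    list(sigma2_between = s2b, sigma2_within = s2w,
         pct_between = 100 * lambda / (1 + lambda),
         mu = prof$mu, lambda = lambda, loglik = prof$loglik,
         method = method, n = gs$N, n_groups = gs$G),
    class = "varcomp_fit"
  )
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept fit (%s): sigma2_b = %.4g, sigma2_w = %.4g\n",
    x$method, x$sigma2_between, x$sigma2_within))
  cat(sprintf("  between-individual share: %.1f%%  (n = %d, groups = %d)\n",
              x$pct_between, x$n, x$n_groups))
  invisible(x)
}

#' Between-individual share of total variance
#'
#' @param fit A `varcomp_fit` from [fit_random_intercept()].
#' @return `100 * sigma2_between / (sigma2_between + sigma2_within)`.
#' @export
pct_between <- function(fit) {
  if (!inherits(fit, "varcomp_fit")) {
    stop("`fit` must be a varcomp_fit", call. = FALSE)
  }
  100 * fit$sigma2_between / (fit$sigma2_between + fit$sigma2_within)
}

#' Likelihood-ratio test of the individual-level random effect
#'
#' Compares the ML fits of the random-intercept model and the
#' intercept-only model without the grouping factor. The statistic is
#' `chi2 = 2 (logLik_full - logLik_null)`, clipped at zero.
#'
#' @details The reported `p_value` uses the naive chi-squared reference with
#' 1 degree of freedom. Because the null hypothesis `sigma2_between = 0`
#' lies on the boundary of the parameter space, this reference is
#' conservative; the 50:50 chi0:chi1 mixture p-value is also returned as
#' `p_value_mixture`.
#'
#' @inheritParams fit_random_intercept
#' @return List with `chi2`, `p_value`, `p_value_mixture`, `loglik_full`,
#'   `loglik_null`.
#' @export
lrt_random_effect <- function(values, groups) {
  if (stats::var(values) == 0) {
    return(list(chi2 = 0, p_value = 1, p_value_mixture = 1,
                loglik_full = NA_real_, loglik_null = NA_real_))
  }
  full <- fit_random_intercept(values, groups, method = "ML")
  n <- length(values)
  s2_null <- sum((values - mean(values))^2) / n
  ll_null <- -n / 2 * (log(2 * pi) + 1 + log(s2_null))
  chi2 <- max(0, 2 * (full$loglik - ll_null))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p_mix <- if (chi2 <= 0) 1 else 0.5 * p
  list(chi2 = chi2, p_value = p, p_value_mixture = p_mix,
       loglik_full = full$loglik, loglik_null = ll_null)
}

#' Variance partitioning for every macro-component in a measurement table
#'
#' Fits [fit_random_intercept()] and [lrt_random_effect()] per component,
#' reproducing the published-style variance-decomposition table.
#'
#' @param measurements Data frame with columns `component`, `sponge_id`,
#'   `g_per_gDW`.
#' @param method Estimation method for the variance shares; both are valid,
#'   REML is the default.
#' @return Data frame with one row per component: `component`,
#'   `pct_between`, `chi2`, `p_value`, `p_value_mixture`,
#'   `sigma2_between`, `sigma2_within`, `n`.
#' @export
variance_partition <- function(measurements, method = c("REML", "ML")) {
  method <- match.arg(method)
  required <- c("component", "sponge_id", "g_per_gDW")
  missing <- setdiff(required, names(measurements))
  if (length(missing)) {
    stop("measurement table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  comps <- unique(measurements$component)
  rows <- lapply(comps, function(cc) {
    sub <- measurements[measurements$component == cc, , drop = FALSE]
    fit <- fit_random_intercept(sub$g_per_gDW, sub$sponge_id, method = method)
    lrt <- lrt_random_effect(sub$g_per_gDW, sub$sponge_id)
    data.frame(component = cc,
               pct_between = fit$pct_between,
               chi2 = lrt$chi2,
               p_value = lrt$p_value,
               p_value_mixture = lrt$p_value_mixture,
               sigma2_between = fit$sigma2_between,
               sigma2_within = fit$sigma2_within,
               n = fit$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
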