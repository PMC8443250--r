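# Causal mediation analysis for a binary treatment, one continuous
# mediator and one continuous outcome: OLS path models, quasi-Bayesian
# Monte-Carlo ACME with percentile intervals, and a nonparametric
# bootstrap alternative.

#' Fit the two mediation path regressions
#'
#' OLS fits of the mediator model M ~ 1 + T and the outcome model
#' Y ~ 1 + T + M (treatment coded Placebo = 0, L-DOPA = 1 by the caller).
#' Returns the path coefficients a (treatment on mediator), b (mediator
#' on outcome, treatment-adjusted), c' (direct effect) and the total
#' effect c from Y ~ 1 + T, together with each model's coefficient
#' covariance. With no further covariates, c = c' + a b holds exactly.
#'
#' @param treatment 0/1 vector, both levels present, n >= 6.
#' @param mediator,outcome Numeric vectors, same length.
#' @return Object of class `mediation_paths`: coefficients `a`, `b`,
#'   `c_prime`, `c_total`, standard errors, per-model covariance blocks,
#'   `n`, and the data (for bootstrapping).
#' @export
fit_paths <- function(treatment, mediator, outcome) {
  n <- length(treatment)
  stopifnot(length(mediator) == n, length(outcome) == n)
  if (n < 6) stop("need at least 6 subjects")
  if (!all(treatment %in% c(0, 1))) stop("treatment must be coded 0/1")
  if (length(unique(treatment)) < 2) stop("treatment must have both levels")
  m_mod <- stats::lm(mediator ~ treatment)
  y_mod <- stats::lm(outcome ~ treatment + mediator)
  t_mod <- stats::lm(outcome ~ treatment)
  if (any(!is.finite(c(stats::coef(m_mod), stats::coef(y_mod))))) {
    stop("rank-deficient path model")
  }
  # zero-residual fits are legitimate here; silence the perfect-fit note
  sm <- suppressWarnings(summary(m_mod))$coefficients
  sy <- suppressWarnings(summary(y_mod))$coefficients
  structure(list(
    a = unname(stats::coef(m_mod)["treatment"]),
    b = unname(stats::coef(y_mod)["mediator"]),
    c_prime = unname(stats::coef(y_mod)["treatment"]),
    c_total = unname(stats::coef(t_mod)["treatment"]),
    se_a = sm["treatment", "Std. Error"],
    se_b = sy["mediator", "Std. Error"],
    vcov_m = suppressWarnings(stats::vcov(m_mod)),
    vcov_y = suppressWarnings(stats::vcov(y_mod)),
    coef_m = stats::coef(m_mod), coef_y = stats::coef(y_mod),
    n = n,
    data = data.frame(treatment = treatment, mediator = mediator,
                      outcome = outcome)),
    class = "mediation_paths")
}

# one multivariate-normal draw block: draws (n x p) from N(mu, Sigma);
# eigen-based square root tolerates singular covariance (zero-noise fits)
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  e <- eigen(sigma, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
  out <- matrix(stats::rnorm(n * p), n, p) %*% t(L) +
    matrix(mu, n, p, byrow = TRUE)
  colnames(out) <- names(mu)
  out
}

mediation_result <- function(draws, paths, level, method, seed, n_draws) {
  acme <- stats::median(draws)
  ci <- unname(stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2)))
  # ties at zero count for both sides, so a degenerate all-zero draw set
  # gives p = 1; continuous draws are unaffected almost surely
  p <- max(2 * min(mean(draws >= 0), mean(draws <= 0)), 1 / n_draws)
  p <- min(p, 1)
  structure(list(
    a = paths$a, b = paths$b, c_total = paths$c_total,
    c_prime = paths$c_prime,
    acme = acme, acme_mean = mean(draws),
    ci_low = ci[1], ci_high = ci[2], level = level,
    p = p, n_draws = n_draws, method = method, seed = seed),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result> %s: ACME = %.4g [%g%% CI %.4g, %.4g], p = %.4g (%d draws)\n",
    x$method, x$acme, 100 * x$level, x$ci_low, x$ci_high, x$p, x$n_draws))
  cat(sprintf("  paths: a = %.4g, b = %.4g, c' = %.4g, c = %.4g\n",
              x$a, x$b, x$c_prime, x$c_total))
  invisible(x)
}

#' Quasi-Bayesian ACME
#'
#' Draws coefficient vectors from the asymptotic normal approximation of
#' each fitted path model (independently across the two models), forms
#' the indirect-effect draws a_i * b_i, and summarises them: the point
#' estimate is the median of draws (the mean is also reported), the
#' interval is the percentile interval at `level`, and the two-sided
#' Monte-Carlo p-value is floored at 1/n_draws.
#'
#' @param paths A [fit_paths()] result.
#' @param n_draws Number of Monte-Carlo draws (>= 100; default 1000).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @return An object of class `mediation_result`.
#' @export
acme_quasi_bayesian <- function(paths, n_draws = 1000, level = 0.95, seed = 1L) {
  stopifnot(inherits(paths, "mediation_paths"))
  if (n_draws < 100) stop("n_draws must be >= 100")
  draws <- withr::with_seed(as.integer(seed), {
    am <- rmvn(n_draws, paths$coef_m, paths$vcov_m)
    ym <- rmvn(n_draws, paths$coef_y, paths$vcov_y)
    am[, "treatment"] * ym[, "mediator"]
  })
  mediation_result(draws, paths, level, "quasi_bayesian", seed, n_draws)
}

#' Nonparametric bootstrap ACME
#'
#' Resamples subjects with replacement, refits both path regressions per
#' resample and uses a* x b* as the indirect-effect draw. Resamples with
#' a single-level treatment are redrawn (at most 100 retries each).
#' Summaries as in [acme_quasi_bayesian()].
#'
#' @param paths A [fit_paths()] result (carries the subject-level data).
#' @param n_draws Number of bootstrap resamples (>= 100; default 1000).
#' @param level Interval level.
#' @param seed Integer seed.
#' @return An object of class `mediation_result`.
#' @export
acme_bootstrap <- function(paths, n_draws = 1000, level = 0.95, seed = 1L) {
  stopifnot(inherits(paths, "mediation_paths"))
  if (n_draws < 100) stop("n_draws must be >= 100")
  d <- paths$data
  n <- nrow(d)
  draws <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_draws), function(i) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        tr <- d$treatment[idx]
        if (length(unique(tr)) == 2) {
          a <- stats::coef(stats::lm(d$mediator[idx] ~ tr))[["tr"]]
          b <- stats::coef(stats::lm(d$outcome[idx] ~ tr + d$mediator[idx]))[[3]]
          # a degenerate resample (collinear mediator) is redrawn too
          if (is.finite(a) && is.finite(b)) return(a * b)
        }
      }
      stop("could not draw a resample with both treatment levels")
    }, numeric(1))
  })
  mediation_result(draws, paths, level, "bootstrap", seed, n_draws)
}
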