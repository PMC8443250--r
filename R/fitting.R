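# Subject-level maximum-likelihood estimation of hybrid-model parameters
# via Nelder-Mead simplex search on a smooth reparameterisation, plus
# cohort-level fitting with per-subject summaries.

BETA_MAX <- 50

# unconstrained <-> natural scales: alpha, omega logistic on [0,1];
# beta scaled-logistic on (0, BETA_MAX)
to_natural <- function(x) {
  c(alpha = stats::plogis(x[1]), omega = stats::plogis(x[2]),
    beta = BETA_MAX * stats::plogis(x[3]))
}
to_unconstrained <- function(alpha, omega, beta) {
  clip <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  c(stats::qlogis(clip(alpha)), stats::qlogis(clip(omega)),
    stats::qlogis(clip(beta / BETA_MAX)))
}

#' Fit hybrid-model parameters for one subject
#'
#' Minimises the Bernoulli negative log-likelihood over (alpha, omega,
#' beta) with a Nelder-Mead simplex search. The box constraints (alpha,
#' omega in [0, 1]; beta in (0, 50]) are handled by a smooth logistic
#' reparameterisation so the printed initialisation (0.5, 0.5, 4) stays
#' interior and the search is unconstrained. The default start is always
#' included; optional random restarts are drawn from alpha, omega ~
#' U(0.1, 0.9) and beta ~ U(0.5, 4), and the best minimum is returned.
#'
#' @param outcomes Binary outcome vector RO_t.
#' @param ratings 0/1 ratings with `NA` for missing; at least 5 observed.
#' @param init Starting [hybrid_params()] (default alpha 0.5, omega 0.5,
#'   beta 4).
#' @param state An [initial_state()] (default v0 0.75, eta0 1).
#' @param restarts Number of additional random starts (default 10).
#' @param seed Seed for the restart draws.
#' @return An object of class `fit_result`: list with `params`
#'   ([hybrid_params()]), `nll`, `n_trials_used`, `converged`, `boundary`,
#'   `n_restarts_used`, `init_used`.
#' @export
fit_subject <- function(outcomes, ratings,
                        init = hybrid_params(0.5, 0.5, 4),
                        state = initial_state(),
                        restarts = 10, seed = 1L) {
  fit_subject_multi(list(list(outcomes = outcomes, ratings = ratings,
                              state = state)),
                    init = init, restarts = restarts, seed = seed)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> alpha=%.3f omega=%.3f beta=%.3f  NLL=%.3f (%d trials%s%s)\n",
    x$params$alpha, x$params$omega, x$params$beta, x$nll, x$n_trials_used,
    if (x$converged) ", converged" else ", NOT converged",
    if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' Fit shared parameters across several outcome/rating streams
#'
#' Minimises the summed negative log-likelihood of several independent
#' streams that share one (alpha, omega, beta) triple but may differ in
#' initial state — e.g. the CS+ stream at v0 = 0.75 and the CS- stream
#' at v0 = 0, or replicate extinction sessions in a recovery study.
#'
#' @param streams List of streams; each element is a list with
#'   `outcomes`, `ratings` and optionally `state` (an
#'   [initial_state()]; defaults to the standard one).
#' @inheritParams fit_subject
#' @return A `fit_result` as in [fit_subject()]; `n_trials_used` counts
#'   observed ratings across streams.
#' @export
fit_subject_multi <- function(streams, init = hybrid_params(0.5, 0.5, 4),
                              restarts = 10, seed = 1L) {
  stopifnot(length(streams) >= 1)
  streams <- lapply(streams, function(s) {
    if (is.null(s$state)) s$state <- initial_state()
    s
  })
  n_obs <- sum(vapply(streams, function(s) sum(!is.na(s$ratings)), numeric(1)))
  if (n_obs < 5) stop("need at least 5 observed ratings (got ", n_obs, ")")
  objective <- function(x) {
    p <- to_natural(x)
    pars <- hybrid_params(p[1], p[2], p[3])
    sum(vapply(streams, function(s) {
      negative_log_likelihood(pars, s$outcomes, s$ratings, s$state)
    }, numeric(1)))
  }
  starts <- list(to_unconstrained(init$alpha, init$omega, init$beta))
  if (restarts > 0) {
    # deterministic coarse pre-scan: the simplex landscape is multimodal
    # (narrow low-omega basins), so the best few grid points always seed
    # additional searches; skipped for single-start quick fits
    pre <- expand.grid(alpha = c(0.1, 0.3, 0.5, 0.7, 0.9),
                       omega = c(0.02, 0.1, 0.3, 0.6, 0.9),
                       beta = c(0.5, 1, 2, 4, 8))
    pre_nll <- vapply(seq_len(nrow(pre)), function(k) {
      objective(to_unconstrained(pre$alpha[k], pre$omega[k], pre$beta[k]))
    }, numeric(1))
    top <- order(pre_nll)[1:3]
    starts <- c(starts, lapply(top, function(k) {
      to_unconstrained(pre$alpha[k], pre$omega[k], pre$beta[k])
    }))
    starts <- c(starts, withr::with_seed(as.integer(seed), {
      lapply(seq_len(restarts), function(i) {
        to_unconstrained(stats::runif(1, 0.1, 0.9), stats::runif(1, 0.1, 0.9),
                         stats::runif(1, 0.5, 4))
      })
    }))
  }
  best <- NULL
  for (s in starts) {
    f0 <- objective(s)
    if (!is.finite(f0)) next
    opt <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("non-finite NLL at every start")
  p <- to_natural(best$par)
  # beta below 0.01 saturates the softmax for any non-zero value, so it is
  # treated as a boundary solution just like the box edges
  boundary <- p["alpha"] < 1e-3 || p["alpha"] > 1 - 1e-3 ||
    p["omega"] < 1e-3 || p["omega"] > 1 - 1e-3 ||
    p["beta"] < 1e-2 || p["beta"] > 0.99 * BETA_MAX
  structure(
    list(params = hybrid_params(p[["alpha"]], p[["omega"]], p[["beta"]]),
         nll = best$value, n_trials_used = n_obs,
         converged = best$convergence == 0, boundary = unname(boundary),
         n_restarts_used = restarts, init_used = init),
    class = "fit_result"
  )
}

#' Fit a cohort of subjects and summarise the latent dynamics
#'
#' Runs [fit_subject()] per subject and augments each row with the three
#' per-subject summaries typically compared between groups: the mean
#' fitted prediction error, the mean associability, and the mean trial
#' learning rate alpha * eta_t. Per-subject errors (for example all
#' ratings missing) are contained as flagged rows rather than aborting
#' the cohort.
#'
#' @param datasets List of subject datasets; each element needs `subject`,
#'   `group`, `outcomes`, `ratings`, and for `streams = "both"` also
#'   `outcomes_minus`/`ratings_minus` (see [generate_cohort()]).
#' @param restarts,seed Passed to [fit_subject()]; the restart seed for
#'   subject i is `seed + i`.
#' @param state An [initial_state()] for the CS+ stream; the CS- stream
#'   of `streams = "both"` starts at v0 = 0.
#' @param streams `"csplus"` (default) fits the CS+ stream only;
#'   `"both"` shares (alpha, omega, beta) across CS+ and CS- streams.
#' @return Data frame, one row per subject, with columns `subject`,
#'   `group`, `alpha`, `omega`, `beta`, `nll`, `n_trials`, `converged`,
#'   `boundary`, `mean_pe`, `mean_assoc`, `mean_lr`, `flag`. Latent
#'   summaries are computed on the CS+ stream.
#' @export
fit_cohort <- function(datasets, restarts = 10, seed = 1L,
                       state = initial_state(),
                       streams = c("csplus", "both")) {
  streams <- match.arg(streams)
  rows <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    base <- data.frame(subject = d$subject, group = d$group,
                       alpha = NA_real_, omega = NA_real_, beta = NA_real_,
                       nll = NA_real_, n_trials = NA_integer_,
                       converged = NA, boundary = NA,
                       mean_pe = NA_real_, mean_assoc = NA_real_,
                       mean_lr = NA_real_, flag = NA_character_,
                       stringsAsFactors = FALSE)
    tryCatch({
      strm <- list(list(outcomes = d$outcomes, ratings = d$ratings,
                        state = state))
      if (streams == "both") {
        om <- if (!is.null(d$outcomes_minus)) d$outcomes_minus
              else rep(0L, length(d$ratings_minus))
        strm <- c(strm, list(list(outcomes = om, ratings = d$ratings_minus,
                                  state = initial_state(v0 = 0, eta0 = state$eta0))))
      }
      fit <- fit_subject_multi(strm, restarts = restarts, seed = seed + i)
      traj <- simulate_latents(fit$params, d$outcomes, state)
      base$alpha <- fit$params$alpha
      base$omega <- fit$params$omega
      base$beta <- fit$params$beta
      base$nll <- fit$nll
      base$n_trials <- fit$n_trials_used
      base$converged <- fit$converged
      base$boundary <- fit$boundary
      base$mean_pe <- mean(traj$pe)
      base$mean_assoc <- mean(traj$eta)
      base$mean_lr <- mean(fit$params$alpha * traj$eta)
      base
    }, error = function(e) {
      base$flag <- conditionMessage(e)
      base
    })
  })
  do.call(rbind, rows)
}
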