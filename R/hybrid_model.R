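# Rescorla-Wagner/Pearce-Hall hybrid learning model: latent recursions,
# softmax observation model for binary US-expectancy reports, and the
# Bernoulli likelihood.

#' Hybrid-model free parameters
#'
#' The three free parameters of the hybrid model: learning rate `alpha`,
#' associability weight `omega` (both on [0, 1]) and the softmax scale
#' `beta` (> 0). `beta` is conventionally called an inverse temperature,
#' but it enters the observation model as a divisor of the value, so large
#' `beta` flattens the response probability towards 0.5.
#'
#' @param alpha Learning rate in [0, 1].
#' @param omega Associability weight in [0, 1].
#' @param beta Softmax scale, > 0.
#' @return An object of class `hybrid_params`.
#' @export
hybrid_params <- function(alpha, omega, beta) {
  stopifnot(is.numeric(alpha), is.numeric(omega), is.numeric(beta),
            length(alpha) == 1, length(omega) == 1, length(beta) == 1)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (omega < 0 || omega > 1) stop("omega must be in [0, 1]")
  if (beta <= 0) stop("beta must be > 0")
  structure(list(alpha = alpha, omega = omega, beta = beta),
            class = "hybrid_params")
}

#' @export
print.hybrid_params <- function(x, ...) {
  cat(sprintf("<hybrid_params> alpha=%.4g omega=%.4g beta=%.4g\n",
              x$alpha, x$omega, x$beta))
  invisible(x)
}

#' Initial latent state
#'
#' Starting points for the value and associability recursions. The default
#' `v0 = 0.75` equals the CS+ reinforcement rate during acquisition (the
#' probability of a US following a CS+), and `eta0 = 1` makes the first
#' associability update fully prediction-error driven.
#'
#' @param v0 Initial value in [0, 1].
#' @param eta0 Initial associability in [0, 1].
#' @return An object of class `initial_state`.
#' @export
initial_state <- function(v0 = 0.75, eta0 = 1) {
  stopifnot(is.numeric(v0), is.numeric(eta0), length(v0) == 1, length(eta0) == 1)
  if (v0 < 0 || v0 > 1) stop("v0 must be in [0, 1]")
  if (eta0 < 0 || eta0 > 1) stop("eta0 must be in [0, 1]")
  structure(list(v0 = v0, eta0 = eta0), class = "initial_state")
}

check_outcomes <- function(outcomes) {
  if (!length(outcomes)) stop("outcomes must be non-empty")
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary (0/1)")
  as.numeric(outcomes)
}

#' Simulate the hybrid model's latent trajectories
#'
#' Runs the coupled recursions over a binary outcome sequence RO_t:
#' \deqn{PE_t = RO_t - v_t}
#' \deqn{v_{t+1} = v_t + \alpha \eta_t PE_t}
#' \deqn{\eta_{t+1} = \omega |PE_t| + (1 - \omega) \eta_t}
#' where the associability entering trial t's value update is the one
#' carried over from trial t-1 (eta_1 = eta0). Both v and eta stay in
#' [0, 1] for admissible inputs because each update is a convex
#' combination.
#'
#' @param params A [hybrid_params()] (beta is unused here).
#' @param outcomes Binary vector of received outcomes RO_t (1 = US
#'   delivered).
#' @param init An [initial_state()].
#' @return An object of class `latent_trajectory`: list with per-trial
#'   vectors `v` (pre-update value), `eta` (associability entering the
#'   update), `pe` (prediction error) and `v_next` (post-update value).
#' @export
simulate_latents <- function(params, outcomes, init = initial_state()) {
  stopifnot(inherits(params, "hybrid_params"), inherits(init, "initial_state"))
  ro <- check_outcomes(outcomes)
  n <- length(ro)
  v <- eta <- pe <- v_next <- numeric(n)
  v_t <- init$v0
  eta_t <- init$eta0
  for (t in seq_len(n)) {
    v[t] <- v_t
    eta[t] <- eta_t
    pe[t] <- ro[t] - v_t
    v_next[t] <- v_t + params$alpha * eta_t * pe[t]
    eta_t <- params$omega * abs(pe[t]) + (1 - params$omega) * eta_t
    v_t <- v_next[t]
  }
  structure(list(v = v, eta = eta, pe = pe, v_next = v_next),
            class = "latent_trajectory")
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat("<latent_trajectory> ", length(x$v), " trials; v in [",
      sprintf("%.3f", min(x$v)), ", ", sprintf("%.3f", max(x$v)), "]\n", sep = "")
  invisible(x)
}

#' Softmax response probability
#'
#' Probability of a "yes" US-expectancy report given the current value:
#' p = 1 / (1 + exp(-v / beta)). Monotone increasing in v; for v in
#' [0, 1] the probability lies in [0.5, 1), so the model cannot produce
#' below-chance expectancy.
#'
#' @param v Value(s), any numeric.
#' @param beta Softmax scale, > 0.
#' @return Probabilities, same length as `v`.
#' @export
response_probability <- function(v, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0) {
    stop("beta must be a positive scalar")
  }
  stats::plogis(v / beta)
}

#' Simulate binary US-expectancy ratings from a latent trajectory
#'
#' Draws rating_t ~ Bernoulli(p_t) with p_t = response_probability(v_t,
#' beta), reproducibly under a fixed seed.
#'
#' @param trajectory A [simulate_latents()] result.
#' @param beta Softmax scale, > 0.
#' @param seed Integer seed.
#' @return Integer vector of 0/1 ratings.
#' @export
simulate_ratings <- function(trajectory, beta, seed) {
  stopifnot(inherits(trajectory, "latent_trajectory"))
  p <- response_probability(trajectory$v, beta)
  withr::with_seed(as.integer(seed), {
    as.integer(stats::runif(length(p)) < p)
  })
}

# clipping bound for log-likelihood terms
LIK_EPS <- 1e-9

#' Negative log-likelihood of binary ratings under the hybrid model
#'
#' Bernoulli negative log-likelihood summed over observed trials. Missing
#' ratings (`NA`) contribute zero but the latent recursion still runs over
#' every trial: learning is driven by outcomes, not by whether a report
#' was recorded. Probabilities are clipped to [1e-9, 1 - 1e-9] before the
#' logarithm.
#'
#' @param params A [hybrid_params()].
#' @param outcomes Binary outcome vector RO_t.
#' @param ratings Vector of 0/1 ratings with `NA` for missing; same length
#'   as `outcomes`.
#' @param init An [initial_state()].
#' @return Scalar NLL (>= 0).
#' @export
negative_log_likelihood <- function(params, outcomes, ratings,
                                    init = initial_state()) {
  if (length(outcomes) != length(ratings)) {
    stop("outcomes and ratings must have equal length")
  }
  obs <- !is.na(ratings)
  if (!any(obs)) stop("all ratings missing: likelihood undefined")
  if (!all(ratings[obs] %in% c(0, 1))) stop("ratings must be 0/1 or NA")
  traj <- simulate_latents(params, outcomes, init)
  p <- response_probability(traj$v, params$beta)
  p <- pmin(pmax(p, LIK_EPS), 1 - LIK_EPS)
  r <- ratings[obs]
  p <- p[obs]
  -sum(r * log(p) + (1 - r) * log(1 - p))
}
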