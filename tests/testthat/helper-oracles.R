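# Independent oracles and small fixture builders shared across test files.
# These deliberately re-derive quantities with different code paths than
# the package implementation.

# Per-trial scalar recursion + incremental likelihood, written as a plain
# loop over scalars (oracle for simulate_latents / negative_log_likelihood).
loop_nll_oracle <- function(alpha, omega, beta, outcomes, ratings,
                            v0 = 0.75, eta0 = 1, eps = 1e-9) {
  v <- v0
  eta <- eta0
  nll <- 0
  for (t in seq_along(outcomes)) {
    p <- 1 / (1 + exp(-v / beta))
    p <- min(max(p, eps), 1 - eps)
    r <- ratings[t]
    if (!is.na(r)) {
      nll <- nll - (r * log(p) + (1 - r) * log(1 - p))
    }
    pe <- outcomes[t] - v
    v <- v + alpha * eta * pe
    eta <- omega * abs(pe) + (1 - omega) * eta
  }
  nll
}

# Closed-form pure Rescorla-Wagner decay under all-omission outcomes
# (omega = 0, eta0 = 1): v_t = v0 * (1 - alpha)^(t - 1).
rw_closed_form <- function(alpha, v0, n) v0 * (1 - alpha)^(seq_len(n) - 1)

# Outcome stream for recovery studies: repeated 24-trial 75%-reinforced
# acquisition blocks alternating with 24-trial extinction blocks,
# truncated to length T ("extinction-structured" long design).
cycled_outcomes <- function(T, seed) {
  withr::with_seed(seed, {
    o <- integer(0)
    while (length(o) < T) {
      acq <- integer(24)
      acq[sample.int(24, 18)] <- 1L
      o <- c(o, acq, integer(24))
    }
    o[seq_len(T)]
  })
}

# Simulate one agent's ratings on an outcome stream.
make_agent_ratings <- function(alpha, omega, beta, outcomes, seed) {
  tr <- simulate_latents(hybrid_params(alpha, omega, beta), outcomes)
  simulate_ratings(tr, beta, seed)
}

# Brute-force NLL over a 3-D parameter grid, vectorised across the grid
# (independent implementation: trial loop over grid-wide vectors).
grid_nll_oracle <- function(outcomes, ratings, alpha_grid, omega_grid,
                            beta_grid, v0 = 0.75, eta0 = 1, eps = 1e-9) {
  g2 <- expand.grid(alpha = alpha_grid, omega = omega_grid)
  T <- length(outcomes)
  V <- matrix(NA_real_, nrow(g2), T)
  v <- rep(v0, nrow(g2))
  eta <- rep(eta0, nrow(g2))
  for (t in seq_len(T)) {
    V[, t] <- v
    pe <- outcomes[t] - v
    v <- v + g2$alpha * eta * pe
    eta <- g2$omega * abs(pe) + (1 - g2$omega) * eta
  }
  obs <- which(!is.na(ratings))
  r <- ratings[obs]
  best <- Inf
  best_par <- c(NA, NA, NA)
  for (b in beta_grid) {
    P <- 1 / (1 + exp(-V[, obs, drop = FALSE] / b))
    P <- pmin(pmax(P, eps), 1 - eps)
    nll <- -(log(P) %*% r + log(1 - P) %*% (1 - r))
    idx <- which.min(nll)
    if (nll[idx] < best) {
      best <- nll[idx]
      best_par <- c(g2$alpha[idx], g2$omega[idx], b)
    }
  }
  list(nll = best, par = best_par)
}
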