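test_that("fit_subject attains at least the generating-parameter likelihood", {
  outcomes <- cycled_outcomes(200, seed = 31)
  truth <- hybrid_params(0.4, 0.3, 1)
  ratings <- make_agent_ratings(0.4, 0.3, 1, outcomes, seed = 32)
  fit <- fit_subject(outcomes, ratings, restarts = 3, seed = 1)
  expect_s3_class(fit, "fit_result")
  expect_lte(fit$nll, negative_log_likelihood(truth, outcomes, ratings))
  # never worse than its own start
  expect_lte(fit$nll,
             negative_log_likelihood(fit$init_used, outcomes, ratings))
  expect_true(fit$converged)
  expect_equal(fit$n_trials_used, 200)
})

test_that("fit_subject is deterministic under a fixed restart seed", {
  outcomes <- rep(0L, 30)
  ratings <- make_agent_ratings(0.5, 0.4, 1.5, outcomes, seed = 5)
  f1 <- fit_subject(outcomes, ratings, restarts = 4, seed = 9)
  f2 <- fit_subject(outcomes, ratings, restarts = 4, seed = 9)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$nll, f2$nll)
})

test_that("degenerate inputs error; saturated data hit the beta boundary", {
  expect_error(fit_subject(rep(0, 4), c(1, 0, 1, 0)), "at least 5")
  expect_error(fit_subject(rep(0, 10), c(1, 0, 1, 0, rep(NA, 6))), "at least 5")
  # constant all-1 ratings with all-omission outcomes: likelihood is
  # monotone towards saturating p, so a boundary solution is expected
  fit <- fit_subject(rep(0L, 40), rep(1L, 40), restarts = 2, seed = 3)
  expect_true(fit$boundary)
  expect_true(fit$converged)
  # p saturated at 1 on every trial means NLL near 0
  expect_lt(fit$nll, 0.5)
})

test_that("trailing missing ratings are equivalent to truncation", {
  outcomes <- cycled_outcomes(60, seed = 41)
  ratings <- make_agent_ratings(0.5, 0.5, 1, outcomes, seed = 42)
  masked <- ratings
  masked[51:60] <- NA
  p <- hybrid_params(0.37, 0.21, 0.8)
  expect_equal(negative_log_likelihood(p, outcomes, masked),
               negative_log_likelihood(p, outcomes[1:50], ratings[1:50]),
               tolerance = 1e-12)
  f_mask <- fit_subject(outcomes, masked, restarts = 2, seed = 7)
  f_trunc <- fit_subject(outcomes[1:50], ratings[1:50], restarts = 2, seed = 7)
  expect_equal(unclass(f_mask$params), unclass(f_trunc$params),
               tolerance = 1e-10)
})

test_that("the reparameterised optimum matches a brute-force grid search", {
  alpha_grid <- seq(0.001, 0.999, length.out = 41)
  omega_grid <- alpha_grid
  beta_grid <- exp(seq(log(0.25), log(50), length.out = 41))
  withr::with_seed(77, {
    for (i in 1:2) {
      outcomes <- cycled_outcomes(100, seed = 700 + i)
      ratings <- make_agent_ratings(runif(1, 0.2, 0.8), runif(1, 0.2, 0.8),
                                    runif(1, 0.5, 3), outcomes, seed = 800 + i)
      fit <- fit_subject(outcomes, ratings, restarts = 10, seed = i)
      grid <- grid_nll_oracle(outcomes, ratings, alpha_grid, omega_grid,
                              beta_grid)
      expect_lt(abs(fit$nll - grid$nll), 0.05)
    }
  })
})

test_that("multi-stream fitting shares parameters across streams", {
  outcomes <- rep(0L, 40)
  truth <- hybrid_params(0.45, 0.35, 1.2)
  tr_plus <- simulate_latents(truth, outcomes)
  tr_minus <- simulate_latents(truth, outcomes, initial_state(v0 = 0))
  r_plus <- simulate_ratings(tr_plus, 1.2, 21)
  r_minus <- simulate_ratings(tr_minus, 1.2, 22)
  streams <- list(
    list(outcomes = outcomes, ratings = r_plus),
    list(outcomes = outcomes, ratings = r_minus,
         state = initial_state(v0 = 0)))
  fit <- fit_subject_multi(streams, restarts = 3, seed = 4)
  ref <- negative_log_likelihood(truth, outcomes, r_plus) +
    negative_log_likelihood(truth, outcomes, r_minus, initial_state(v0 = 0))
  expect_lte(fit$nll, ref)
  expect_equal(fit$n_trials_used, 80)
})

test_that("fit_cohort returns one row per subject and contains errors", {
  outcomes <- rep(0L, 24)
  datasets <- lapply(1:6, function(i) {
    list(subject = sprintf("s%02d", i), group = if (i <= 3) "placebo" else "ldopa",
         outcomes = outcomes,
         ratings = make_agent_ratings(0.4, 0.4, 1, outcomes, seed = i))
  })
  fits <- fit_cohort(datasets, restarts = 1, seed = 2)
  expect_equal(nrow(fits), 6)
  expect_true(all(is.na(fits$flag)))
  expect_true(all(c("mean_pe", "mean_assoc", "mean_lr") %in% names(fits)))
  # latent summaries recomputed at the fitted parameters
  tr1 <- simulate_latents(hybrid_params(fits$alpha[1], fits$omega[1],
                                        fits$beta[1]), outcomes)
  expect_equal(fits$mean_pe[1], mean(tr1$pe), tolerance = 1e-12)
  expect_equal(fits$mean_lr[1], mean(fits$alpha[1] * tr1$eta), tolerance = 1e-12)
  # an all-missing subject is flagged, not fatal
  datasets[[3]]$ratings <- rep(NA_integer_, 24)
  fits2 <- fit_cohort(datasets, restarts = 1, seed = 2)
  expect_equal(nrow(fits2), 6)
  expect_equal(sum(!is.na(fits2$flag)), 1)
  expect_match(fits2$flag[3], "at least 5")
})

test_that("group comparison of fitted mean PE is calibrated under the null", {
  # scaled-down null-calibration study: 100 replications of two groups of
  # 12 drawn from identical parameter distributions, day-2-length streams
  n_rep <- 100
  outcomes <- rep(0L, 48)
  rejections <- withr::with_seed(2024, {
    vapply(seq_len(n_rep), function(rep) {
      datasets <- lapply(1:24, function(i) {
        a <- runif(1, 0.2, 0.8); o <- runif(1, 0.2, 0.8); b <- runif(1, 0.5, 3)
        list(subject = i, group = if (i <= 12) "a" else "b",
             outcomes = outcomes,
             ratings = make_agent_ratings(a, o, b, outcomes,
                                          seed = sample.int(1e6, 1)))
      })
      fits <- fit_cohort(datasets, restarts = 0, seed = rep)
      gt <- group_test(fits$mean_pe[fits$group == "a"],
                       fits$mean_pe[fits$group == "b"])
      gt$p < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.10)
})
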