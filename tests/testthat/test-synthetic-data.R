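small_config <- function(...) {
  cohort_config(n_placebo = 4, n_ldopa = 5, master_seed = 7, ...)
}

test_that("cohorts are reproducible and sized per config", {
  c1 <- generate_cohort(small_config())
  c2 <- generate_cohort(small_config())
  expect_identical(c1, c2)
  expect_length(c1, 9)
  expect_equal(sum(vapply(c1, `[[`, character(1), "group") == "placebo"), 4)
  expect_equal(sum(vapply(c1, `[[`, character(1), "group") == "ldopa"), 5)
  # default emulated cohort is 22 placebo / 24 L-DOPA
  cfg <- cohort_config()
  expect_equal(cfg$n_placebo, 22)
  expect_equal(cfg$n_ldopa, 24)
  expect_error(cohort_config(n_placebo = 1), "invalid config")
  expect_error(cohort_config(scr_noise_sd = -1), "scr_noise_sd")
})

test_that("subject datasets are internally consistent", {
  cohort <- generate_cohort(small_config(missing_rate = 0.1))
  for (s in cohort) {
    expect_length(s$ratings, 24)  # day-2 CS+ trials
    expect_true(all(s$ratings %in% c(0L, 1L, NA)))
    expect_length(s$trajectory$v, 24)
    expect_length(s$scr$csplus, 24)
    expect_true(all(s$scr$csplus >= 0 & s$scr$csplus <= 1))
    expect_equal(max(c(s$scr$csplus, s$scr$csminus)), 1)
    expect_equal(s$outcomes, rep(0L, 24))
    expect_equal(s$treatment, as.numeric(s$group == "ldopa"))
  }
  # missingness switch produces some missing ratings at 10%
  miss <- mean(is.na(unlist(lapply(cohort, `[[`, "ratings"))))
  expect_gt(miss, 0)
  expect_lt(miss, 0.3)
})

test_that("noise-free mediation chain shifts groups by exactly a*b", {
  cfg <- small_config(vmpfc_noise_sd = 0, scr_diff_noise_sd = 0, med_direct = 0)
  cohort <- generate_cohort(cfg)
  grp <- vapply(cohort, `[[`, character(1), "group")
  scr_diff <- vapply(cohort, `[[`, numeric(1), "scr_diff_retrieval")
  gap <- mean(scr_diff[grp == "ldopa"]) - mean(scr_diff[grp == "placebo"])
  expect_equal(gap, cfg$med_a * cfg$med_b, tolerance = 1e-12)
})

test_that("agents respect degenerate parameter limits and calibrate", {
  sched <- build_extinction(5)
  # alpha = 0: constant value, constant response probability
  ag0 <- generate_agent(hybrid_params(0, 0.5, 2), sched, seed = 1)
  expect_equal(ag0$trajectory$v, rep(0.75, 24))
  # beta -> 0+ with positive v saturates ratings at 1
  ag_sat <- generate_agent(hybrid_params(0.2, 0.5, 1e-9), sched, seed = 2)
  expect_equal(ag_sat$ratings, rep(1L, 24))
  # per-trial empirical yes-rate tracks the model probability
  p <- hybrid_params(0.4, 0.4, 1.5)
  traj <- simulate_latents(p, outcomes_for_cs(sched, "CS_PLUS"))
  p_model <- response_probability(traj$v, 1.5)
  rmat <- vapply(1:1000, function(i) simulate_ratings(traj, 1.5, i),
                 integer(24))
  expect_lt(max(abs(rowMeans(rmat) - p_model)), 0.05)
})

test_that("synthetic BOLD recovers betas and checks dimensions", {
  sched <- build_extinction(2)
  d <- build_design(sched, list(), n_scans = 470)
  beta_true <- c(2, 1, -0.5, 0.75)
  y0 <- generate_bold(d, beta_true, noise_sd = 0, seed = 1)
  fit <- fit_first_level(y0, d)
  expect_equal(unname(fit$betas[, 1]), beta_true, tolerance = 1e-8)
  expect_error(generate_bold(d, c(1, 2), noise_sd = 0, seed = 1),
               "per design column")
  y <- generate_bold(d, beta_true, noise_sd = 1, seed = 2, n_voxels = 3)
  expect_equal(dim(y), c(470, 3))
  expect_identical(generate_bold(d, beta_true, 1, seed = 2),
                   generate_bold(d, beta_true, 1, seed = 2))
})

test_that("the full pipeline runs end to end on one cohort", {
  cohort <- generate_cohort(small_config())
  fits <- fit_cohort(cohort, restarts = 1, seed = 3)
  expect_equal(nrow(fits), length(cohort))
  expect_true(all(is.na(fits$flag)))
  expect_true(all(fits$alpha >= 0 & fits$alpha <= 1))
  gm <- group_mean_modulators(lapply(cohort, `[[`, "trajectory"))
  assoc_orth <- orthogonalize(gm$mean_assoc, gm$mean_pe)
  d <- build_design(cohort[[1]]$schedules$day2,
                    list(pe = list(on = "us_omission", values = gm$mean_pe),
                         assoc = list(on = "us_omission", values = assoc_orth)),
                    n_scans = 460)
  expect_equal(ncol(d$X), 6)
  paths <- fit_paths(vapply(cohort, `[[`, numeric(1), "treatment"),
                     vapply(cohort, `[[`, numeric(1), "vmpfc"),
                     vapply(cohort, `[[`, numeric(1), "scr_diff_retrieval"))
  res <- acme_quasi_bayesian(paths, seed = 4)
  expect_s3_class(res, "mediation_result")
  expect_true(is.finite(res$acme))
})

test_that("the generated indirect effect is positive on average", {
  # a < 0 and b < 0 make the true ACME positive (a*b = 0.0436); average
  # the point estimate over several regenerated scalar cohorts
  acmes <- vapply(1:10, function(i) {
    d <- generate_mediation_data(seed = 100 + i)
    paths <- fit_paths(d$treatment, d$vmpfc, d$scr_diff)
    acme_quasi_bayesian(paths, seed = i)$acme
  }, numeric(1))
  expect_gt(mean(acmes), 0)
})

test_that("cohort files round-trip through the CLI writer", {
  out_dir <- withr::local_tempdir()
  cohort <- extinctrl_cli(c("make-cohort", "--out-dir", out_dir,
                            "--n-placebo", "3", "--n-ldopa", "3",
                            "--seed", "11"))
  expect_length(cohort, 6)
  ratings <- read_ratings_csv(file.path(out_dir, "ratings.csv"))
  expect_equal(nrow(ratings), 6 * 24)
  expect_equal(ratings$rating[1:24], cohort[[1]]$ratings)
  scr <- read_scr_csv(file.path(out_dir, "scr.csv"))
  expect_equal(scr$value[scr$subject == "sub-002" & scr$cs_type == "CS_PLUS"],
               cohort[[2]]$scr$csplus, tolerance = 1e-6)
  med <- read_mediation_csv(file.path(out_dir, "mediation.csv"))
  expect_equal(med$vmpfc, vapply(cohort, `[[`, numeric(1), "vmpfc"),
               tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(out_dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$med_a, -2.2957)
  sched <- read_events_tsv(file.path(out_dir, "events_day2_sub-001.tsv"))
  expect_equal(sched$events, cohort[[1]]$schedules$day2$events,
               tolerance = 1e-12)
})

test_that("CLI simulate-schedule and mediate subcommands work", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  suppressMessages(extinctrl_cli(c("simulate-schedule", "--day", "2",
                                   "--seed", "5", "--out", tsv)))
  sched <- read_events_tsv(tsv)
  expect_equal(nrow(sched$events), 48)
  med_csv <- withr::local_tempfile(fileext = ".csv")
  d <- generate_mediation_data(seed = 3)
  write_mediation_csv(data.frame(subject = seq_len(nrow(d)),
                                 group = ifelse(d$treatment == 1, "ldopa",
                                                "placebo"),
                                 vmpfc = d$vmpfc, scr_diff = d$scr_diff),
                      med_csv)
  out_json <- withr::local_tempfile(fileext = ".json")
  res <- suppressMessages(
    extinctrl_cli(c("mediate", "--in", med_csv, "--method", "qb",
                    "--draws", "500", "--seed", "9", "--out", out_json)))
  expect_s3_class(res, "mediation_result")
  back <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  expect_equal(back$acme, res$acme, tolerance = 1e-12)
})
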