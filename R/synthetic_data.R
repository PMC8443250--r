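# Ground-truth cohort generation: hybrid-model agents on the three-day
# schedule, a between-group vmPFC shift with an indirect-only effect on
# differential SCR, and synthetic BOLD from a stick-function design.

#' Cohort generator configuration
#'
#' Defaults emulate the reference design: 22 placebo and 24 L-DOPA
#' subjects; both groups share the same learning-parameter distributions
#' (the behavioural null); the mediation chain uses the reported path
#' magnitudes a = -2.2957 (treatment on vmPFC), b = -0.01898 (vmPFC on
#' differential SCR) with no direct effect, and noise SDs 1.3 (mediator)
#' and 0.05 (outcome). Learning parameters are drawn on transformed
#' scales: logit-normal for alpha and omega, log-normal for beta.
#'
#' @param n_placebo,n_ldopa Group sizes.
#' @param alpha_mean,alpha_sd Logit-scale mean/SD for the learning rate.
#' @param omega_mean,omega_sd Logit-scale mean/SD for the associability
#'   weight.
#' @param beta_meanlog,beta_sdlog Log-scale mean/SD for the softmax
#'   scale.
#' @param med_a,med_b,med_direct Mediation path coefficients (treatment
#'   coded placebo = 0, L-DOPA = 1).
#' @param vmpfc_intercept,scr_diff_intercept Intercepts of the mediator
#'   and outcome models.
#' @param vmpfc_noise_sd,scr_diff_noise_sd Residual SDs of mediator and
#'   outcome.
#' @param scr_noise_sd Trial-wise SCR noise SD (before range correction).
#' @param missing_rate Per-trial probability of a missing rating.
#' @param bold_noise_sd,n_scans,TR_s BOLD harness settings.
#' @param master_seed Master seed; everything downstream derives from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_placebo = 22, n_ldopa = 24,
                          alpha_mean = stats::qlogis(0.35), alpha_sd = 0.8,
                          omega_mean = stats::qlogis(0.4), omega_sd = 0.8,
                          beta_meanlog = log(1.5), beta_sdlog = 0.4,
                          med_a = -2.2957, med_b = -0.01898, med_direct = 0,
                          vmpfc_intercept = 0, scr_diff_intercept = 0.1,
                          vmpfc_noise_sd = 1.3, scr_diff_noise_sd = 0.05,
                          scr_noise_sd = 0.1, missing_rate = 0,
                          bold_noise_sd = 1, n_scans = 460,
                          TR_s = DEFAULT_TR_S, master_seed = 1L) {
  cfg <- as.list(environment())
  bad <- character(0)
  if (n_placebo < 2 || n_ldopa < 2) bad <- c(bad, "group sizes must be >= 2")
  for (nm in c("alpha_sd", "omega_sd", "beta_sdlog", "vmpfc_noise_sd",
               "scr_diff_noise_sd", "scr_noise_sd", "bold_noise_sd")) {
    if (cfg[[nm]] < 0) bad <- c(bad, paste(nm, "must be >= 0"))
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    bad <- c(bad, "missing_rate must be in [0, 1)")
  }
  if (n_scans < 1 || TR_s <= 0) bad <- c(bad, "invalid scan settings")
  if (length(bad)) stop("invalid config: ", paste(bad, collapse = "; "))
  structure(cfg, class = "cohort_config")
}

draw_params <- function(cfg) {
  hybrid_params(
    alpha = stats::plogis(stats::rnorm(1, cfg$alpha_mean, cfg$alpha_sd)),
    omega = stats::plogis(stats::rnorm(1, cfg$omega_mean, cfg$omega_sd)),
    beta = exp(stats::rnorm(1, cfg$beta_meanlog, cfg$beta_sdlog))
  )
}

#' Generate one model agent on a schedule
#'
#' Simulates latent trajectories over the schedule's CS+ outcome stream
#' and draws binary US-expectancy ratings through the softmax observation
#' model.
#'
#' @param params True [hybrid_params()].
#' @param schedule A [session_schedule()].
#' @param seed Integer seed for the rating draws.
#' @param init An [initial_state()].
#' @return List with `ratings` (0/1 vector) and `trajectory`
#'   (`latent_trajectory`).
#' @export
generate_agent <- function(params, schedule, seed, init = initial_state()) {
  outcomes <- outcomes_for_cs(schedule, "CS_PLUS")
  traj <- simulate_latents(params, outcomes, init)
  ratings <- simulate_ratings(traj, params$beta, seed)
  list(ratings = ratings, trajectory = traj, outcomes = outcomes)
}

# corrected-scale SCR trial series: baseline + slope * v_t + noise,
# clipped at zero, then log-range-corrected within the series pair
simulate_scr_pair <- function(v_plus, v_minus, noise_sd,
                              s0 = 0.1, s1 = 0.6) {
  n <- length(v_plus)
  raw_p <- pmax(s0 + s1 * v_plus + stats::rnorm(n, 0, noise_sd), 0)
  raw_m <- pmax(s0 + s1 * v_minus + stats::rnorm(n, 0, noise_sd), 0)
  grouping <- rep(1L, 2 * n)
  corr <- log_range_correct(c(raw_p, raw_m), grouping)
  list(csplus = corr[1:n], csminus = corr[(n + 1):(2 * n)])
}

#' Generate a ground-truth cohort
#'
#' Per subject: draws true learning parameters (identical distributions in
#' both groups by default), builds the three day schedules, simulates
#' latents and binary ratings for the day-2 CS+ stream (and a CS- stream
#' started at v0 = 0), generates corrected SCR trial series as a monotone
#' function of value plus noise, and draws the mediation chain
#' vmPFC = intercept + a * group + noise and
#' scr_diff = intercept + direct * group + b * vmPFC + noise.
#' Fully reproducible under `master_seed`.
#'
#' @param config A [cohort_config()].
#' @return List of subject datasets; each element carries `subject`,
#'   `group` (`"placebo"`/`"ldopa"`), `treatment` (0/1), `schedules`,
#'   `true_params`, `outcomes`, `ratings` (day-2 CS+), `ratings_minus`,
#'   `trajectory`, `trajectory_minus`, `scr` (day-2 corrected series),
#'   `fear` (start/end VAS per CS), `vmpfc`, `scr_diff_retrieval`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_placebo + config$n_ldopa
  groups <- rep(c("placebo", "ldopa"), c(config$n_placebo, config$n_ldopa))
  withr::with_seed(as.integer(config$master_seed), {
    lapply(seq_len(n), function(i) {
      grp <- groups[i]
      tr <- as.numeric(grp == "ldopa")
      sub_seed <- as.integer(config$master_seed) + i
      schedules <- list(day1 = build_acquisition(sub_seed),
                        day2 = build_extinction(sub_seed),
                        day3 = build_day3(sub_seed))
      params <- draw_params(config)
      agent <- generate_agent(params, schedules$day2, seed = sub_seed)
      out_minus <- outcomes_for_cs(schedules$day2, "CS_MINUS")
      traj_minus <- simulate_latents(params, out_minus,
                                     initial_state(v0 = 0, eta0 = 1))
      ratings_minus <- simulate_ratings(traj_minus, params$beta,
                                        seed = sub_seed + 1000003L)
      ratings <- agent$ratings
      if (config$missing_rate > 0) {
        miss <- stats::runif(length(ratings)) < config$missing_rate
        ratings[miss] <- NA_integer_
      }
      scr <- simulate_scr_pair(agent$trajectory$v, traj_minus$v,
                               config$scr_noise_sd)
      fear <- list(
        csplus = round(pmin(pmax(
          100 * agent$trajectory$v[c(1, length(agent$trajectory$v))] +
            stats::rnorm(2, 0, 5), 0), 100)),
        csminus = round(pmin(pmax(
          100 * traj_minus$v[c(1, length(traj_minus$v))] +
            stats::rnorm(2, 0, 5), 0), 100)))
      vmpfc <- config$vmpfc_intercept + config$med_a * tr +
        stats::rnorm(1, 0, config$vmpfc_noise_sd)
      scr_diff <- config$scr_diff_intercept + config$med_direct * tr +
        config$med_b * vmpfc + stats::rnorm(1, 0, config$scr_diff_noise_sd)
      list(subject = sprintf("sub-%03d", i), group = grp, treatment = tr,
           schedules = schedules, true_params = params,
           outcomes = agent$outcomes, ratings = ratings,
           ratings_minus = ratings_minus, trajectory = agent$trajectory,
           trajectory_minus = traj_minus, scr = scr, fear = fear,
           vmpfc = vmpfc, scr_diff_retrieval = scr_diff)
    })
  })
}

#' Generate subject-level mediation data only
#'
#' Lightweight generator for the scalar mediation chain (no schedules or
#' trial series), used for calibration and recovery studies.
#'
#' @param n_placebo,n_ldopa Group sizes.
#' @param a,b,direct Path coefficients.
#' @param vmpfc_intercept,scr_diff_intercept Model intercepts.
#' @param vmpfc_noise_sd,scr_diff_noise_sd Residual SDs.
#' @param seed Integer seed.
#' @return Data frame with `treatment`, `vmpfc`, `scr_diff`.
#' @export
generate_mediation_data <- function(n_placebo = 22, n_ldopa = 24,
                                    a = -2.2957, b = -0.01898, direct = 0,
                                    vmpfc_intercept = 0,
                                    scr_diff_intercept = 0.1,
                                    vmpfc_noise_sd = 1.3,
                                    scr_diff_noise_sd = 0.05, seed = 1L) {
  treatment <- rep(c(0, 1), c(n_placebo, n_ldopa))
  withr::with_seed(as.integer(seed), {
    vmpfc <- vmpfc_intercept + a * treatment +
      stats::rnorm(length(treatment), 0, vmpfc_noise_sd)
    scr_diff <- scr_diff_intercept + direct * treatment + b * vmpfc +
      stats::rnorm(length(treatment), 0, scr_diff_noise_sd)
    data.frame(treatment = treatment, vmpfc = vmpfc, scr_diff = scr_diff)
  })
}

#' Generate synthetic BOLD from a design matrix
#'
#' Y = X beta + Gaussian white noise, the standard GLM test harness.
#'
#' @param design A [build_design()] result.
#' @param betas Coefficient vector, one per design column.
#' @param noise_sd White-noise SD.
#' @param seed Integer seed.
#' @param n_voxels Number of independent time series to draw.
#' @return Numeric matrix (scans x voxels).
#' @export
generate_bold <- function(design, betas, noise_sd = 1, seed = 1L,
                          n_voxels = 1) {
  stopifnot(inherits(design, "design_matrix"))
  if (length(betas) != ncol(design$X)) {
    stop("betas must have one entry per design column (",
         ncol(design$X), ")")
  }
  mu <- as.numeric(design$X %*% betas)
  withr::with_seed(as.integer(seed), {
    matrix(mu, nrow = length(mu), ncol = n_voxels) +
      matrix(stats::rnorm(length(mu) * n_voxels, 0, noise_sd),
             nrow = length(mu))
  })
}
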