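# Trial-wise parametric regressors, canonical HRF convolution on the scan
# grid, and a desk-scale first-level GLM.

DEFAULT_TR_S <- 1.493

#' Group-mean trial-wise modulators
#'
#' Element-wise mean across subjects of the fitted prediction-error and
#' associability trajectories, trial-aligned. These sample-average terms
#' are the standard choice for modulating the US-omission regressor when
#' individual fits are noisy.
#'
#' @param trajectories List of [simulate_latents()] results of equal
#'   length.
#' @return List with `mean_pe` and `mean_assoc` vectors.
#' @export
group_mean_modulators <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  lens <- vapply(trajectories, function(tr) length(tr$pe), integer(1))
  if (length(unique(lens)) != 1) stop("trajectories differ in length")
  pe <- rowMeans(vapply(trajectories, `[[`, numeric(lens[1]), "pe"))
  eta <- rowMeans(vapply(trajectories, `[[`, numeric(lens[1]), "eta"))
  list(mean_pe = pe, mean_assoc = eta)
}

#' Orthogonalise one modulator with respect to another
#'
#' Mean-centres both vectors and removes from `x` its projection onto
#' `wrt`, returning a residual orthogonal to the centred `wrt`. Applied to
#' trial-wise modulators before convolution (serial orthogonalisation
#' convention).
#'
#' @param x Numeric vector to residualise.
#' @param wrt Numeric vector to orthogonalise against; must not be
#'   constant.
#' @return Residual vector, same length as `x`.
#' @export
orthogonalize <- function(x, wrt) {
  if (length(x) != length(wrt)) stop("x and wrt must have equal length")
  w <- wrt - mean(wrt)
  if (all(abs(w) < 1e-12)) stop("wrt is constant after centring")
  xc <- x - mean(x)
  xc - as.numeric(crossprod(xc, w) / crossprod(w)) * w
}

#' Canonical double-gamma haemodynamic response function
#'
#' The standard two-gamma HRF (response peak 6 s, undershoot peak 16 s,
#' unit dispersions, undershoot ratio 1/6) sampled on a grid and
#' peak-normalised to a maximum of 1.
#'
#' @param dt_s Sampling interval in seconds (a TR, or a finer microtime
#'   step).
#' @param duration_s Kernel length in seconds (default 32).
#' @return Numeric vector of kernel samples starting at t = 0.
#' @export
canonical_hrf <- function(dt_s, duration_s = 32) {
  stopifnot(dt_s > 0)
  t <- seq(0, duration_s, by = dt_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# microtime resolution for stick placement before downsampling to TRs
MICROTIME_DT_S <- 0.1

# place weighted sticks on a microtime grid, convolve with the HRF, and
# sample at scan onsets
convolve_sticks <- function(onsets_s, weights, n_scans, TR_s) {
  t_end <- n_scans * TR_s + 32
  n_micro <- ceiling(t_end / MICROTIME_DT_S) + 1
  u <- numeric(n_micro)
  idx <- round(onsets_s / MICROTIME_DT_S) + 1
  if (any(idx < 1 | idx > n_micro)) stop("event onset outside the scan window")
  for (k in seq_along(idx)) u[idx[k]] <- u[idx[k]] + weights[k]
  h <- canonical_hrf(MICROTIME_DT_S)
  conv <- stats::convolve(u, rev(h), type = "open")[seq_len(n_micro)]
  scan_idx <- round(((seq_len(n_scans) - 1) * TR_s) / MICROTIME_DT_S) + 1
  conv[scan_idx]
}

#' Build a first-level design matrix from a schedule
#'
#' Constructs HRF-convolved stick regressors on the scan grid: CS+ onsets,
#' CS- onsets, US-omission onsets (CS+ onset + 5 s on unreinforced CS+
#' trials), one column per parametric modulator (mean-centred, placed on
#' its parent events, convolved), and an intercept. Events are modelled
#' as zero-duration sticks; CS duration is not modelled as a boxcar.
#'
#' @param schedule A [session_schedule()].
#' @param modulators Named list; each element is a list with `on` (one of
#'   `"csplus"`, `"csminus"`, `"us_omission"`) and `values` (one per
#'   parent event, trial order).
#' @param n_scans Number of volumes.
#' @param TR_s Repetition time in seconds (default 1.493).
#' @param include_habituation Model habituation trials too? Default
#'   `FALSE`.
#' @return An object of class `design_matrix`: list with `times_s`, `X`
#'   (scans x regressors matrix), `names`, `TR_s`.
#' @export
build_design <- function(schedule, modulators = list(), n_scans,
                         TR_s = DEFAULT_TR_S, include_habituation = FALSE) {
  stopifnot(inherits(schedule, "session_schedule"), n_scans > 0, TR_s > 0)
  ev <- schedule$events
  if (!include_habituation) ev <- ev[ev$phase != "habituation", , drop = FALSE]
  streams <- list(
    csplus = ev$onset_s[ev$cs_type == "CS_PLUS"],
    csminus = ev$onset_s[ev$cs_type == "CS_MINUS"],
    us_omission = ev$onset_s[ev$cs_type == "CS_PLUS" & !ev$reinforced] + US_OFFSET_S
  )
  cols <- list(intercept = rep(1, n_scans))
  for (nm in names(streams)) {
    if (length(streams[[nm]])) {
      cols[[nm]] <- convolve_sticks(streams[[nm]], rep(1, length(streams[[nm]])),
                                    n_scans, TR_s)
    }
  }
  for (nm in names(modulators)) {
    mod <- modulators[[nm]]
    on <- match.arg(mod$on, names(streams))
    onsets <- streams[[on]]
    if (length(mod$values) != length(onsets)) {
      stop("modulator '", nm, "' has ", length(mod$values),
           " values but its parent stream '", on, "' has ", length(onsets),
           " events")
    }
    cols[[nm]] <- convolve_sticks(onsets, mod$values - mean(mod$values),
                                  n_scans, TR_s)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(times_s = (seq_len(n_scans) - 1) * TR_s, X = X,
                 names = colnames(X), TR_s = TR_s),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), " scans (TR ", x$TR_s, " s) x ",
      ncol(x$X), " regressors: ", paste(x$names, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Fit a first-level GLM by ordinary least squares
#'
#' @param Y Numeric matrix (scans x voxels) or vector of one time series.
#' @param design A [build_design()] result (or a plain numeric matrix).
#' @return Object of class `first_level_fit`: `betas` (regressors x
#'   voxels), `sigma2` residual variance per voxel, `df`, plus the design
#'   pieces needed for contrasts.
#' @export
fit_first_level <- function(Y, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("Y rows must equal the number of scans")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qr_x, Y)
  resid <- Y - X %*% betas
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  structure(list(betas = betas, sigma2 = sigma2, df = df,
                 xtx_inv = chol2inv(chol(crossprod(X))),
                 names = colnames(X)),
            class = "first_level_fit")
}

#' Contrast estimate and t-statistic from a first-level fit
#'
#' @param fit A [fit_first_level()] result.
#' @param contrast Numeric contrast vector, one weight per regressor.
#' @return Data frame with `estimate`, `se`, `t`, one row per voxel.
#' @export
contrast_t <- function(fit, contrast) {
  stopifnot(inherits(fit, "first_level_fit"),
            length(contrast) == nrow(fit$betas))
  est <- as.numeric(crossprod(contrast, fit$betas))
  var_c <- as.numeric(crossprod(contrast, fit$xtx_inv %*% contrast))
  se <- sqrt(var_c * fit$sigma2)
  data.frame(estimate = est, se = se, t = ifelse(se > 0, est / se, NA_real_))
}

#' Write a design matrix to TSV with a JSON sidecar
#'
#' The TSV holds one column per regressor; the sidecar records the
#' regressor names and TR so the design round-trips bit-exactly through
#' [read_design()].
#'
#' @param design A [build_design()] result.
#' @param path Output TSV path; the sidecar is written at `path` with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  df <- as.data.frame(design$X)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(list(names = design$names, TR_s = design$TR_s),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a design matrix written by [write_design()]
#'
#' @param path TSV path (sidecar expected alongside).
#' @return A `design_matrix` object.
#' @export
read_design <- function(path) {
  sidecar <- sub("\\.[^.]*$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  X <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  colnames(X) <- meta$names
  structure(list(times_s = (seq_len(nrow(X)) - 1) * meta$TR_s, X = X,
                 names = meta$names, TR_s = meta$TR_s),
            class = "design_matrix")
}
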