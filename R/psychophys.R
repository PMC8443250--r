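# Post-processing of trial-wise skin-conductance amplitudes and fear
# ratings: log and range correction, block averaging, differential and
# reinstatement contrasts, and the associated significance tests.

#' Logarithmise and range-correct SCR amplitudes
#'
#' Applies `ln(1 + amplitude)` (so zero-scored non-reactions stay defined)
#' and divides by the per-group maximum of the transformed values. In the
#' standard workflow the grouping is subject-by-day, with the maximum
#' taken across both CS types, so within each subject-day the corrected
#' maximum is exactly 1. All-zero groups pass through as zeros.
#'
#' @param amplitudes Non-negative amplitudes in microsiemens (`NA` for
#'   missing trials).
#' @param grouping Factor-like vector (e.g. `interaction(subject, day)`)
#'   defining the range-correction groups; default one group.
#' @param log_fun Transform applied before range correction; default
#'   `log1p`, configurable (e.g. `identity`).
#' @return Corrected values in [0, 1], same length and order as the
#'   input.
#' @export
log_range_correct <- function(amplitudes,
                              grouping = rep(1L, length(amplitudes)),
                              log_fun = log1p) {
  if (any(amplitudes < 0, na.rm = TRUE)) stop("amplitudes must be >= 0")
  stopifnot(length(grouping) == length(amplitudes))
  x <- log_fun(amplitudes)
  out <- x
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    m <- suppressWarnings(max(x[idx], na.rm = TRUE))
    if (is.finite(m) && m > 0) out[idx] <- x[idx] / m
  }
  out
}

#' Range-correct VAS fear ratings
#'
#' Divides ratings (0-100 visual analogue scale) by the per-group maximum
#' (per subject per day in the standard workflow). All-zero groups pass
#' through unchanged.
#'
#' @param ratings Values in [0, 100] (`NA` allowed).
#' @param grouping Range-correction groups as in [log_range_correct()].
#' @return Corrected values in [0, 1].
#' @export
range_correct_rating <- function(ratings, grouping = rep(1L, length(ratings))) {
  if (any(ratings < 0 | ratings > 100, na.rm = TRUE)) {
    stop("ratings must lie in [0, 100]")
  }
  log_range_correct(ratings, grouping, log_fun = identity)
}

#' Average a trial series into blocks
#'
#' Means over consecutive blocks of `block_size` trials (default 8, so 24
#' extinction trials give 3 blocks), ignoring missing values; a block
#' with all values missing yields `NA`. A trailing partial block is kept
#' and flagged with a warning.
#'
#' @param values Trial values (`NA` for missing).
#' @param block_size Trials per block; must be positive.
#' @return Numeric vector of block means.
#' @export
block_average <- function(values, block_size = 8) {
  if (block_size <= 0) stop("block_size must be positive")
  n <- length(values)
  if (n %% block_size != 0) {
    warning("length ", n, " is not a multiple of block_size ", block_size,
            "; trailing partial block retained")
  }
  blocks <- ceiling(seq_len(n) / block_size)
  out <- tapply(values, blocks, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  as.numeric(out)
}

#' Differential response (CS+ minus CS-)
#'
#' @param csplus,csminus Aligned value vectors of equal length.
#' @return Element-wise difference.
#' @export
differential <- function(csplus, csminus) {
  if (length(csplus) != length(csminus)) {
    stop("csplus and csminus must have equal length")
  }
  csplus - csminus
}

#' Before/after reinstatement contrast
#'
#' Means of the last `k` pre-reinstatement trials and the first `k`
#' post-reinstatement trials per CS, plus the differential (CS+ - CS-)
#' of those means. The transient-probe convention is `k = 3`; `k = 8`
#' compares whole blocks.
#'
#' @param pre_plus,post_plus CS+ values before/after the reinstatement
#'   USs (retrieval block; reinstatement-test block).
#' @param pre_minus,post_minus Same for the CS-.
#' @param k Trials averaged on each side of the boundary.
#' @return List with `pre_mean` and `post_mean` (named per CS),
#'   `pre_diff`, `post_diff`.
#' @export
reinstatement_contrast <- function(pre_plus, post_plus, pre_minus, post_minus,
                                   k = 3) {
  if (k < 1) stop("k must be >= 1")
  lens <- c(length(pre_plus), length(post_plus), length(pre_minus),
            length(post_minus))
  if (k > min(lens)) {
    stop("k = ", k, " exceeds the ", min(lens), " trials available")
  }
  last_k <- function(v) v[(length(v) - k + 1):length(v)]
  pre <- c(csplus = mean(last_k(pre_plus), na.rm = TRUE),
           csminus = mean(last_k(pre_minus), na.rm = TRUE))
  post <- c(csplus = mean(post_plus[1:k], na.rm = TRUE),
            csminus = mean(post_minus[1:k], na.rm = TRUE))
  list(pre_mean = pre, post_mean = post,
       pre_diff = unname(pre["csplus"] - pre["csminus"]),
       post_diff = unname(post["csplus"] - post["csminus"]))
}

#' Independent-groups t-test with effect size
#'
#' Pooled-variance (default) or Welch independent t-test with Cohen's d
#' (pooled SD). One-sided alternatives follow R's convention:
#' `"less"` tests mean(a) < mean(b).
#'
#' @param a,b Per-subject scalars, one vector per group (>= 2 each).
#' @param sided `"two"`, `"less"` or `"greater"`.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return List with `t`, `df`, `p`, `d`, `mean_diff`.
#' @export
group_test <- function(a, b, sided = c("two", "less", "greater"),
                       var_equal = TRUE) {
  sided <- match.arg(sided)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 subjects per group")
  alt <- switch(sided, two = "two.sided", less = "less", greater = "greater")
  tt <- stats::t.test(a, b, alternative = alt, var.equal = var_equal)
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  d <- if (sp > 0) (mean(a) - mean(b)) / sp else NA_real_
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = d, mean_diff = mean(a) - mean(b))
}

#' Holm family-wise correction helper
#'
#' @param p Vector of p-values forming one family.
#' @return Holm-adjusted p-values.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Two-sided Pearson correlation with Fisher-z interval
#'
#' @param x,y Finite numeric vectors, n >= 3, non-constant.
#' @param level Confidence level for the Fisher-z interval.
#' @return List with `r`, `t`, `df`, `p` (two-sided), `ci` (length 2).
#' @export
pearson_correlation <- function(x, y, level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  z <- atanh(r)
  zse <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(1 - (1 - level) / 2) * zse)
  list(r = r, t = tstat, df = n - 2, p = p, ci = ci)
}

#' Day-wise missing-data exclusion filter
#'
#' Flags subject-days whose fraction of missing trials exceeds a
#' threshold (default one third), the usual day-wise exclusion rule.
#'
#' @param values Trial values with `NA` for missing.
#' @param grouping Subject-day grouping vector.
#' @param max_missing_frac Exclusion threshold (default 1/3).
#' @return Logical vector, `TRUE` where the subject-day is retained.
#' @export
exclusion_filter <- function(values, grouping, max_missing_frac = 1 / 3) {
  keep_group <- tapply(values, grouping, function(v) mean(is.na(v)) <= max_missing_frac)
  unname(keep_group[as.character(grouping)])
}
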