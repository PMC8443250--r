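# Plain-text readers/writers for the tabular interchange formats:
# trial-wise ratings, latent trajectories, SCR series, mediation input.

#' Write trial-wise binary ratings to CSV
#'
#' Columns `subject`, `day`, `trial_index`, `cs_type`, `rating`
#' (0/1/`n/a`).
#'
#' @param df Data frame with those columns (`rating` may contain `NA`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(df, path) {
  needed <- c("subject", "day", "trial_index", "cs_type", "rating")
  stopifnot(all(needed %in% names(df)))
  out <- df[needed]
  out$rating <- ifelse(is.na(out$rating), "n/a", as.character(out$rating))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ratings CSV written by [write_ratings_csv()]
#'
#' @param path Input path.
#' @return Data frame with `rating` as integer (`NA` for `n/a`).
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "n/a", stringsAsFactors = FALSE)
  df$rating <- as.integer(df$rating)
  df
}

#' Export a latent trajectory to CSV
#'
#' Columns `trial_index`, `v`, `eta`, `pe`.
#'
#' @param trajectory A [simulate_latents()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "latent_trajectory"))
  utils::write.csv(
    data.frame(trial_index = seq_along(trajectory$v), v = trajectory$v,
               eta = trajectory$eta, pe = trajectory$pe),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write trial-wise SCR or fear-rating values to CSV
#'
#' Columns `subject`, `group`, `day`, `trial_index`, `cs_type`, `value`.
#'
#' @param df Data frame with those columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scr_csv <- function(df, path) {
  needed <- c("subject", "group", "day", "trial_index", "cs_type", "value")
  stopifnot(all(needed %in% names(df)))
  out <- df[needed]
  out$value <- ifelse(is.na(out$value), "n/a", format(out$value, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial-value CSV written by [write_scr_csv()]
#'
#' @param path Input path.
#' @return Data frame with numeric `value`.
#' @export
read_scr_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "n/a", stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  df
}

#' Write subject-level mediation input to CSV
#'
#' Columns `subject`, `group`, `vmpfc`, `scr_diff`.
#'
#' @param df Data frame with those columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mediation_csv <- function(df, path) {
  needed <- c("subject", "group", "vmpfc", "scr_diff")
  stopifnot(all(needed %in% names(df)))
  utils::write.csv(df[needed], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mediation CSV written by [write_mediation_csv()]
#'
#' @param path Input path.
#' @return Data frame with a 0/1 `treatment` column added (placebo = 0,
#'   ldopa = 1).
#' @export
read_mediation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$treatment <- as.numeric(df$group == "ldopa")
  df
}
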