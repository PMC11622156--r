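#' Censor sensitivities at a detection-floor threshold
#'
#' Perimetric sensitivities below roughly 20 dB are dominated by retest
#' noise. Censoring replaces every value strictly below the threshold with
#' the threshold itself; a value equal to the threshold is left alone and
#' not flagged.
#'
#' @param sensitivity raw sensitivity (dB); vectorized.
#' @param threshold censoring threshold (dB). `-Inf` disables censoring.
#' @return A list with `value` (`pmax(sensitivity, threshold)`) and
#'   `was_censored` (logical, `sensitivity < threshold`).
#' @examples
#' censor_value(15, 21)  # value 21, censored
#' censor_value(21, 21)  # value 21, not censored (strict "below")
#' @export
censor_value <- function(sensitivity, threshold) {
  stopifnot(all(sensitivity >= 0))
  list(value = pmax(sensitivity, threshold),
       was_censored = sensitivity < threshold)
}

#' A censoring-threshold configuration
#'
#' @param threshold_III,threshold_V censoring thresholds in dB for stimulus
#'   III and V; each in \[0, 40\].
#' @return An object of class `censor_config`.
#' @export
censor_config <- function(threshold_III, threshold_V) {
  stopifnot(is.numeric(threshold_III), is.numeric(threshold_V),
            threshold_III >= 0, threshold_III <= 40,
            threshold_V >= 0, threshold_V <= 40)
  structure(list(threshold_III = threshold_III, threshold_V = threshold_V),
            class = "censor_config")
}

#' @export
print.censor_config <- function(x, ...) {
  cat(sprintf("<censor_config> t_III = %g dB, t_V = %g dB\n",
              x$threshold_III, x$threshold_V))
  invisible(x)
}

#' Build pointwise TD pairs from field pairs
#'
#' The atomic unit of every statistic in the package: one row per
#' non-blind-spot location per field pair (52 rows per pair), carrying the
#' censored, age-corrected total deviations of both stimuli and censorship
#' flags. Flags refer to the *raw* sensitivities (strictly below the
#' threshold); `pair_censored` is TRUE when at least one of the two is
#' censored.
#'
#' @param pairs a list of [vf_pair()] objects.
#' @param cfg a [censor_config()].
#' @param norm_III,norm_V normative tables for the two stimuli.
#' @return A data frame of class `vf_point_pairs` with columns
#'   `subject_id`, `session_id`, `cohort`, `eye`, `x_deg`, `y_deg`,
#'   `td_iii_db`, `td_v_db`, `censored_iii`, `censored_v`, `pair_censored`.
#' @export
make_point_pairs <- function(pairs, cfg, norm_III, norm_V) {
  if (inherits(pairs, "vf_pair")) pairs <- list(pairs)
  stopifnot(inherits(cfg, "censor_config") || is.list(cfg))
  m <- .pair_matrices(pairs, norm_III, norm_V)
  grids <- list(OD = vf_grid_seeing("OD"), OS = vf_grid_seeing("OS"))
  meta <- function(f) vapply(pairs, function(p) p$field_III[[f]],
                             character(1))
  each <- function(v) rep(v, each = 52L)
  eyes <- meta("eye")
  pp <- data.frame(
    subject_id = each(meta("subject_id")),
    session_id = each(meta("session_id")),
    cohort = each(meta("cohort")),
    eye = each(eyes),
    x_deg = unlist(lapply(eyes, function(e) grids[[e]]$x_deg)),
    y_deg = unlist(lapply(eyes, function(e) grids[[e]]$y_deg)),
    td_iii_db = pmax(m$raw3, cfg$threshold_III) - m$exp3,
    td_v_db = pmax(m$raw5, cfg$threshold_V) - m$exp5,
    censored_iii = m$raw3 < cfg$threshold_III,
    censored_v = m$raw5 < cfg$threshold_V)
  pp$pair_censored <- pp$censored_iii | pp$censored_v
  class(pp) <- c("vf_point_pairs", "data.frame")
  attr(pp, "censor_config") <- cfg
  pp
}

#' Write a TD point-pair table to CSV
#'
#' @param pp a `vf_point_pairs` data frame from [make_point_pairs()].
#' @param path output CSV path.
#' @export
write_point_pairs <- function(pp, path) {
  utils::write.csv(as.data.frame(pp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Flat numeric snapshot of a list of vf_pairs, used by the vectorized grid
# search: raw sensitivities and normative expectations for both stimuli,
# location-parallel across all pairs.
.pair_matrices <- function(pairs, norm_III, norm_V) {
  raw3 <- unlist(lapply(pairs, function(p) unname(p$field_III$sens)))
  raw5 <- unlist(lapply(pairs, function(p) unname(p$field_V$sens)))
  exp3 <- unlist(lapply(pairs, function(p)
    unname(.expected_for_field(p$field_III, norm_III))))
  exp5 <- unlist(lapply(pairs, function(p)
    unname(.expected_for_field(p$field_V, norm_V))))
  list(raw3 = raw3, raw5 = raw5, exp3 = exp3, exp5 = exp5)
}
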