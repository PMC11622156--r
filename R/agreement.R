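#' Summarize pointwise TD differences by censorship class
#'
#' For the difference `d = TD_V - TD_III` over all point pairs: mean and
#' sample SD overall and within the censored (at least one stimulus
#' censored) and uncensored subgroups, plus a two-sided one-sample t-test
#' of the mean difference against zero (`df = n_total - 1`). With zero
#' variance the t statistic is undefined and returned as `NA`.
#'
#' @param pp a `vf_point_pairs` data frame ([make_point_pairs()]).
#' @return A list with counts (`n_total`, `n_censored`, `n_uncensored`,
#'   `prop_censored`), subgroup `mean`/`sd` entries, and `t_statistic`,
#'   `df`, `p_value`.
#' @export
summarize_diffs <- function(pp) {
  if (nrow(pp) < 2L) stop("need at least 2 point pairs", call. = FALSE)
  d <- pp$td_v_db - pp$td_iii_db
  cen <- pp$pair_censored
  msd <- function(v) {
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) >= 2L) stats::sd(v) else NA_real_)
  }
  all_ <- msd(d); c_ <- msd(d[cen]); u_ <- msd(d[!cen])
  if (all_[["sd"]] > 0) {
    tt <- stats::t.test(d, mu = 0)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  } else {
    t_stat <- NA_real_; df <- length(d) - 1L; p <- NA_real_
  }
  list(n_total = length(d), n_censored = sum(cen),
       n_uncensored = sum(!cen), prop_censored = mean(cen),
       mean_diff_all = all_[["mean"]], sd_diff_all = all_[["sd"]],
       mean_diff_censored = c_[["mean"]], sd_diff_censored = c_[["sd"]],
       mean_diff_uncensored = u_[["mean"]], sd_diff_uncensored = u_[["sd"]],
       t_statistic = t_stat, df = df, p_value = p)
}

#' Ordinary least-squares fit of TD_V on TD_III
#'
#' The agreement scatter fixes the axis roles: x is the size III total
#' deviation, y is the size V total deviation, and the fit is compared
#' against the line of unity y = x. `r_squared` is `1 - SSE/SST` from the
#' same fit (identical to the squared Pearson correlation for simple OLS).
#'
#' @param pp a `vf_point_pairs` data frame with at least 3 rows.
#' @return A list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_line <- function(pp) {
  if (nrow(pp) < 3L) stop("need at least 3 point pairs", call. = FALSE)
  x <- pp$td_iii_db; y <- pp$td_v_db
  if (stats::var(x) == 0)
    stop("all TD_III values identical: slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (sst == 0) 1 else 1 - sse / sst,
       n = length(x))
}

#' Bland-Altman analysis of the two stimuli
#'
#' Per point pair: mean `m = (TD_III + TD_V)/2` and difference
#' `d = TD_V - TD_III`; limits of agreement are `mean(d) +/- k_sd * sd(d)`.
#' The default multiplier is 2 SD (overridable to 1.96).
#'
#' @param pp a `vf_point_pairs` data frame with at least 2 rows.
#' @param k_sd limits-of-agreement multiplier (default 2).
#' @return A list with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `k_sd` and the per-point `table` (columns `mean`, `diff`).
#' @export
bland_altman <- function(pp, k_sd = 2) {
  if (nrow(pp) < 2L) stop("need at least 2 point pairs", call. = FALSE)
  m <- (pp$td_iii_db + pp$td_v_db) / 2
  d <- pp$td_v_db - pp$td_iii_db
  mu <- mean(d); s <- stats::sd(d)
  list(mean_diff = mu, sd_diff = s,
       loa_low = mu - k_sd * s, loa_high = mu + k_sd * s,
       k_sd = k_sd, table = data.frame(mean = m, diff = d))
}

#' Agreement battery for size III vs size V total deviations
#'
#' Bundles the package's full agreement analysis of a pointwise TD pair
#' table: subgroup difference summaries and paired t-test
#' ([summarize_diffs()]), OLS fit against the line of unity ([fit_line()])
#' and Bland-Altman limits of agreement ([bland_altman()]). Point pairs are
#' treated as independent observations, as is conventional for pooled
#' pointwise perimetry comparisons; see [cluster_bootstrap_diff()] for a
#' robustness check that resamples whole fields instead.
#'
#' @param pp a `vf_point_pairs` data frame ([make_point_pairs()]).
#' @param k_sd Bland-Altman limits-of-agreement multiplier (default 2).
#' @return An object of class `vf_agreement`: the [summarize_diffs()]
#'   fields plus `fit` and `bland_altman`. Methods: `print`, `coef`
#'   (slope, intercept, r_squared), `plot` (scatter with unity/fit lines,
#'   or Bland-Altman with `which = "ba"`).
#' @export
vf_agreement <- function(pp, k_sd = 2) {
  s <- summarize_diffs(pp)
  s$fit <- fit_line(pp)
  s$bland_altman <- bland_altman(pp, k_sd = k_sd)
  class(s) <- "vf_agreement"
  s
}

#' @export
print.vf_agreement <- function(x, ...) {
  cat("Agreement of size III vs size V total deviations (d = TD_V - TD_III)\n")
  cat(sprintf("  %d point pairs: %d censored (%.0f%%), %d uncensored\n",
              x$n_total, x$n_censored, 100 * x$prop_censored,
              x$n_uncensored))
  cat(sprintf("  diff, censored:   %+.1f ± %.1f dB\n",
              x$mean_diff_censored, x$sd_diff_censored))
  cat(sprintf("  diff, uncensored: %+.1f ± %.1f dB\n",
              x$mean_diff_uncensored, x$sd_diff_uncensored))
  cat(sprintf("  diff, all:        %+.1f ± %.1f dB  (t = %.2f, df = %d, p = %.3g)\n",
              x$mean_diff_all, x$sd_diff_all, x$t_statistic, x$df,
              x$p_value))
  cat(sprintf("  best fit: y = %+.2f + %.2f x   (r² = %.2f; unity: y = x)\n",
              x$fit$intercept, x$fit$slope, x$fit$r_squared))
  cat(sprintf("  Bland-Altman LoA (%.2f SD): [%.2f, %.2f] dB\n",
              x$bland_altman$k_sd, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  invisible(x)
}

#' @export
coef.vf_agreement <- function(object, ...) {
  c(slope = object$fit$slope, intercept = object$fit$intercept,
    r_squared = object$fit$r_squared)
}

#' Agreement plots
#'
#' `which = "scatter"` draws the TD_III vs TD_V scatter with the line of
#' unity (dashed) and the OLS fit (solid); `which = "ba"` draws the
#' Bland-Altman plot with mean difference and limits of agreement.
#'
#' @param x a `vf_agreement` object. To plot, rebuild the per-point data
#'   with the same `vf_point_pairs` table via the `pp` argument.
#' @param pp the `vf_point_pairs` table the object was built from.
#' @param which `"scatter"` or `"ba"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vf_agreement <- function(x, pp = NULL, which = c("scatter", "ba"), ...) {
  which <- match.arg(which)
  if (which == "scatter") {
    if (is.null(pp))
      stop("scatter plot needs the original point-pair table (pp =)",
           call. = FALSE)
    graphics::plot(pp$td_iii_db, pp$td_v_db,
                   col = ifelse(pp$pair_censored, "#d95f0255", "#1b9e7755"),
                   pch = 16, xlab = "TD, size III (dB)",
                   ylab = "TD, size V (dB)", ...)
    graphics::abline(0, 1, lty = 2, col = "darkgreen")
    graphics::abline(x$fit$intercept, x$fit$slope, lwd = 2)
  } else {
    ba <- x$bland_altman
    graphics::plot(ba$table$mean, ba$table$diff, pch = 16, col = "#2166ac55",
                   xlab = "mean of pair (dB)", ylab = "TD_V - TD_III (dB)",
                   ...)
    graphics::abline(h = ba$mean_diff, lty = 2, col = "grey40")
    graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2, col = "red")
  }
  invisible(x)
}

#' Cluster bootstrap of the mean TD difference
#'
#' The pooled t-test treats each of the 52 locations of each field pair as
#' independent, which understates uncertainty when deviations are
#' correlated within a field. This robustness check resamples whole field
#' pairs (clusters keyed by subject/session/eye) with replacement and
#' returns a percentile confidence interval for the mean difference.
#'
#' @param pp a `vf_point_pairs` data frame.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed.
#' @return List with `mean_diff`, `ci_low`, `ci_high`, `n_clusters`,
#'   `n_boot`.
#' @export
cluster_bootstrap_diff <- function(pp, n_boot = 1000, conf = 0.95,
                                   seed = 1) {
  key <- paste(pp$subject_id, pp$session_id, pp$eye, sep = "\r")
  d_by <- split(pp$td_v_db - pp$td_iii_db, key)
  k <- length(d_by)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b)
    mean(unlist(d_by[sample.int(k, k, replace = TRUE)])), numeric(1))
  a <- (1 - conf) / 2
  list(mean_diff = mean(pp$td_v_db - pp$td_iii_db),
       ci_low = unname(stats::quantile(boots, a)),
       ci_high = unname(stats::quantile(boots, 1 - a)),
       n_clusters = k, n_boot = n_boot)
}
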