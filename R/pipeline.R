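#' Load a run configuration from YAML
#'
#' Thin wrapper over [yaml::read_yaml()]; the returned list feeds
#' [run_simulate()], [run_optimize()], [run_agree()] or [run_report()],
#' whose documented fields define the schema. Command-line flags (see
#' `inst/cli/vfcensor.R`) override file values.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
load_run_config <- function(path) yaml::read_yaml(path)

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# exactly one input route: a fields CSV or a simulation spec
.resolve_pairs <- function(config) {
  has_csv <- !is.null(config$fields_csv)
  has_sim <- !is.null(config$simulate)
  if (has_csv == has_sim)
    stop("exactly one of fields_csv or simulate must be given",
         call. = FALSE)
  if (has_csv) {
    fields <- read_vf_fields(config$fields_csv,
                             schema_config = config$schema %||% list())
    pairs <- pair_same_day(fields)
  } else {
    s <- config$simulate
    spec <- cohort_spec(s$cohort %||% "GLAUCOMA", n_pairs = s$n_pairs,
                        n_participants = s$n_participants,
                        age_mean = s$age_mean, age_sd = s$age_sd,
                        severity_mean = s$severity_mean,
                        severity_sd = s$severity_sd,
                        pattern = s$pattern %||% list(),
                        seed = s$seed %||% config$seed %||% 1)
    pairs <- generate_cohort(spec, noise = .resolve_noise(config))
  }
  if (!is.null(config$cohort_filter)) {
    keep <- vapply(pairs, function(p) p$field_III$cohort, character(1)) ==
      toupper(config$cohort_filter)
    message(sprintf("cohort filter %s: kept %d of %d pairs",
                    config$cohort_filter, sum(keep), length(pairs)))
    pairs <- pairs[keep]
  }
  pairs
}

.resolve_noise <- function(config) {
  if (is.null(config$noise)) return(noise_model())
  do.call(noise_model, config$noise)
}

.resolve_norms <- function(config) {
  if (!is.null(config$normative_csv)) {
    list(III = read_normative_csv(config$normative_csv, "III"),
         V = read_normative_csv(config$normative_csv, "V"))
  } else {
    args <- config$normative %||% list()
    list(III = do.call(synthesize_normative, c(list(stimulus = "III"), args)),
         V = do.call(synthesize_normative, c(list(stimulus = "V"), args)))
  }
}

#' Simulate a cohort and write it to disk
#'
#' Writes the long-format fields CSV plus a JSON sidecar recording the full
#' resolved specification (including the seed), so the run can be repeated
#' to byte-identical output from the sidecar alone.
#'
#' @param config list with `simulate` (a sub-list of [cohort_spec()]
#'   fields), optional `noise` ([noise_model()] fields), optional `seed`
#'   (used when `simulate$seed` is absent), and `out_dir`.
#' @return Invisibly, a list with `fields_csv` and `sidecar` paths.
#' @export
run_simulate <- function(config) {
  if (is.null(config$simulate))
    stop("run_simulate needs a simulate: block", call. = FALSE)
  s <- config$simulate
  spec <- cohort_spec(s$cohort %||% "GLAUCOMA", n_pairs = s$n_pairs,
                      n_participants = s$n_participants,
                      age_mean = s$age_mean, age_sd = s$age_sd,
                      severity_mean = s$severity_mean,
                      severity_sd = s$severity_sd,
                      pattern = s$pattern %||% list(),
                      seed = s$seed %||% config$seed %||% 1)
  noise <- .resolve_noise(config)
  norms <- .resolve_norms(config)
  pairs <- generate_cohort(spec, noise, norms$III, norms$V)
  out <- .ensure_dir(config$out_dir %||% ".")
  csv <- file.path(out, "fields.csv")
  write_vf_fields(pairs, csv)
  sidecar <- file.path(out, "simulate_config.json")
  .write_json(list(command = "simulate",
                   simulate = unclass(spec),
                   noise = unclass(noise),
                   n_pairs_written = length(pairs),
                   fields_csv = basename(csv)),
              sidecar)
  message(sprintf("run_simulate: wrote %d pairs (%d rows) to %s",
                  length(pairs), length(pairs) * 104L, csv))
  invisible(list(fields_csv = csv, sidecar = sidecar, pairs = pairs))
}

#' Fit censoring thresholds from a config
#'
#' Resolves the input pairs (CSV or simulation), runs
#' [fit_censor_thresholds()] and writes the result JSON (grids, matrices,
#' best pair, objective) plus the heatmap CSV.
#'
#' @param config list with exactly one of `fields_csv` / `simulate`,
#'   optional `normative_csv` or `normative` parameter list, optional
#'   `grid_III`, `grid_V` (vectors or `list(from, to)`), `min_count`,
#'   `cohort_filter`, `noise`, `seed`, and `out_dir`.
#' @return Invisibly, the `censor_fit` (with `$paths` attached).
#' @export
run_optimize <- function(config) {
  pairs <- .resolve_pairs(config)
  norms <- .resolve_norms(config)
  as_grid <- function(gr, default) {
    if (is.null(gr)) default
    else if (is.list(gr)) seq(gr$from, gr$to, by = gr$by %||% 1)
    else gr
  }
  fit <- fit_censor_thresholds(
    pairs,
    grid_III = as_grid(config$grid_III, 15:30),
    grid_V = as_grid(config$grid_V, 15:30),
    min_count = config$min_count %||% 30,
    mean_tol = config$mean_tol %||% 0.1,
    norm_III = norms$III, norm_V = norms$V)
  out <- .ensure_dir(config$out_dir %||% ".")
  jpath <- file.path(out, "thresholds.json")
  .write_json(list(command = "optimize",
                   grid_III = fit$grid_III, grid_V = fit$grid_V,
                   best = unclass(fit$best),
                   objective_db = fit$objective,
                   sd_at_best_db = fit$sd_at_best,
                   n_at_best = fit$n_at_best,
                   tie_break = fit$tie_break,
                   min_count = fit$min_count,
                   mean_tol = fit$mean_tol,
                   n_pairs = fit$n_pairs,
                   mean_diff = fit$mean_diff,
                   n_censored = fit$n_censored),
              jpath)
  hpath <- file.path(out, "heatmap.csv")
  write_heatmap_csv(fit, hpath)
  message(sprintf("run_optimize: best thresholds t_III = %g, t_V = %g (%s)",
                  fit$best$threshold_III, fit$best$threshold_V,
                  fit$tie_break))
  fit$paths <- list(json = jpath, heatmap_csv = hpath)
  invisible(fit)
}

#' Run the agreement battery from a config
#'
#' Builds pointwise TD pairs at the configured thresholds and writes the
#' [vf_agreement()] summary JSON plus the per-point CSV.
#'
#' @param config list with exactly one of `fields_csv` / `simulate`,
#'   `thresholds` (list with `threshold_III`, `threshold_V`), optional
#'   `loa_k` (Bland-Altman multiplier), plus the shared fields of
#'   [run_optimize()].
#' @return Invisibly, the `vf_agreement` (with `$paths` attached).
#' @export
run_agree <- function(config) {
  if (is.null(config$thresholds))
    stop("run_agree needs thresholds: {threshold_III, threshold_V}",
         call. = FALSE)
  pairs <- .resolve_pairs(config)
  norms <- .resolve_norms(config)
  cfg <- censor_config(config$thresholds$threshold_III,
                       config$thresholds$threshold_V)
  pp <- make_point_pairs(pairs, cfg, norms$III, norms$V)
  agr <- vf_agreement(pp, k_sd = config$loa_k %||% 2)
  out <- .ensure_dir(config$out_dir %||% ".")
  jpath <- file.path(out, "agreement.json")
  ba <- agr$bland_altman
  .write_json(list(command = "agree", thresholds = unclass(cfg),
                   n_total = agr$n_total, n_censored = agr$n_censored,
                   n_uncensored = agr$n_uncensored,
                   prop_censored = agr$prop_censored,
                   mean_diff_all = agr$mean_diff_all,
                   sd_diff_all = agr$sd_diff_all,
                   mean_diff_censored = agr$mean_diff_censored,
                   sd_diff_censored = agr$sd_diff_censored,
                   mean_diff_uncensored = agr$mean_diff_uncensored,
                   sd_diff_uncensored = agr$sd_diff_uncensored,
                   t_statistic = agr$t_statistic, df = agr$df,
                   p_value = agr$p_value,
                   fit = agr$fit,
                   bland_altman = ba[c("mean_diff", "sd_diff", "loa_low",
                                       "loa_high", "k_sd")]),
              jpath)
  cpath <- file.path(out, "point_pairs.csv")
  write_point_pairs(pp, cpath)
  message(sprintf(
    "run_agree: %d point pairs, censored diff %+.2f ± %.2f dB, slope %.3f",
    agr$n_total, agr$mean_diff_censored, agr$sd_diff_censored,
    agr$fit$slope))
  agr$paths <- list(json = jpath, point_pairs_csv = cpath)
  invisible(agr)
}

#' Full simulate-optimize-agree pipeline
#'
#' Simulates the configured cohort, fits the censoring thresholds on it,
#' runs the agreement battery at the fitted optimum, and writes all
#' artifacts into one output directory.
#'
#' @param config as [run_simulate()] plus the optional grid/min_count
#'   fields of [run_optimize()].
#' @return Invisibly, list with `simulate`, `fit`, `agreement`.
#' @export
run_report <- function(config) {
  sim <- run_simulate(config)
  sub <- config
  sub$simulate <- NULL
  sub$fields_csv <- sim$fields_csv
  fit <- run_optimize(sub)
  sub$thresholds <- unclass(fit$best)
  agr <- run_agree(sub)
  invisible(list(simulate = sim[c("fields_csv", "sidecar")], fit = fit,
                 agreement = agr))
}
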