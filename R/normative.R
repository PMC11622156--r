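#' Synthesize a parametric hill-of-vision normative table
#'
#' The proprietary perimeter normative databases (size III SITA, size V
#' full-threshold) are not publicly available, so the package ships a
#' parametric surrogate: expected normal sensitivity falls off linearly with
#' eccentricity from a foveal peak, size V sits a uniform offset above size
#' III (its larger stimulus recruits more spatial summation), and age acts
#' linearly through a per-decade slope. The censoring/TD machinery is
#' invariant to which normative table is plugged in; a measured table can be
#' supplied via [read_normative_csv()].
#'
#' @param stimulus `"III"` or `"V"`.
#' @param peak_db foveal peak sensitivity at the reference age, dB
#'   (default 34).
#' @param ecc_slope_db_per_deg loss of sensitivity per degree of
#'   eccentricity, dB/deg (default 0.25).
#' @param v_offset_db uniform dB bonus of stimulus V over stimulus III
#'   (default +4; applied only when `stimulus = "V"`).
#' @param age_slope_db_per_decade ageing slope, dB per decade, applied
#'   uniformly to all locations (default -0.7).
#' @param reference_age age in years at which the table's mean sensitivities
#'   hold exactly (default 45).
#' @return An object of class `vf_norm`: a 52-row data frame (OD frame) with
#'   columns `x_deg`, `y_deg`, `mean_sensitivity_ref_db`,
#'   `age_slope_db_per_decade` and attributes `stimulus`, `reference_age`.
#' @examples
#' n3 <- synthesize_normative("III")
#' expected_sensitivity(n3, 3, 3, age_years = 45)  # ~32.94 dB
#' @export
synthesize_normative <- function(stimulus = c("III", "V"), peak_db = 34,
                                 ecc_slope_db_per_deg = 0.25,
                                 v_offset_db = 4,
                                 age_slope_db_per_decade = -0.7,
                                 reference_age = 45) {
  stimulus <- normalize_stimulus(match.arg(stimulus))
  if (!is.numeric(peak_db) || peak_db <= 0)
    stop("peak_db must be positive", call. = FALSE)
  g <- vf_grid_seeing("OD")
  ecc <- sqrt(g$x_deg^2 + g$y_deg^2)
  mean_ref <- peak_db - ecc_slope_db_per_deg * ecc +
    if (stimulus == "V") v_offset_db else 0
  tab <- data.frame(x_deg = g$x_deg, y_deg = g$y_deg,
                    mean_sensitivity_ref_db = mean_ref,
                    age_slope_db_per_decade = age_slope_db_per_decade)
  new_vf_norm(tab, stimulus, reference_age)
}

new_vf_norm <- function(tab, stimulus, reference_age) {
  stopifnot(nrow(tab) == 52L,
            all(c("x_deg", "y_deg", "mean_sensitivity_ref_db",
                  "age_slope_db_per_decade") %in% names(tab)))
  keys <- vf_grid_seeing("OD")$loc
  rownames(tab) <- .loc_key(tab$x_deg, tab$y_deg)
  if (!setequal(rownames(tab), keys))
    stop("normative table must cover exactly the 52 seeing 24-2 locations",
         call. = FALSE)
  tab <- tab[keys, , drop = FALSE]
  structure(tab, stimulus = stimulus,
            reference_age = as.numeric(reference_age),
            class = c("vf_norm", "data.frame"))
}

#' @export
print.vf_norm <- function(x, ...) {
  cat(sprintf("<vf_norm> stimulus %s, reference age %.0f, 52 locations\n",
              attr(x, "stimulus"), attr(x, "reference_age")))
  cat(sprintf("  mean sensitivity %.1f-%.1f dB, age slope %.2f dB/decade\n",
              min(x$mean_sensitivity_ref_db), max(x$mean_sensitivity_ref_db),
              mean(x$age_slope_db_per_decade)))
  invisible(x)
}

#' Expected normal sensitivity at a location and age
#'
#' Linear age model: `mean_ref(p) + age_slope(p) * (age - reference_age)/10`.
#' The normative table lives in the right-eye (OD) frame; pass
#' `eye = "OS"` to look up a left-eye location (x is mirrored).
#'
#' @param norm a `vf_norm` table.
#' @param x_deg,y_deg location, degrees (may be vectors).
#' @param age_years age in years, in \[10, 110\].
#' @param eye frame of the supplied coordinates, `"OD"` (default) or `"OS"`.
#' @return Expected sensitivity in dB (vectorized over locations).
#' @export
expected_sensitivity <- function(norm, x_deg, y_deg, age_years,
                                 eye = c("OD", "OS")) {
  stopifnot(inherits(norm, "vf_norm"))
  eye <- match.arg(eye)
  if (age_years < 10 || age_years > 110)
    stop("age_years must be in [10, 110]", call. = FALSE)
  if (eye == "OS") x_deg <- -x_deg
  key <- .loc_key(x_deg, y_deg)
  bs <- key %in% c("15:3", "15:-3")
  if (any(bs))
    stop("blind-spot location has no normative value: ",
         paste0("(", sub(":", ", ", key[bs]), ")", collapse = ", "),
         call. = FALSE)
  idx <- match(key, rownames(norm))
  if (anyNA(idx))
    stop("location not on the 24-2 grid: ", key[which(is.na(idx))[1]],
         call. = FALSE)
  norm$mean_sensitivity_ref_db[idx] +
    norm$age_slope_db_per_decade[idx] *
      (age_years - attr(norm, "reference_age")) / 10
}

# expected sensitivities for a whole field, in the field's own location order
.expected_for_field <- function(field, norm) {
  if (attr(norm, "stimulus") != field$stimulus)
    stop(sprintf("normative table is for stimulus %s but field is %s",
                 attr(norm, "stimulus"), field$stimulus), call. = FALSE)
  xy <- do.call(rbind, strsplit(names(field$sens), ":", fixed = TRUE))
  e <- expected_sensitivity(norm, as.integer(xy[, 1]), as.integer(xy[, 2]),
                            field$age_years, eye = field$eye)
  names(e) <- names(field$sens)
  e
}

#' Censor a field and convert it to total deviation
#'
#' Applies the censoring rule first -- every raw sensitivity strictly below
#' `censor_threshold` is replaced by the threshold -- and then subtracts the
#' age-corrected normative expectation at each location. The
#' censor-then-convert order matters: censoring acts on raw sensitivities,
#' not on deviations.
#'
#' @param field a `vf_field`.
#' @param norm the `vf_norm` table for the field's stimulus.
#' @param censor_threshold censoring threshold in dB; use `-Inf` for no
#'   censoring (the plain deviation field).
#' @return An object of class `vf_td`: list with `td` (named numeric, dB,
#'   signed), `censored` (named logical, raw value was below threshold),
#'   `stimulus`, `threshold`, `age_years`.
#' @export
compute_td <- function(field, norm, censor_threshold = -Inf) {
  stopifnot(inherits(field, "vf_field"))
  e <- .expected_for_field(field, norm)
  cen <- censor_value(field$sens, censor_threshold)
  structure(list(td = cen$value - e, censored = cen$was_censored,
                 stimulus = field$stimulus, threshold = censor_threshold,
                 age_years = field$age_years),
            class = "vf_td")
}

#' @export
print.vf_td <- function(x, ...) {
  cat(sprintf(
    "<vf_td> stimulus %s, threshold %s dB: mean TD %.2f dB (%d/%d censored)\n",
    x$stimulus, format(x$threshold), mean(x$td), sum(x$censored),
    length(x$td)))
  invisible(x)
}

#' Read / write a normative table CSV
#'
#' Columns: `stimulus`, `x_deg`, `y_deg`, `mean_sensitivity_ref_db`,
#' `age_slope_db_per_decade`; the reference age travels in a leading
#' `# reference_age: <years>` comment line.
#'
#' @param path CSV path.
#' @param stimulus which stimulus to extract (a file may hold both).
#' @return A `vf_norm` table.
#' @export
read_normative_csv <- function(path, stimulus = c("III", "V")) {
  stimulus <- normalize_stimulus(match.arg(stimulus))
  first <- readLines(path, n = 1L)
  ref_age <- 45
  if (grepl("^#", first)) {
    m <- regmatches(first, regexpr("[0-9.]+", first))
    if (length(m)) ref_age <- as.numeric(m)
  }
  tab <- utils::read.csv(path, comment.char = "#")
  tab$stimulus <- vapply(tab$stimulus, normalize_stimulus, character(1))
  tab <- tab[tab$stimulus == stimulus,
             c("x_deg", "y_deg", "mean_sensitivity_ref_db",
               "age_slope_db_per_decade")]
  new_vf_norm(tab, stimulus, ref_age)
}

#' @rdname read_normative_csv
#' @param norms a single `vf_norm` or list of them (e.g. III and V).
#' @export
write_normative_csv <- function(norms, path) {
  if (inherits(norms, "vf_norm")) norms <- list(norms)
  ref <- unique(vapply(norms, attr, numeric(1), "reference_age"))
  if (length(ref) != 1L)
    stop("all tables written together must share a reference age",
         call. = FALSE)
  rows <- do.call(rbind, lapply(norms, function(n)
    data.frame(stimulus = attr(n, "stimulus"), x_deg = n$x_deg,
               y_deg = n$y_deg,
               mean_sensitivity_ref_db = n$mean_sensitivity_ref_db,
               age_slope_db_per_decade = n$age_slope_db_per_decade)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# reference_age: %g", ref), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
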