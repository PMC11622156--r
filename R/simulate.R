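#' Specification of a simulated perimetry cohort
#'
#' Defaults emulate the demographic and repeated-measures structure of the
#' two clinical cohorts the method targets: a moderate-to-severe glaucoma
#' cohort (120 participants, 1053 same-day III/V pairs, age 67.8 +/- 9.3
#' years, arcuate deficits) and a NAION cohort (586 participants, 939
#' pairs, age 61.3 +/- 7.7 years, altitudinal deficits). Ages are truncated
#' to \[19, 90\] years. `severity` is the peak depth of the deficit pattern
#' in dB; draws are truncated to \[0, 30\].
#'
#' @param cohort `"GLAUCOMA"` or `"NAION"`.
#' @param n_pairs number of same-day field pairs to simulate.
#' @param n_participants number of distinct participants; pairs are
#'   assigned round-robin, so repeated sessions per participant arise
#'   whenever `n_pairs > n_participants`.
#' @param age_mean,age_sd participant age distribution, years.
#' @param severity_mean,severity_sd participant-level peak deficit, dB.
#' @param pattern list of pattern parameters. Glaucoma: `ecc_min`,
#'   `ecc_max` (Bjerrum annulus bounds, degrees), `nasal_step`
#'   (logical), `nasal_step_frac` (deficit fraction applied at the nasal
#'   step). NAION: `transition_width_deg` (width of the smooth band across
#'   the horizontal meridian; 0 gives a hard altitudinal step).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the spec (including this seed).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort = c("GLAUCOMA", "NAION"), n_pairs = NULL,
                        n_participants = NULL, age_mean = NULL,
                        age_sd = NULL, severity_mean = NULL,
                        severity_sd = NULL, pattern = list(), seed = 1) {
  cohort <- match.arg(toupper(cohort), c("GLAUCOMA", "NAION"))
  def <- if (cohort == "GLAUCOMA") {
    list(n_pairs = 1053L, n_participants = 120L, age_mean = 67.8,
         age_sd = 9.3, severity_mean = 18, severity_sd = 6,
         pattern = list(ecc_min = 10, ecc_max = 21, nasal_step = TRUE,
                        nasal_step_frac = 0.5))
  } else {
    list(n_pairs = 939L, n_participants = 586L, age_mean = 61.3,
         age_sd = 7.7, severity_mean = 16, severity_sd = 6,
         pattern = list(transition_width_deg = 6))
  }
  spec <- list(
    cohort = cohort,
    n_pairs = as.integer(n_pairs %||% def$n_pairs),
    n_participants = as.integer(n_participants %||% def$n_participants),
    age_mean = age_mean %||% def$age_mean,
    age_sd = age_sd %||% def$age_sd,
    severity_mean = severity_mean %||% def$severity_mean,
    severity_sd = severity_sd %||% def$severity_sd,
    pattern = utils::modifyList(def$pattern, pattern),
    seed = as.integer(seed))
  if (spec$n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  if (spec$n_participants < 1L)
    stop("n_participants must be >= 1", call. = FALSE)
  if (spec$age_sd < 0 || spec$severity_sd < 0)
    stop("dispersions must be non-negative", call. = FALSE)
  structure(spec, class = "cohort_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %s: %d pairs / %d participants, age %.1f ± %.1f, severity %.0f ± %.0f dB, seed %d\n",
    x$cohort, x$n_pairs, x$n_participants, x$age_mean, x$age_sd,
    x$severity_mean, x$severity_sd, x$seed))
  invisible(x)
}

#' Observation-noise model for simulated fields
#'
#' Captures the two variability regimes of static perimetry. Above the
#' stimulus-specific sensitivity floor, test-retest noise is Gaussian with
#' an SD that grows as sensitivity falls: `sigma_low` at 30 dB rising
#' linearly to `sigma_high` at the floor (clamped outside). Below the
#' floor, thresholds are unrepeatable; in the default `"uniform"` mode a
#' sub-floor true sensitivity is observed as a draw from the discrete
#' uniform distribution on `{0, ..., floor - 1}` (noise-dominated), while
#' `"clamp"` mode keeps the Gaussian model everywhere (no noise floor),
#' which is useful for demonstrating the threshold search when the floors
#' do not exist.
#'
#' Default sigmas follow published pointwise inter-test variability: 1.3 to
#' 3.0 dB for size III and 1.2 to 2.0 dB for size V. Default floors are 21
#' dB (III) and 24 dB (V).
#'
#' @param sigma_low_III,sigma_high_III,sigma_low_V,sigma_high_V Gaussian
#'   noise SDs (dB) at 30 dB and at the floor, per stimulus.
#' @param floor_III,floor_V sensitivity floors (dB), each in \[10, 30\].
#' @param sub_floor_mode `"uniform"` or `"clamp"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_low_III = 1.3, sigma_high_III = 3.0,
                        sigma_low_V = 1.2, sigma_high_V = 2.0,
                        floor_III = 21, floor_V = 24,
                        sub_floor_mode = c("uniform", "clamp")) {
  sub_floor_mode <- match.arg(sub_floor_mode)
  stopifnot(sigma_low_III <= sigma_high_III, sigma_low_V <= sigma_high_V,
            floor_III >= 10, floor_III <= 30, floor_V >= 10, floor_V <= 30)
  structure(list(sigma_low_III = sigma_low_III,
                 sigma_high_III = sigma_high_III,
                 sigma_low_V = sigma_low_V, sigma_high_V = sigma_high_V,
                 floor_III = floor_III, floor_V = floor_V,
                 sub_floor_mode = sub_floor_mode),
            class = "noise_model")
}

#' True deficit pattern for one simulated eye
#'
#' Draws a disease-typical deficit field D(p) >= 0 dB over the 52 seeing
#' locations (OD frame; anatomic mapping to OS is positional). NAION:
#' altitudinal loss -- one hemifield (superior or inferior, chosen at
#' random from the current RNG stream) depressed by `severity`, with a
#' linear transition band of configurable width across the horizontal
#' meridian. Glaucoma: arcuate loss -- `severity` over a Bjerrum annulus
#' (10--21 degrees eccentricity by default) restricted to one hemifield,
#' plus an optional nasal step at reduced depth.
#'
#' @param cohort `"GLAUCOMA"` or `"NAION"`.
#' @param severity peak deficit depth, dB (>= 0).
#' @param pattern pattern parameter list (see [cohort_spec()]).
#' @return Named numeric vector of deficits (dB) over the OD seeing grid.
#' @export
true_deficit_field <- function(cohort, severity, pattern = list()) {
  cohort <- match.arg(toupper(cohort), c("GLAUCOMA", "NAION"))
  stopifnot(severity >= 0)
  g <- vf_grid_seeing("OD")
  hemi <- sample(c(1, -1), 1L)        # +1 = superior hemifield affected
  if (cohort == "NAION") {
    w <- pattern$transition_width_deg %||% 6
    frac <- if (w > 0) pmin(pmax(0.5 + hemi * g$y_deg / w, 0), 1)
            else as.numeric(hemi * g$y_deg > 0)
  } else {
    ecc <- sqrt(g$x_deg^2 + g$y_deg^2)
    lo <- pattern$ecc_min %||% 10; hi <- pattern$ecc_max %||% 21
    frac <- as.numeric(ecc >= lo & ecc <= hi & hemi * g$y_deg > 0)
    if (isTRUE(pattern$nasal_step)) {
      ns <- (pattern$nasal_step_frac %||% 0.5) *
        as.numeric(g$x_deg <= -15 & hemi * g$y_deg > 0)
      frac <- pmax(frac, ns)
    }
  }
  d <- severity * frac
  names(d) <- g$loc
  d
}

#' Observe a true field through the noise model
#'
#' Applies the stimulus-specific noise regime of [noise_model()] to a
#' vector of true sensitivities and rounds to integer dB, clamped to
#' \[0, 50\], mirroring perimeter output.
#'
#' @param true_sens numeric vector of true sensitivities, dB in \[0, 50\].
#' @param stimulus `"III"` or `"V"`.
#' @param noise a [noise_model()].
#' @return Integer-valued observed sensitivities (same length/names).
#' @export
observe_field <- function(true_sens, stimulus = c("III", "V"),
                          noise = noise_model()) {
  stimulus <- normalize_stimulus(match.arg(stimulus))
  stopifnot(all(true_sens >= 0), all(true_sens <= 50))
  if (stimulus == "III") {
    flo <- noise$floor_III; s_lo <- noise$sigma_low_III
    s_hi <- noise$sigma_high_III
  } else {
    flo <- noise$floor_V; s_lo <- noise$sigma_low_V
    s_hi <- noise$sigma_high_V
  }
  n <- length(true_sens)
  # sigma(s): s_hi at the floor, s_lo at 30 dB, linear in between
  frac <- pmin(pmax((30 - true_sens) / (30 - flo), 0), 1)
  sigma <- s_lo + (s_hi - s_lo) * frac
  obs <- round(true_sens + stats::rnorm(n, 0, sigma))
  if (noise$sub_floor_mode == "uniform") {
    below <- true_sens < flo
    if (any(below))
      obs[below] <- sample.int(as.integer(flo), sum(below),
                               replace = TRUE) - 1L
  }
  obs <- pmin(pmax(obs, 0), 50)
  names(obs) <- names(true_sens)
  obs
}

#' Generate a simulated cohort of same-day III/V field pairs
#'
#' Fully deterministic given `spec$seed`. Per participant: an age (normal,
#' truncated to \[19, 90\]), a tested eye, a peak severity (normal,
#' truncated to \[0, 30\]) and one deficit pattern draw; the same true
#' deficit D(p) underlies both stimuli, so stimulus differences arise only
#' through the normative surfaces, floors and observation noise. Pairs are
#' assigned to participants round-robin; repeat sessions of one
#' participant share the true field and differ only in independent
#' observation noise. True sensitivity per stimulus is
#' `expected_sensitivity - D`, clamped to \[0, 50\], then observed through
#' the noise model independently for each stimulus.
#'
#' @param spec a [cohort_spec()].
#' @param noise a [noise_model()].
#' @param norm_III,norm_V normative tables (default: parametric surrogate).
#' @return List of [vf_pair()] objects, length `spec$n_pairs`.
#' @export
generate_cohort <- function(spec, noise = noise_model(),
                            norm_III = synthesize_normative("III"),
                            norm_V = synthesize_normative("V")) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  np <- spec$n_participants
  ages <- .rnorm_trunc(np, spec$age_mean, spec$age_sd, 19, 90)
  sevs <- .rnorm_trunc(np, spec$severity_mean, spec$severity_sd, 0, 30)
  eyes <- sample(c("OD", "OS"), np, replace = TRUE)
  deficits <- lapply(sevs, function(s)
    true_deficit_field(spec$cohort, s, spec$pattern))
  subj_ids <- sprintf("%s%04d", substr(spec$cohort, 1, 1), seq_len(np))
  part_of_pair <- rep_len(seq_len(np), spec$n_pairs)
  g_od <- vf_grid_seeing("OD")
  pairs <- vector("list", spec$n_pairs)
  for (i in seq_len(spec$n_pairs)) {
    k <- part_of_pair[i]
    eye <- eyes[k]
    keys <- vf_grid_seeing(eye)$loc      # positionally anatomic match to OD
    e3 <- expected_sensitivity(norm_III, g_od$x_deg, g_od$y_deg, ages[k])
    e5 <- expected_sensitivity(norm_V, g_od$x_deg, g_od$y_deg, ages[k])
    true3 <- pmin(pmax(e3 - deficits[[k]], 0), 50)
    true5 <- pmin(pmax(e5 - deficits[[k]], 0), 50)
    obs3 <- observe_field(true3, "III", noise)
    obs5 <- observe_field(true5, "V", noise)
    names(obs3) <- names(obs5) <- keys
    sid <- sprintf("S%05d", i)
    f3 <- vf_field(subj_ids[k], spec$cohort, eye, sid, "III", ages[k], obs3)
    f5 <- vf_field(subj_ids[k], spec$cohort, eye, sid, "V", ages[k], obs5)
    pairs[[i]] <- vf_pair(f3, f5)
  }
  pairs
}

# truncated normal via rejection; deterministic under the current seed
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Participant-level demographics of a simulated cohort
#'
#' @param pairs list of `vf_pair` objects.
#' @return Data frame with one row per distinct subject: `subject_id`,
#'   `cohort`, `age_years`.
#' @export
cohort_participants <- function(pairs) {
  tab <- unique(data.frame(
    subject_id = vapply(pairs, function(p) p$field_III$subject_id,
                        character(1)),
    cohort = vapply(pairs, function(p) p$field_III$cohort, character(1)),
    age_years = vapply(pairs, function(p) p$field_III$age_years,
                       numeric(1))))
  rownames(tab) <- NULL
  tab
}
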