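# Shared fixtures, all built in code.

# flat normative tables: expected sensitivity `peak` dB everywhere, at any
# age (zero ageing slope) -- makes hand computation of TDs trivial
flat_norm <- function(stimulus, peak = 30) {
  synthesize_normative(stimulus, peak_db = peak, ecc_slope_db_per_deg = 0,
                       v_offset_db = 0, age_slope_db_per_decade = 0)
}

# one field with constant (or per-location) sensitivities
make_field <- function(sens = 30, subject = "s1", session = "d1",
                       eye = "OD", stimulus = "III", age = 45,
                       cohort = "GLAUCOMA") {
  keys <- vf_grid_seeing(eye)$loc
  s <- rep_len(sens, 52)
  names(s) <- keys
  vf_field(subject, cohort, eye, session, stimulus, age, s)
}

# a same-day pair with constant sensitivities per stimulus
make_pair <- function(sens_III = 30, sens_V = 30, subject = "s1",
                      session = "d1", eye = "OD", age = 45,
                      cohort = "GLAUCOMA") {
  vf_pair(
    make_field(sens_III, subject, session, eye, "III", age, cohort),
    make_field(sens_V, subject, session, eye, "V", age, cohort))
}

# set the sensitivity of field `fld` at the i-th seeing location
set_loc <- function(fld, i, value) {
  fld$sens[i] <- value
  fld
}

# independent naive re-implementation of the threshold search used as the
# brute-force oracle: evaluates every cell via evaluate_cell() and applies
# the documented selection rule (min |mean| with near-ties within mean_tol
# broken by lowest SD, then lowest t_III, then t_V)
naive_grid_search <- function(pairs, grid_III, grid_V, min_count,
                              mean_tol, norm_III, norm_V) {
  cells <- expand.grid(t3 = grid_III, t5 = grid_V)
  res <- lapply(seq_len(nrow(cells)), function(k)
    evaluate_cell(pairs, cells$t3[k], cells$t5[k], norm_III, norm_V))
  cells$mean <- vapply(res, `[[`, numeric(1), "mean_diff")
  cells$sd <- vapply(res, `[[`, numeric(1), "sd_diff")
  cells$n <- vapply(res, `[[`, numeric(1), "n_censored")
  ok <- cells$n >= min_count & !is.na(cells$mean)
  stopifnot(any(ok))
  obj <- ifelse(ok, abs(cells$mean), Inf)
  tied <- which(obj <= min(obj) + mean_tol)
  sds <- ifelse(is.na(cells$sd[tied]), Inf, cells$sd[tied])
  tied <- tied[sds == min(sds)]
  tied <- tied[order(cells$t3[tied], cells$t5[tied])][1]
  list(best = c(cells$t3[tied], cells$t5[tied]), cells = cells)
}
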