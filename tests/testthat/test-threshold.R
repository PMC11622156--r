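n3f <- flat_norm("III"); n5f <- flat_norm("V")

test_that("evaluate_cell summarizes the censored subset", {
  # nothing censored
  e <- evaluate_cell(list(make_pair(30, 30)), 21, 24, n3f, n5f)
  expect_equal(e$n_censored, 0L)
  expect_true(is.na(e$mean_diff))

  # a single censored point pair with d = td_V - td_III = 2:
  # III raw 10 -> 21, TD -9; V raw 23 uncensored (t_V = 0), TD -7
  p <- make_pair(25, 23)
  p$field_III <- set_loc(p$field_III, 1, 10)
  e1 <- evaluate_cell(list(p), 21, 0, n3f, n5f)
  expect_equal(e1$n_censored, 1L)
  expect_equal(e1$mean_diff, 2)
  expect_true(is.na(e1$sd_diff))

  # three censored points with diffs {1, -1, 0}
  p2 <- make_pair(25, 25)
  p2$field_III <- set_loc(p2$field_III, 1, 10)
  p2$field_III <- set_loc(p2$field_III, 2, 10)
  p2$field_III <- set_loc(p2$field_III, 3, 10)
  p2$field_V <- set_loc(p2$field_V, 1, 22)   # TD -8, d = +1
  p2$field_V <- set_loc(p2$field_V, 2, 20)   # TD -10, d = -1
  p2$field_V <- set_loc(p2$field_V, 3, 21)   # TD -9, d = 0
  e3 <- evaluate_cell(list(p2), 21, 0, n3f, n5f)
  expect_equal(e3$n_censored, 3L)
  expect_equal(e3$mean_diff, 0)
  expect_equal(e3$sd_diff, 1)                # sample SD, denominator n - 1
})

test_that("identical stimuli give a zero surface and lawful tie-break", {
  set.seed(3)
  # V raw values identical to III, with identical flat norms
  pairs <- lapply(1:4, function(i) {
    f3 <- make_field(sample(5:30, 52, TRUE), subject = paste0("s", i))
    f5 <- f3; f5$stimulus <- "V"
    vf_pair(f3, f5)
  })
  n5_same <- flat_norm("V")                  # same values as the III table
  fit <- fit_censor_thresholds(pairs, grid_III = 20:23, grid_V = 20:23,
                               min_count = 1, norm_III = n3f,
                               norm_V = n5_same)
  # equal thresholds clamp both stimuli identically: zero mean difference
  diag_cells <- cbind(as.character(20:23), as.character(20:23))
  defined <- !is.na(fit$mean_diff[diag_cells])
  expect_true(all(fit$mean_diff[diag_cells][defined] == 0))
  # off the diagonal the higher V threshold pushes the difference positive
  expect_gt(fit$mean_diff["20", "23"], 0)
  # all-zero means tie; SD then lowest thresholds decide
  expect_match(fit$tie_break, "tie")
  naive <- naive_grid_search(pairs, 20:23, 20:23, 1, 0.1, n3f, n5_same)
  expect_equal(unname(coef(fit)), naive$best)
})

test_that("grid search matches the brute-force oracle on toy data", {
  p1 <- make_pair(25, 25); p1$field_III <- set_loc(p1$field_III, 1, 12)
  p2 <- make_pair(25, 25); p2$field_V <- set_loc(p2$field_V, 2, 18)
  p3 <- make_pair(25, 25)
  p3$field_III <- set_loc(p3$field_III, 3, 8)
  p3$field_V <- set_loc(p3$field_V, 3, 14)
  toy <- list(p1, p2, p3)
  fit <- fit_censor_thresholds(toy, grid_III = c(20, 22),
                               grid_V = c(19, 23), min_count = 1,
                               norm_III = n3f, norm_V = n5f)
  naive <- naive_grid_search(toy, c(20, 22), c(19, 23), 1, 0.1, n3f, n5f)
  expect_equal(unname(coef(fit)), naive$best)
  for (k in seq_len(nrow(naive$cells))) {
    i <- as.character(naive$cells$t3[k]); j <- as.character(naive$cells$t5[k])
    expect_equal(fit$mean_diff[i, j], naive$cells$mean[k])
    expect_equal(fit$n_censored[i, j], naive$cells$n[k])
  }
})

test_that("vectorized search equals the naive path on simulated cohorts", {
  for (seed in 1:3) {
    pairs <- generate_cohort(cohort_spec("NAION", n_pairs = 15,
                                         n_participants = 8, seed = seed))
    for (tol in c(0, 0.1)) {
      fit <- fit_censor_thresholds(pairs, grid_III = 18:22, grid_V = 21:25,
                                   min_count = 5, mean_tol = tol)
      naive <- naive_grid_search(pairs, 18:22, 21:25, 5, tol,
                                 synthesize_normative("III"),
                                 synthesize_normative("V"))
      expect_equal(unname(coef(fit)), naive$best)
      got <- fit$mean_diff[cbind(as.character(naive$cells$t3),
                                 as.character(naive$cells$t5))]
      expect_equal(unname(got), naive$cells$mean)
      got_sd <- fit$sd_diff[cbind(as.character(naive$cells$t3),
                                  as.character(naive$cells$t5))]
      expect_equal(unname(got_sd), naive$cells$sd)
    }
  }
})

test_that("strict argmin (mean_tol = 0) satisfies the optimality invariant", {
  pairs <- generate_cohort(cohort_spec("GLAUCOMA", n_pairs = 20,
                                       n_participants = 10, seed = 5))
  fit <- fit_censor_thresholds(pairs, grid_III = 18:22, grid_V = 21:25,
                               min_count = 5, mean_tol = 0)
  eligible <- fit$n_censored >= 5 & !is.na(fit$mean_diff)
  expect_true(all(abs(fit$objective) <= abs(fit$mean_diff[eligible])))
  expect_equal(dim(fit$mean_diff), c(5L, 5L))
})

test_that("results are invariant to the order of field pairs", {
  pairs <- generate_cohort(cohort_spec("NAION", n_pairs = 12,
                                       n_participants = 6, seed = 2))
  f1 <- fit_censor_thresholds(pairs, grid_III = 19:21, grid_V = 22:24,
                              min_count = 5)
  f2 <- fit_censor_thresholds(rev(pairs), grid_III = 19:21, grid_V = 22:24,
                              min_count = 5)
  expect_equal(f1$mean_diff, f2$mean_diff)
  expect_equal(f1$sd_diff, f2$sd_diff)
  expect_equal(coef(f1), coef(f2))
})

test_that("an unreachable min_count errors with advice", {
  pairs <- list(make_pair(35, 35), make_pair(34, 36))
  expect_error(
    fit_censor_thresholds(pairs, grid_III = 15:16, grid_V = 15:16,
                          min_count = 30, norm_III = n3f, norm_V = n5f),
    "larger cohort")
})
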