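# minimal point-pair table builder: d = td_v - td_iii
pp_from <- function(td_iii, td_v, censored = FALSE) {
  n <- length(td_iii)
  data.frame(subject_id = "s", session_id = as.character(seq_len(n)),
             cohort = "GLAUCOMA", eye = "OD", x_deg = 3, y_deg = 3,
             td_iii_db = td_iii, td_v_db = td_v,
             censored_iii = rep_len(censored, n),
             censored_v = FALSE,
             pair_censored = rep_len(censored, n))
}

test_that("difference summaries and t-test match hand computation", {
  pp <- pp_from(c(0, 0, 0), c(1, 2, 3))
  s <- summarize_diffs(pp)
  expect_equal(s$mean_diff_all, 2)
  expect_equal(s$sd_diff_all, 1)
  expect_equal(s$t_statistic, 2 * sqrt(3), tolerance = 1e-12)  # mean/(sd/sqrt(n))
  expect_equal(s$df, 2)
  expect_equal(s$n_uncensored, 3L)
  expect_true(is.na(s$mean_diff_censored))

  # degenerate: identical pairs -> zero variance, t undefined
  s0 <- summarize_diffs(pp_from(c(1, 1), c(1, 1)))
  expect_equal(s0$mean_diff_all, 0)
  expect_equal(s0$sd_diff_all, 0)
  expect_true(is.na(s0$t_statistic))

  expect_error(summarize_diffs(pp_from(0, 0)), "at least 2")
})

test_that("overall mean is the count-weighted subgroup mean", {
  set.seed(9)
  pp <- pp_from(rnorm(40), rnorm(40), censored = rep(c(TRUE, FALSE), 20))
  s <- summarize_diffs(pp)
  expect_equal(s$n_total, s$n_censored + s$n_uncensored)
  expect_equal(s$prop_censored, s$n_censored / s$n_total)
  expect_equal(
    (s$mean_diff_censored * s$n_censored +
       s$mean_diff_uncensored * s$n_uncensored) / s$n_total,
    s$mean_diff_all)
})

test_that("OLS fit matches closed-form normal equations", {
  # exact identity line
  f1 <- fit_line(pp_from(c(-10, -5, 0, 5), c(-10, -5, 0, 5)))
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$intercept, 0, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)

  f2 <- fit_line(pp_from(c(0, 1, 2), c(0, 2, 4)))
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 0, tolerance = 1e-12)

  # closed-form oracle on noisy data
  set.seed(4)
  x <- rnorm(25, -8, 5); y <- 0.9 * x - 0.3 + rnorm(25)
  f3 <- fit_line(pp_from(x, y))
  b_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a_hat <- mean(y) - b_hat * mean(x)
  expect_equal(f3$slope, b_hat, tolerance = 1e-10)
  expect_equal(f3$intercept, a_hat, tolerance = 1e-10)
  expect_equal(f3$r_squared, stats::cor(x, y)^2, tolerance = 1e-10)

  expect_error(fit_line(pp_from(c(1, 1, 1), c(0, 1, 2))), "identical")
  expect_error(fit_line(pp_from(c(1, 2), c(0, 1))), "at least 3")
})

test_that("OLS agrees with brute-force SSE minimization on a toy", {
  set.seed(11)
  x <- runif(10, -15, 0); y <- x + rnorm(10, 0, 2)
  f <- fit_line(pp_from(x, y))
  # nested grid refinement of (intercept, slope) over the SSE surface
  a <- 0; b <- 1; half_a <- 10; half_b <- 2
  for (round in 1:8) {
    as <- seq(a - half_a, a + half_a, length.out = 41)
    bs <- seq(b - half_b, b + half_b, length.out = 41)
    sse <- outer(as, bs, function(ai, bi)
      vapply(seq_along(ai), function(k)
        sum((y - ai[k] - bi[k] * x)^2), numeric(1)))
    w <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    a <- as[w[1]]; b <- bs[w[2]]
    half_a <- half_a / 10; half_b <- half_b / 10
  }
  expect_equal(f$intercept, a, tolerance = 5e-4)
  expect_equal(f$slope, b, tolerance = 5e-4)
})

test_that("Bland-Altman limits follow mean(d) +/- k * sd(d)", {
  ba0 <- bland_altman(pp_from(c(1, 2), c(1, 2)))
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba <- bland_altman(pp_from(c(0, 0), c(1, -1)))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -2 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$table$mean, c(0.5, -0.5))

  ba196 <- bland_altman(pp_from(c(0, 0), c(1, -1)), k_sd = 1.96)
  expect_equal(ba196$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_error(bland_altman(pp_from(0, 0)), "at least 2")
})

test_that("2-SD limits cover about 95% of Gaussian differences", {
  set.seed(21)
  n <- 1e4
  pp <- pp_from(rnorm(n, -5, 3), rnorm(n, -5, 3))
  ba <- bland_altman(pp)
  inside <- mean(ba$table$diff > ba$loa_low & ba$table$diff < ba$loa_high)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
})

test_that("swapping stimulus roles negates the analysis", {
  set.seed(13)
  x <- rnorm(30, -6, 4); y <- x + rnorm(30)
  pp <- pp_from(x, y)
  pp_sw <- pp_from(y, x)
  s <- summarize_diffs(pp); s_sw <- summarize_diffs(pp_sw)
  expect_equal(s_sw$mean_diff_all, -s$mean_diff_all)
  expect_equal(s_sw$t_statistic, -s$t_statistic)
  ba <- bland_altman(pp); ba_sw <- bland_altman(pp_sw)
  expect_equal(ba_sw$loa_low, -ba$loa_high)
  expect_equal(ba_sw$loa_high, -ba$loa_low)
  # slope inverts exactly only on a perfect line
  exact <- pp_from(c(-9, -6, -3, 0), c(-17, -11, -5, 1))  # y = 2x + 1
  expect_equal(fit_line(pp_from(exact$td_v_db, exact$td_iii_db))$slope,
               1 / fit_line(exact)$slope, tolerance = 1e-12)
})

test_that("the agreement object bundles all components coherently", {
  set.seed(17)
  n3 <- flat_norm("III"); n5 <- flat_norm("V")
  pairs <- lapply(1:5, function(i)
    make_pair(sample(5:35, 52, TRUE), sample(5:35, 52, TRUE),
              subject = paste0("s", i)))
  pp <- make_point_pairs(pairs, censor_config(21, 24), n3, n5)
  agr <- vf_agreement(pp)
  expect_s3_class(agr, "vf_agreement")
  expect_equal(agr$n_total, 260L)
  expect_equal(unname(coef(agr)["slope"]), agr$fit$slope)
  expect_equal(agr$bland_altman$mean_diff, agr$mean_diff_all)
  expect_output(print(agr), "Agreement")
})

test_that("cluster bootstrap brackets the pooled mean difference", {
  set.seed(19)
  pairs <- lapply(1:8, function(i)
    make_pair(sample(10:35, 52, TRUE), sample(10:35, 52, TRUE),
              subject = paste0("s", i), session = paste0("d", i)))
  pp <- make_point_pairs(pairs, censor_config(21, 24),
                         flat_norm("III"), flat_norm("V"))
  cb <- cluster_bootstrap_diff(pp, n_boot = 200, seed = 3)
  expect_equal(cb$n_clusters, 8L)
  expect_lt(cb$ci_low, cb$mean_diff)
  expect_gt(cb$ci_high, cb$mean_diff)
})
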