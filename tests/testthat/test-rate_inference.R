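test_that("ploidy estimation recovers a noiseless aneuploid karyotype and bias", {
  k <- rep(2L, 22); k[7] <- 3L; k[10] <- 1L
  fx <- generate_expression_fixture(k, bias = 0.8, noise_sigma = 0, seed = 3)
  est <- estimate_ploidy(fx)
  expect_equal(est$copies, k)
  expect_equal(est$scale, 0.8, tolerance = 1e-12)
  expect_equal(est$bias, 0.2, tolerance = 1e-12)
  expect_equal(min(est$error_profile$error), 0, tolerance = 1e-20)
  # assumed-diploid chromosomes are reported as copy 2
  expect_true(all(est$table$copies[est$table$assumed_diploid] == 2L))
})

test_that("a fully diploid tumor yields all 2s with x* = 1 by the tie rule", {
  fx <- generate_expression_fixture(rep(2L, 22), bias = 1.3, noise_sigma = 0,
                                    seed = 5)
  est <- estimate_ploidy(fx)
  expect_equal(est$copies, rep(2L, 22))
  expect_equal(est$x_star, 1L)
  expect_true(all(est$error_profile$error < 1e-20))
})

test_that("subclonal (half-integer) SCNAs inflate the rounding error but stay integer", {
  k <- rep(2L, 22)
  fx <- generate_expression_fixture(k, bias = 1, noise_sigma = 0, seed = 8)
  # overwrite chr5 with a 2.5-copy expression ratio (subclonal SCNA) and make
  # it look significant
  fx$tumor_mean[5] <- 1.25 * fx$normal_mean[5]
  fx$de_pvalue[5] <- 1e-6
  est <- estimate_ploidy(fx)
  expect_gt(min(est$error_profile$error), 1e-3)
  expect_true(all(est$copies == round(est$copies)))
})

test_that("copy calls are invariant to rescaling all tumor means", {
  k <- random_karyotype(seed = 21)
  fx <- generate_expression_fixture(k, bias = 1.1, noise_sigma = 0.01, seed = 22)
  est1 <- estimate_ploidy(fx)
  fx2 <- dplyr::mutate(fx, tumor_mean = tumor_mean * 7.3)
  est2 <- estimate_ploidy(fx2)
  expect_equal(est2$copies, est1$copies)       # scale absorbed into bias
  expect_equal(est2$scale, 7.3 * est1$scale, tolerance = 1e-12)
})

test_that("ploidy estimation recovers random karyotypes under realistic noise", {
  n_trials <- 200
  exact0 <- 0
  exact <- 0
  for (s in seq_len(n_trials)) {
    k <- random_karyotype(seed = 1000 + s)
    bias <- withr::with_seed(2000 + s, stats::runif(1, 0.5, 1.5))
    fx0 <- generate_expression_fixture(k, bias = bias, noise_sigma = 0,
                                       seed = 3000 + s)
    if (identical(estimate_ploidy(fx0)$copies, k)) exact0 <- exact0 + 1
    fx <- generate_expression_fixture(k, bias = bias, noise_sigma = 0.02,
                                      seed = 3000 + s)
    if (identical(estimate_ploidy(fx)$copies, k)) exact <- exact + 1
  }
  expect_equal(exact0, n_trials)              # noiseless: always exact
  expect_gte(exact / n_trials, 0.95)          # sigma = 0.02: >= 95% exact
})

test_that("estimate_ploidy validates its inputs", {
  fx <- generate_expression_fixture(rep(2L, 22), seed = 1)
  bad <- fx; bad$normal_mean[3] <- 0
  expect_error(estimate_ploidy(bad), "positive")
  expect_error(estimate_ploidy(fx[, 1:2]), "missing column")
})

test_that("linear calibration fits exactly and degrades to noise correctly", {
  # exact line through 2 points
  two <- tibble::tibble(x = c(1, 2), y = c(2.1, 4.1))
  fit2 <- fit_linear_calibration(two)
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0.1, tolerance = 1e-12)

  # noiseless 5-point line recovered with adjusted R^2 = 1
  tab <- generate_calibration_table(-0.5, 3, x_grid = 1:5, noise_sd = 0)
  fit <- fit_linear_calibration(tab, response_name = "turnover")
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 3, tolerance = 1e-12)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-9)

  # permuting responses destroys the association
  perm <- withr::with_seed(9, tibble::tibble(x = seq(0, 1, length.out = 40),
                                             y = sample(2 * x + 1)))
  fit_null <- fit_linear_calibration(perm)
  expect_lt(abs(fit_null$adj_r_squared), 0.2)

  expect_error(fit_linear_calibration(tibble::tibble(x = rep(1, 5), y = 1:5)),
               "degenerate")
})

test_that("turnover prediction is affine and flags beyond-homeostasis cells", {
  tab <- generate_calibration_table(2, 0.1, x_grid = c(0, 0.5), noise_sd = 0)
  fit <- fit_linear_calibration(tab, response_name = "turnover")
  out <- predict_turnover(fit, 0.3)
  expect_equal(out$turnover, 0.7, tolerance = 1e-12)
  expect_false(out$exceeds_homeostasis)
  expect_message(out2 <- predict_turnover(fit, 0.47), "turnover > 1")
  expect_equal(out2$turnover, 1.04, tolerance = 1e-12)
  expect_true(out2$exceeds_homeostasis)
  # zero slope: constant turnover
  fit0 <- fit_linear_calibration(tibble::tibble(x = c(0, 1), y = c(0.4, 0.4)))
  expect_equal(predict_turnover(fit0, c(-2, 5))$turnover, c(0.4, 0.4))
})

test_that("missegregation prediction inverts the log2-percent response and divides by ploidy", {
  # identity calibration: L = gamma
  ident <- fit_linear_calibration(tibble::tibble(x = c(0, 1), y = c(0, 1)),
                                  response_name = "log2_pct_lagging")
  out <- predict_missegregation(ident, gamma = 3, ploidy = 4)
  expect_equal(out$per_division_rate, 0.08)   # 2^3 percent
  expect_equal(out$beta, 0.02)
  expect_false(out$clipped)

  # L = log2(100): a certain missegregation, clipped at 1 for ploidy 1
  expect_message(
    outc <- predict_missegregation(ident, gamma = log2(150), ploidy = 1),
    "clipped")
  expect_equal(outc$beta, 1)
  expect_true(outc$clipped)

  # constant calibration: beta = 0.05 / ploidy
  const5 <- fit_linear_calibration(tibble::tibble(x = c(0, 1),
                                                  y = rep(log2(5), 2)),
                                   response_name = "log2_pct_lagging")
  out3 <- predict_missegregation(const5, gamma = c(0.2, 0.9), ploidy = c(2, 5))
  expect_equal(out3$beta, 0.05 / c(2, 5), tolerance = 1e-12)
  expect_error(predict_missegregation(ident, 1, ploidy = 0), "ploidy")
})

test_that("calibration round-trip reproduces the generating line exactly", {
  for (ab in list(c(2, 0.1), c(-0.5, 3), c(0, 0.7))) {
    tab <- generate_calibration_table(ab[1], ab[2], x_grid = seq(0, 1, 0.25),
                                      noise_sd = 0)
    fit <- fit_linear_calibration(tab)
    expect_equal(predict_turnover(fit, tab$x)$turnover, tab$y,
                 tolerance = 1e-12)
  }
})

test_that("tidiers expose per-chromosome tables and one-row summaries", {
  k <- rep(2L, 22); k[4] <- 4L
  fx <- generate_expression_fixture(k, bias = 0.9, noise_sigma = 0, seed = 2)
  est <- estimate_ploidy(fx)
  td <- tidy(est)
  expect_equal(nrow(td), 22L)
  expect_equal(td$copies[4], 4L)
  g <- glance(est)
  expect_equal(g$ploidy, sum(k))
  fit <- fit_linear_calibration(generate_calibration_table(1, 0, 1:4))
  expect_equal(tidy(fit)$estimate, c(0, 1), tolerance = 1e-12)
  expect_equal(glance(fit)$n, 4L)
})
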