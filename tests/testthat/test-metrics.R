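perfect_ps <- function(n = 10, seed = 1) {
  withr::with_seed(seed, {
    e <- runif(n, -4, 3)
    tibble::tibble(solute_id = sprintf("S%02d", 1:n), predicted = e,
                   experimental = e)
  })
}

test_that("error statistics match hand arithmetic on 3-point sets", {
  ps <- data.frame(solute_id = c("a", "b", "c"), predicted = c(1, -1, 2),
                   experimental = c(0, 0, 0))
  es <- error_stats(ps)
  expect_equal(es$mse, 2 / 3)
  expect_equal(es$aue, 4 / 3)
  expect_equal(es$rmse, sqrt(2))
  expect_equal(unlist(error_stats(perfect_ps())), c(mse = 0, aue = 0, rmse = 0))
})

test_that("rmse >= aue >= |mse| on random sets (property)", {
  for (seed in 1:30) {
    ps <- gen_prediction_set(prediction_set_spec(
      n_solutes = 5 + seed %% 20, slope = 1 + seed / 30, bias = seed / 10 - 1,
      noise_sigma = 1, seed = seed))
    es <- error_stats(ps)
    expect_gte(es$rmse + 1e-12, es$aue)
    expect_gte(es$aue + 1e-12, abs(es$mse))
  }
})

test_that("pearson_r matches the covariance formula and handles exact fits", {
  ps <- perfect_ps(8, seed = 2)
  ps$predicted <- 2 * ps$experimental + 1
  expect_equal(pearson_r(ps), 1.0)
  ps$predicted <- -ps$experimental
  expect_equal(pearson_r(ps), -1.0)
  ps5 <- gen_prediction_set(prediction_set_spec(n_solutes = 5, noise_sigma = 2,
                                                seed = 3))
  expect_equal(pearson_r(ps5), pearson_oracle(ps5$predicted, ps5$experimental),
               tolerance = 1e-12)
})

test_that("zero-variance input is an explicit undefined signal, not 0", {
  ps <- perfect_ps(6, seed = 4)
  ps$predicted <- 0
  expect_warning(r <- pearson_r(ps), class = "dielbal_undefined_correlation")
  expect_true(is.na(r))
  expect_warning(tau <- kendall_tau(ps), class = "dielbal_undefined_correlation")
  expect_true(is.na(tau))
})

test_that("kendall_tau is exact on ordered sets and one adjacent swap", {
  ps <- perfect_ps(7, seed = 5)
  ps$predicted <- rank(ps$experimental) # same ordering, no ties
  expect_equal(kendall_tau(ps), 1.0)
  swap <- data.frame(solute_id = c("a", "b", "c"), experimental = c(1, 2, 3),
                     predicted = c(1, 3, 2))
  expect_equal(kendall_tau(swap), 1 / 3)
})

test_that("kendall_tau equals O(n^2) pair enumeration on 100 random sets", {
  for (seed in 1:100) {
    withr::with_seed(seed, {
      n <- 10
      x <- sample(1:6, n, replace = TRUE) # ties likely
      y <- x + sample(-2:2, n, replace = TRUE)
    })
    ps <- tibble::tibble(solute_id = seq_len(10), predicted = x,
                         experimental = y)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    expect_equal(kendall_tau(ps), tau_b_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("bootstrap is seed-deterministic and degenerates to zero spread", {
  ps <- gen_prediction_set(prediction_set_spec(n_solutes = 20, noise_sigma = 1,
                                               seed = 6))
  a <- bootstrap_metric(ps, "mse", n_boot = 300, seed = 42)
  b <- bootstrap_metric(ps, "mse", n_boot = 300, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, bootstrap_metric(ps, "mse", n_boot = 300, seed = 43)))
  zero <- perfect_ps(12, seed = 7)
  expect_equal(bootstrap_metric(zero, "mse", n_boot = 200, seed = 1)$stddev, 0)
  expect_error(bootstrap_metric(ps, "nope", n_boot = 200),
               class = "dielbal_value_error")
  expect_error(bootstrap_metric(ps, "mse", n_boot = 10),
               class = "dielbal_value_error")
})

test_that("error_profile orders by experimental value with id tie-break", {
  ps <- data.frame(solute_id = c("b", "a", "c"), predicted = c(1, 2, 3),
                   experimental = c(0.5, 0.5, -1))
  prof <- error_profile(ps)
  expect_equal(prof$solute_id, c("c", "a", "b"))
  expect_equal(prof$signed_error, c(4, 1.5, 0.5))
})

test_that("a positive error slope shows in the profile's sign pattern", {
  ps <- gen_prediction_set(prediction_set_spec(n_solutes = 40, slope = 2,
                                               bias = 0, noise_sigma = 0.2,
                                               seed = 8))
  prof <- error_profile(ps)
  lead <- head(prof$signed_error, 10)
  trail <- tail(prof$signed_error, 10)
  expect_gt(mean(lead < 0), 0.8)
  expect_gt(mean(trail > 0), 0.8)
})

test_that("dynamic range is max minus min", {
  expect_equal(dynamic_range(c(-4, 3)), 7.0)
  expect_equal(dynamic_range(rep(1.3, 5)), 0.0)
  expect_equal(dynamic_range(c(1.5, -2.5, 0)), 4.0)
})

test_that("evaluate populates every field coherently", {
  ps <- perfect_ps(15, seed = 9)
  rep <- evaluate(ps, n_boot = 200, seed = 1)
  expect_equal(rep$mse, 0)
  expect_equal(rep$rmse, 0)
  expect_equal(rep$pearson_r, 1.0)
  expect_equal(rep$ols_slope, 1.0)
  expect_equal(rep$ols_intercept, 0.0, tolerance = 1e-12)
  g <- glance(rep)
  expect_equal(nrow(g), 1L)
  td <- tidy(rep)
  expect_true(all(c("metric", "value", "boot_mean", "boot_stddev") %in% names(td)))
  expect_equal(td$value[td$metric == "rmse"], 0)
})

test_that("evaluating the null baseline gives aue = mean |experimental|", {
  ps <- gen_prediction_set(prediction_set_spec(n_solutes = 53, seed = 10))
  ps$predicted <- null_baseline(ps$solute_id)$predicted
  rep <- evaluate(ps, n_boot = 200, seed = 1)
  expect_equal(rep$aue, mean(abs(ps$experimental)))
  expect_equal(rep$rmse, sqrt(mean(ps$experimental^2)))
  expect_true(is.na(rep$pearson_r))
  expect_true(is.na(rep$kendall_tau))
  expect_equal(rep$dynamic_range_pred, 0)
})

test_that("evaluate recovers a generator's slope and analytic mse", {
  spec <- prediction_set_spec(n_solutes = 50, slope = 2, bias = 1,
                              noise_sigma = 0, seed = 11)
  ps <- gen_prediction_set(spec)
  rep <- evaluate(ps, n_boot = 200, seed = 1)
  expect_equal(rep$ols_slope, 2.0, tolerance = 1e-9)
  expect_equal(rep$mse, 1 + mean(ps$experimental), tolerance = 1e-9)
  expect_equal(rep$dynamic_range_pred, 2 * rep$dynamic_range_exp,
               tolerance = 1e-9)
})

test_that("metrics are scale-equivariant (property)", {
  ps <- gen_prediction_set(prediction_set_spec(n_solutes = 25, slope = 1.4,
                                               noise_sigma = 0.8, seed = 12))
  for (c_scale in c(0.5, 2, 10)) {
    ps2 <- dplyr::mutate(ps, predicted = c_scale * predicted,
                         experimental = c_scale * experimental)
    expect_equal(unlist(error_stats(ps2)), c_scale * unlist(error_stats(ps)),
                 tolerance = 1e-12)
    expect_equal(pearson_r(ps2), pearson_r(ps), tolerance = 1e-12)
    expect_equal(kendall_tau(ps2), kendall_tau(ps), tolerance = 1e-12)
  }
})

test_that("report plots build without error", {
  ps <- gen_prediction_set(prediction_set_spec(n_solutes = 20, slope = 1.5,
                                               noise_sigma = 0.5, seed = 13))
  rep <- evaluate(ps, n_boot = 200, seed = 1)
  p1 <- autoplot(rep)
  p2 <- plot_error_profile(ps)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
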