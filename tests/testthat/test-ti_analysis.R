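test_that("default schedules match the published lambda grids", {
  np <- default_schedule("nonpolar")
  expect_equal(np$values, c(0.0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.55, 0.6,
                            0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95, 1.0))
  pol <- default_schedule("polar")
  expect_length(pol$values, 6L)
  expect_equal(pol$values, c(0.0, 0.2, 0.4, 0.6, 0.8, 1.0))
  expect_error(default_schedule("other"))
})

test_that("lambda schedules enforce their invariants", {
  expect_error(lambda_schedule(c(0, 0.5)), class = "dielbal_value_error")
  expect_error(lambda_schedule(c(0, 0.5, 0.5, 1)), class = "dielbal_value_error")
  expect_error(lambda_schedule(1), class = "dielbal_value_error")
})

test_that("window_mean block-averages: mean of all samples, stderr of block means", {
  expect_equal(window_mean(c(1, 3), n_blocks = 2),
               list(mean = 2.0, stderr = 1.0))
  wm <- window_mean(rep(4.2, 50), n_blocks = 5)
  expect_equal(wm$mean, 4.2)
  expect_equal(wm$stderr, 0.0)
  expect_error(window_mean(c(1, 2), n_blocks = 3), class = "dielbal_value_error")
})

test_that("block stderr tracks the i.i.d. closed form sigma/sqrt(n)", {
  # for uncorrelated samples the block estimate targets sd(x)/sqrt(n);
  # average over seeds to beat its own sampling noise
  n <- 1000
  sigma <- 3
  est <- vapply(1:100, function(seed) {
    withr::with_seed(seed, window_mean(rnorm(n, 0, sigma), n_blocks = 5)$stderr)
  }, 0)
  expect_equal(mean(est), sigma / sqrt(n), tolerance = 0.2)
})

test_that("trapezoid integration is exact for constant and affine integrands", {
  for (leg in c("nonpolar", "polar")) {
    s <- default_schedule(leg)
    expect_equal(integrate_ti(s, rep(-5, length(s$values)))$dG, -5.0)
    expect_equal(integrate_ti(s, 12 * s$values)$dG, 6.0)
    expect_equal(integrate_ti(s, 3 - 4 * s$values)$dG, 1.0)
  }
  # arbitrary uneven valid schedule
  s2 <- lambda_schedule(c(0, 0.13, 0.4, 0.77, 1), "nonpolar")
  expect_equal(integrate_ti(s2, 2 + 7 * s2$values)$dG, 5.5)
})

test_that("quadratic integrand matches the fine-grid interpolant oracle", {
  s <- default_schedule("nonpolar")
  means <- 3 * s$values^2
  got <- integrate_ti(s, means)$dG
  expect_equal(got, 1.0, tolerance = 0.01)
  oracle <- trapz_interp_oracle(s$values, means)
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("integration is linear and reverses with the integrand (property)", {
  s <- default_schedule("nonpolar")
  for (seed in 1:20) {
    withr::with_seed(seed, {
      f <- rnorm(length(s$values))
      g <- rnorm(length(s$values))
      a <- runif(1, -3, 3)
    })
    expect_equal(integrate_ti(s, a * f + g)$dG,
                 a * integrate_ti(s, f)$dG + integrate_ti(s, g)$dG,
                 tolerance = 1e-12)
    expect_equal(integrate_ti(s, -f)$dG, -integrate_ti(s, f)$dG)
  }
})

test_that("uncertainty propagates stderrs through trapezoid weights in quadrature", {
  s <- lambda_schedule(c(0, 0.5, 1), "polar")
  # weights are (0.25, 0.5, 0.25)
  res <- integrate_ti(s, c(0, 0, 0), stderrs = c(4, 2, 4))
  expect_equal(res$uncertainty, sqrt((0.25 * 4)^2 + (0.5 * 2)^2 + (0.25 * 4)^2))
  expect_error(integrate_ti(s, c(0, 0)), class = "dielbal_value_error")
})

test_that("ti_windows reduces long and summary tables identically", {
  s <- default_schedule("polar")
  long <- gen_ti_windows(ti_profile_spec(c(1, 2), noise_sigma = 0,
                                         samples_per_window = 50), s)$windows
  w <- ti_windows(long)
  expect_equal(w$lambda, s$values)
  expect_equal(w$mean, 1 + 2 * s$values, tolerance = 1e-12)
  expect_equal(w$stderr, rep(0, 6))
  summ <- ti_windows(data.frame(lambda = s$values, mean = 1 + 2 * s$values,
                                stderr = 0.1))
  expect_equal(summ$mean, w$mean)
})

test_that("solvation free energy is the sum of the two legs", {
  np <- data.frame(lambda = default_schedule("nonpolar")$values, mean = 2,
                   stderr = 0)
  pol <- data.frame(lambda = default_schedule("polar")$values, mean = -12,
                    stderr = 0)
  res <- solvation_free_energy(np, pol, "sol", "wat")
  expect_equal(res$dG_np, 2.0)
  expect_equal(res$dG_pol, -12.0)
  expect_equal(res$dG_solv, -10.0)
  expect_identical(res$dG_solv, res$dG_np + res$dG_pol)
})

test_that("leg uncertainties of 0.3 and 0.4 combine to 0.5", {
  # single-interval schedules make the leg uncertainty equal the
  # quadrature sum of its two half-weighted windows; build legs whose
  # totals are exactly 0.3 and 0.4
  s <- lambda_schedule(c(0, 1), "polar")
  u_np <- integrate_ti(s, c(0, 0), stderrs = c(0.3, 0.3) * sqrt(2))$uncertainty
  u_pol <- integrate_ti(s, c(0, 0), stderrs = c(0.4, 0.4) * sqrt(2))$uncertainty
  expect_equal(u_np, 0.3, tolerance = 1e-12)
  expect_equal(u_pol, 0.4, tolerance = 1e-12)
  expect_equal(sqrt(u_np^2 + u_pol^2), 0.5, tolerance = 1e-12)

  np <- data.frame(lambda = c(0, 1), mean = 0, stderr = 0.3 * sqrt(2))
  pol <- data.frame(lambda = c(0, 1), mean = 0, stderr = 0.4 * sqrt(2))
  expect_equal(solvation_free_energy(np, pol)$uncertainty, 0.5,
               tolerance = 1e-12)
})

test_that("both legs zero gives zero free energy and zero uncertainty", {
  np <- data.frame(lambda = default_schedule("nonpolar")$values, mean = 0,
                   stderr = 0)
  pol <- data.frame(lambda = default_schedule("polar")$values, mean = 0,
                    stderr = 0)
  res <- solvation_free_energy(np, pol)
  expect_equal(res$dG_solv, 0.0)
  expect_equal(res$uncertainty, 0.0)
})

test_that("equilibration discard drops the leading fraction of samples", {
  d <- data.frame(lambda = rep(c(0, 1), each = 10),
                  sample = rep(c(100, 1), times = c(5, 15)))
  # first half of the lambda=0 window is the value 100
  w0 <- ti_windows(d, n_blocks = 2, discard_fraction = 0.5)
  expect_equal(w0$mean[w0$lambda == 0], 1)
  expect_equal(w0$n_samples[w0$lambda == 0], 5L)
})
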