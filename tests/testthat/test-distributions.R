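test_that("Carothers mean DP and its inverse agree on exact values and round-trip", {
  expect_equal(carothers_mean_dp(0), 1)
  expect_equal(carothers_mean_dp(2 / 3), 5)
  expect_equal(carothers_mean_dp(9 / 11), 10)
  expect_equal(imbalance_for_mean_dp(1), 0)
  expect_equal(imbalance_for_mean_dp(5), 2 / 3)
  expect_equal(imbalance_for_mean_dp(10), 9 / 11)

  r <- seq(0, 0.99, by = 0.07)
  expect_equal(imbalance_for_mean_dp(carothers_mean_dp(r)), r, tolerance = 1e-12)
  expect_true(all(diff(carothers_mean_dp(r)) > 0))

  expect_error(carothers_mean_dp(1), "must be numeric")
  expect_error(carothers_mean_dp(-0.1), "must be numeric")
  expect_error(imbalance_for_mean_dp(0.5), ">= 1")
})

test_that("odd-length Flory pmf normalizes over odd x and has the Carothers mean", {
  expect_equal(flory_odd_pmf(1, 0), 1)
  expect_equal(flory_odd_pmf(1, 0.37), 1 - 0.37)
  expect_equal(flory_odd_pmf(c(2, 4, 6), 0.5), c(0, 0, 0))

  for (r in c(0.2, 2 / 3, 9 / 11)) {
    x <- seq(1, 4001, by = 2)
    p <- flory_odd_pmf(x, r)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(sum(x * p), carothers_mean_dp(r), tolerance = 1e-9)
  }
})

test_that("standard Flory pmf matches direct evaluation and mean 1/(1-p)", {
  expect_equal(flory_pmf(1, 0), 1)
  expect_equal(flory_pmf(2, 0.5), 0.25)
  y <- 1:2000
  p <- flory_pmf(y, 0.9)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(sum(y * p), 10, tolerance = 1e-6)
})

test_that("samplers are degenerate at zero and hit their analytic means", {
  withr::with_seed(1, {
    expect_true(all(sample_flory_odd(100, 0) == 1L))
    expect_true(all(sample_flory(100, 0) == 1L))

    x5 <- sample_flory_odd(1e5, 2 / 3)
    expect_true(all(x5 %% 2L == 1L))
    expect_equal(mean(x5), 5, tolerance = 0.05 / 5)

    x10 <- sample_flory_odd(1e5, 9 / 11)
    expect_equal(mean(x10), 10, tolerance = 0.1 / 10)

    y9 <- sample_flory(1e5, 0.9)
    expect_true(all(y9 >= 1L))
    expect_equal(mean(y9), 10, tolerance = 0.1 / 10)
    y5 <- sample_flory(1e5, 0.5)
    expect_equal(mean(y5), 2, tolerance = 0.02 / 2)
  })
})

test_that("sampled lengths match their pmfs (chi-square, alpha = 0.01)", {
  withr::with_seed(7, {
    x <- sample_flory_odd(5e4, 2 / 3)
    cap <- 41 # pool the geometric tail so expected counts stay above ~5
    x_cap <- pmin(x, cap)
    lev <- seq(1, cap, by = 2)
    obs <- tabulate(factor(x_cap, levels = lev))
    prob <- flory_odd_pmf(lev, 2 / 3)
    prob[length(prob)] <- 1 - sum(prob[-length(prob)])
    expect_gt(stats::chisq.test(obs, p = prob)$p.value, 0.01)

    y <- sample_flory(5e4, 0.9)
    cap_y <- 60
    y_cap <- pmin(y, cap_y)
    obs_y <- tabulate(factor(y_cap, levels = 1:cap_y))
    prob_y <- flory_pmf(1:cap_y, 0.9)
    prob_y[cap_y] <- 1 - sum(prob_y[-cap_y])
    expect_gt(stats::chisq.test(obs_y, p = prob_y)$p.value, 0.01)
  })
})

test_that("feed-fraction solver reproduces the published splits and round-trips", {
  all_acid <- solve_feed_fractions(0.20, 5, 10, share_in_acid = 1)
  expect_equal(all_acid$f_acid, 0.50)
  expect_equal(all_acid$f_diol, 0)

  all_diol <- solve_feed_fractions(0.20, 5, 10, share_in_acid = 0)
  expect_equal(all_diol$f_acid, 0)
  expect_equal(all_diol$f_diol, 1 / 3)

  balanced <- solve_feed_fractions(0.20, 5, 10, share_in_acid = 0.4)
  expect_equal(balanced$f_acid, 0.20)
  expect_equal(balanced$f_diol, 0.20)

  discrete <- solve_feed_fractions(0.20, 5, 11, share_in_acid = 1)
  expect_equal(discrete$f_acid, 1.6 / 3)

  # round-trip: recomputed overall U equals the requested budget
  withr::with_seed(3, {
    for (i in 1:25) {
      u <- runif(1, 0, 0.3)
      s <- runif(1)
      dpa <- runif(1, 1, 9)
      dpd <- runif(1, 3, 15)
      sol <- solve_feed_fractions(u, dpa, dpd, s)
      expect_equal(overall_u_fraction(sol$f_acid, sol$f_diol, dpa, dpd), u,
                   tolerance = 1e-12)
    }
  })

  expect_error(solve_feed_fractions(0.9, 5, 10, 1), "diacid pool")
  expect_error(solve_feed_fractions(0.9, 5, 10, 0), "diol pool")
})
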