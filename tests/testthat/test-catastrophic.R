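test_that("oop shares use the requested denominator and stay in [0, 1]", {
  ds <- toy_survey(total = c(100, 100, 50), food = c(50, 20, 50),
                   oop = c(10, 0, 0))
  expect_equal(oop_share(ds, "total_expenditure"), c(0.10, 0, 0))
  expect_equal(oop_share(ds, "capacity_to_pay"), c(0.20, 0, 0))
  # zero capacity with zero OOP is a 0 share, not NaN
  expect_equal(oop_share(ds, "capacity_to_pay")[3], 0)
  # OOP above capacity to pay clamps at 1 with a warning
  ds2 <- toy_survey(total = 100, food = 60, oop = 50)
  expect_warning(s <- oop_share(ds2, "capacity_to_pay"), "clamped")
  expect_equal(s, 1)
})

test_that("head count and overshoot match hand-enumerated values", {
  shares <- c(0.02, 0.08, 0.12, 0.30, 0.05)
  expect_equal(head_count(shares, 0.10), 0.40)
  ov <- overshoot(shares, 0.10)
  expect_equal(ov$household_overshoot, c(0, 0, 0.02, 0.20, 0))
  expect_equal(ov$mean_overshoot, 0.044)
  expect_equal(ov$mpo, 0.11)
  # exceedance is strict: shares at the threshold do not count
  expect_equal(head_count(rep(0.10, 4), 0.10), 0)
  expect_equal(overshoot(rep(0.10, 4), 0.10)$mean_overshoot, 0)
  # H = 0 leaves MPO undefined
  ov0 <- overshoot(c(0.01, 0.02), 0.10)
  expect_false(ov0$mpo_defined)
  expect_true(is.na(ov0$mpo))
  # weighted head count = sum(w E)/sum(w)
  expect_equal(head_count(shares, 0.10, weights = c(1, 1, 2, 1, 1)),
               3 / 6)
  expect_error(head_count(numeric(0), 0.1), class = "finprot_input_error")
})

test_that("concentration index matches the hand-computed worked example", {
  e <- c(0, 0, 0, 1, 1)
  x <- 1:5
  # r = (0.1, 0.3, 0.5, 0.7, 0.9); mu = 0.4; cov = 0.12; C = 0.6
  expect_equal(fractional_rank(x), seq(0.1, 0.9, by = 0.2))
  expect_equal(concentration_index(e, x), 0.6)
  # reversing the ranking flips the sign
  expect_equal(concentration_index(e, -x), -0.6)
  # constant outcome has zero covariance
  expect_equal(concentration_index(rep(2, 5), x), 0)
  expect_error(concentration_index(c(0, 0), 1:2),
               class = "finprot_undefined_error")
  expect_error(concentration_index(1, 1), class = "finprot_input_error")
})

test_that("concentration index agrees with the O(N^2) double-sum oracle", {
  for (seed in 1:6) {
    n <- withr::with_seed(seed, sample(5:200, 1))
    dat <- withr::with_seed(seed + 100, list(
      y = runif(n), x = rnorm(n), w = runif(n, 0.2, 3)))
    dat$y[1] <- dat$y[1] + 1  # ensure non-zero mean
    expect_equal(concentration_index(dat$y, dat$x),
                 oracle_concentration_index(dat$y, dat$x),
                 tolerance = 1e-10)
    expect_equal(concentration_index(dat$y, dat$x, weights = dat$w),
                 oracle_concentration_index(dat$y, dat$x, dat$w),
                 tolerance = 1e-10)
  }
})

test_that("fractional ranks handle ties deterministically, with an average option", {
  x <- c(5, 1, 5, 2)
  r <- fractional_rank(x)
  # ties keep input order: the first 5 ranks below the second
  expect_equal(r, c(0.625, 0.125, 0.875, 0.375))
  ra <- fractional_rank(x, tie_rank = "average")
  expect_equal(ra, c(0.75, 0.125, 0.75, 0.375))
  # weighted ranks are midpoints of the cumulative weight intervals
  expect_equal(fractional_rank(c(10, 20, 30), weights = c(1, 2, 1)),
               c(0.125, 0.5, 0.875))
})

test_that("rank-weighted measures equal the direct weighted sum (identity oracle)", {
  for (seed in c(3, 9, 27)) {
    ds <- random_survey(150, seed = seed)
    for (den in c("total_expenditure", "capacity_to_pay")) {
      res <- catastrophic_measures(ds, 0.1, den, weights_mode = "sampling")
      rank_var <- if (den == "total_expenditure") ds$total_expenditure
                  else capacity_to_pay(ds)
      r <- fractional_rank(rank_var, weights = ds$weight)
      expect_equal(res$weighted_head_count,
                   oracle_rank_weighted_mean(res$exceed_indicator, r, ds$weight),
                   tolerance = 1e-10)
      expect_equal(res$weighted_overshoot,
                   oracle_rank_weighted_mean(res$household_overshoot, r, ds$weight),
                   tolerance = 1e-10)
    }
  }
})

test_that("rank weighting moves measures in the direction of the concentration", {
  out <- rank_weighted_measures(H = 0.055, O = 0.0058, C_E = 0.09, C_O = 0.25)
  expect_equal(out$weighted_head_count, 0.05005)
  expect_equal(out$weighted_overshoot, 0.0058 * 0.75)
  expect_equal(rank_weighted_measures(H = 0.2, C_E = 0)$weighted_head_count, 0.2)
  # pro-poor concentration (negative index) inflates the weighted count
  expect_gt(rank_weighted_measures(H = 0.2, C_E = -0.3)$weighted_head_count, 0.2)
})

test_that("H and O are non-increasing in z and MPO decomposes O", {
  ds <- random_survey(400, seed = 5)
  for (den in c("total_expenditure", "capacity_to_pay")) {
    shares <- suppressWarnings(oop_share(ds, den))
    zs <- seq(0.02, 0.6, by = 0.02)
    h <- vapply(zs, function(z) head_count(shares, z), numeric(1))
    o <- vapply(zs, function(z) overshoot(shares, z)$mean_overshoot, numeric(1))
    expect_true(all(diff(h) <= 0))
    expect_true(all(diff(o) <= 0))
    for (z in c(0.05, 0.1, 0.25)) {
      ov <- overshoot(shares, z)
      h1 <- head_count(shares, z)
      if (h1 > 0) expect_equal(ov$mpo * h1, ov$mean_overshoot, tolerance = 1e-12)
    }
  }
  # capacity-to-pay shares dominate total-expenditure shares household-wise
  st <- oop_share(ds, "total_expenditure")
  sc <- suppressWarnings(oop_share(ds, "capacity_to_pay"))
  expect_true(all(sc >= st))
  expect_gte(head_count(sc, 0.1), head_count(st, 0.1))
})

test_that("concentration index is bounded by 1 for non-negative outcomes", {
  cs <- vapply(1:1000, function(seed) {
    dat <- withr::with_seed(seed, {
      n <- sample(2:40, 1)
      list(y = rexp(n) * rbinom(n, 1, 0.7) + 1e-9, x = rnorm(n),
           w = runif(n, 0.1, 5))
    })
    concentration_index(dat$y, dat$x, weights = dat$w)
  }, numeric(1))
  expect_true(all(abs(cs) <= 1))
})

test_that("catastrophic_table spans the default grid and small-N edge cases", {
  ds <- random_survey(300, seed = 21)
  tab <- suppressWarnings(catastrophic_table(ds))
  expect_length(tab, 7)
  expect_equal(vapply(tab, function(r) r$threshold, numeric(1)),
               default_thresholds()$z)
  expect_error(catastrophic_table(ds, default_thresholds()[0, ]),
               class = "finprot_input_error")
  # only the top-expenditure household exceeds -> strongly pro-rich index
  ds2 <- toy_survey(total = c(10, 20, 30, 40, 1000), food = rep(1, 5),
                    oop = c(0, 0, 0, 0, 500))
  res <- catastrophic_measures(ds2, 0.25, "total_expenditure")
  expect_equal(res$head_count, 0.2)
  expect_equal(res$ci_incidence, 0.8)  # 2*(0.9 - 0.5) for the richest unit
  expect_lt(res$weighted_head_count, res$head_count)
})
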