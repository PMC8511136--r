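test_that("time_to_cutoff recovers closed-form crossing times", {
  lam <- 0.04
  p <- model_params(lambda = lam, surviving_fraction = 0.5, epsilon = 0,
                    gamma0 = 0, V0 = 10)
  tr <- simulate_trajectory(p, numeric(0), c(0, 500))
  # untreated doubling: tau = ln 2 / lambda
  rec <- time_to_cutoff(tr, cutoff_volume = 20, horizon = 500)
  expect_true(rec$event)
  expect_lt(abs(rec$time - log(2) / lam), 0.01)
  # baseline already at/above the cutoff
  rec0 <- time_to_cutoff(tr, cutoff_volume = 5, horizon = 500)
  expect_equal(rec0$time, 0)
  expect_true(rec0$event)
  # censoring at the horizon when never crossed
  recc <- time_to_cutoff(tr, cutoff_volume = 1e12, horizon = 500)
  expect_false(recc$event)
  expect_equal(recc$time, 500)
  # fallback cutoff = 1.2 x baseline
  recf <- time_to_cutoff(tr, horizon = 500)
  expect_lt(abs(recf$time - log(1.2) / lam), 0.01)
  expect_error(time_to_cutoff(tr, cutoff_volume = -1), "cutoff")
})

test_that("time_to_cutoff agrees with a fine grid scan on treated arms", {
  set.seed(21)
  for (k in 1:5) {
    p <- random_params()
    arm <- simulate_arm(p, make_irt(n_fractions = 5, boost = TRUE,
                                    horizon = 1200))
    cutoff <- 1.5 * p$V0
    rec <- time_to_cutoff(arm, cutoff, horizon = 1200)
    ts <- seq(0, 1200, by = 0.001)
    vs <- trajectory_volume(arm$trajectory, ts)
    hit <- which(vs >= cutoff)
    if (length(hit) == 0) {
      expect_false(rec$event)
    } else {
      expect_true(rec$event)
      expect_lt(abs(rec$time - ts[hit[1]]), 0.01)
    }
  }
})

test_that("km_estimate matches the product-limit computation", {
  # all events at distinct times, no censoring
  r <- data.frame(time = 1:4, event = TRUE)
  km <- km_estimate(r)
  expect_equal(km$survival, c(1, 0.75, 0.5, 0.25, 0))
  # all censored: flat at 1
  km1 <- km_estimate(data.frame(time = c(5, 7), event = FALSE))
  expect_true(all(km1$survival == 1))
  # mixed censoring, hand product-limit: events at 1,3,5, censored 2,4
  km2 <- km_estimate(data.frame(time = 1:5,
                                event = c(TRUE, FALSE, TRUE, FALSE, TRUE)))
  s <- km2$survival[match(c(1, 3, 5), km2$time)]
  expect_equal(s, c(4 / 5, 4 / 5 * 2 / 3, 0))
  # no censoring: equals the empirical survival function
  set.seed(3)
  tt <- sample(1:50, 12)
  km3 <- km_estimate(data.frame(time = tt, event = TRUE))
  expect_equal(km3$survival[-1], 1 - ecdf(tt)(sort(unique(tt))))
  expect_error(km_estimate(data.frame()), "records")
})

test_that("logrank_test matches a hand hypergeometric tally", {
  # fully separated 5+5 example: every term written out
  a <- data.frame(time = 1:5, event = TRUE)
  b <- data.frame(time = 6:10, event = TRUE)
  # observed-minus-expected for group A at its event times; afterwards A's
  # risk set is empty and all terms vanish
  U <- (1 - 5 / 10) + (1 - 4 / 9) + (1 - 3 / 8) + (1 - 2 / 7) + (1 - 1 / 6)
  V <- (5 * 5) / 10^2 + (4 * 5) / 9^2 + (3 * 5) / 8^2 + (2 * 5) / 7^2 +
    (1 * 5) / 6^2
  lr <- logrank_test(a, b)
  expect_equal(lr$statistic, U^2 / V, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(U^2 / V, 1, lower.tail = FALSE))
  # identical groups: statistic 0, p 1
  lr0 <- logrank_test(a, a)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  # label swap symmetry
  lr_sw <- logrank_test(b, a)
  expect_equal(lr_sw$p_value, lr$p_value)
  expect_gte(lr$statistic, 0)
  # all-censored in both groups: warning and p = 1
  cens <- data.frame(time = c(10, 20), event = FALSE)
  expect_warning(lrc <- logrank_test(cens, cens), "no events")
  expect_equal(lrc$p_value, 1)
  expect_error(logrank_test(a, data.frame()), "non-empty")
})

test_that("ranksum_test enumerates exactly for tiny samples", {
  # x=(1,2) vs y=(3,4): W = 0; of the C(4,2) = 6 equally likely rank
  # assignments exactly one is as extreme each side -> two-sided p = 1/3
  rs <- ranksum_test(c(1, 2), c(3, 4))
  expect_equal(rs$p_value, 1 / 3)
  expect_equal(unname(rs$statistic), 0)
  # identical samples: p = 1
  x <- c(1, 2, 3)
  expect_equal(ranksum_test(x, x)$p_value, 1)
  # p invariant under common monotone transform (rank property)
  set.seed(8)
  u <- runif(6); v <- runif(7)
  expect_equal(ranksum_test(u, v)$p_value,
               ranksum_test(exp(5 * u), exp(5 * v))$p_value)
})

test_that("pearson_corr matches the direct formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_corr(x, 2 * x + 1)$rho, 1)
  expect_equal(pearson_corr(x, -x)$rho, -1)
  set.seed(5)
  a <- rnorm(10); b <- rnorm(10)
  pc <- pearson_corr(a, b)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pc$rho, r_direct, tolerance = 1e-12)
  tstat <- r_direct * sqrt(8 / (1 - r_direct^2))
  expect_equal(pc$p_value, 2 * pt(-abs(tstat), df = 8), tolerance = 1e-12)
  expect_error(pearson_corr(a, rep(1, 10)), "variance")
  expect_error(pearson_corr(1:2, 1:2), "length")
})

test_that("geud reduces correctly and matches direct summation", {
  uni <- data.frame(dose_gy = 35, fractional_volume = 1)
  expect_equal(geud(uni), 35)
  for (a in c(-10, -1, 2)) expect_equal(geud(uni, a), 35)
  dvh <- data.frame(dose_gy = c(30, 36), fractional_volume = c(0.5, 0.5))
  g <- geud(dvh, -10)
  expect_equal(g, (0.5 * 30^-10 + 0.5 * 36^-10)^(-1 / 10), tolerance = 1e-10)
  expect_true(g > 30 && g < 36 && g < 33) # nearer the minimum dose
  # monotone in every bin dose, bounded by [min, max] for a < 0
  dvh2 <- data.frame(dose_gy = c(31, 36), fractional_volume = c(0.5, 0.5))
  expect_gt(geud(dvh2, -10), g)
  expect_error(geud(data.frame(dose_gy = c(0, 30),
                               fractional_volume = c(0.5, 0.5))), "zero dose")
  expect_error(geud(dvh, 0), "exponent")
  expect_error(geud(data.frame(dose_gy = 30, fractional_volume = 0.8)),
               "sum to 1")
})

test_that("classify_group implements the four response groups", {
  expect_equal(classify_group(100, 60, 60), 1L)
  expect_equal(classify_group(100, 60, 120), 2L)
  expect_equal(classify_group(100, 110, 150), 3L)
  expect_equal(classify_group(100, 110, 110), 4L)
  expect_equal(classify_group(100, 100, 100), 4L)  # three-way tie
  # tolerance: within 1 day counts as equal
  expect_equal(classify_group(100, 99.5, 100.5), 4L)
  expect_equal(classify_group(100, 120, 120.5), 4L)
})
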