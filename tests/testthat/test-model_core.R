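test_that("live_volume_analytic matches exponential limits", {
  p <- model_params(lambda = 0.065, surviving_fraction = 0.5,
                    epsilon = 0.01, V0 = 1)
  # pure exponential doubling when the drug term is off
  expect_equal(live_volume_analytic(1, 0, p, 0, log(2) / 0.065), 2.0)
  # gamma = lambda with epsilon -> 0: growth and kill cancel
  p0 <- model_params(lambda = 0.065, surviving_fraction = 0.5,
                     epsilon = 0, V0 = 1)
  expect_equal(live_volume_analytic(5, 0.065, p0, 0, 123), 5)
})

test_that("live_volume_analytic agrees with the RK4 oracle", {
  p <- model_params(lambda = 0.065, surviving_fraction = 0.5,
                    epsilon = 0.01, gamma0 = 0.065, V0 = 10)
  got <- live_volume_analytic(10, 0.065, p, 0, 42)
  ref <- rk4_oracle(p, numeric(0), 42, h = 0.005)
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("live_volume_analytic validates its domain", {
  p <- model_params(lambda = 0.065, surviving_fraction = 0.5,
                    epsilon = 0.01, V0 = 1)
  expect_error(live_volume_analytic(1, 0, p, 10, 5), "t_ref")
  expect_error(live_volume_analytic(Inf, 0, p, 0, 5), "finite")
})

test_that("epsilon -> 0+ is continuous across the branch switch", {
  p_lim <- model_params(lambda = 0.065, surviving_fraction = 0.5,
                        epsilon = 0, V0 = 1)
  p_eps <- model_params(lambda = 0.065, surviving_fraction = 0.5,
                        epsilon = 1e-12, V0 = 1)
  for (t in c(1, 42, 300)) {
    a <- live_volume_analytic(7, 0.03, p_lim, 0, t)
    b <- live_volume_analytic(7, 0.03, p_eps, 0, t)
    expect_lt(abs(a / b - 1), 1e-6)
  }
})

test_that("dead_volume_decay follows one exponential half-life", {
  expect_equal(dead_volume_decay(0, 0.1, 17), 0)
  expect_equal(dead_volume_decay(3.4, 0.1, 0), 3.4)
  expect_equal(dead_volume_decay(8, 0.065, log(2) / 0.065), 4.0)
  expect_error(dead_volume_decay(1, 0.1, -1), "dt")
})

test_that("apply_fraction transfers (1-S) of viable volume, conserving total", {
  st <- tumor_state(0, 10, 2)
  expect_identical(apply_fraction(st, 1), st)
  z <- apply_fraction(tumor_state(0, 3, 1), 0)
  expect_equal(c(z$V_live, z$V_dead), c(0, 4))
  # the median fitted surviving fraction of the study cohort
  y <- apply_fraction(st, 0.41)
  expect_equal(c(y$V_live, y$V_dead), c(4.1, 7.9))
  expect_equal(y$V_live + y$V_dead, st$V_live + st$V_dead)
  expect_error(apply_fraction(st, 1.2), "surviving_fraction")
})

test_that("simulate_trajectory with S = 1 equals the untreated solution", {
  p <- model_params(lambda = 0.05, surviving_fraction = 1,
                    epsilon = 2e-3, gamma0 = 0.05, V0 = 12)
  te <- seq(0, 300, by = 10)
  tr <- simulate_trajectory(p, fraction_times = c(0, 42, 84, 126, 168),
                            eval_times = te)
  untreated <- live_volume_analytic(12, 0.05, p, 0, te)
  rows <- !tr$is_fraction_pre & !tr$is_fraction_post
  expect_equal(tr$V_total_cm3[rows], untreated[!(te %in% c(0, 42, 84, 126, 168))],
               tolerance = 1e-12)
  expect_equal(trajectory_volume(tr, te), untreated, tolerance = 1e-12)
})

test_that("single fraction at t0 with gamma0=lambda, eps=0 has closed form", {
  # live compartment is frozen (growth and kill cancel); the dead half decays
  lam <- 0.065
  p <- model_params(lambda = lam, surviving_fraction = 0.5, epsilon = 0,
                    gamma0 = lam, V0 = 8)
  t <- c(0, 5, 50, 200)
  tr <- simulate_trajectory(p, 0, t)
  expect_equal(trajectory_volume(tr, t), 4 + 4 * exp(-lam * t),
               tolerance = 1e-12)
})

test_that("trajectory table exposes the pre/post fraction discontinuity", {
  p <- model_params(lambda = 0.065, surviving_fraction = 0.4,
                    epsilon = 1e-3, V0 = 10)
  tr <- simulate_trajectory(p, c(0, 42), c(10, 42, 80))
  pre <- tr[tr$is_fraction_pre & tr$day == 42, ]
  post <- tr[tr$is_fraction_post & tr$day == 42, ]
  expect_equal(post$V_live_cm3, 0.4 * pre$V_live_cm3)
  expect_equal(post$V_total_cm3, pre$V_total_cm3) # conservation
  # eval day coinciding with a fraction is represented by the pair only
  expect_equal(sum(tr$day == 42), 2L)
  expect_error(simulate_trajectory(p, c(42, 0), c(10, 80)), "sorted")
  expect_error(simulate_trajectory(p, 0, c(80, 10)), "increasing")
})

test_that("simulate_trajectory matches the event-driven RK4 oracle", {
  # 10 random in-bounds draws, 5 intermittent fractions (the heavier
  # 50-draw sweep runs in the acceptance suite)
  set.seed(11)
  te <- seq(0, 210, by = 7)
  ft <- c(0, 42, 84, 126, 168)
  for (k in 1:10) {
    p <- random_params()
    got <- trajectory_volume(simulate_trajectory(p, ft, te), te)
    ref <- rk4_oracle(p, ft, te)
    expect_lt(max(abs(got / ref - 1)), 1e-8)
  }
})

test_that("volumes stay non-negative and respond monotonically", {
  set.seed(4)
  te <- seq(0, 400, by = 5)
  for (k in 1:10) {
    p <- random_params()
    v <- trajectory_volume(simulate_trajectory(p, c(0, 42, 84), te), te)
    expect_true(all(v >= 0))
  }
  # V(t) non-increasing in gamma0, non-decreasing in lambda (pointwise)
  base <- list(lambda = 0.05, surviving_fraction = 0.5, epsilon = 1e-3,
               V0 = 10)
  v_of <- function(lambda = base$lambda, gamma0 = 0.03) {
    p <- model_params(lambda = lambda, surviving_fraction = 0.5,
                      epsilon = 1e-3, gamma0 = gamma0, V0 = 10)
    trajectory_volume(simulate_trajectory(p, c(0, 42), te), te)
  }
  expect_true(all(v_of(gamma0 = 0.06) <= v_of(gamma0 = 0.03) + 1e-12))
  expect_true(all(v_of(lambda = 0.08) >= v_of(lambda = 0.05) - 1e-12))
})

test_that("model_params enforces the published bounds", {
  expect_error(model_params(lambda = 0.2, surviving_fraction = 0.5,
                            epsilon = 0.01, V0 = 1), "lambda")
  expect_error(model_params(surviving_fraction = -0.1, epsilon = 0.01,
                            V0 = 1), "surviving_fraction")
  expect_error(model_params(surviving_fraction = 0.5, epsilon = 0.2,
                            V0 = 1), "epsilon")
  expect_error(model_params(surviving_fraction = 0.5, epsilon = 0.01,
                            V0 = -1), "V0")
})
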