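test_that("the step fit reproduces worked examples and degenerate cases", {
  # perfect step: accepted at and below 12, rejected above
  fit <- fit_step_threshold(c(2, 5, 8, 12, 20, 26), c(1, 1, 1, 1, 0, 0), 30)
  expect_identical(fit$theta, 16.5)
  expect_identical(fit$loss, 0)
  expect_false(fit$clamped)

  all_in <- fit_step_threshold(1:30, rep(1, 30), 30)
  expect_identical(all_in$theta, 30.5)
  expect_true(all_in$clamped)

  all_out <- fit_step_threshold(1:30, rep(0, 30), 30)
  expect_identical(all_out$theta, 0.5)
  expect_true(all_out$clamped)

  expect_error(fit_step_threshold(1:3, c(1, 1, 0), 30), "Too few")

  td <- tidy(fit)
  expect_identical(td$theta, 16.5)
  expect_identical(glance(fit)$accuracy, 1)
})

test_that("the step fit matches an exhaustive brute force on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:120, 1)
    epoch_max <- sample(c(5, 15, 30), 1)
    offers <- sample(1:epoch_max, n, replace = TRUE)
    theta_true <- runif(1, 0, epoch_max)
    noise <- runif(n) < 0.2
    outcomes <- xor(offers < theta_true, noise)
    fit <- fit_step_threshold(offers, outcomes, epoch_max)
    expect_identical(fit$theta, brute_force_step(offers, outcomes, epoch_max))
  }
})

test_that("promoting sub-threshold offers to accepts never lowers theta", {
  set.seed(55)
  for (i in 1:40) {
    offers <- sample(1:30, 60, replace = TRUE)
    outcomes <- runif(60) < plogis(0.8 * (12 - offers))
    f1 <- fit_step_threshold(offers, outcomes, 30)
    raised <- outcomes | (offers < f1$theta)
    f2 <- fit_step_threshold(offers, raised, 30)
    expect_gte(f2$theta, f1$theta)
  }
})

test_that("block thresholds recover step-policy ground truth within the grid", {
  coh <- step_cohort()
  gt <- ground_truth_thresholds(coh)
  for (zone in c("OZ", "WZ")) {
    th <- block_thresholds(coh$trials, zone, days = c(18, 29))
    truth_col <- if (zone == "OZ") "theta_oz" else "theta_wz"
    j <- dplyr::inner_join(th, gt, by = c("mouse_id", "restaurant"))
    expect_identical(nrow(j), 16L)
    expect_true(all(abs(j$theta - j[[truth_col]]) <= 0.5))
  }
})

test_that("wait-zone fits use entered trials only; 1-s epochs clamp", {
  coh <- fixture_cohort()
  oz <- block_thresholds(coh$trials, "OZ", c(18, 26))
  wz <- block_thresholds(coh$trials, "WZ", c(18, 26))
  j <- dplyr::inner_join(oz, wz, by = c("mouse_id", "restaurant"),
                         suffix = c("_oz", "_wz"))
  expect_true(all(j$n_trials_wz <= j$n_trials_oz))

  one_s <- block_thresholds(coh$trials, "OZ", c(1, 7))
  expect_true(all(one_s$clamped[!is.na(one_s$theta)]))
  expect_true(all(one_s$theta[!is.na(one_s$theta)] %in% c(0.5, 1.5)))
})

test_that("daily fits report restaurants below the trial floor as missing", {
  coh <- fixture_cohort()
  daily <- block_thresholds(coh$trials, "WZ", c(18, 20), by = "day",
                            min_trials = 5)
  expect_true(all(c("day", "theta", "n_trials") %in% names(daily)))
  expect_true(all(is.na(daily$theta[daily$n_trials < 5])))
  expect_true(all(!is.na(daily$theta[daily$n_trials >= 5]) |
                    daily$n_trials[!is.na(daily$theta)] >= 5))
})

test_that("flavor ranking sorts by earnings with flagged stable ties", {
  s <- build_session(
    offer_s = rep(1, 12), oz_outcome = rep("enter", 12),
    wz_outcome = rep(c("earn", "quit", "earn", "quit"), 3),
    wz_time_spent_s = rep(c(1, 0.4, 1, 0.4), 3),
    day = 7L
  )
  # earns by restaurant: r1 = 3, r2 = 0, r3 = 3, r4 = 0
  rk <- rank_flavors(s)
  expect_identical(rk$restaurant[rk$rank == 1], 1L)
  expect_identical(rk$restaurant[rk$rank == 2], 3L)
  expect_true(all(rk$tie_broken))

  s2 <- build_session(
    offer_s = rep(1, 8), oz_outcome = rep("enter", 8),
    wz_outcome = c("earn", "quit", "quit", "quit",
                   "earn", "earn", "quit", "quit"),
    wz_time_spent_s = c(1, 0, 0, 0, 1, 1, 0, 0), day = 7L
  )
  # earns: r1 = 2, r2 = 1, r3 = 0, r4 = 0
  rk2 <- rank_flavors(s2)
  expect_identical(rk2$restaurant[rk2$rank <= 2], c(1L, 2L))
  expect_false(any(rk2$tie_broken[rk2$rank <= 2]))
})

test_that("day-7 rankings recover generative flavor preferences", {
  pol <- policy_params(theta_oz = 10, theta_wz = 10, softness_beta = 100,
                       pref_weights = c(0.4, 0.3, 0.2, 0.1))
  set.seed(77)
  hits <- vapply(1:200, function(i) {
    s <- simulate_session(pol, day = 7)
    rk <- rank_flavors(dplyr::filter(s, !truncated))
    identical(rk$restaurant[order(rk$rank)], 1:4)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
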