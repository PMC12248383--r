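test_that("sessions are reproducible under a fixed seed and respect the budget", {
  pol <- policy_params(theta_oz = 12, theta_wz = 10)
  set.seed(5)
  a <- simulate_session(pol, day = 20)
  set.seed(5)
  b <- simulate_session(pol, day = 20)
  expect_identical(a, b)

  full <- dplyr::filter(a, !truncated)
  elapsed <- sum(full$oz_latency_s + full$wz_time_spent_s + full$consume_s +
                   full$travel_s)
  expect_lte(elapsed, 1800)
  expect_lte(sum(a$truncated), 1L)
  # serial order starts at restaurant 1 and cycles
  expect_identical(a$restaurant[1:8], rep(1:4, 2))

  zero <- epoch_schedule(session_budget_s = 0)
  expect_identical(nrow(simulate_session(pol, 20, zero)), 0L)
})

test_that("a sharp policy skips offers above threshold with probability 1", {
  pol <- policy_params(theta_oz = 10, theta_wz = 10, softness_beta = 100)
  set.seed(1)
  for (i in 1:20) {
    tr <- simulate_trial(pol, offer_s = 18L, restaurant = 1L)
    expect_identical(tr$oz_outcome, "skip")
  }
  for (i in 1:20) {
    tr <- simulate_trial(pol, offer_s = 4L, restaurant = 1L)
    expect_identical(tr$oz_outcome, "enter")
  }
})

test_that("the regret bonus raises acceptance only after a flagged quit", {
  # baseline acceptance ~0, bonus rho = 1 forces acceptance when memory set
  pol <- policy_params(theta_oz = 2, theta_wz = 2, softness_beta = 100,
                       regret_rho = 1)
  set.seed(2)
  with_mem <- replicate(30, simulate_trial(pol, 10L, 1L, memory = TRUE)$oz_outcome)
  no_mem <- replicate(30, simulate_trial(pol, 10L, 1L, memory = FALSE)$oz_outcome)
  expect_true(all(with_mem == "enter"))
  expect_true(all(no_mem == "skip"))
})

test_that("the quit hazard follows base * (l > theta) * max(0, 1 - kappa s)", {
  # force acceptance; theta_wz = 0 keeps the hazard gate open for all l >= 1
  pol <- policy_params(theta_oz = 30, theta_wz = 0, softness_beta = 100,
                       base_quit_hazard = 0.5, sunk_kappa = 0.2)
  set.seed(3)
  sess <- do.call(rbind, lapply(1:160, function(i) {
    simulate_trial(pol, 20L, 1L)
  }))
  quits <- floor(sess$wz_time_spent_s[sess$wz_outcome == "quit"])
  # empirical hazard at state s: quit at s among trials that reached s
  haz <- function(s) {
    at_risk <- sum(quits >= s) + sum(sess$wz_outcome == "earn")
    sum(quits == s) / at_risk
  }
  # h(0) = 0.5, h(3) = 0.5 * (1 - 0.6) = 0.2, h(s >= 5) = 0
  expect_equal(haz(0), 0.5, tolerance = 0.12)
  expect_equal(haz(3), 0.2, tolerance = 0.12)
  expect_identical(sum(quits >= 5), 0L)

  # kappa = 0: hazard flat in s while the gate is open
  pol0 <- policy_params(theta_oz = 30, theta_wz = 5, softness_beta = 100,
                        base_quit_hazard = 0.4, sunk_kappa = 0)
  set.seed(4)
  sess0 <- do.call(rbind, lapply(1:300, function(i) simulate_trial(pol0, 15L, 1L)))
  quits0 <- floor(sess0$wz_time_spent_s[sess0$wz_outcome == "quit"])
  n_earn <- sum(sess0$wz_outcome == "earn")
  haz0 <- vapply(0:3, function(s) {
    sum(quits0 == s) / (sum(quits0 >= s) + n_earn)
  }, numeric(1))
  expect_true(all(abs(haz0 - 0.4) < 0.12))
  # gate closes when l <= theta_wz: offer 15, theta 5 -> no quits past s = 9
  expect_identical(sum(quits0 >= 10), 0L)
})

test_that("cohort simulation records ground truth and a week-1 learning ramp", {
  coh <- fixture_cohort()
  expect_identical(nrow(coh$ground_truth), 8L)
  expect_identical(sort(unique(coh$trials$group)),
                   c("F-GFP", "F-LINC", "M-GFP", "M-LINC"))
  expect_identical(length(unique(coh$trials$day)), 16L)
  gt <- ground_truth_thresholds(coh)
  expect_identical(nrow(gt), 32L)
  expect_true(all(gt$theta_wz >= 0 & gt$theta_wz <= 30))

  earns <- coh$trials %>%
    dplyr::filter(day %in% c(1, 7), wz_outcome == "earn") %>%
    dplyr::count(mouse_id, day)
  wide <- tidyr::pivot_wider(earns, names_from = day, values_from = n)
  expect_gt(mean(wide$`7` - wide$`1`), 0)
})

test_that("free-roam probes scale day-8 occupancy with day-7 earnings", {
  pol <- policy_params()
  earn <- c(60, 40, 20, 5)
  set.seed(11)
  reps <- lapply(1:200, function(i) {
    simulate_free_roam_pair(pol, earn, cpp_gain = 1.5)
  })
  # occupancy never exceeds the probe duration
  sums <- vapply(reps, function(r) max(tapply(r$wz_time_s, r$probe_day, sum)),
                 numeric(1))
  expect_true(all(sums <= 1200))
  # time deltas rank with earnings
  rho <- vapply(reps, function(r) {
    d <- r$wz_time_s[r$probe_day == 8] - r$wz_time_s[r$probe_day == 0]
    cor(d, earn, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho), 0.5)

  # cpp_gain = 0: no systematic pre/post difference
  set.seed(12)
  d0 <- rowMeans(vapply(1:200, function(i) {
    r <- simulate_free_roam_pair(pol, earn, cpp_gain = 0)
    r$wz_time_s[r$probe_day == 8] - r$wz_time_s[r$probe_day == 0]
  }, numeric(4)))
  expect_true(all(abs(d0) < 10))
})
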