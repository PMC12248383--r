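test_that("yield sweep peaks at the closed-form optimum", {
  surf <- simulate_yield_surface(0:30, replicates = 150, seed = 41)
  argmax <- surf$threshold_s[which.max(surf$mean_pellets)]
  expect_identical(argmax, 10L)
  expect_identical(surf$mean_pellets[surf$threshold_s == 0], 0)
  expect_lt(surf$mean_pellets[surf$threshold_s == 30],
            surf$mean_pellets[surf$threshold_s == 10])
  # closed form: T* = sqrt(2 M h) = sqrt(2 * 30 * 5/3) = 10, independent of c
  expect_equal(closed_form_optimal_threshold(30, 5 / 3), 10)
  expect_identical(which.max(yield_rate(1:30)), 10L)

  fm <- food_max_thresholds(surf)
  expect_equal(fm$theta, rep(10, 4))

  # argmax is stable across independent seeds
  surf2 <- simulate_yield_surface(5:15, replicates = 150, seed = 99)
  expect_identical(surf2$threshold_s[which.max(surf2$mean_pellets)], 10L)
})

test_that("doubling the overhead moves the optimum as sqrt(2 M h)", {
  sim <- yield_sim_params(overhead_s = 10 / 3)
  surf <- simulate_yield_surface(5:25, sim, replicates = 200, seed = 42)
  argmax <- surf$threshold_s[which.max(surf$mean_pellets)]
  expect_lte(abs(argmax - closed_form_optimal_threshold(30, 10 / 3)), 1)
})

test_that("subjective-value thresholds respect preference structure", {
  # uniform weights reduce to the food-maximizing policy
  sva <- subjective_value_thresholds(rep(25, 4), method = "analytic")
  expect_equal(sva$theta, rep(10, 4))

  # graded weights give thresholds nonincreasing in preference rank
  svb <- subjective_value_thresholds(c(40, 30, 20, 10), method = "analytic")
  expect_true(all(diff(svb$theta) <= 0))
  expect_gt(svb$theta[1], 10)
  expect_lt(svb$theta[4], 10)

  # a zero-weight restaurant is never worth waiting in
  svc <- subjective_value_thresholds(c(50, 30, 20, 0), method = "analytic")
  expect_equal(svc$theta[4], 0)

  expect_error(subjective_value_thresholds(c(0, 0, 0, 0)), "all zero")
})

test_that("the analytic coordinate search matches an exhaustive oracle", {
  grid <- c(0, 4, 7, 10, 13, 16, 20)
  for (earn in list(c(40, 30, 20, 10), c(50, 30, 20, 0), c(10, 10, 40, 40))) {
    got <- subjective_value_thresholds(earn, method = "analytic", grid = grid)
    # independent brute force over the full grid on the closed-form rate
    w <- earn / sum(earn)
    combos <- as.matrix(expand.grid(grid, grid, grid, grid))
    obj <- apply(combos, 1, function(T4) {
      p <- T4 / 30
      sum(w * p) / (4 * 5 / 3 + sum(p * ((T4 + 1) / 2 + 1.5)))
    })
    best <- combos[which.max(obj), ]
    expect_equal(got$theta, unname(best))
  }
})

test_that("simulated and analytic subjective-value optima agree closely", {
  set.seed(1)
  sim <- subjective_value_thresholds(c(40, 30, 20, 10), replicates = 150,
                                     method = "coordinate")
  ana <- subjective_value_thresholds(c(40, 30, 20, 10), method = "analytic")
  expect_true(all(abs(sim$theta - ana$theta) <= 2))
})

test_that("Euclidean distances satisfy the metric axioms and examples", {
  obs <- tibble::tibble(mouse_id = "m1", day = 20L, restaurant = 1:4,
                        theta = c(10, 10, 10, 14), zone = "WZ")
  theo <- tibble::tibble(restaurant = 1:4, theta = 10)
  d <- euclidean_distance_series(obs, theo)
  expect_identical(d$distance, 4)
  expect_true(d$complete)

  same <- dplyr::mutate(obs, theta = 10)
  expect_identical(euclidean_distance_series(same, theo)$distance, 0)

  # permutation consistency
  perm <- obs
  perm$theta <- c(14, 10, 10, 10)
  expect_identical(euclidean_distance_series(perm, theo)$distance, 4)

  # missing restaurants are reported, not interpolated
  incomplete <- obs
  incomplete$theta[2] <- NA
  di <- euclidean_distance_series(incomplete, theo)
  expect_true(is.na(di$distance))
  expect_false(di$complete)
})

test_that("near-optimal simulants score closer to food-max than mismatched ones", {
  # theta_oz = 30 admits all offers so the wait-zone fit sees both classes
  mk <- function(theta) list(G = group_preset(
    theta_oz = 30, theta_wz = theta, softness_beta = 100,
    base_quit_hazard = 1, theta_oz_sd = 0, theta_wz_sd = 0))
  near <- simulate_cohort(2, mk(10.5), days = 18:23, seed = 5150)
  far <- simulate_cohort(2, mk(c(3.5, 24.5, 17.5, 5.5)), days = 18:23,
                         seed = 5151)
  theo <- tibble::tibble(restaurant = 1:4, theta = 10)
  d_near <- euclidean_distance_series(
    block_thresholds(near$trials, "WZ", c(18, 23), by = "day"), theo)
  d_far <- euclidean_distance_series(
    block_thresholds(far$trials, "WZ", c(18, 23), by = "day"), theo)
  expect_lt(mean(d_near$distance, na.rm = TRUE),
            mean(d_far$distance, na.rm = TRUE))
  expect_lt(mean(d_near$distance, na.rm = TRUE), 2)
})
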