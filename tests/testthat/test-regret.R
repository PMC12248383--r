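th_all10 <- function(mouse = "m1") {
  tibble::tibble(mouse_id = mouse, restaurant = 1:4, theta = 10, zone = "WZ")
}

test_that("sequence arms follow the violation/nonviolation rules", {
  # r1: skip of value +5 (offer 5), then r2: offer 13 (value -3) -> type-1 violation
  # r3: enter-quit of value -3 (offer 13), then r4: offer 14 (value -4) -> type-2 violation
  # next lap r1: earn of value -2 (offer 12), then r2: offer 13 -> no arm
  s <- build_session(
    offer_s = c(5, 13, 13, 14, 12, 13),
    oz_outcome = c("skip", "skip", "enter", "skip", "enter", "skip"),
    wz_outcome = c("none", "none", "quit", "none", "earn", "none"),
    wz_time_spent_s = c(0, 0, 2.5, 0, 12, 0)
  )
  pairs <- extract_sequences(s, th_all10(), days = c(18, 45))
  t1v <- dplyr::filter(pairs, type == 1, arm == "violation")
  expect_identical(nrow(t1v), 1L)
  expect_identical(t1v$t1_restaurant, 1L)
  expect_identical(t1v$t1_offer_value, 5)
  expect_identical(t1v$t_offer_value, -3)
  t2v <- dplyr::filter(pairs, type == 2, arm == "violation")
  expect_identical(nrow(t2v), 1L)
  expect_identical(t2v$t1_restaurant, 3L)
  expect_false(t2v$readout_accept)
  # the earn of a negative-value offer defines no arm at t-1
  expect_false(any(pairs$t1_restaurant == 1L & pairs$type == 2))
  # skips of negative offers are type-2 nonviolations
  expect_true(any(pairs$type == 2 & pairs$arm == "nonviolation"))
})

test_that("per-stratum delta arithmetic and arm symmetry hold", {
  mk_pairs <- function(arm, n, accepts) {
    tibble::tibble(
      mouse_id = "m1", day = 20L, type = 2L, arm = arm,
      t1_restaurant = 1L, t_restaurant = 2L,
      t1_offer_value = -3, t_offer_value = -3,
      bin_t1 = -2, bin_t = -2,
      readout_accept = rep(c(TRUE, FALSE), c(accepts, n - accepts))
    )
  }
  pairs <- dplyr::bind_rows(mk_pairs("violation", 10, 5),
                            mk_pairs("nonviolation", 10, 3))
  d <- sequence_delta(pairs, 2L, min_pairs = 5)
  expect_equal(d$delta, 0.2)
  expect_identical(d$n_violation, 10L)

  flipped <- dplyr::mutate(pairs, arm = ifelse(arm == "violation",
                                               "nonviolation", "violation"))
  d2 <- sequence_delta(flipped, 2L, min_pairs = 5)
  expect_equal(d2$delta, -d$delta)
})

test_that("retained strata always contain both arms with matched bins", {
  coh <- fixture_cohort()
  th <- block_thresholds(coh$trials, "WZ", c(18, 26))
  pairs <- extract_sequences(coh$trials, th, c(18, 26))
  strata <- pairs %>%
    dplyr::count(mouse_id, type, t1_restaurant, bin_t1, bin_t, arm) %>%
    tidyr::pivot_wider(names_from = arm, values_from = n)
  # recompute the per-mouse delta by hand for type 2 and compare
  both <- dplyr::filter(strata, type == 2, !is.na(violation),
                        !is.na(nonviolation))
  manual <- pairs %>%
    dplyr::filter(type == 2) %>%
    dplyr::inner_join(both, by = c("mouse_id", "type", "t1_restaurant",
                                   "bin_t1", "bin_t")) %>%
    dplyr::group_by(mouse_id, t1_restaurant, bin_t1, bin_t, arm) %>%
    dplyr::summarise(p = mean(readout_accept), n = dplyr::n(),
                     .groups = "drop") %>%
    tidyr::pivot_wider(names_from = arm, values_from = c(p, n)) %>%
    dplyr::mutate(w = n_violation * n_nonviolation /
                    (n_violation + n_nonviolation)) %>%
    dplyr::group_by(mouse_id) %>%
    dplyr::summarise(delta = sum(w * (p_violation - p_nonviolation)) / sum(w),
                     .groups = "drop")
  auto <- sequence_delta(pairs, 2L, min_pairs = 1)
  j <- dplyr::inner_join(manual, auto, by = "mouse_id")
  expect_gt(nrow(j), 4)
  expect_equal(j$delta.x, j$delta.y)
})

test_that("cohort tests handle degenerate and closed-form cases", {
  zeros <- tibble::tibble(delta = rep(0, 6))
  res <- cohort_sign_test(zeros)
  expect_identical(res$t_stat, 0)
  expect_identical(res$p_t, 1)

  pos <- tibble::tibble(delta = runif(10, 0.05, 0.2))
  res2 <- cohort_sign_test(pos)
  expect_equal(res2$p_sign, 2 * (1 / 2)^10)
  expect_identical(res2$direction, "positive")

  expect_error(cohort_sign_test(c(0.1, 0.2)), "at least 3")
})

test_that("rho is recovered by type-2 deltas and leaves type 1 null", {
  presets <- list(R = group_preset(
    theta_oz = 10, theta_wz = 10, softness_beta = 0.4, base_quit_hazard = 0.6,
    regret_rho = 0.25, theta_oz_sd = 0, theta_wz_sd = 0))
  coh <- simulate_cohort(8, presets, days = 18:29, seed = 2024)
  th <- block_thresholds(coh$trials, "WZ", c(18, 29))
  pairs <- extract_sequences(coh$trials, th, c(18, 29))
  d2 <- sequence_delta(pairs, 2L)
  d1 <- sequence_delta(pairs, 1L)
  expect_gte(nrow(d2), 6)
  expect_equal(mean(d2$delta), 0.25, tolerance = 0.25)
  expect_lt(abs(mean(d1$delta)), 0.05)
})
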