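test_that("surface bookkeeping matches single-trial expectations", {
  # one 10-s offer quit at 4.6 s: survived states s = 0..4, never earned
  s <- build_session(offer_s = c(10, 10), oz_outcome = c("enter", "enter"),
                     wz_outcome = c("quit", "earn"),
                     wz_time_spent_s = c(4.6, 10))
  surf <- stay_survival_surface(s, days = c(18, 45), min_count = 1)
  quit_cells <- dplyr::filter(surf, s <= 4)
  expect_identical(nrow(quit_cells), 5L)
  expect_true(all(quit_cells$p_earn == 0.5))  # quit + earn trial share s<=4
  expect_true(all(quit_cells$l == 10 - quit_cells$s))
  # the earn trial alone contributes s = 5..9 (state s = 10 is the outcome)
  earn_cells <- dplyr::filter(surf, s >= 5)
  expect_identical(max(surf$s), 9L)
  expect_true(all(earn_cells$p_earn == 1))

  all_earn <- build_session(offer_s = c(8, 5, 8), oz_outcome = rep("enter", 3))
  surf2 <- stay_survival_surface(all_earn, days = c(18, 45), min_count = 1)
  expect_true(all(surf2$p_earn == 1))
})

test_that("the 0-s control is the just-entered column of the surface", {
  coh <- fixture_cohort()
  surf <- stay_survival_surface(coh$trials, c(18, 26))
  ctrl <- zero_sunk_control(surf)
  s0 <- dplyr::filter(as.data.frame(surf), s == 0)
  expect_identical(ctrl$p_earn, s0$p_earn)
  expect_identical(ctrl$n, s0$n)

  # offers of one length define the control at that time-left only
  only30 <- build_session(offer_s = rep(30, 6), oz_outcome = rep("enter", 6))
  surf30 <- stay_survival_surface(only30, c(18, 45), min_count = 1)
  ctrl30 <- zero_sunk_control(surf30)
  expect_identical(ctrl30$l, 30L)
  expect_identical(attr(ctrl30, "missing_l"), 1:29)
})

test_that("a memoryless policy yields an l-dependent, s-invariant surface", {
  # analytic survival: p(earn | s, l) = (1 - h)^(l - theta) for l > theta
  pol <- policy_params(theta_oz = 30, theta_wz = 6, softness_beta = 100,
                       base_quit_hazard = 0.3, sunk_kappa = 0)
  set.seed(31)
  trials <- dplyr::bind_rows(lapply(1:30, function(i) {
    simulate_session(pol, 25, mouse_id = sprintf("m%02d", i))
  }))
  surf <- stay_survival_surface(trials, c(18, 45), min_count = 50)
  ana <- function(l) ifelse(l <= 6, 1, (1 - 0.3)^(l - 6))
  chk <- dplyr::filter(surf, valid, l <= 15)
  expect_gt(nrow(chk), 50)
  expect_lt(mean(abs(chk$p_earn - ana(chk$l))), 0.025)
  # every cell sits within binomial sampling error of the analytic survival
  z <- abs(chk$p_earn - ana(chk$l)) /
    sqrt(pmax(ana(chk$l) * (1 - ana(chk$l)), 0.01) / chk$n)
  expect_lt(mean(z > 4), 0.01)
  # at matched time left, the count-weighted departure across s is negligible
  dep <- chk %>%
    dplyr::group_by(l) %>%
    dplyr::mutate(dev = p_earn - sum(p_earn * n) / sum(n)) %>%
    dplyr::ungroup()
  expect_lt(sum(abs(dep$dev) * dep$n) / sum(dep$n), 0.03)
})

test_that("the delta envelope is zero at s = 0 and escalates with kappa > 0", {
  presets <- list(K = group_preset(
    theta_oz = 14, theta_wz = 9, softness_beta = 0.8, base_quit_hazard = 0.5,
    sunk_kappa = 0.2, theta_oz_sd = 0, theta_wz_sd = 0))
  coh <- simulate_cohort(8, presets, days = 18:27, seed = 909)
  surf <- stay_survival_surface(coh$trials, c(18, 27))
  env <- sunk_delta_envelope(surf, bootstrap_reps = 300, seed = 1)
  expect_identical(env$delta[env$s == 0], 0)
  # escalation is expressed where above-threshold cells stay populated
  # (s = 1..3 at this cohort size); the envelope returns to 0 beyond
  mid <- dplyr::filter(env, s >= 1, s <= 3)
  expect_true(all(mid$delta > 0))
  expect_true(all(mid$lo > 0))
  expect_true(all(env$delta >= 0, na.rm = TRUE))
})

test_that("offer-zone deliberation time shows no sunk-cost effect", {
  # a homogeneous cohort: pooled cells then have no between-mouse composition
  # bias, so deliberation time is unconfounded with acceptance
  presets <- list(H = group_preset(
    theta_oz = 14, theta_wz = 9, softness_beta = 0.8, base_quit_hazard = 0.5,
    sunk_kappa = 0.2, theta_oz_sd = 0, theta_wz_sd = 0))
  coh <- simulate_cohort(8, presets, days = 18:27, seed = 4242)
  surf_oz <- stay_survival_surface(coh$trials, c(18, 27), zone = "OZ")
  env_oz <- sunk_delta_envelope(surf_oz, bootstrap_reps = 300, seed = 2)
  chk <- dplyr::filter(env_oz, s >= 1, !is.na(delta), n_l >= 30)
  expect_gt(nrow(chk), 1)
  # deliberation time never *raises* acceptance, and any residual effect
  # (a small negative budget-truncation artifact) is negligible next to the
  # wait-zone escalation in the same animals
  expect_true(all(chk$delta < 0.01))
  expect_true(all(abs(chk$delta) < 0.05))
  surf_wz <- stay_survival_surface(coh$trials, c(18, 27))
  env_wz <- sunk_delta_envelope(surf_wz, bootstrap_reps = 300, seed = 3)
  wz_mid <- dplyr::filter(env_wz, s >= 1, s <= 3)
  expect_gt(min(wz_mid$delta), max(abs(chk$delta)) * 2)
})

test_that("no entered trials yields an empty surface and envelope", {
  skips <- build_session(offer_s = c(5, 7), oz_outcome = c("skip", "skip"),
                         wz_outcome = c("none", "none"),
                         wz_time_spent_s = c(0, 0))
  surf <- stay_survival_surface(skips, c(18, 45))
  expect_identical(nrow(surf), 0L)
  expect_identical(nrow(sunk_delta_envelope(surf)), 0L)
})
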