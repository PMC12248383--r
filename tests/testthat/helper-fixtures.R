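# Shared fixtures: a hand-built session constructor, independent oracles,
# and cached simulated cohorts (built once per test run).

# Construct a schema-complete session from outcome specifications. Restaurant
# order, tones, flavors, timing bookkeeping and the truncation flag are filled
# in so the result passes validate_trials().
build_session <- function(offer_s, oz_outcome, wz_outcome = NULL,
                          wz_time_spent_s = NULL, oz_latency_s = 1,
                          consume_s = NULL, travel_s = 1,
                          mouse_id = "m1", day = 30L, start_restaurant = 1L) {
  n <- length(offer_s)
  if (is.null(wz_outcome)) {
    wz_outcome <- ifelse(oz_outcome == "enter", "earn", "none")
  }
  if (is.null(wz_time_spent_s)) {
    wz_time_spent_s <- ifelse(wz_outcome == "earn", offer_s, 0)
  }
  if (is.null(consume_s)) consume_s <- ifelse(wz_outcome == "earn", 1.5, 0)
  oz_latency_s <- rep_len(oz_latency_s, n)
  travel_s <- rep_len(travel_s, n)
  consume_s <- rep_len(consume_s, n)
  restaurant <- ((start_restaurant - 1L + seq_len(n) - 1L) %% 4L) + 1L
  dur <- oz_latency_s + wz_time_spent_s + consume_s + travel_s
  tibble::tibble(
    mouse_id = mouse_id,
    day = as.integer(day),
    trial_index = seq_len(n),
    restaurant = restaurant,
    flavor = restaurant_flavor(restaurant),
    offer_s = as.integer(offer_s),
    tone_hz = tone_frequency(offer_s),
    oz_outcome = oz_outcome,
    oz_latency_s = as.numeric(oz_latency_s),
    wz_outcome = wz_outcome,
    wz_time_spent_s = as.numeric(wz_time_spent_s),
    consume_s = as.numeric(consume_s),
    travel_s = as.numeric(travel_s),
    t_start_s = c(0, cumsum(dur))[seq_len(n)],
    truncated = FALSE
  )
}

# Independent brute-force oracle for the step-threshold fit: explicit loop
# over candidates, counting errors of the rule "accept iff offer < theta",
# with the documented tie-break applied by hand.
brute_force_step <- function(offers, outcomes, epoch_max) {
  cands <- seq(0.5, epoch_max + 0.5, by = 1)
  best_loss <- Inf
  best <- c()
  for (th in cands) {
    loss <- 0
    for (i in seq_along(offers)) {
      pred <- offers[i] < th
      if (pred != as.logical(outcomes[i])) loss <- loss + 1
    }
    if (loss < best_loss) {
      best_loss <- loss
      best <- th
    } else if (loss == best_loss) {
      best <- c(best, th)
    }
  }
  best[floor(length(best) / 2) + 1]
}

# Cohort cache: heavy simulated cohorts built once and reused across tests.
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# Small mixed cohort with the default group presets: week 1 + early scarcity.
fixture_cohort <- function() {
  cached("mixed", function() {
    simulate_cohort(2, days = c(1:7, 18:26), seed = 424242)
  })
}

# Step-policy cohort with known half-integer thresholds for recovery tests.
step_presets <- function(n_groups = 2) {
  list(
    A = group_preset(theta_oz = c(12.5, 9.5, 15.5, 6.5),
                     theta_wz = c(10.5, 7.5, 12.5, 4.5),
                     softness_beta = 100, base_quit_hazard = 1,
                     theta_oz_sd = 0, theta_wz_sd = 0),
    B = group_preset(theta_oz = c(8.5, 17.5, 11.5, 20.5),
                     theta_wz = c(6.5, 14.5, 9.5, 18.5),
                     softness_beta = 100, base_quit_hazard = 1,
                     theta_oz_sd = 0, theta_wz_sd = 0)
  )[seq_len(n_groups)]
}

step_cohort <- function() {
  cached("step", function() {
    simulate_cohort(2, step_presets(), days = 18:29, seed = 31415)
  })
}
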