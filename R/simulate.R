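# Agent-based generative model of Restaurant Row behavior.
#
# Sessions are simulated serially: the agent cycles restaurants 1-2-3-4,
# deliberates in the offer zone, optionally waits out (or quits) the cued
# countdown, consumes on earns, and travels on, spending a fixed 1800-s
# budget. All randomness comes from the current RNG state, so a single
# set.seed upstream makes every output reproducible.

# Vectorized core: simulate outcomes for a fixed stream of offers and
# restaurants on one day. The wait-zone process (would-quit state) is drawn
# independently of the accept draw, which keeps everything vectorizable; the
# only sequential part is the regret-memory chain, looped only when
# regret_rho > 0.
sim_trials_core <- function(policy, offers, restaurants, day, mem0 = FALSE) {
  p <- policy
  n <- length(offers)
  r <- restaurants
  mult <- 1 + p$learning_gain * exp(-(day - 1) / p$learning_tau_days)
  scale <- p$pref_weights / max(p$pref_weights)
  p_base <- pmin(1, scale[r] * plogis(p$softness_beta * (p$theta_oz[r] - offers)))
  u_accept <- runif(n)

  # per-second quit hazard over states s = 0..29 for each trial
  S <- 30L
  sgrid <- 0:(S - 1L)
  H <- outer(sgrid, seq_len(n), function(s, i) {
    active <- (s < offers[i]) & ((offers[i] - s) > p$theta_wz[r[i]])
    p$base_quit_hazard * pmax(0, 1 - p$sunk_kappa * s) * active
  })
  M <- matrix(runif(S * n), S, n) < H
  hit <- colSums(M) > 0                                # would quit if entered
  fs <- max.col(t(M), ties.method = "first") - 1L      # first-quit state
  quit_frac <- runif(n)
  neg_value <- (p$theta_wz[r] - offers) < 0

  if (p$regret_rho > 0 && n > 0) {
    accept <- logical(n)
    mem <- isTRUE(mem0)
    for (i in seq_len(n)) {
      accept[i] <- u_accept[i] < min(1, p_base[i] + p$regret_rho * mem)
      mem <- accept[i] && hit[i] && neg_value[i]
    }
    mem_out <- mem
  } else {
    accept <- u_accept < p_base
    mem_out <- if (n > 0) accept[n] && hit[n] && neg_value[n] else isTRUE(mem0)
  }

  quit <- accept & hit
  earn <- accept & !hit
  spent <- numeric(n)
  spent[earn] <- offers[earn]
  # times are recorded at microsecond resolution so trial tables round-trip
  # exactly through text
  spent[quit] <- round(fs[quit] + pmin(quit_frac[quit], 0.999999), 6)
  consume <- numeric(n)
  consume[earn] <- round(rgamma(sum(earn), shape = 9, rate = 9 / p$consume_s), 6)

  list(
    accept = accept,
    wz_outcome = ifelse(accept, ifelse(hit, "quit", "earn"), "none"),
    spent = spent,
    consume = consume,
    oz_latency = round(rgamma(n, shape = 4,
                              rate = 4 / (p$oz_latency_mean_s * mult)), 6),
    travel = round(rgamma(n, shape = 4,
                          rate = 4 / (p$travel_mean_s * mult)), 6),
    mem_out = mem_out
  )
}

core_to_tibble <- function(core, offers, restaurants, mouse_id, day,
                           first_index = 1L, t0 = 0) {
  n <- length(offers)
  dur <- core$oz_latency + core$spent + core$consume + core$travel
  t_start <- round(t0 + c(0, cumsum(dur))[seq_len(n)], 6)
  tibble(
    mouse_id = mouse_id,
    day = as.integer(day),
    trial_index = first_index - 1L + seq_len(n),
    restaurant = as.integer(restaurants),
    flavor = restaurant_flavor(restaurants),
    offer_s = as.integer(offers),
    tone_hz = tone_frequency(offers),
    oz_outcome = ifelse(core$accept, "enter", "skip"),
    oz_latency_s = core$oz_latency,
    wz_outcome = core$wz_outcome,
    wz_time_spent_s = core$spent,
    consume_s = core$consume,
    travel_s = core$travel,
    t_start_s = t_start,
    truncated = FALSE
  )
}

#' Simulate a single restaurant encounter
#'
#' Runs the generative policy on one offer. Mainly useful for inspecting the
#' policy; [simulate_session()] is the workhorse.
#'
#' @param policy An [policy_params()] object.
#' @param offer_s Integer offer in seconds.
#' @param restaurant Restaurant index 1-4.
#' @param memory `TRUE` if the previous trial was an enter-then-quit of a
#'   negatively valued offer (triggers the `regret_rho` bonus).
#' @param day Day index (sets the acquisition-ramp multiplier and, in
#'   [simulate_session()], the offer range).
#' @return A one-row trial tibble.
#' @export
simulate_trial <- function(policy, offer_s, restaurant, memory = FALSE, day = 30L) {
  core <- sim_trials_core(policy, offer_s, restaurant, day, mem0 = memory)
  core_to_tibble(core, offer_s, restaurant, "sim", day)
}

#' Simulate one daily session
#'
#' Generates trials serially (restaurants cycling 1-2-3-4) against the
#' session's 1800-s budget, with offers drawn uniformly from the day's
#' scheduled range. A trial still in progress when the budget expires is kept
#' with `truncated = TRUE`; estimators exclude truncated trials.
#'
#' @inheritParams simulate_trial
#' @param day Day index within the schedule.
#' @param schedule An [epoch_schedule()].
#' @param mouse_id Identifier stamped on the trials.
#' @return A trial tibble (possibly empty for a zero budget).
#' @export
simulate_session <- function(policy, day, schedule = epoch_schedule(),
                             mouse_id = "m01") {
  budget <- schedule$session_budget_s
  empty <- core_to_tibble(sim_trials_core(policy, integer(0), integer(0), day),
                          integer(0), integer(0), mouse_id, day)
  if (budget <= 0) return(empty)
  rng <- offer_range_for_day(day, schedule)
  pieces <- list()
  tot <- 0
  mem <- FALSE
  r_next <- 1L
  idx_next <- 1L
  repeat {
    nc <- 512L
    offers <- if (rng[1] == rng[2]) rep(rng[1], nc) else
      as.integer(floor(runif(nc, rng[1], rng[2] + 1L)))
    rest <- ((r_next - 1L + 0:(nc - 1L)) %% 4L) + 1L
    core <- sim_trials_core(policy, offers, rest, day, mem0 = mem)
    chunk <- core_to_tibble(core, offers, rest, mouse_id, day,
                            first_index = idx_next, t0 = tot)
    t_end <- chunk$t_start_s + chunk$oz_latency_s + chunk$wz_time_spent_s +
      chunk$consume_s + chunk$travel_s
    keep <- chunk$t_start_s < budget
    chunk <- chunk[keep, , drop = FALSE]
    chunk$truncated <- t_end[keep] > budget
    pieces[[length(pieces) + 1L]] <- chunk
    if (any(chunk$truncated) || nrow(chunk) < nc) break
    tot <- t_end[nc]
    mem <- core$mem_out
    r_next <- (rest[nc] %% 4L) + 1L
    idx_next <- idx_next + nc
  }
  bind_rows(pieces)
}

#' Simulate the day-0 / day-8 free-roam probe pair
#'
#' Task-free 20-min probes bracketing week 1. Day-0 wait-zone occupancy is
#' uniform across restaurants in expectation; day-8 occupancy gains
#' `cpp_gain` seconds per pellet earned in that restaurant on day 7
#' (conditioned place preference scaling with experienced reward), with entry
#' counts perturbed weakly. Occupancies are capped so their sum never exceeds
#' the probe duration.
#'
#' @param policy An [policy_params()] object (reserved for future couplings;
#'   occupancy is policy-independent at present).
#' @param day7_earnings Per-restaurant pellet counts from the day-7 session.
#' @param cpp_gain Seconds of day-8 occupancy per day-7 pellet (0 disables
#'   the place-preference effect).
#' @param base_time_s,base_entries Baseline per-restaurant occupancy seconds
#'   and entry count.
#' @param probe_duration_s Probe length in seconds.
#' @param mouse_id Identifier stamped on the rows.
#' @return A free-roam tibble: 8 rows (2 probe days x 4 restaurants).
#' @export
simulate_free_roam_pair <- function(policy, day7_earnings, cpp_gain = 1,
                                    base_time_s = 65, base_entries = 15,
                                    probe_duration_s = 1200,
                                    mouse_id = "m01") {
  stopifnot(length(day7_earnings) == 4, all(day7_earnings >= 0))
  draw <- function(mean_time, mean_entries) {
    t <- rgamma(4, shape = 8, rate = 8 / mean_time)
    if (sum(t) > probe_duration_s) t <- t * probe_duration_s / sum(t)
    tibble(
      restaurant = 1:4,
      wz_entries = rpois(4, mean_entries),
      wz_time_s = t
    )
  }
  pre <- draw(rep(base_time_s, 4), rep(base_entries, 4))
  post <- draw(base_time_s + cpp_gain * day7_earnings,
               base_entries + 0.05 * cpp_gain * day7_earnings)
  bind_rows(
    mutate(pre, mouse_id = mouse_id, probe_day = 0L),
    mutate(post, mouse_id = mouse_id, probe_day = 8L)
  ) %>%
    select(dplyr::all_of(c("mouse_id", "probe_day", "restaurant",
                           "wz_entries", "wz_time_s")))
}

draw_policy_from_preset <- function(preset) {
  args <- preset$args
  jitter4 <- function(mu, sd) pmin(30, pmax(0, rnorm(4, rep_len(mu, 4), sd)))
  if (!is.null(args$theta_oz)) {
    args$theta_oz <- jitter4(args$theta_oz, preset$theta_oz_sd %||% 0)
  }
  if (!is.null(args$theta_wz)) {
    args$theta_wz <- jitter4(args$theta_wz, preset$theta_wz_sd %||% 0)
  }
  do.call(policy_params, args)
}

#' Simulate a full cohort with recorded ground truth
#'
#' Draws each mouse's policy from its group preset, simulates every scheduled
#' day's session plus the day-0/day-8 free-roam pair, and records the
#' generative parameters for parameter-recovery testing.
#'
#' @param n_per_group Mice per group.
#' @param group_presets Named list of [group_preset()]s (default:
#'   [default_group_presets()], four sex-by-treatment groups).
#' @param schedule An [epoch_schedule()].
#' @param days Days to simulate (default: the full schedule).
#' @param seed Optional integer seed (`set.seed` once up front).
#' @param cpp_gain Passed to [simulate_free_roam_pair()]; probes are only
#'   generated when day 7 is simulated.
#' @return An `rr_cohort`: a list with `trials` (one tidy table, with a
#'   `group` column), `free_roam`, and `ground_truth` (one row per mouse with
#'   the policy stored as a list column).
#' @export
#' @examples
#' \donttest{
#' coh <- simulate_cohort(2, days = 1:3, seed = 1)
#' dplyr::count(coh$trials, mouse_id, day)
#' }
simulate_cohort <- function(n_per_group = 10,
                            group_presets = default_group_presets(),
                            schedule = epoch_schedule(),
                            days = NULL,
                            seed = NULL,
                            cpp_gain = 1) {
  stopifnot(n_per_group >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(days)) {
    days <- seq(min(schedule$blocks$day_start), max(schedule$blocks$day_end))
  }
  trials <- list()
  roam <- list()
  gt <- list()
  for (g in names(group_presets)) {
    for (i in seq_len(n_per_group)) {
      mid <- sprintf("%s-%02d", g, i)
      pol <- draw_policy_from_preset(group_presets[[g]])
      sess <- lapply(days, function(d) simulate_session(pol, d, schedule, mid))
      tr <- bind_rows(sess)
      tr$group <- g
      trials[[mid]] <- tr
      if (7L %in% days) {
        earn7 <- vapply(1:4, function(r) {
          sum(tr$day == 7L & tr$restaurant == r & tr$wz_outcome == "earn")
        }, numeric(1))
        roam[[mid]] <- simulate_free_roam_pair(pol, earn7, cpp_gain,
                                               probe_duration_s = schedule$probe_duration_s,
                                               mouse_id = mid)
      }
      gt[[mid]] <- tibble(mouse_id = mid, group = g, policy = list(pol))
    }
  }
  structure(
    list(
      trials = bind_rows(trials),
      free_roam = if (length(roam)) bind_rows(roam) else NULL,
      ground_truth = bind_rows(gt)
    ),
    class = "rr_cohort"
  )
}

#' @export
print.rr_cohort <- function(x, ...) {
  cat("<rr_cohort> ", nrow(x$ground_truth), " mice, ",
      nrow(x$trials), " trials across ",
      length(unique(x$trials$day)), " days\n", sep = "")
  invisible(x)
}

#' Ground-truth thresholds of a simulated cohort, tidied
#'
#' @param cohort An `rr_cohort` from [simulate_cohort()].
#' @return A tibble with one row per mouse and restaurant: `theta_oz`,
#'   `theta_wz`, `sunk_kappa`, `regret_rho`.
#' @export
ground_truth_thresholds <- function(cohort) {
  purrr::map_dfr(seq_len(nrow(cohort$ground_truth)), function(i) {
    pol <- cohort$ground_truth$policy[[i]]
    tibble(
      mouse_id = cohort$ground_truth$mouse_id[i],
      restaurant = 1:4,
      theta_oz = pol$theta_oz,
      theta_wz = pol$theta_wz,
      sunk_kappa = pol$sunk_kappa,
      regret_rho = pol$regret_rho
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
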