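# Session-level descriptive metrics: laps, earnings, the six-epoch time
# budget, and the conditioned-place-preference delta scores.

#' Partition session time into the behavioral epochs
#'
#' Six mutually exclusive epochs tile a session: enter time and skip time
#' (offer-zone deliberation of accepted vs rejected offers), quit time and
#' earn time (wait-zone countdown ending in a quit vs a pellet), consumption
#' time, and travel time. `scheme = "four"` merges earn + consumption and
#' drops travel, leaving the four major choice behaviors. Fractions are of
#' the session budget; the remainder (unused budget plus any truncated-trial
#' time) is reported as `frac_remainder`, so for the six-epoch scheme the
#' fractions plus remainder sum to 1.
#'
#' @param trials A validated trial table (any number of sessions).
#' @param scheme `"six"` (default) or `"four"`.
#' @param budget_s Session budget, seconds.
#' @return A tibble with one row per (mouse, day) and one column per epoch
#'   fraction, plus `elapsed_s`.
#' @export
time_budget_partition <- function(trials, scheme = c("six", "four"),
                                  budget_s = 1800) {
  scheme <- match.arg(scheme)
  if (any(trials$oz_latency_s < 0 | trials$wz_time_spent_s < 0 |
            trials$consume_s < 0 | trials$travel_s < 0)) {
    abort("Negative epoch durations in the trial table.")
  }
  out <- trials %>%
    filter(!.data$truncated) %>%
    group_by(.data$mouse_id, .data$day) %>%
    summarise(
      enter_s = sum(.data$oz_latency_s[.data$oz_outcome == "enter"]),
      skip_s = sum(.data$oz_latency_s[.data$oz_outcome == "skip"]),
      quit_s = sum(.data$wz_time_spent_s[.data$wz_outcome == "quit"]),
      earn_s = sum(.data$wz_time_spent_s[.data$wz_outcome == "earn"]),
      consume_s = sum(.data$consume_s),
      travel_s = sum(.data$travel_s),
      .groups = "drop"
    ) %>%
    mutate(elapsed_s = .data$enter_s + .data$skip_s + .data$quit_s +
             .data$earn_s + .data$consume_s + .data$travel_s)
  if (scheme == "six") {
    out %>%
      mutate(
        frac_enter = .data$enter_s / budget_s,
        frac_skip = .data$skip_s / budget_s,
        frac_quit = .data$quit_s / budget_s,
        frac_earn = .data$earn_s / budget_s,
        frac_consume = .data$consume_s / budget_s,
        frac_travel = .data$travel_s / budget_s,
        frac_remainder = 1 - .data$elapsed_s / budget_s
      )
  } else {
    out %>%
      mutate(
        frac_enter = .data$enter_s / budget_s,
        frac_skip = .data$skip_s / budget_s,
        frac_quit = .data$quit_s / budget_s,
        frac_earn = (.data$earn_s + .data$consume_s) / budget_s
      )
  }
}

#' Session-level behavioral metrics
#'
#' Laps (completed four-restaurant circuits in the correct direction), total
#' and per-restaurant earnings, a distance proxy (laps x lap length; the
#' trial table carries no tracking coordinates, so this is an approximation),
#' and the six-epoch time-budget fractions.
#'
#' @param trials A validated trial table.
#' @param lap_length_m Maze circuit length in meters (default 1).
#' @param budget_s Session budget, seconds.
#' @return A tibble with one row per (mouse, day).
#' @export
session_metrics <- function(trials, lap_length_m = 1, budget_s = 1800) {
  counts <- trials %>%
    filter(!.data$truncated) %>%
    group_by(.data$mouse_id, .data$day) %>%
    summarise(
      n_trials = n(),
      laps = sum(.data$restaurant == 4L),
      earns_total = sum(.data$wz_outcome == "earn"),
      earns_r1 = sum(.data$wz_outcome == "earn" & .data$restaurant == 1L),
      earns_r2 = sum(.data$wz_outcome == "earn" & .data$restaurant == 2L),
      earns_r3 = sum(.data$wz_outcome == "earn" & .data$restaurant == 3L),
      earns_r4 = sum(.data$wz_outcome == "earn" & .data$restaurant == 4L),
      n_quits = sum(.data$wz_outcome == "quit"),
      .groups = "drop"
    ) %>%
    mutate(distance_proxy_m = .data$laps * lap_length_m)
  budget <- time_budget_partition(trials, "six", budget_s)
  left_join(counts, budget, by = c("mouse_id", "day"))
}

#' Conditioned-place-preference delta scores
#'
#' Post-minus-pre (day 8 minus day 0) change in free-roam wait-zone entries
#' and occupancy per restaurant, mapped onto the day-7 flavor-preference
#' ranks (rank 1 = most pellets earned on day 7). A place preference learned
#' from task experience shows up as positive time deltas concentrated at the
#' preferred ranks.
#'
#' @param free_roam A free-roam table with both probe days for the mouse
#'   (columns as in [read_free_roam()]).
#' @param day7_ranking A [rank_flavors()] table for the same mouse's day-7
#'   session.
#' @return A tibble: `mouse_id`, `rank`, `restaurant`, `delta_entries`,
#'   `delta_time_s`.
#' @export
cpp_delta <- function(free_roam, day7_ranking) {
  m <- unique(free_roam$mouse_id)
  if (length(m) != 1) abort("`free_roam` must contain exactly one mouse.")
  if (!setequal(unique(free_roam$probe_day), c(0L, 8L))) {
    abort("Need both probe days (0 and 8).")
  }
  wide <- free_roam %>%
    tidyr::pivot_wider(id_cols = "restaurant", names_from = "probe_day",
                       values_from = c("wz_entries", "wz_time_s"))
  wide %>%
    mutate(
      mouse_id = m,
      delta_entries = .data$wz_entries_8 - .data$wz_entries_0,
      delta_time_s = .data$wz_time_s_8 - .data$wz_time_s_0
    ) %>%
    left_join(select(day7_ranking, dplyr::all_of(c("restaurant", "rank"))),
              by = "restaurant") %>%
    arrange(.data$rank) %>%
    select(dplyr::all_of(c("mouse_id", "rank", "restaurant", "delta_entries",
                           "delta_time_s")))
}
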