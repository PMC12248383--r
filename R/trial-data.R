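# Canonical trial table: schema, validation, and CSV I/O.
#
# The whole package works on one tidy trial table: one row per restaurant
# encounter. Sessions are the (mouse_id, day) groups of that table; the
# session-level constants (budget, epoch) derive from the schedule.

RR_FLAVORS <- c("chocolate", "banana", "grape", "plain")

# Fixed restaurant -> flavor assignment used throughout.
#' Flavor served at each restaurant
#'
#' Restaurants 1-4 serve chocolate, banana, grape, and plain pellets
#' respectively.
#'
#' @param restaurant Integer vector in 1..4.
#' @return Character vector of flavor names.
#' @export
restaurant_flavor <- function(restaurant) {
  RR_FLAVORS[restaurant]
}

# Column order of the on-disk trial table.
rr_trial_cols <- function() {
  c("mouse_id", "day", "trial_index", "restaurant", "flavor", "offer_s",
    "tone_hz", "oz_outcome", "oz_latency_s", "wz_outcome", "wz_time_spent_s",
    "consume_s", "travel_s", "t_start_s", "truncated")
}

rr_trial_col_types <- function() {
  readr::cols(
    mouse_id = readr::col_character(),
    day = readr::col_integer(),
    trial_index = readr::col_integer(),
    restaurant = readr::col_integer(),
    flavor = readr::col_character(),
    offer_s = readr::col_integer(),
    tone_hz = readr::col_integer(),
    oz_outcome = readr::col_character(),
    oz_latency_s = readr::col_double(),
    wz_outcome = readr::col_character(),
    wz_time_spent_s = readr::col_double(),
    consume_s = readr::col_double(),
    travel_s = readr::col_double(),
    t_start_s = readr::col_double(),
    truncated = readr::col_logical()
  )
}

sort_trials <- function(trials) {
  arrange(trials, .data$mouse_id, .data$day, .data$trial_index)
}

#' Validate a trial table
#'
#' Checks every structural invariant of the trial table and returns a report
#' of violations rather than throwing. An empty report means the table is
#' sound. The rules checked here are the single source of truth for the
#' preconditions of every estimator in the package.
#'
#' Rules: `wz_none_iff_skip` (a wait-zone outcome exists iff the offer was
#' accepted), `earn_time_equals_offer`, `quit_time_in_range`
#' (0 <= time spent < offer on quits), `tone_code` (pitch matches the
#' 4000 + 387*(offer-1) mapping), `serial_order` (restaurants advance
#' cyclically 1-2-3-4), `offer_in_epoch_range`, `nonnegative_times`, and
#' `budget` (summed epoch durations of non-truncated trials fit the session
#' budget).
#'
#' @param trials A trial table (see [read_trials()] for the schema).
#' @param schedule An [epoch_schedule()].
#' @return A tibble with columns `mouse_id`, `day`, `trial_index`, `rule`;
#'   zero rows when all invariants hold.
#' @export
validate_trials <- function(trials, schedule = epoch_schedule()) {
  trials <- as_tibble(trials)
  need <- setdiff(rr_trial_cols(), names(trials))
  if (length(need)) {
    abort(paste0("Trial table is missing column(s): ", paste(need, collapse = ", ")))
  }
  trials <- sort_trials(trials)
  viol <- function(mask, rule) {
    if (!any(mask, na.rm = TRUE)) return(NULL)
    mask[is.na(mask)] <- TRUE
    tibble(
      mouse_id = trials$mouse_id[mask],
      day = trials$day[mask],
      trial_index = trials$trial_index[mask],
      rule = rule
    )
  }
  skip <- trials$oz_outcome == "skip"
  reports <- list(
    viol(!(trials$oz_outcome %in% c("enter", "skip")) |
           !(trials$wz_outcome %in% c("earn", "quit", "none")), "outcome_labels"),
    viol((trials$wz_outcome == "none") != skip, "wz_none_iff_skip"),
    viol(trials$wz_outcome == "earn" &
           trials$wz_time_spent_s != trials$offer_s, "earn_time_equals_offer"),
    viol(trials$wz_outcome == "quit" &
           (trials$wz_time_spent_s < 0 |
              trials$wz_time_spent_s >= trials$offer_s), "quit_time_in_range"),
    viol(skip & trials$wz_time_spent_s != 0, "skip_has_zero_wz_time"),
    viol(trials$tone_hz != RR_TONE_BASE_HZ +
           RR_TONE_STEP_HZ * (trials$offer_s - 1L), "tone_code"),
    viol(trials$flavor != restaurant_flavor(trials$restaurant), "flavor_map"),
    viol(trials$oz_latency_s < 0 | trials$consume_s < 0 |
           trials$travel_s < 0 | trials$t_start_s < 0, "nonnegative_times"),
    viol(trials$wz_outcome != "earn" & trials$consume_s != 0, "consume_only_on_earn")
  )
  # serial restaurant order within a session
  ser <- trials %>%
    group_by(.data$mouse_id, .data$day) %>%
    mutate(.prev = lag(.data$restaurant),
           .bad_serial = !is.na(.data$.prev) &
             .data$restaurant != (.data$.prev %% 4L) + 1L) %>%
    ungroup()
  reports <- c(reports, list(viol(ser$.bad_serial, "serial_order")))
  # offer within the day's scheduled range
  rng <- vapply(trials$day, function(d) {
    ok <- tryCatch(offer_range_for_day(d, schedule), error = function(e) c(NA_integer_, NA_integer_))
    ok
  }, integer(2))
  bad_offer <- is.na(rng[1, ]) | trials$offer_s < rng[1, ] | trials$offer_s > rng[2, ]
  reports <- c(reports, list(viol(bad_offer, "offer_in_epoch_range")))
  # budget conservation per session (non-truncated trials only)
  bud <- trials %>%
    filter(!.data$truncated) %>%
    group_by(.data$mouse_id, .data$day) %>%
    summarise(
      elapsed = sum(.data$oz_latency_s + .data$wz_time_spent_s +
                      .data$consume_s + .data$travel_s),
      trial_index = if (n() > 0) min(.data$trial_index) else NA_integer_,
      .groups = "drop"
    ) %>%
    filter(.data$elapsed > schedule$session_budget_s + 1e-3)
  if (nrow(bud)) {
    reports <- c(reports, list(tibble(
      mouse_id = bud$mouse_id, day = bud$day,
      trial_index = bud$trial_index, rule = "budget"
    )))
  }
  out <- bind_rows(reports)
  if (nrow(out) == 0) {
    return(tibble(mouse_id = character(), day = integer(),
                  trial_index = integer(), rule = character()))
  }
  sort_trials(out)
}

#' Write a trial table to CSV
#'
#' Rows are written sorted by (mouse, day, trial index) in a fixed column
#' order, so write-load-write is byte-identical. If the table carries a
#' `group` column (cohort treatment labels), the labels go to a JSON sidecar
#' `<path>.json` rather than into the CSV, keeping the CSV schema fixed.
#'
#' @param trials A validated trial table.
#' @param path Output CSV path.
#' @param sidecar Path for the cohort-metadata JSON sidecar; `NULL` for
#'   `<path>.json`. Only written when `trials` has a `group` column.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, sidecar = NULL) {
  trials <- as_tibble(trials)
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  if ("group" %in% names(trials) && nrow(trials) > 0) {
    groups <- trials %>%
      distinct(.data$mouse_id, .data$group) %>%
      arrange(.data$mouse_id)
    jsonlite::write_json(
      list(groups = groups),
      sidecar, dataframe = "columns", auto_unbox = FALSE, digits = NA
    )
  }
  out <- trials %>%
    sort_trials() %>%
    select(dplyr::all_of(rr_trial_cols()))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Loads a trial table written by [write_trials()] (or any file matching the
#' documented schema), validates every invariant, and returns the trials
#' sorted by (mouse, day, trial index). Group labels are re-attached from the
#' JSON sidecar when present.
#'
#' @param path CSV path.
#' @param sidecar Sidecar JSON path (`NULL` for `<path>.json`; silently
#'   skipped when absent).
#' @param schedule An [epoch_schedule()] used for validation.
#' @param validate If `TRUE` (default), abort on any invariant violation,
#'   naming the offending rows.
#' @return A tibble of trials, one row per restaurant encounter.
#' @export
read_trials <- function(path, sidecar = NULL, schedule = epoch_schedule(),
                        validate = TRUE) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  need <- setdiff(rr_trial_cols(), hdr)
  if (length(need)) {
    abort(paste0("Trial file is missing column(s): ", paste(need, collapse = ", ")))
  }
  trials <- readr::read_csv(path, col_types = rr_trial_col_types()) %>%
    select(dplyr::all_of(rr_trial_cols())) %>%
    sort_trials()
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$groups)) {
      trials <- left_join(trials, as_tibble(meta$groups), by = "mouse_id")
    }
  }
  if (validate) {
    rep <- validate_trials(trials, schedule)
    if (nrow(rep)) {
      ex <- head(rep, 5)
      abort(paste0(
        "Trial table fails validation (", nrow(rep), " violation(s)); first: ",
        paste(sprintf("[%s day %d trial %d: %s]", ex$mouse_id, ex$day,
                      ex$trial_index, ex$rule), collapse = " ")
      ))
    }
  }
  trials
}

#' Write / read free-roam probe logs
#'
#' Free-roam probes are 20-min task-free sessions on day 0 (pre) and day 8
#' (post) used for conditioned-place-preference scoring. The table has one
#' row per mouse, probe day, and restaurant, with wait-zone entry counts and
#' occupancy seconds.
#'
#' @param free_roam A free-roam table with columns `mouse_id`, `probe_day`,
#'   `restaurant`, `wz_entries`, `wz_time_s`.
#' @param path CSV path.
#' @return For the writer, `path` invisibly; for the reader, a tibble.
#' @export
write_free_roam <- function(free_roam, path) {
  out <- free_roam %>%
    as_tibble() %>%
    select(dplyr::all_of(c("mouse_id", "probe_day", "restaurant",
                           "wz_entries", "wz_time_s"))) %>%
    arrange(.data$mouse_id, .data$probe_day, .data$restaurant)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_free_roam
#' @export
read_free_roam <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    mouse_id = readr::col_character(),
    probe_day = readr::col_integer(),
    restaurant = readr::col_integer(),
    wz_entries = readr::col_integer(),
    wz_time_s = readr::col_double()
  ))
}

#' Session index of a trial table
#'
#' One row per (mouse, day) with the epoch label, trial count, and group
#' label when available. Sessions with zero trials exist only in the
#' simulator's ground-truth record, not here.
#'
#' @inheritParams validate_trials
#' @return A tibble of sessions.
#' @export
session_index <- function(trials, schedule = epoch_schedule()) {
  trials %>%
    group_by(.data$mouse_id, .data$day) %>%
    summarise(
      n_trials = n(),
      n_truncated = sum(.data$truncated),
      .groups = "drop"
    ) %>%
    mutate(epoch = vapply(.data$day, epoch_label_for_day, character(1),
                          schedule = schedule),
           budget_s = schedule$session_budget_s)
}
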