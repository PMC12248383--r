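# Fixed structure of the Restaurant Row task: the block schedule of offer
# ranges, the tone-pitch cost code, and offer sampling.

#' The epoch schedule of the task
#'
#' Restaurant Row is run for 45 consecutive daily sessions. Offer delays are
#' drawn uniformly from an epoch-dependent range that widens in blocks: 1 s
#' only during week 1, then 1-5 s, 1-15 s, and finally 1-30 s for the
#' remainder of testing. Task-free probe sessions (free roam, 20 min) occur on
#' day 0 and day 8.
#'
#' @param blocks A data frame with columns `day_start`, `day_end`,
#'   `offer_min_s`, `offer_max_s` tiling days 1-45 without overlap. Defaults to
#'   the standard protocol.
#' @param session_budget_s Daily foraging budget in seconds (default 1800,
#'   i.e. 30 min).
#' @param probe_days Integer days on which free-roam probes run.
#' @param probe_duration_s Probe duration in seconds (default 1200).
#'
#' @return An object of class `rr_schedule`: a list with the validated block
#'   table and session constants.
#' @export
#' @examples
#' sched <- epoch_schedule()
#' offer_range_for_day(13, sched)
epoch_schedule <- function(blocks = NULL,
                           session_budget_s = 1800,
                           probe_days = c(0L, 8L),
                           probe_duration_s = 1200) {
  if (is.null(blocks)) {
    blocks <- tibble(
      day_start   = c(1L, 8L, 13L, 18L),
      day_end     = c(7L, 12L, 17L, 45L),
      offer_min_s = c(1L, 1L, 1L, 1L),
      offer_max_s = c(1L, 5L, 15L, 30L)
    )
  }
  blocks <- as_tibble(blocks)
  req <- c("day_start", "day_end", "offer_min_s", "offer_max_s")
  if (!all(req %in% names(blocks))) {
    abort("`blocks` must have columns day_start, day_end, offer_min_s, offer_max_s.")
  }
  blocks <- arrange(blocks, .data$day_start)
  days <- unlist(Map(seq, blocks$day_start, blocks$day_end))
  if (anyDuplicated(days) || !setequal(days, seq(min(blocks$day_start), max(blocks$day_end)))) {
    abort("Schedule blocks must tile the day range without overlap.")
  }
  if (any(blocks$offer_min_s > blocks$offer_max_s) || any(blocks$offer_min_s < 1)) {
    abort("Offer ranges must satisfy 1 <= offer_min_s <= offer_max_s.")
  }
  structure(
    list(
      blocks = blocks,
      session_budget_s = session_budget_s,
      probe_days = as.integer(probe_days),
      probe_duration_s = probe_duration_s
    ),
    class = "rr_schedule"
  )
}

#' @export
print.rr_schedule <- function(x, ...) {
  cat("<rr_schedule> ", nrow(x$blocks), " blocks, days ",
      min(x$blocks$day_start), "-", max(x$blocks$day_end),
      ", budget ", x$session_budget_s, " s\n", sep = "")
  print(x$blocks)
  invisible(x)
}

# Base pitch and step of the tone cost code, Hz.
RR_TONE_BASE_HZ <- 4000L
RR_TONE_STEP_HZ <- 387L

#' Tone pitch cueing an offer delay
#'
#' Offers are cued by pure tones whose pitch encodes the delay: a 1-s offer is
#' 4000 Hz and each additional second of delay adds 387 Hz, so the 1-30 s range
#' spans 4000-15223 Hz. During the countdown the pitch steps back down 387 Hz
#' per second, ending at 4000 Hz at the moment of earning.
#'
#' @param offer_s Integer offer delay(s) in seconds, each in 1-30.
#' @return Integer tone frequency/frequencies in Hz.
#' @seealso [offer_from_tone()] for the inverse mapping.
#' @export
#' @examples
#' tone_frequency(c(1, 4, 30))
tone_frequency <- function(offer_s) {
  if (length(offer_s) == 0) return(integer(0))
  if (any(is.na(offer_s)) || any(offer_s != as.integer(offer_s)) ||
      any(offer_s < 1) || any(offer_s > 30)) {
    abort("`offer_s` must be integer seconds in 1..30.")
  }
  RR_TONE_BASE_HZ + RR_TONE_STEP_HZ * (as.integer(offer_s) - 1L)
}

#' Recover an offer delay from its tone pitch
#'
#' Exact inverse of [tone_frequency()] on the 1-30 s offer grid.
#'
#' @param tone_hz Integer tone frequency/frequencies in Hz.
#' @return Integer offer delay(s) in seconds.
#' @export
offer_from_tone <- function(tone_hz) {
  off <- (tone_hz - RR_TONE_BASE_HZ) / RR_TONE_STEP_HZ + 1
  if (any(is.na(off)) || any(off != round(off)) || any(off < 1) || any(off > 30)) {
    abort("`tone_hz` is not on the tone code grid 4000 + 387*(offer - 1), offer in 1..30.")
  }
  as.integer(round(off))
}

#' Offer range in force on a given day
#'
#' @param day Integer day index within the schedule.
#' @param schedule An [epoch_schedule()].
#' @return Integer vector `c(min_s, max_s)`.
#' @export
offer_range_for_day <- function(day, schedule = epoch_schedule()) {
  stopifnot(inherits(schedule, "rr_schedule"))
  b <- schedule$blocks
  hit <- which(day >= b$day_start & day <= b$day_end)
  if (length(day) != 1 || length(hit) != 1) {
    abort(paste0("Day ", paste(day, collapse = ","), " is not covered by the schedule."))
  }
  c(b$offer_min_s[hit], b$offer_max_s[hit])
}

#' Epoch label for a day
#'
#' @inheritParams offer_range_for_day
#' @return A label such as `"1s"` or `"1-30s"`.
#' @export
epoch_label_for_day <- function(day, schedule = epoch_schedule()) {
  rng <- offer_range_for_day(day, schedule)
  if (rng[1] == rng[2]) paste0(rng[1], "s") else paste0(rng[1], "-", rng[2], "s")
}

#' Sample offer delays for a day
#'
#' Offers are integer seconds drawn uniformly from the day's scheduled range.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param n Number of offers to draw.
#' @inheritParams offer_range_for_day
#' @return Integer vector of offers in seconds.
#' @export
sample_offer <- function(n, day, schedule = epoch_schedule()) {
  rng <- offer_range_for_day(day, schedule)
  if (rng[1] == rng[2]) return(rep(rng[1], n))
  as.integer(floor(runif(n, rng[1], rng[2] + 1L)))
}
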