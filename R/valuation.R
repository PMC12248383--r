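# Trial economics: offer value, value left at quit, quit categories, and
# quit-latency aggregates. All values are in seconds relative to the mouse's
# wait-zone threshold.

#' Offer value relative to the wait-zone threshold
#'
#' The value of an offer is the wait-zone threshold minus the cued delay:
#' `theta_wz - offer_s`. Negative values mark offers above the animal's
#' willingness to wait (e.g., threshold 10 s, offer 18 s, value -8 s).
#'
#' @param theta_wz Wait-zone threshold(s), seconds.
#' @param offer_s Cued offer(s), seconds.
#' @return Offer value(s), seconds; `NA` propagates (trials lacking a
#'   threshold are excluded downstream).
#' @export
#' @examples
#' offer_value(10, 18) # -8
offer_value <- function(theta_wz, offer_s) {
  theta_wz - offer_s
}

#' Time left and value left at the moment of quitting
#'
#' The countdown time remaining at quit is `offer_s - wz_time_spent_s`; the
#' value left is the wait-zone threshold minus that remaining time. Negative
#' value left marks a remaining wait not worth finishing, i.e. a time-saving
#' quit (e.g., threshold 10 s, offer 18 s, quit after 4 s: 14 s remain,
#' value left -4 s).
#'
#' @inheritParams offer_value
#' @param wz_time_spent_s Seconds already waited at the quit; must satisfy
#'   `0 <= wz_time_spent_s < offer_s`.
#' @return A tibble with `time_left_s` and `value_left`.
#' @export
#' @examples
#' value_left(10, 18, 4)
value_left <- function(theta_wz, offer_s, wz_time_spent_s) {
  if (any(wz_time_spent_s < 0 | wz_time_spent_s >= offer_s, na.rm = TRUE)) {
    abort("Quits require 0 <= wz_time_spent_s < offer_s.")
  }
  time_left <- offer_s - wz_time_spent_s
  tibble(time_left_s = time_left, value_left = theta_wz - time_left)
}

#' Classify a quit by its economics
#'
#' Quits partition into three mutually exclusive categories by the signs of
#' offer value and value left: `advantageous` (negative offer value, negative
#' value left: a time-saving correction of a bad acceptance),
#' `late_negative` (negative offer value but non-negative value left: the
#' mouse quit after the point where staying had become worthwhile), and
#' `positive_offer` (the accepted offer itself was at or below threshold).
#' Boundary zeros count as "positive/below-threshold".
#'
#' @param offer_value,value_left Numeric vectors, seconds.
#' @return A factor with levels `advantageous`, `late_negative`,
#'   `positive_offer`.
#' @export
classify_quit <- function(offer_value, value_left) {
  out <- ifelse(offer_value >= 0, "positive_offer",
                ifelse(value_left < 0, "advantageous", "late_negative"))
  factor(out, levels = c("advantageous", "late_negative", "positive_offer"))
}

#' Per-trial quit economics for a cohort
#'
#' Joins wait-zone thresholds onto every (non-truncated) quit trial in the
#' day range and computes offer value, time left, value left, and the quit
#' category. Trials whose mouse-restaurant threshold is missing are dropped
#' and counted in the `n_missing_theta` attribute.
#'
#' @param trials A validated trial table.
#' @param thresholds A WZ threshold table from [block_thresholds()].
#' @param days Day range (inclusive); default the 1-30 s scarcity block,
#'   whose offer spread is what makes the categories meaningful.
#' @return A tibble keyed by trial with the economic quantities.
#' @export
quit_economics <- function(trials, thresholds, days = c(18, 45)) {
  th <- thresholds %>%
    filter(.data$zone == "WZ") %>%
    select(dplyr::all_of(c("mouse_id", "restaurant", "theta")))
  quits <- trials %>%
    filter(!.data$truncated, .data$day >= days[1], .data$day <= days[2],
           .data$wz_outcome == "quit") %>%
    left_join(th, by = c("mouse_id", "restaurant"))
  n_missing <- sum(is.na(quits$theta))
  quits <- quits %>% filter(!is.na(.data$theta))
  vl <- value_left(quits$theta, quits$offer_s, quits$wz_time_spent_s)
  out <- quits %>%
    select(dplyr::all_of(c("mouse_id", "day", "trial_index", "restaurant",
                           "flavor", "offer_s", "wz_time_spent_s", "theta"))) %>%
    mutate(
      offer_value = offer_value(.data$theta, .data$offer_s),
      time_left_s = vl$time_left_s,
      value_left = vl$value_left,
      category = classify_quit(.data$offer_value, .data$value_left)
    )
  attr(out, "n_missing_theta") <- n_missing
  out
}

#' Quit-latency and quit-category aggregates
#'
#' Summarizes quit behavior per grouping key: mean latency to quit (seconds
#' waited before quitting), mean value left, and counts per quit category.
#'
#' @inheritParams quit_economics
#' @param group_by Character vector of grouping columns of the trial table
#'   (e.g. `"mouse_id"`, or `c("mouse_id", "flavor")`).
#' @return A tibble of aggregates; zero rows when there are no quits.
#' @export
quit_latency_stats <- function(trials, thresholds, group_by = "mouse_id",
                               days = c(18, 45)) {
  econ <- quit_economics(trials, thresholds, days)
  if (nrow(econ) == 0) {
    return(tibble())
  }
  econ %>%
    group_by(across(dplyr::all_of(group_by))) %>%
    summarise(
      n_quits = n(),
      mean_quit_latency_s = mean(.data$wz_time_spent_s),
      mean_value_left = mean(.data$value_left),
      n_advantageous = sum(.data$category == "advantageous"),
      n_late_negative = sum(.data$category == "late_negative"),
      n_positive_offer = sum(.data$category == "positive_offer"),
      .groups = "drop"
    )
}
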