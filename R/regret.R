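# Regret-related trial-pair sequence analysis.
#
# Two scenario types, each contrasting an economically suboptimal choice on
# trial t-1 (violation) against a matched control (nonviolation), with the
# readout being acceptance of a low-value offer on trial t:
#   type 1: skipping a high-value offer (violation) vs accepting it
#           (nonviolation);
#   type 2: entering then quitting a low-value offer (violation) vs skipping
#           it (nonviolation).
# "High/low value" is offer value (theta_wz - offer) >= 0 / < 0 relative to
# the mouse's own wait-zone threshold. Arms are stratified by (restaurant of
# trial t-1, offer-value bin at t-1, offer-value bin at t) so violation and
# control pairs match on offer values, flavor identities (fixed by the
# restaurant), and serial position.

#' Extract violation / nonviolation trial-pair sequences
#'
#' Scans consecutive restaurant encounters within each session and labels the
#' type-1 and type-2 sequence arms defined above. Readout trials must carry a
#' negative offer value. Mice lacking a wait-zone threshold in any restaurant
#' are excluded (listed in the `excluded_mice` attribute). Strata (restaurant
#' x value-bin combination) in which a mouse lacks one of the two arms are
#' dropped at the delta stage.
#'
#' @param trials A validated trial table.
#' @param thresholds A WZ threshold table from [block_thresholds()].
#' @param days Day range, default the 1-30 s block.
#' @param value_bin_s Width of the offer-value matching bins, seconds
#'   (default 2).
#' @param type1_nonviolation `"accept"` counts both earns and quits of the
#'   high-value offer as the type-1 control (default); `"earn"` restricts to
#'   earns.
#' @return A tibble of pairs: `mouse_id`, `day`, `type`, `arm`, restaurant
#'   and offer-value details of both trials, value bins, and
#'   `readout_accept`.
#' @export
extract_sequences <- function(trials, thresholds, days = c(18, 45),
                              value_bin_s = 2,
                              type1_nonviolation = c("accept", "earn")) {
  type1_nonviolation <- match.arg(type1_nonviolation)
  th <- thresholds %>%
    filter(.data$zone == "WZ", !is.na(.data$theta)) %>%
    select(dplyr::all_of(c("mouse_id", "restaurant", "theta")))
  complete <- th %>% count(.data$mouse_id) %>% filter(.data$n == 4L)
  excluded <- setdiff(unique(trials$mouse_id), complete$mouse_id)
  dat <- trials %>%
    filter(!.data$truncated, .data$day >= days[1], .data$day <= days[2],
           .data$mouse_id %in% complete$mouse_id) %>%
    left_join(th, by = c("mouse_id", "restaurant")) %>%
    mutate(ov = offer_value(.data$theta, .data$offer_s)) %>%
    arrange(.data$mouse_id, .data$day, .data$trial_index)

  paired <- dat %>%
    group_by(.data$mouse_id, .data$day) %>%
    mutate(
      prev_index = lag(.data$trial_index),
      prev_restaurant = lag(.data$restaurant),
      prev_ov = lag(.data$ov),
      prev_oz = lag(.data$oz_outcome),
      prev_wz = lag(.data$wz_outcome)
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$prev_index),
           .data$trial_index == .data$prev_index + 1L,
           .data$ov < 0)

  t1_ctrl_ok <- if (type1_nonviolation == "accept") {
    paired$prev_oz == "enter"
  } else {
    paired$prev_wz == "earn"
  }
  mk <- function(mask, type, arm) {
    d <- paired[mask, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    tibble(
      mouse_id = d$mouse_id, day = d$day, type = type, arm = arm,
      t1_restaurant = d$prev_restaurant, t_restaurant = d$restaurant,
      t1_offer_value = d$prev_ov, t_offer_value = d$ov,
      bin_t1 = floor(d$prev_ov / value_bin_s),
      bin_t = floor(d$ov / value_bin_s),
      readout_accept = d$oz_outcome == "enter"
    )
  }
  out <- bind_rows(
    mk(paired$prev_ov >= 0 & paired$prev_oz == "skip", 1L, "violation"),
    mk(paired$prev_ov >= 0 & t1_ctrl_ok, 1L, "nonviolation"),
    mk(paired$prev_ov < 0 & paired$prev_wz == "quit", 2L, "violation"),
    mk(paired$prev_ov < 0 & paired$prev_oz == "skip", 2L, "nonviolation")
  )
  if (is.null(out)) out <- tibble()
  attr(out, "excluded_mice") <- excluded
  attr(out, "value_bin_s") <- value_bin_s
  out
}

#' Per-mouse regret delta scores
#'
#' Within each mouse and stratum (restaurant at t-1, value bin at t-1, value
#' bin at t) holding both arms, computes the difference in readout acceptance
#' rates, p(accept | violation) - p(accept | nonviolation), then combines
#' strata weighted by the effective pair count
#' `n_v * n_nv / (n_v + n_nv)`. Mice with fewer than `min_pairs` pairs in
#' either arm (after stratum matching) are dropped and listed in the
#' `dropped_mice` attribute.
#'
#' @param pairs Output of [extract_sequences()].
#' @param type Scenario type, 1 or 2.
#' @param min_pairs Minimum matched pairs per arm and mouse (default 5).
#' @return A tibble: `mouse_id`, `type`, `delta`, `n_violation`,
#'   `n_nonviolation`.
#' @export
sequence_delta <- function(pairs, type, min_pairs = 5) {
  stopifnot(type %in% c(1L, 2L))
  dat <- if (nrow(pairs) == 0 || !"type" %in% names(pairs)) {
    tibble()
  } else {
    filter(pairs, .data$type == .env$type)
  }
  if (nrow(dat) == 0) {
    return(tibble(mouse_id = character(), type = integer(), delta = numeric(),
                  n_violation = integer(), n_nonviolation = integer()))
  }
  strata <- dat %>%
    group_by(.data$mouse_id, .data$t1_restaurant, .data$bin_t1, .data$bin_t,
             .data$arm) %>%
    summarise(n = n(), p = mean(.data$readout_accept), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "arm", values_from = c("n", "p")) %>%
    filter(!is.na(.data$n_violation), !is.na(.data$n_nonviolation))
  all_mice <- unique(dat$mouse_id)
  out <- strata %>%
    mutate(w = .data$n_violation * .data$n_nonviolation /
             (.data$n_violation + .data$n_nonviolation)) %>%
    group_by(.data$mouse_id) %>%
    summarise(
      delta = sum(.data$w * (.data$p_violation - .data$p_nonviolation)) /
        sum(.data$w),
      n_violation = sum(.data$n_violation),
      n_nonviolation = sum(.data$n_nonviolation),
      .groups = "drop"
    ) %>%
    filter(.data$n_violation >= min_pairs,
           .data$n_nonviolation >= min_pairs) %>%
    mutate(type = as.integer(.env$type), .after = "mouse_id")
  attr(out, "dropped_mice") <- setdiff(all_mice, out$mouse_id)
  out
}

#' Cohort-level test of regret deltas against zero
#'
#' One-sample tests of the per-mouse delta scores against 0: the one-sample
#' t statistic and the exact (binomial) sign test are both reported.
#'
#' @param deltas Output of [sequence_delta()], or a numeric vector of
#'   per-mouse deltas.
#' @return A one-row tibble: `n`, `mean_delta`, `t_stat`, `p_t`, `n_pos`,
#'   `n_nonzero`, `p_sign`, `direction`.
#' @export
cohort_sign_test <- function(deltas) {
  d <- if (is.data.frame(deltas)) deltas$delta else deltas
  d <- d[!is.na(d)]
  if (length(d) < 3) abort("Need at least 3 mice with defined deltas.")
  if (stats::sd(d) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(d, mu = 0)
  }
  n_pos <- sum(d > 0)
  n_nonzero <- sum(d != 0)
  p_sign <- if (n_nonzero == 0) 1 else binom.test(n_pos, n_nonzero)$p.value
  tibble(
    n = length(d),
    mean_delta = mean(d),
    t_stat = unname(tt$statistic),
    p_t = tt$p.value,
    n_pos = n_pos,
    n_nonzero = n_nonzero,
    p_sign = p_sign,
    direction = if (mean(d) > 0) "positive" else if (mean(d) < 0) "negative" else "zero"
  )
}
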