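# Indifference-point estimation: Heaviside step fits of enter/skip (offer
# zone) and earn/quit (wait zone) choices against the cued offer, plus the
# day-7 flavor ranking.

step_grid <- function(epoch_max) seq(0.5, epoch_max + 0.5, by = 1)

# Minimal fast fitter shared by fit_step_threshold and block_thresholds.
fit_step_core <- function(offers, outcomes, epoch_max) {
  grid <- step_grid(epoch_max)
  # 0-1 loss of the rule "accept iff offer < theta" at each grid candidate
  losses <- vapply(grid, function(th) sum(outcomes != (offers < th)), numeric(1))
  cands <- grid[losses == min(losses)]
  k <- length(cands)
  theta <- cands[floor(k / 2) + 1L]
  list(
    theta = theta,
    loss = min(losses),
    clamped = theta == grid[1] || theta == grid[length(grid)],
    grid = grid,
    losses = losses
  )
}

#' Fit a Heaviside step threshold to binary choices
#'
#' Estimates the indifference point of accept-type choices as a function of
#' the cued offer by minimizing the 0-1 loss of the rule "accept iff
#' offer < theta" over the half-integer candidate grid
#' `0.5, 1.5, ..., epoch_max + 0.5`. The half-integer grid makes every
#' integer offer unambiguous under the strict inequality. Ties in the loss
#' are broken by the middle element of the minimizing set (the upper of the
#' two middles when the set has even size). Single-class data (all accepted
#' or all rejected) yield the corresponding grid endpoint with
#' `clamped = TRUE` rather than an error.
#'
#' @param offers Integer offers in seconds.
#' @param outcomes Logical (or 0/1) accept indicator: enter vs skip in the
#'   offer zone, earn vs quit in the wait zone.
#' @param epoch_max Largest offer of the epoch (sets the grid top).
#' @param min_trials Minimum observations required (default 5).
#' @return An object of class `rr_step_fit`: list with `theta` (seconds),
#'   `loss` (0-1 loss at `theta`), `clamped`, `n`, and the full grid/loss
#'   profile. Use [tidy()] / [glance()] for tibble views.
#' @export
#' @examples
#' fit_step_threshold(c(2, 5, 8, 12, 20, 26), c(1, 1, 1, 1, 0, 0), 30)$theta
fit_step_threshold <- function(offers, outcomes, epoch_max, min_trials = 5) {
  outcomes <- as.logical(outcomes)
  if (length(offers) != length(outcomes) || anyNA(offers) || anyNA(outcomes)) {
    abort("`offers` and `outcomes` must be equal-length and complete.")
  }
  if (length(offers) < min_trials) {
    abort(paste0("Too few trials for a threshold fit (", length(offers),
                 " < ", min_trials, ")."))
  }
  fit <- fit_step_core(offers, outcomes, epoch_max)
  fit$n <- length(offers)
  fit$offers <- offers
  fit$outcomes <- outcomes
  class(fit) <- "rr_step_fit"
  fit
}

#' @export
print.rr_step_fit <- function(x, ...) {
  cat("<rr_step_fit> theta = ", x$theta, " s (loss ", x$loss, "/", x$n,
      if (x$clamped) ", clamped" else "", ")\n", sep = "")
  invisible(x)
}

#' @method tidy rr_step_fit
#' @export
tidy.rr_step_fit <- function(x, ...) {
  tibble(theta = x$theta, loss = x$loss, n = x$n, clamped = x$clamped)
}

#' @method glance rr_step_fit
#' @export
glance.rr_step_fit <- function(x, ...) {
  tibble(theta = x$theta, loss = x$loss, n = x$n, clamped = x$clamped,
         accuracy = 1 - x$loss / x$n)
}

#' Per-mouse, per-restaurant thresholds over a day range
#'
#' Pools all (non-truncated) trials of `days` and fits one step threshold per
#' mouse and restaurant. Offer-zone fits use enter vs skip on every
#' encounter; wait-zone fits use earn vs quit on entered trials only, so a
#' restaurant's WZ trial count never exceeds its OZ count. Restaurants with
#' fewer than `min_trials` usable trials (or with the zone's choice entirely
#' absent) are reported with `theta = NA` rather than extrapolated.
#'
#' Thresholds pooled over the final scarcity block (days 18-45) are the
#' default input to all value computations; per-day fits (`by = "day"`) feed
#' the optimality time courses.
#'
#' @param trials A validated trial table.
#' @param zone `"OZ"` or `"WZ"`.
#' @param days Length-2 day range (inclusive), default `c(18, 45)`.
#' @param by `"block"` for one pooled fit per mouse-restaurant, `"day"` for
#'   daily fits.
#' @param min_trials Minimum trials per fit.
#' @param schedule An [epoch_schedule()] (sets the grid top from the range's
#'   largest scheduled offer).
#' @return A tibble: `mouse_id`, (`day`,) `restaurant`, `zone`, `theta`,
#'   `loss`, `n_trials`, `clamped`.
#' @export
block_thresholds <- function(trials, zone = c("WZ", "OZ"), days = c(18, 45),
                             by = c("block", "day"), min_trials = 5,
                             schedule = epoch_schedule()) {
  zone <- match.arg(zone)
  by <- match.arg(by)
  stopifnot(length(days) == 2, days[1] <= days[2])
  b <- schedule$blocks
  cover <- b$day_end >= days[1] & b$day_start <= days[2]
  if (!any(cover)) abort("`days` falls outside the schedule.")
  epoch_max <- max(b$offer_max_s[cover])

  dat <- trials %>%
    filter(!.data$truncated, .data$day >= days[1], .data$day <= days[2])
  if (zone == "WZ") {
    dat <- dat %>%
      filter(.data$oz_outcome == "enter") %>%
      mutate(.accept = .data$wz_outcome == "earn")
  } else {
    dat <- dat %>% mutate(.accept = .data$oz_outcome == "enter")
  }
  keys <- c("mouse_id", if (by == "day") "day", "restaurant")
  dat %>%
    group_by(across(dplyr::all_of(keys))) %>%
    summarise(
      {
        if (n() < min_trials) {
          tibble(theta = NA_real_, loss = NA_real_, n_trials = n(),
                 clamped = NA)
        } else {
          f <- fit_step_core(.data$offer_s, .data$.accept, epoch_max)
          tibble(theta = f$theta, loss = f$loss, n_trials = n(),
                 clamped = f$clamped)
        }
      },
      .groups = "drop"
    ) %>%
    mutate(zone = zone, .after = dplyr::last_col())
}

#' Rank restaurants by end-of-session earnings
#'
#' Restaurants are ranked 1 (most earned) to 4 by the session's earned-pellet
#' totals; the day-7 ranking defines each mouse's revealed flavor preference
#' order used by the place-preference and subjective-value analyses. Ties are
#' broken by restaurant order and flagged.
#'
#' @param session Trials of a single (mouse, day) session.
#' @return A tibble: `mouse_id`, `day`, `rank`, `restaurant`, `flavor`,
#'   `earns`, `tie_broken`.
#' @export
rank_flavors <- function(session) {
  session <- as_tibble(session)
  if (nrow(session) == 0) abort("`session` has no trials.")
  if (nrow(distinct(session, .data$mouse_id, .data$day)) != 1) {
    abort("`session` must contain exactly one (mouse_id, day) session.")
  }
  tibble(
    mouse_id = session$mouse_id[1],
    day = session$day[1],
    restaurant = 1:4,
    flavor = restaurant_flavor(1:4),
    earns = vapply(1:4, function(r) {
      sum(session$restaurant == r & session$wz_outcome == "earn")
    }, numeric(1))
  ) %>%
    mutate(tie_broken = .data$earns %in% .data$earns[duplicated(.data$earns)]) %>%
    arrange(dplyr::desc(.data$earns), .data$restaurant) %>%
    mutate(rank = row_number(), .before = "restaurant")
}
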