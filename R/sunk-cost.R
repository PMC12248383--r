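# Sunk-cost survival analysis: p(earn) on a (time spent, time left) grid, the
# 0-s just-entered control, and the bootstrap delta envelope.
#
# A trial with offer o that was still in the wait zone after s whole seconds
# contributes to cell (s, l = o - s): earns contribute survived-cells
# s = 0..o-1 (at s = o the outcome is realized, not a decision state), quits
# contribute s = 0..floor(time spent). The cell value is the fraction of
# contributing trials that ultimately earned. Comparing cells at matched time
# left l across different s isolates the effect of time already invested from
# temporal distance to the reward.

#' Stay/earn survival surface over (time spent, time left)
#'
#' Bins all accepted (wait-zone) trials of the day range into
#' (time spent, time left) pairs with a 1-s sliding window and computes the
#' probability of ultimately earning in each cell. With `zone = "OZ"` the
#' same bookkeeping is applied to offer-zone deliberation: trials contribute
#' states `s = 0..floor(oz latency)` at fixed `l = offer`, with "earn"
#' meaning the offer was accepted — the control analysis for showing that
#' sunk-cost sensitivity is specific to the wait zone.
#'
#' @param trials A validated trial table.
#' @param days Day range (inclusive), default the 1-30 s block.
#' @param min_count Minimum trials for a cell to be considered valid.
#' @param zone `"WZ"` (default) or `"OZ"`.
#' @return An `rr_sunk_surface`: a tibble with columns `s`, `l`, `p_earn`,
#'   `n`, `valid`, carrying per-mouse cell counts as attributes for
#'   [sunk_delta_envelope()]'s mouse-level bootstrap.
#' @export
stay_survival_surface <- function(trials, days = c(18, 45), min_count = 5,
                                  zone = c("WZ", "OZ")) {
  zone <- match.arg(zone)
  dat <- trials %>%
    filter(!.data$truncated, .data$day >= days[1], .data$day <= days[2])
  if (zone == "WZ") {
    dat <- dat %>% filter(.data$oz_outcome == "enter")
    s_max <- ifelse(dat$wz_outcome == "earn",
                    dat$offer_s - 1L,
                    floor(dat$wz_time_spent_s))
    earned <- dat$wz_outcome == "earn"
  } else {
    s_max <- floor(dat$oz_latency_s)
    earned <- dat$oz_outcome == "enter"
  }
  empty <- tibble(s = integer(), l = integer(), p_earn = numeric(),
                  n = integer(), valid = logical())
  if (nrow(dat) == 0) {
    return(structure(empty, class = c("rr_sunk_surface", class(empty)),
                     min_count = min_count, zone = zone))
  }
  reps <- s_max + 1L
  idx <- rep.int(seq_len(nrow(dat)), reps)
  s <- sequence(reps) - 1L
  l <- if (zone == "WZ") dat$offer_s[idx] - s else dat$offer_s[idx]
  cells <- tibble(
    mouse_id = dat$mouse_id[idx],
    restaurant = dat$restaurant[idx],
    s = as.integer(s),
    l = as.integer(l),
    earned = earned[idx]
  )
  per_unit <- cells %>%
    group_by(.data$mouse_id, .data$restaurant, .data$s, .data$l) %>%
    summarise(n = n(), earned = sum(.data$earned), .groups = "drop")
  pooled <- per_unit %>%
    group_by(.data$s, .data$l) %>%
    summarise(n = sum(.data$n), earned = sum(.data$earned), .groups = "drop") %>%
    mutate(p_earn = .data$earned / .data$n, valid = .data$n >= min_count) %>%
    select(dplyr::all_of(c("s", "l", "p_earn", "n", "valid"))) %>%
    arrange(.data$s, .data$l)
  # dense count matrices per (mouse, restaurant) unit for the envelope
  S <- max(pooled$s)
  L <- max(pooled$l)
  units <- per_unit %>%
    distinct(.data$mouse_id, .data$restaurant) %>%
    arrange(.data$mouse_id, .data$restaurant)
  ukey <- paste(units$mouse_id, units$restaurant)
  cell_id <- function(s, l) s * L + l  # l in 1..L
  K <- (S + 1L) * L
  N <- matrix(0, nrow(units), K, dimnames = list(ukey, NULL))
  E <- matrix(0, nrow(units), K)
  ui <- match(paste(per_unit$mouse_id, per_unit$restaurant), ukey)
  ci <- cell_id(per_unit$s, per_unit$l)
  N[cbind(ui, ci)] <- per_unit$n
  E[cbind(ui, ci)] <- per_unit$earned
  structure(
    pooled,
    class = c("rr_sunk_surface", class(pooled)),
    min_count = min_count, zone = zone, days = days,
    S = S, L = L, unit_mouse = units$mouse_id, N = N, E = E
  )
}

#' The 0-s sunk (just-entered) control row
#'
#' The control condition recalculates p(earn) as a function of time left from
#' trials at the moment of entry only (time spent = 0), i.e. trials whose
#' offer equals the time left. Identical to the `s == 0` rows of the surface.
#'
#' @param surface An `rr_sunk_surface`.
#' @return A tibble `l`, `p_earn`, `n`, `valid`; the `missing_l` attribute
#'   lists time-left values absent from the control.
#' @export
zero_sunk_control <- function(surface) {
  out <- surface %>%
    filter(.data$s == 0L) %>%
    select(dplyr::all_of(c("l", "p_earn", "n", "valid")))
  full_l <- seq_len(max(c(surface$l, 0L)))
  attr(out, "missing_l") <- setdiff(full_l, out$l)
  out
}

#' Sunk-cost delta envelope with mouse-level bootstrap CI
#'
#' The envelope is computed within mouse-restaurant units and then averaged:
#' for each unit and time-spent value `s`, `p_earn(s, l) - p_earn(0, l)` is
#' averaged over the time-left values `l` where both that unit's sunk cell
#' and its 0-s control cell hold at least `min_count` trials (the common-`l`
#' restriction keeps the two conditions on the same offer mix). Unit scores
#' are averaged into per-mouse delta scores and those into the cohort
#' envelope, so every animal (and every restaurant within it) acts as its own
#' control — differences in patience between mice or between flavors cannot
#' masquerade as a sunk-cost effect. Confidence intervals are a nonparametric
#' bootstrap over mice.
#'
#' By construction `delta = 0` exactly at `s = 0`. A positive envelope means
#' time already invested raises the probability of staying to earn at matched
#' time left — sensitivity to sunk costs.
#'
#' @param surface An `rr_sunk_surface` from [stay_survival_surface()] (its
#'   `min_count` applies per mouse-restaurant unit here).
#' @param bootstrap_reps Bootstrap replicates (default 1000).
#' @param seed Optional seed for the bootstrap resampling.
#' @param conf_level CI level (default 0.95).
#' @param min_l Minimum number of common time-left values for a mouse to
#'   contribute at a given `s`.
#' @return A tibble: `s`, `delta`, `lo`, `hi`, `n_mice` (contributing mice),
#'   `n_l` (median common time-left count among them); `delta` is `NA` where
#'   no mouse has a defined score.
#' @export
sunk_delta_envelope <- function(surface, bootstrap_reps = 1000, seed = NULL,
                                conf_level = 0.95, min_l = 2) {
  stopifnot(inherits(surface, "rr_sunk_surface"))
  if (nrow(surface) == 0) {
    return(tibble(s = integer(), delta = numeric(), lo = numeric(),
                  hi = numeric(), n_mice = integer(), n_l = integer()))
  }
  if (!is.null(seed)) set.seed(seed)
  S <- attr(surface, "S")
  L <- attr(surface, "L")
  N <- attr(surface, "N")     # units x cells trial counts
  E <- attr(surface, "E")     # units x cells earn counts
  min_count <- attr(surface, "min_count")
  unit_mouse <- attr(surface, "unit_mouse")
  mice <- unique(unit_mouse)
  n_mice <- length(mice)
  cell_id <- function(s, l) s * L + l

  # per-unit (mouse x restaurant) delta scores: Du[unit, s+1]
  P <- E / N                  # NaN where empty
  OK <- N >= min_count
  Du <- matrix(NA_real_, nrow(N), S + 1L)
  NLu <- matrix(0L, nrow(N), S + 1L)
  Du[, 1L] <- 0
  NLu[, 1L] <- as.integer(rowSums(OK[, cell_id(0L, 1:L), drop = FALSE]))
  for (s in seq_len(S)) {
    ls <- 1:L
    sunk <- cell_id(s, ls)
    ctrl <- cell_id(0L, ls)
    common <- OK[, sunk, drop = FALSE] & OK[, ctrl, drop = FALSE]
    diff <- (P[, sunk, drop = FALSE] - P[, ctrl, drop = FALSE]) * common
    k <- rowSums(common)
    d <- ifelse(k >= min_l, rowSums(diff, na.rm = TRUE) / k, NA_real_)
    Du[, s + 1L] <- d
    NLu[, s + 1L] <- as.integer(k)
  }
  # average units into per-mouse scores: D[mouse, s+1]
  mi <- match(unit_mouse, mice)
  D <- matrix(NA_real_, n_mice, S + 1L)
  NL <- matrix(0L, n_mice, S + 1L)
  for (j in seq_len(S + 1L)) {
    D[, j] <- vapply(seq_len(n_mice), function(m) {
      v <- Du[mi == m, j]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    NL[, j] <- vapply(seq_len(n_mice), function(m) {
      v <- NLu[mi == m, j][!is.na(Du[mi == m, j])]
      if (!length(v)) 0L else as.integer(sum(v))
    }, integer(1))
  }

  delta <- colMeans(D, na.rm = TRUE)
  delta[is.nan(delta)] <- NA_real_
  n_contrib <- colSums(!is.na(D))
  n_l_med <- vapply(seq_len(S + 1L), function(j) {
    v <- NL[!is.na(D[, j]), j]
    if (!length(v)) 0L else as.integer(round(median(v)))
  }, integer(1))

  alpha <- (1 - conf_level) / 2
  boot <- matrix(NA_real_, bootstrap_reps, S + 1L)
  for (b in seq_len(bootstrap_reps)) {
    idx <- sample.int(n_mice, n_mice, replace = TRUE)
    boot[b, ] <- colMeans(D[idx, , drop = FALSE], na.rm = TRUE)
  }
  lo <- apply(boot, 2, quantile, probs = alpha, na.rm = TRUE, names = FALSE)
  hi <- apply(boot, 2, quantile, probs = 1 - alpha, na.rm = TRUE,
              names = FALSE)
  lo[1L] <- hi[1L] <- 0

  tibble(
    s = 0:S,
    delta = delta,
    lo = as.numeric(lo),
    hi = as.numeric(hi),
    n_mice = as.integer(n_contrib),
    n_l = n_l_med
  )
}
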