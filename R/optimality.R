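# Theoretical food-maximizing and subjective-value-maximizing thresholds via
# yield simulation, and Euclidean-distance optimality scoring of observed
# threshold policies.

#' Timing parameters of the yield simulation
#'
#' The yield simulator runs an idealized agent through sessions: it visits
#' restaurants serially, accepts any offer at or below its threshold, always
#' waits accepted offers out, and pays a fixed non-waiting overhead (travel +
#' deliberation) per restaurant plus a consumption time per pellet.
#'
#' In the continuous limit with uniform offers on `[0, M]`, overhead `h`, and
#' consumption `c`, the pellet rate is proportional to
#' `T / (M*h + T^2/2 + c*T)`, maximized at `T* = sqrt(2*M*h)` independent of
#' `c`. The defaults (`h = 5/3` s, `c = 1.5` s) place the optimum of the
#' 1-30 s environment at 10 s.
#'
#' @param offer_min_s,offer_max_s Uniform integer offer range, seconds.
#' @param budget_s Session budget, seconds.
#' @param overhead_s Non-waiting time per restaurant visit, seconds.
#' @param consume_s Consumption time per earned pellet, seconds.
#' @return A list of class `rr_yield_params`.
#' @export
yield_sim_params <- function(offer_min_s = 1L, offer_max_s = 30L,
                             budget_s = 1800, overhead_s = 5 / 3,
                             consume_s = 1.5) {
  structure(
    list(offer_min_s = as.integer(offer_min_s),
         offer_max_s = as.integer(offer_max_s),
         budget_s = budget_s, overhead_s = overhead_s, consume_s = consume_s),
    class = "rr_yield_params"
  )
}

#' Closed-form yield rate and optimal threshold
#'
#' `yield_rate()` gives the expected pellet rate (pellets per second) of a
#' deterministic accept-iff-`offer <= T` policy under uniform integer offers
#' on `1..M`; `closed_form_optimal_threshold()` gives the continuous-offer
#' optimum `sqrt(2*M*h)`.
#'
#' @param T_s Threshold(s), seconds.
#' @param M Offer maximum, seconds.
#' @param h Per-restaurant overhead, seconds.
#' @param consume_s Consumption time, seconds.
#' @return A numeric rate / threshold.
#' @export
yield_rate <- function(T_s, M = 30, h = 5 / 3, consume_s = 1.5) {
  T_s / (M * h + T_s * (T_s + 1) / 2 + consume_s * T_s)
}

#' @rdname yield_rate
#' @export
closed_form_optimal_threshold <- function(M = 30, h = 5 / 3) {
  sqrt(2 * M * h)
}

# One batch of replicate offer streams, shared across candidate thresholds
# (common random numbers sharply reduce the variance of argmax comparisons).
make_offer_streams <- function(sim, replicates) {
  n_big <- ceiling(sim$budget_s / sim$overhead_s) + 8L
  lapply(seq_len(replicates), function(i) {
    list(
      offers = as.integer(floor(runif(n_big, sim$offer_min_s,
                                      sim$offer_max_s + 1L))),
      rest = ((seq_len(n_big) - 1L) %% 4L) + 1L
    )
  })
}

# Pellets (optionally weighted per restaurant) earned in one session by a
# deterministic per-restaurant-threshold policy.
yield_session <- function(stream, thresholds4, sim, weights = rep(1, 4)) {
  accept <- stream$offers <= thresholds4[stream$rest]
  dur <- sim$overhead_s + accept * (stream$offers + sim$consume_s)
  done <- cumsum(dur) <= sim$budget_s
  sum(weights[stream$rest][accept & done])
}

#' Yield surface of a common threshold
#'
#' Sweeps a single accept threshold shared by all restaurants across
#' `threshold_grid` and simulates `replicates` sessions per candidate (the
#' same replicate offer streams are reused across candidates), recording mean
#' pellets per session.
#'
#' @param threshold_grid Candidate common thresholds, seconds.
#' @param sim An [yield_sim_params()].
#' @param replicates Sessions per grid point (>= 100 recommended).
#' @param seed Optional seed.
#' @return An `rr_yield_surface` tibble: `threshold_s`, `mean_pellets`,
#'   `se_pellets`.
#' @export
#' @examples
#' \donttest{
#' surf <- simulate_yield_surface(replicates = 100, seed = 1)
#' surf$threshold_s[which.max(surf$mean_pellets)] # 10
#' }
simulate_yield_surface <- function(threshold_grid = 1:30,
                                   sim = yield_sim_params(),
                                   replicates = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  streams <- make_offer_streams(sim, replicates)
  res <- lapply(threshold_grid, function(T_s) {
    pellets <- vapply(streams, yield_session, numeric(1),
                      thresholds4 = rep(T_s, 4), sim = sim)
    c(mean(pellets), stats::sd(pellets) / sqrt(replicates))
  })
  out <- tibble(
    threshold_s = threshold_grid,
    mean_pellets = vapply(res, `[`, numeric(1), 1),
    se_pellets = vapply(res, `[`, numeric(1), 2)
  )
  structure(out, class = c("rr_yield_surface", class(out)),
            sim = sim, replicates = replicates)
}

#' Food-maximizing threshold vector
#'
#' The common threshold maximizing mean pellets, replicated across the four
#' restaurants (the food-maximizing policy ignores flavor). Ties take the
#' lowest threshold and are flagged in the `tie` attribute.
#'
#' @param surface An `rr_yield_surface`.
#' @return A tibble `restaurant`, `theta`.
#' @export
food_max_thresholds <- function(surface) {
  best <- max(surface$mean_pellets)
  cand <- surface$threshold_s[surface$mean_pellets == best]
  out <- tibble(restaurant = 1:4, theta = cand[1])
  attr(out, "tie") <- length(cand) > 1
  out
}

#' Subjective-value-maximizing threshold vector
#'
#' Transforms pellet yield into subjective value by weighting each
#' restaurant's earnings with the mouse's day-7 earn ratios (revealed flavor
#' preference under 1-s offers), then searches for the per-restaurant
#' threshold 4-vector maximizing total subjective value per session under the
#' shared time budget. `method = "coordinate"` runs coordinate ascent on the
#' simulated objective (common random numbers across candidates);
#' `"exhaustive"` evaluates the full grid (use a coarse grid);
#' `"analytic"` maximizes the closed-form expected value rate by coordinate
#' ascent (deterministic, fast).
#'
#' @param day7_earnings Per-restaurant pellet counts from day 7 (>= 0, not
#'   all zero).
#' @param sim An [yield_sim_params()].
#' @param replicates Sessions per objective evaluation (simulation methods).
#' @param seed Optional seed.
#' @param method Search strategy (see above).
#' @param grid Candidate thresholds per restaurant (include 0: a restaurant
#'   with zero weight is never worth its waiting time).
#' @param max_sweeps Coordinate-ascent sweep cap.
#' @return A tibble `restaurant`, `theta`, `weight`; the attained objective
#'   is in the `objective` attribute.
#' @export
subjective_value_thresholds <- function(day7_earnings,
                                        sim = yield_sim_params(),
                                        replicates = 200, seed = NULL,
                                        method = c("coordinate", "exhaustive",
                                                   "analytic"),
                                        grid = 0:30, max_sweeps = 8) {
  method <- match.arg(method)
  if (length(day7_earnings) != 4 || any(day7_earnings < 0)) {
    abort("`day7_earnings` must be 4 nonnegative counts.")
  }
  if (sum(day7_earnings) == 0) abort("Day-7 earnings are all zero.")
  w <- day7_earnings / sum(day7_earnings)
  if (!is.null(seed)) set.seed(seed)

  if (method == "analytic") {
    M <- sim$offer_max_s
    objective <- function(T4) {
      p <- pmin(pmax(T4, 0), M) / M
      num <- sum(w * p)
      den <- 4 * sim$overhead_s +
        sum(p * ((pmin(pmax(T4, 0), M) + 1) / 2 + sim$consume_s))
      sim$budget_s * num / den
    }
  } else {
    streams <- make_offer_streams(sim, replicates)
    objective <- function(T4) {
      mean(vapply(streams, yield_session, numeric(1),
                  thresholds4 = T4, sim = sim, weights = w))
    }
  }

  if (method == "exhaustive") {
    combos <- as.matrix(expand.grid(grid, grid, grid, grid))
    if (nrow(combos) > 2e5) abort("Exhaustive grid too large; coarsen `grid`.")
    vals <- apply(combos, 1, objective)
    T4 <- combos[which.max(vals), ]
    obj <- max(vals)
  } else {
    t_star <- closed_form_optimal_threshold(sim$offer_max_s, sim$overhead_s)
    T4 <- rep(grid[which.min(abs(grid - t_star))], 4)
    obj <- objective(T4)
    for (sweep in seq_len(max_sweeps)) {
      changed <- FALSE
      for (r in 1:4) {
        vals <- vapply(grid, function(g) {
          cand <- T4; cand[r] <- g; objective(cand)
        }, numeric(1))
        g_best <- grid[which.max(vals)]
        if (g_best != T4[r] && max(vals) > obj) {
          T4[r] <- g_best
          obj <- max(vals)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  out <- tibble(restaurant = 1:4, theta = unname(T4), weight = w)
  attr(out, "objective") <- obj
  out
}

#' Daily Euclidean distance between observed and theoretical thresholds
#'
#' For each mouse and day, the distance
#' `sqrt(sum_r (theta_obs_r - theta_theo_r)^2)` between the observed
#' four-restaurant threshold vector and a theoretical vector. Days with any
#' missing restaurant threshold are reported `complete = FALSE` with
#' `distance = NA`, never interpolated.
#'
#' @param observed Daily thresholds from
#'   `block_thresholds(..., by = "day")` (one zone).
#' @param theoretical A tibble with `restaurant`, `theta` (e.g. from
#'   [food_max_thresholds()]) or a length-4 numeric vector.
#' @return A tibble: `mouse_id`, `day`, `zone`, `distance`, `complete`.
#' @export
euclidean_distance_series <- function(observed, theoretical) {
  if (is.numeric(theoretical)) {
    theoretical <- tibble(restaurant = 1:4, theta = rep_len(theoretical, 4))
  }
  stopifnot(length(unique(observed$zone)) == 1)
  observed %>%
    left_join(rename(theoretical, theta_theo = "theta"), by = "restaurant") %>%
    group_by(.data$mouse_id, .data$day, .data$zone) %>%
    summarise(
      complete = sum(!is.na(.data$theta)) == 4L,
      distance = if (sum(!is.na(.data$theta)) == 4L) {
        sqrt(sum((.data$theta - .data$theta_theo)^2))
      } else NA_real_,
      .groups = "drop"
    )
}

#' Optimality scores for a cohort
#'
#' Convenience wrapper producing the per-mouse-day distances to the
#' food-maximizing and subjective-value-maximizing theoretical thresholds,
#' for both zones, over the 1-30 s block.
#'
#' @param trials A validated trial table (must include day 7 for the
#'   subjective-value basis).
#' @param days Day range for the daily threshold fits.
#' @param sim An [yield_sim_params()].
#' @param replicates Sessions per grid point of the common-threshold sweep.
#' @param sv_method Method for [subjective_value_thresholds()]; the
#'   deterministic `"analytic"` search is the default here because it runs
#'   per mouse.
#' @param seed Optional seed.
#' @param min_trials Minimum trials per daily fit.
#' @return A tibble: `mouse_id`, `day`, `zone`, `d_food`, `d_subjective`,
#'   `complete`.
#' @export
optimality_scores <- function(trials, days = c(18, 45),
                              sim = yield_sim_params(), replicates = 200,
                              sv_method = "analytic", seed = NULL,
                              min_trials = 5) {
  if (!is.null(seed)) set.seed(seed)
  surface <- simulate_yield_surface(1:30, sim, replicates)
  food <- food_max_thresholds(surface)
  day7 <- trials %>% filter(.data$day == 7L)
  mice <- unique(trials$mouse_id)
  sv <- purrr::map_dfr(mice, function(m) {
    earn7 <- vapply(1:4, function(r) {
      sum(day7$mouse_id == m & day7$restaurant == r &
            day7$wz_outcome == "earn")
    }, numeric(1))
    if (sum(earn7) == 0) {
      return(tibble(mouse_id = m, restaurant = 1:4, theta = NA_real_))
    }
    th <- subjective_value_thresholds(earn7, sim, replicates,
                                      method = sv_method)
    tibble(mouse_id = m, restaurant = 1:4, theta = th$theta)
  })
  purrr::map_dfr(c("OZ", "WZ"), function(z) {
    daily <- block_thresholds(trials, zone = z, days = days, by = "day",
                              min_trials = min_trials)
    d_food <- euclidean_distance_series(daily, food) %>%
      rename(d_food = "distance")
    d_sv <- daily %>%
      group_by(.data$mouse_id) %>%
      dplyr::group_modify(function(g, key) {
        theo <- sv %>% filter(.data$mouse_id == key$mouse_id) %>%
          select(dplyr::all_of(c("restaurant", "theta")))
        if (all(is.na(theo$theta))) {
          return(distinct(g, .data$day, .data$zone) %>%
                   mutate(distance = NA_real_, complete = FALSE))
        }
        g$mouse_id <- key$mouse_id
        euclidean_distance_series(g, theo) %>% select(-"mouse_id")
      }) %>%
      ungroup() %>%
      rename(d_subjective = "distance") %>%
      select(dplyr::all_of(c("mouse_id", "day", "zone", "d_subjective")))
    d_food %>% left_join(d_sv, by = c("mouse_id", "day", "zone")) %>%
      select(dplyr::all_of(c("mouse_id", "day", "zone", "d_food",
                             "d_subjective", "complete")))
  })
}
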