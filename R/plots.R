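# ggplot2 views of the main result types.

#' Plot a step-threshold fit
#'
#' Observed accept/reject outcomes against the cued offer with the fitted
#' Heaviside step overlaid.
#'
#' @param object An `rr_step_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot rr_step_fit
#' @export
autoplot.rr_step_fit <- function(object, ...) {
  pts <- tibble(offer_s = object$offers, accept = as.numeric(object$outcomes))
  step <- tibble(
    offer_s = c(min(pts$offer_s), object$theta, object$theta, max(pts$offer_s)),
    accept = c(1, 1, 0, 0)
  )
  ggplot2::ggplot(pts, ggplot2::aes(.data$offer_s, .data$accept)) +
    ggplot2::geom_jitter(width = 0, height = 0.03, alpha = 0.4) +
    ggplot2::geom_line(data = step, color = "firebrick") +
    ggplot2::geom_vline(xintercept = object$theta, linetype = 2) +
    ggplot2::labs(x = "offer (s)", y = "p(accept)",
                  title = sprintf("step threshold = %.1f s", object$theta)) +
    ggplot2::theme_minimal()
}

#' Plot a sunk-cost survival surface
#'
#' p(earn) against time left, one line per time already spent; the black
#' 0-s line is the just-entered control.
#'
#' @param object An `rr_sunk_surface`.
#' @param max_s Largest time-spent line to draw.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot rr_sunk_surface
#' @export
autoplot.rr_sunk_surface <- function(object, max_s = 10, ...) {
  dat <- as_tibble(object) %>% filter(.data$valid, .data$s <= max_s)
  ggplot2::ggplot(dat, ggplot2::aes(.data$l, .data$p_earn,
                                    color = factor(.data$s),
                                    group = factor(.data$s))) +
    ggplot2::geom_line() +
    ggplot2::scale_color_viridis_d(name = "time spent (s)") +
    ggplot2::labs(x = "time left (s)", y = "p(earn)") +
    ggplot2::theme_minimal()
}

#' Plot a sunk-cost delta envelope
#'
#' The mean change in p(earn) attributable to time already invested, with
#' its bootstrap CI ribbon.
#'
#' @param envelope Output of [sunk_delta_envelope()].
#' @param max_s Largest time-spent value to draw.
#' @return A ggplot.
#' @export
plot_sunk_envelope <- function(envelope, max_s = 15) {
  dat <- filter(envelope, .data$s <= max_s, !is.na(.data$delta))
  ggplot2::ggplot(dat, ggplot2::aes(.data$s, .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time already spent (s)",
                  y = expression(Delta ~ "p(earn) vs 0-s control")) +
    ggplot2::theme_minimal()
}

#' Plot session time-budget fractions
#'
#' Stacked per-day fractions of the session budget in each behavioral epoch,
#' averaged over mice.
#'
#' @param partition Output of [time_budget_partition()] (six-epoch scheme).
#' @return A ggplot.
#' @export
plot_time_budget <- function(partition) {
  long <- partition %>%
    select(dplyr::all_of(c("mouse_id", "day")),
           dplyr::starts_with("frac_")) %>%
    tidyr::pivot_longer(dplyr::starts_with("frac_"),
                        names_to = "epoch", values_to = "fraction",
                        names_prefix = "frac_") %>%
    group_by(.data$day, .data$epoch) %>%
    summarise(fraction = mean(.data$fraction), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$fraction,
                                     fill = .data$epoch)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "day", y = "fraction of session budget") +
    ggplot2::theme_minimal()
}

#' Plot per-mouse regret deltas
#'
#' Dot plot of per-mouse delta scores by scenario type with the cohort mean.
#'
#' @param deltas Output of [sequence_delta()] (one or both types, row-bound).
#' @return A ggplot.
#' @export
plot_regret_deltas <- function(deltas) {
  ggplot2::ggplot(deltas, ggplot2::aes(factor(.data$type), .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          color = "firebrick") +
    ggplot2::labs(x = "scenario type",
                  y = "p(accept | violation) - p(accept | nonviolation)") +
    ggplot2::theme_minimal()
}
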