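# Generative policy parameters for the task simulator, and group presets.

#' Generative policy parameters for a simulated mouse
#'
#' The simulator's behavioral policy. Accept/skip in the offer zone follows a
#' softened threshold rule: the probability of entering is
#' `accept_scale[r] * plogis(softness_beta * (theta_oz[r] - offer))`, where
#' `accept_scale[r] = pref_weights[r] / max(pref_weights)` lets flavor
#' preference modulate acceptance even when all offers share one delay (as in
#' week 1). After an enter-then-quit of a negatively valued offer
#' (offer above `theta_wz`), `regret_rho` is added to the next trial's accept
#' probability — the generative counterpart of type-2 regret compensation.
#'
#' Once waiting, the per-second quit hazard at `s` seconds already spent with
#' `l` seconds left is
#' `base_quit_hazard * (l > theta_wz[r]) * max(0, 1 - sunk_kappa * s)`:
#' quits only occur while the remaining delay exceeds the wait-zone threshold
#' (so they are economically advantageous by construction), and time already
#' invested scales the hazard down — `sunk_kappa` is the generative sunk-cost
#' escalation parameter.
#'
#' @param theta_oz,theta_wz Per-restaurant thresholds in seconds (length 4, or
#'   scalars recycled), each in `[0, 30]`.
#' @param softness_beta Inverse temperature of the accept rule, per second;
#'   large values approach a Heaviside step policy.
#' @param base_quit_hazard Per-second quit probability while remaining delay
#'   exceeds `theta_wz`, in `[0, 1]`.
#' @param sunk_kappa Sunk-cost escalation slope (>= 0, dimensionless).
#' @param regret_rho Post-quit compensation bonus added to the next accept
#'   probability, in `[0, 1]`.
#' @param pref_weights Flavor preference weights for restaurants 1-4
#'   (positive; normalized to sum to 1).
#' @param oz_latency_mean_s Mean offer-zone deliberation time, seconds.
#' @param travel_mean_s Mean hallway travel time between restaurants, seconds.
#' @param consume_s Mean pellet consumption time, seconds.
#' @param learning_gain,learning_tau_days Week-1 acquisition ramp: latency and
#'   travel means on day `d` are multiplied by
#'   `1 + learning_gain * exp(-(d - 1) / learning_tau_days)`, so early
#'   sessions are slow and earnings rise across week 1.
#'
#' @return An object of class `rr_policy`.
#' @export
#' @examples
#' pol <- policy_params(theta_oz = 12, theta_wz = 10)
policy_params <- function(theta_oz = 12,
                          theta_wz = 10,
                          softness_beta = 0.5,
                          base_quit_hazard = 0.5,
                          sunk_kappa = 0,
                          regret_rho = 0,
                          pref_weights = rep(0.25, 4),
                          oz_latency_mean_s = 2,
                          travel_mean_s = 4,
                          consume_s = 1.5,
                          learning_gain = 1.5,
                          learning_tau_days = 2) {
  theta_oz <- rep_len(theta_oz, 4)
  theta_wz <- rep_len(theta_wz, 4)
  if (any(theta_oz < 0 | theta_oz > 30) || any(theta_wz < 0 | theta_wz > 30)) {
    abort("Thresholds must lie in [0, 30] seconds.")
  }
  if (base_quit_hazard < 0 || base_quit_hazard > 1 ||
      regret_rho < 0 || regret_rho > 1 || sunk_kappa < 0) {
    abort("Require base_quit_hazard, regret_rho in [0, 1] and sunk_kappa >= 0.")
  }
  if (length(pref_weights) != 4 || any(pref_weights <= 0)) {
    abort("`pref_weights` must be 4 positive weights.")
  }
  pref_weights <- pref_weights / sum(pref_weights)
  structure(
    list(
      theta_oz = theta_oz, theta_wz = theta_wz,
      softness_beta = softness_beta, base_quit_hazard = base_quit_hazard,
      sunk_kappa = sunk_kappa, regret_rho = regret_rho,
      pref_weights = pref_weights,
      oz_latency_mean_s = oz_latency_mean_s, travel_mean_s = travel_mean_s,
      consume_s = consume_s,
      learning_gain = learning_gain, learning_tau_days = learning_tau_days
    ),
    class = "rr_policy"
  )
}

#' @export
print.rr_policy <- function(x, ...) {
  cat("<rr_policy>\n",
      " theta_oz: ", paste(round(x$theta_oz, 2), collapse = ", "), "\n",
      " theta_wz: ", paste(round(x$theta_wz, 2), collapse = ", "), "\n",
      " beta ", x$softness_beta, ", hazard ", x$base_quit_hazard,
      ", kappa ", x$sunk_kappa, ", rho ", x$regret_rho, "\n", sep = "")
  invisible(x)
}

#' Group-level policy presets for cohort simulation
#'
#' A preset is a list of `policy_params()` arguments plus between-mouse
#' standard deviations (`theta_oz_sd`, `theta_wz_sd`) used when drawing each
#' mouse's policy. `default_group_presets()` supplies illustrative presets for
#' the four sex-by-treatment groups, qualitatively echoing the reported
#' pattern (positive sunk-cost and type-2 regret sensitivity in most groups,
#' absent type-2 sensitivity in control females, both enhanced in treated
#' females); they are illustrative defaults, not fitted values.
#'
#' @param ... Arguments forwarded to [policy_params()].
#' @param theta_oz_sd,theta_wz_sd Between-mouse SDs of the thresholds,
#'   seconds.
#' @return `group_preset()` returns a preset list; `default_group_presets()` a
#'   named list of four presets.
#' @export
group_preset <- function(..., theta_oz_sd = 1, theta_wz_sd = 1) {
  list(args = list(...), theta_oz_sd = theta_oz_sd, theta_wz_sd = theta_wz_sd)
}

#' @rdname group_preset
#' @export
default_group_presets <- function() {
  base <- list(
    theta_oz = c(14, 12, 10, 8),
    theta_wz = c(12, 10, 8, 6),
    softness_beta = 0.5,
    base_quit_hazard = 0.5,
    pref_weights = c(0.31, 0.27, 0.23, 0.19)
  )
  mk <- function(kappa, rho) {
    do.call(group_preset, c(base, list(sunk_kappa = kappa, regret_rho = rho)))
  }
  list(
    "M-GFP"  = mk(0.10, 0.15),
    "F-GFP"  = mk(0.08, 0.00),
    "M-LINC" = mk(0.10, 0.15),
    "F-LINC" = mk(0.18, 0.20)
  )
}

#' A near-deterministic step policy preset
#'
#' Convenience preset for parameter-recovery studies: a very sharp accept rule
#' (large `softness_beta`), immediate quits above threshold
#' (`base_quit_hazard = 1`), no sunk-cost or regret terms, and uniform flavor
#' weights, so offer-zone and wait-zone choices are Heaviside in the offer.
#'
#' @param theta_oz,theta_wz Per-restaurant thresholds, seconds. Half-integer
#'   values make the implied step unambiguous on the integer offer grid.
#' @param ... Further [policy_params()] overrides.
#' @return An `rr_policy`.
#' @export
step_policy <- function(theta_oz, theta_wz, ...) {
  policy_params(
    theta_oz = theta_oz, theta_wz = theta_wz,
    softness_beta = 100, base_quit_hazard = 1,
    sunk_kappa = 0, regret_rho = 0,
    pref_weights = rep(0.25, 4), ...
  )
}
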