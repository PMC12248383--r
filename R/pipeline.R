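# Reproducible end-to-end runs: config container, YAML round trip, and the
# eight-stage pipeline (simulate -> validate -> thresholds -> valuation ->
# sunk cost -> regret -> optimality -> summaries).

#' Pipeline run configuration
#'
#' All analysis defaults mirror the task's standard settings (30-min budget,
#' 45 days, probes on days 0/8, analyses over the 1-30 s block, 1-s survival
#' window) and every estimator knob is exposed. A config plus its seed
#' determines every output bit-for-bit; stage seeds are derived from the root
#' seed by fixed offsets so stages are independently re-runnable.
#'
#' @param n_per_group Simulated mice per group.
#' @param days Days to simulate.
#' @param analysis_days Day range for the economic analyses.
#' @param min_trials Minimum trials per threshold fit.
#' @param min_count Minimum trials per survival-surface cell.
#' @param value_bin_s Regret value-matching bin width, seconds.
#' @param min_pairs Minimum matched pairs per regret arm.
#' @param bootstrap_reps Envelope bootstrap replicates.
#' @param yield_replicates Sessions per yield-surface grid point.
#' @param sv_method Search method for [subjective_value_thresholds()].
#' @param cpp_gain Simulator place-preference gain, s per pellet.
#' @param lap_length_m Lap length for the distance proxy.
#' @param seed Root seed.
#' @param group_presets Named list of [group_preset()]s.
#' @return A list of class `rr_config`.
#' @export
rr_config <- function(n_per_group = 10,
                      days = 1:45,
                      analysis_days = c(18, 45),
                      min_trials = 5,
                      min_count = 5,
                      value_bin_s = 2,
                      min_pairs = 5,
                      bootstrap_reps = 1000,
                      yield_replicates = 300,
                      sv_method = "analytic",
                      cpp_gain = 1,
                      lap_length_m = 1,
                      seed = 17,
                      group_presets = default_group_presets()) {
  structure(
    list(
      n_per_group = n_per_group, days = days, analysis_days = analysis_days,
      min_trials = min_trials, min_count = min_count,
      value_bin_s = value_bin_s, min_pairs = min_pairs,
      bootstrap_reps = bootstrap_reps, yield_replicates = yield_replicates,
      sv_method = sv_method, cpp_gain = cpp_gain,
      lap_length_m = lap_length_m, seed = seed,
      group_presets = group_presets
    ),
    class = "rr_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' Scalar and vector settings round-trip through YAML; group presets given in
#' the file as lists of [policy_params()] arguments (plus `theta_oz_sd`,
#' `theta_wz_sd`) are rebuilt into presets. Settings absent from the file
#' keep their [rr_config()] defaults.
#'
#' @param path YAML path.
#' @param config An `rr_config`.
#' @return `read_run_config()` returns an `rr_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- rr_config()
  if (!is.null(raw$group_presets)) {
    raw$group_presets <- lapply(raw$group_presets, function(p) {
      sds <- list(theta_oz_sd = p$theta_oz_sd %||% 1,
                  theta_wz_sd = p$theta_wz_sd %||% 1)
      p$theta_oz_sd <- NULL
      p$theta_wz_sd <- NULL
      do.call(group_preset, c(p, sds))
    })
  }
  if (!is.null(raw$days) && length(raw$days) == 2 && !is.null(raw$days_as_range)) {
    raw$days <- seq(raw$days[1], raw$days[2])
    raw$days_as_range <- NULL
  }
  for (k in intersect(names(raw), names(cfg))) cfg[[k]] <- raw[[k]]
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$group_presets <- lapply(config$group_presets, function(p) {
    c(p$args, list(theta_oz_sd = p$theta_oz_sd, theta_wz_sd = p$theta_wz_sd))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes all eight stages against a freshly simulated cohort and writes
#' every stage's tables plus a manifest (`manifest.json` with the config,
#' derived stage seeds, stage file lists, and MD5 checksums) into `out_dir`.
#' Any stage error aborts with the stage name; files written by earlier
#' stages are preserved.
#'
#' @param config An [rr_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = rr_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(simulate = config$seed, bootstrap = config$seed + 1L,
                yield = config$seed + 2L)
  schedule <- epoch_schedule()
  manifest <- list(
    package_version = as.character(utils::packageVersion("rrow")),
    seeds = seeds,
    stages = list()
  )
  files <- character()
  out <- function(name) file.path(out_dir, name)
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    manifest$stages[[name]] <<- res
    files <<- c(files, unlist(res))
    invisible(NULL)
  }

  env <- new.env()
  stage("simulate", function() {
    set.seed(seeds$simulate)
    env$cohort <- simulate_cohort(config$n_per_group, config$group_presets,
                                  schedule, config$days,
                                  cpp_gain = config$cpp_gain)
    write_trials(env$cohort$trials, out("trials.csv"))
    if (!is.null(env$cohort$free_roam)) {
      write_free_roam(env$cohort$free_roam, out("free_roam.csv"))
    }
    gt <- ground_truth_thresholds(env$cohort) %>%
      left_join(select(env$cohort$ground_truth,
                       dplyr::all_of(c("mouse_id", "group"))),
                by = "mouse_id")
    jsonlite::write_json(gt, out("ground_truth.json"),
                         dataframe = "columns", digits = NA)
    c("trials.csv", "trials.csv.json",
      if (!is.null(env$cohort$free_roam)) "free_roam.csv",
      "ground_truth.json")
  })
  stage("validate", function() {
    rep <- validate_trials(env$cohort$trials, schedule)
    readr::write_csv(rep, out("validation.csv"))
    if (nrow(rep)) abort(paste0(nrow(rep), " invariant violation(s)."))
    "validation.csv"
  })
  stage("thresholds", function() {
    env$th <- bind_rows(
      block_thresholds(env$cohort$trials, "OZ", config$analysis_days,
                       min_trials = config$min_trials, schedule = schedule),
      block_thresholds(env$cohort$trials, "WZ", config$analysis_days,
                       min_trials = config$min_trials, schedule = schedule)
    )
    daily <- bind_rows(
      block_thresholds(env$cohort$trials, "OZ", config$analysis_days, "day",
                       min_trials = config$min_trials, schedule = schedule),
      block_thresholds(env$cohort$trials, "WZ", config$analysis_days, "day",
                       min_trials = config$min_trials, schedule = schedule)
    )
    readr::write_csv(env$th, out("thresholds_block.csv"))
    readr::write_csv(daily, out("thresholds_daily.csv"))
    c("thresholds_block.csv", "thresholds_daily.csv")
  })
  stage("valuation", function() {
    econ <- quit_economics(env$cohort$trials, env$th, config$analysis_days)
    readr::write_csv(econ, out("quit_economics.csv"))
    stats <- quit_latency_stats(env$cohort$trials, env$th,
                                days = config$analysis_days)
    readr::write_csv(stats, out("quit_stats.csv"))
    c("quit_economics.csv", "quit_stats.csv")
  })
  stage("sunk_cost", function() {
    surf <- stay_survival_surface(env$cohort$trials, config$analysis_days,
                                  config$min_count)
    env_tbl <- sunk_delta_envelope(surf, config$bootstrap_reps,
                                   seed = seeds$bootstrap)
    readr::write_csv(as_tibble(surf), out("sunk_surface.csv"))
    readr::write_csv(env_tbl, out("sunk_envelope.csv"))
    c("sunk_surface.csv", "sunk_envelope.csv")
  })
  stage("regret", function() {
    pairs <- extract_sequences(env$cohort$trials, env$th,
                               config$analysis_days, config$value_bin_s)
    deltas <- bind_rows(
      sequence_delta(pairs, 1L, config$min_pairs),
      sequence_delta(pairs, 2L, config$min_pairs)
    )
    readr::write_csv(deltas, out("regret_deltas.csv"))
    tests <- purrr::map_dfr(split(deltas, deltas$type), function(d) {
      if (sum(!is.na(d$delta)) < 3) return(tibble())
      mutate(cohort_sign_test(d), type = d$type[1], .before = 1)
    })
    readr::write_csv(tests, out("regret_tests.csv"))
    c("regret_deltas.csv", "regret_tests.csv")
  })
  stage("optimality", function() {
    set.seed(seeds$yield)
    opt <- optimality_scores(env$cohort$trials, config$analysis_days,
                             replicates = config$yield_replicates,
                             sv_method = config$sv_method,
                             min_trials = config$min_trials)
    readr::write_csv(opt, out("optimality.csv"))
    "optimality.csv"
  })
  stage("summaries", function() {
    sm <- session_metrics(env$cohort$trials, config$lap_length_m)
    readr::write_csv(sm, out("session_metrics.csv"))
    outfiles <- "session_metrics.csv"
    if (!is.null(env$cohort$free_roam) && 7L %in% config$days) {
      cpp <- purrr::map_dfr(
        unique(env$cohort$free_roam$mouse_id),
        function(m) {
          s7 <- filter(env$cohort$trials, .data$mouse_id == m, .data$day == 7L)
          if (nrow(s7) == 0) return(tibble())
          cpp_delta(filter(env$cohort$free_roam, .data$mouse_id == m),
                    rank_flavors(s7))
        }
      )
      readr::write_csv(cpp, out("cpp_deltas.csv"))
      outfiles <- c(outfiles, "cpp_deltas.csv")
    }
    outfiles
  })

  manifest$config <- unclass(config)
  manifest$config$group_presets <- NULL
  manifest$files <- as.list(setNames(
    unname(tools::md5sum(file.path(out_dir, files))), files
  ))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
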