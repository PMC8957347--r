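#' Pipeline configuration
#'
#' Collects everything a full run needs: the seed, sample size, task
#' specifications, generator population settings, bootstrap size and
#' analysis thresholds. A configuration can also be read from a YAML or
#' JSON file with [read_run_config()]; fields not given keep their
#' defaults. Validation happens here, before any compute.
#'
#' @param seed Integer seed driving every random stage.
#' @param n_participants Number of simulated participants.
#' @param n_boot Bootstrap replicates for the simulated-trajectory null
#'   (>= 1).
#' @param omission_cutoff_ms Go-RT omission cutoff.
#' @param motor_time_ms Electromechanical delay for the TMS-in-burst rule.
#' @param skew_threshold Residual-skewness threshold for the log-transform
#'   rule.
#' @param min_bin_trials Minimum surviving trials a participant x coil x bin
#'   cell needs to enter the state-space distance analysis (default 5, the
#'   usual minimum MEP count for a stable conditional mean; late cue-locked
#'   bins can be left with very few trials by the TMS-in-burst rule, and a
#'   bootstrap of a near-empty pool cannot represent sampling noise). The
#'   excitability models and rise-onset post hocs use all bins.
#' @param bootstrap_compare `"pair"` or `"original"` (see
#'   [bootstrap_simulated_trajectories()]).
#' @param generator Named list of overrides passed to
#'   [draw_participants()] (population means and SDs).
#' @param specs List of [task_spec()]s.
#' @param output_dir Directory for tables, figures and the manifest; `NULL`
#'   keeps everything in memory.
#' @return A `run_config` list.
#' @export
#' @examples
#' run_config(seed = 1, n_participants = 4, n_boot = 100)
run_config <- function(seed = 1, n_participants = 16, n_boot = 1000,
                       omission_cutoff_ms = 1000, motor_time_ms = 50,
                       skew_threshold = 1, min_bin_trials = 5,
                       bootstrap_compare = c("pair", "original"),
                       generator = list(),
                       specs = list(task_spec("SST"), task_spec("GoOnly")),
                       output_dir = NULL) {
  check_number(seed, "seed")
  check_number(n_participants, "n_participants", min = 2)
  check_number(n_boot, "n_boot", min = 1)
  check_number(omission_cutoff_ms, "omission_cutoff_ms", min = 0, strict_min = TRUE)
  check_number(motor_time_ms, "motor_time_ms", min = 0)
  check_number(skew_threshold, "skew_threshold", min = 0, strict_min = TRUE)
  check_number(min_bin_trials, "min_bin_trials", min = 1)
  bootstrap_compare <- arg_match(bootstrap_compare)
  if (!is.list(generator)) abort("`generator` must be a named list")
  if (!is.list(specs) || !all(vapply(specs, inherits, logical(1), "task_spec"))) {
    abort("`specs` must be a list of task_spec objects")
  }
  structure(
    list(seed = as.integer(seed), n_participants = as.integer(n_participants),
         n_boot = as.integer(n_boot),
         omission_cutoff_ms = omission_cutoff_ms,
         motor_time_ms = motor_time_ms, skew_threshold = skew_threshold,
         min_bin_trials = as.integer(min_bin_trials),
         bootstrap_compare = bootstrap_compare, generator = generator,
         specs = specs, output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`). Recognized top-level fields are the arguments of
#'   [run_config()]; `specs` entries are passed to [task_spec()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$specs)) {
    raw$specs <- map(raw$specs, function(s) do.call(task_spec, as.list(s)))
  }
  if (!is.null(raw$generator)) raw$generator <- as.list(raw$generator)
  do.call(run_config, raw)
}

write_stage <- function(tbl, name, dir) {
  if (is.null(dir)) return(invisible(NULL))
  readr::write_csv(as_tibble(tbl), file.path(dir, paste0(name, ".csv")))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one synthetic experiment: simulate -> behavioral
#' summary -> MEP preprocessing and binning (cue- and response-locked) ->
#' state-space trajectories, real distance series and bootstrap null ->
#' mixed-model inference (cue-locked CSE, response-locked CSE, and the
#' real-vs-simulated distance comparison per metric and alignment) -> rise
#' onset post hocs. When `config$output_dir` is set, every table is written
#' as CSV together with a JSON manifest (package version, seed, config,
#' exclusion accounting), and the standard figures as PDF.
#'
#' @param config A [run_config()].
#' @param trials Optional pre-existing trial table (e.g. read from CSV with
#'   the [simulate_dataset()] schema); when `NULL`, data are simulated from
#'   the config. Schema violations are reported with the offending column.
#' @return Invisibly, a named list bundle: `trials`, `behavior`, `binned`
#'   (cue/response), `trajectories`, `distances`, `models`, `arm_tests`
#'   (calibrated paired real-vs-simulated tests), `rise_onset`,
#'   `accounting`, `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(seed = 2, n_participants = 6, n_boot = 50))
#' res$behavior
#' }
run_pipeline <- function(config = run_config(), trials = NULL) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config")
  dir <- config$output_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  if (is.null(trials)) {
    trials <- do.call(simulate_dataset, c(
      list(n_participants = config$n_participants, seed = config$seed,
           specs = config$specs),
      config$generator
    ))
  } else {
    validate_trials(trials)
  }
  write_stage(trials, "trials", dir)

  behavior <- summarize_behavior(trials,
                                 omission_cutoff_ms = config$omission_cutoff_ms)
  write_stage(behavior, "behavior", dir)

  prepped <- prepare_mep(trials, omission_cutoff_ms = config$omission_cutoff_ms,
                         motor_time_ms = config$motor_time_ms)
  accounting <- prepped |>
    group_by(.data$exclusion_reason) |>
    summarise(n = n(), .groups = "drop") |>
    mutate(reason = if_else(is.na(.data$exclusion_reason), "retained",
                            .data$exclusion_reason)) |>
    select("reason", "n")
  stopifnot(sum(accounting$n) == nrow(prepped))

  binned <- list(
    cue_locked = bin_cue_locked(prepped),
    response_locked = bin_response_locked(prepped)
  )
  write_stage(binned$cue_locked, "binned_cue_locked", dir)
  write_stage(binned$response_locked, "binned_response_locked", dir)

  # Distance analysis works on bins with a stable trial count.
  binned_dist <- list(
    cue_locked = bin_cue_locked(prepped, min_trials = config$min_bin_trials),
    response_locked = bin_response_locked(prepped,
                                          min_trials = config$min_bin_trials)
  )
  trajectories <- map(binned_dist, build_trajectories, scope = "participant",
                      incomplete = "drop")
  group_traj <- map(binned, build_trajectories, scope = "group",
                    incomplete = "drop")

  distances <- imap(binned_dist, function(b, align) {
    real <- distance_series(trajectories[[align]], strict = FALSE)
    sim <- bootstrap_simulated_trajectories(
      prepped, alignment = align, n_boot = config$n_boot,
      compare = config$bootstrap_compare, summarize = TRUE,
      missing_bins = "drop", min_trials = config$min_bin_trials,
      n_template = filter(b, .data$task == "SST"),
      seed = config$seed + 7919L * match(align, names(binned_dist))
    )
    assemble_comparison_table(real, sim)
  })
  write_stage(distances$cue_locked, "distances_cue_locked", dir)
  write_stage(distances$response_locked, "distances_response_locked", dir)

  models <- list(
    cse_cue = fit_mixed(binned$cue_locked, "mean_norm_mep",
                        c("coil", "task", "bin"),
                        skew_threshold = config$skew_threshold),
    cse_response = fit_mixed(binned$response_locked, "mean_norm_mep",
                             c("coil", "task", "bin"),
                             skew_threshold = config$skew_threshold)
  )
  for (align in names(distances)) {
    for (metric in c("euclidean", "cosine")) {
      tbl <- filter(distances[[align]], .data$metric == !!metric)
      models[[paste("distance", metric, align, sep = "_")]] <-
        fit_mixed(tbl, "distance", c("bin", "analysis_type"),
                  skew_threshold = config$skew_threshold)
    }
  }
  arm_tests <- imap(distances, function(tbl, align) {
    mutate(compare_real_simulated(tbl), alignment = align)
  }) |> list_rbind()
  rise_onset <- posthoc_rise_onset(binned$cue_locked)

  manifest <- list(
    package = "stopstate",
    version = as.character(packageVersion("stopstate")),
    seed = config$seed,
    n_participants = config$n_participants,
    n_boot = config$n_boot,
    bootstrap_compare = config$bootstrap_compare,
    min_bin_trials = config$min_bin_trials,
    omission_cutoff_ms = config$omission_cutoff_ms,
    motor_time_ms = config$motor_time_ms,
    n_trials = nrow(trials),
    exclusions = as.list(setNames(accounting$n, accounting$reason)),
    transforms = map(models, function(m) m$transform),
    rise_onset = as.list(setNames(rise_onset$onset$onset_bin,
                                  rise_onset$onset$task))
  )
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    model_terms <- imap(models, function(m, nm) mutate(tidy(m), model = nm)) |>
      list_rbind()
    write_stage(model_terms, "model_terms", dir)
    write_stage(arm_tests, "arm_tests", dir)
    for (f in c("cue_locked", "response_locked")) {
      ggsave_quiet(file.path(dir, paste0("excitability_", f, ".pdf")),
                   plot_excitability(binned[[f]]))
      ggsave_quiet(file.path(dir, paste0("trajectory_", f, ".pdf")),
                   plot_trajectory(group_traj[[f]]))
      ggsave_quiet(file.path(dir, paste0("distances_", f, ".pdf")),
                   plot_distances(distances[[f]]))
    }
  }

  invisible(list(
    trials = trials, behavior = behavior, binned = binned,
    trajectories = trajectories, group_trajectories = group_traj,
    distances = distances, models = models, arm_tests = arm_tests,
    rise_onset = rise_onset, accounting = accounting, manifest = manifest
  ))
}

ggsave_quiet <- function(path, plot) {
  suppressMessages(ggplot2::ggsave(path, plot, width = 8, height = 5))
}

# Schema check for ingested trial tables; names the offending column/row.
validate_trials <- function(trials) {
  required <- c(participant_id = "character", task = "character",
                coil = "character", trial_type = "character",
                tms_time_ms = "numeric", rt_ms = "numeric",
                responded = "logical", mep_mv = "numeric",
                excluded = "logical")
  stopifnot_cols(trials, names(required), "trial table")
  for (col in names(required)) {
    mode_ok <- switch(required[[col]],
      character = is.character(trials[[col]]) || is.factor(trials[[col]]),
      numeric = is.numeric(trials[[col]]),
      logical = is.logical(trials[[col]])
    )
    if (!mode_ok) {
      abort(sprintf("trial table column `%s` must be %s", col, required[[col]]))
    }
  }
  bad_type <- which(!trials$trial_type %in% c(.trial_types, "catch"))
  if (length(bad_type) > 0) {
    abort(sprintf("trial table column `trial_type` has invalid value in row %d",
                  bad_type[1]))
  }
  bad_rt <- which(trials$responded & is.na(trials$rt_ms))
  if (length(bad_rt) > 0) {
    abort(sprintf("trial table column `rt_ms` missing for responding row %d",
                  bad_rt[1]))
  }
  if (!"ssd_ms" %in% names(trials)) {
    abort("trial table is missing required column: ssd_ms")
  }
  bad_ssd <- which(trials$trial_type == "stop" & is.na(trials$ssd_ms))
  if (length(bad_ssd) > 0) {
    abort(sprintf("trial table column `ssd_ms` missing for stop row %d",
                  bad_ssd[1]))
  }
  invisible(trials)
}
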