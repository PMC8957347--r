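#' EMG trace container
#'
#' A light container for one trial's surface EMG sweep: a numeric sample
#' vector, its sampling rate (the published recordings were digitized at
#' 5 kHz), and the trace-coordinate time of the first sample.
#'
#' @param samples_mv Numeric vector of EMG amplitudes (mV).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param t0_ms Time of the first sample in trace coordinates (ms).
#' @return An `emg_trace` object.
#' @export
#' @examples
#' tr <- emg_trace(sin(seq(0, 2 * pi, length.out = 100)), 5000)
#' peak_to_peak(tr, 0, 20)
emg_trace <- function(samples_mv, sampling_rate_hz = 5000, t0_ms = 0) {
  if (!is.numeric(samples_mv) || length(samples_mv) == 0) {
    abort("`samples_mv` must be a non-empty numeric vector")
  }
  check_number(sampling_rate_hz, "sampling_rate_hz", min = 0, strict_min = TRUE)
  structure(
    list(samples_mv = as.numeric(samples_mv),
         sampling_rate_hz = sampling_rate_hz,
         t0_ms = t0_ms),
    class = "emg_trace"
  )
}

trace_times_ms <- function(trace) {
  trace$t0_ms + (seq_along(trace$samples_mv) - 1) * 1000 / trace$sampling_rate_hz
}

#' Peak-to-peak amplitude in a trace window
#'
#' Max minus min of the samples falling in `[window_start_ms,
#' window_end_ms)`, the standard measure of MEP size.
#'
#' @param trace An [emg_trace()].
#' @param window_start_ms,window_end_ms Window bounds in trace coordinates.
#' @return Amplitude in mV.
#' @export
peak_to_peak <- function(trace, window_start_ms, window_end_ms) {
  if (!inherits(trace, "emg_trace")) abort("`trace` must be an emg_trace")
  if (window_start_ms >= window_end_ms) {
    abort("`window_start_ms` must be < `window_end_ms`")
  }
  t <- trace_times_ms(trace)
  sel <- t >= window_start_ms & t < window_end_ms
  if (!any(sel)) abort("empty window: no samples in [start, end)")
  x <- trace$samples_mv[sel]
  max(x) - min(x)
}

#' Simulate a single-trial EMG trace
#'
#' Builds a synthetic sweep containing Gaussian baseline noise, a biphasic
#' MEP of programmed peak-to-peak amplitude starting ~20 ms after the TMS
#' pulse, and (when a response occurs) a rectangular-envelope EMG burst from
#' `burst_onset_ms` onward. Used for round-trip tests of [peak_to_peak()]
#' and [detect_burst_onset()]; real acquisition hardware is out of scope.
#'
#' @param amplitude_mv Programmed MEP peak-to-peak amplitude.
#' @param tms_time_ms TMS pulse time in trace coordinates.
#' @param burst_onset_ms EMG burst onset time, or `NA` for no burst.
#' @param duration_ms,sampling_rate_hz Sweep length and sampling rate.
#' @param noise_sd_mv Baseline noise SD.
#' @return An [emg_trace()].
#' @export
simulate_emg_trace <- function(amplitude_mv, tms_time_ms = 100,
                               burst_onset_ms = NA, duration_ms = 500,
                               sampling_rate_hz = 5000, noise_sd_mv = 0.01) {
  n <- ceiling(duration_ms * sampling_rate_hz / 1000)
  t <- (seq_len(n) - 1) * 1000 / sampling_rate_hz
  x <- rnorm(n, 0, noise_sd_mv)
  # biphasic MEP: one sine cycle over ~15 ms, starting 20 ms post-TMS
  mep_start <- tms_time_ms + 20
  in_mep <- t >= mep_start & t < mep_start + 15
  x[in_mep] <- x[in_mep] +
    (amplitude_mv / 2) * sin(2 * pi * (t[in_mep] - mep_start) / 15)
  if (!is.na(burst_onset_ms)) {
    in_burst <- t >= burst_onset_ms
    x[in_burst] <- x[in_burst] + rnorm(sum(in_burst), 0, 20 * noise_sd_mv)
  }
  emg_trace(x, sampling_rate_hz, t0_ms = 0)
}

#' Detect EMG burst onset by threshold crossing
#'
#' Automated stand-in for the visual preprocessing of the source recordings:
#' the burst onset is the first time the rectified signal exceeds `k` times
#' the baseline SD continuously for at least `min_duration_ms`. The baseline
#' SD is estimated from the pre-TMS portion of the trace.
#'
#' @param trace An [emg_trace()].
#' @param tms_time_ms TMS time; samples before it define the baseline.
#' @param k Threshold multiplier.
#' @param min_duration_ms Minimum supra-threshold run length.
#' @return Burst onset time (ms) or `NA` if no burst is detected.
#' @export
detect_burst_onset <- function(trace, tms_time_ms, k = 3, min_duration_ms = 5) {
  if (!inherits(trace, "emg_trace")) abort("`trace` must be an emg_trace")
  t <- trace_times_ms(trace)
  base <- trace$samples_mv[t < tms_time_ms]
  if (length(base) < 10) abort("not enough pre-TMS samples to estimate baseline")
  thr <- k * sd(base)
  # ignore the MEP itself: search from 40 ms post-TMS
  searchable <- t >= tms_time_ms + 40
  above <- abs(trace$samples_mv) > thr & searchable
  run_len <- ceiling(min_duration_ms * trace$sampling_rate_hz / 1000)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= run_len)
  if (length(hit) == 0) return(NA_real_)
  t[starts[hit[1]]]
}

#' Exclude trials where TMS fell in or after the EMG burst
#'
#' A MEP is only a clean excitability probe if the pulse precedes voluntary
#' muscle activity, so trials where TMS arrived during or after the EMG
#' burst are excluded. By default the burst onset is taken as
#' `rt - motor_time_ms` (the electromechanical delay between EMG onset and
#' the registered key press); supply a `burst_onset_ms` column to use
#' measured onsets instead. Non-responding trials (successful stops,
#' baseline/catch trials, lapses) are never excluded by this rule.
#'
#' @param trials Trial tibble.
#' @param motor_time_ms Electromechanical delay used when no measured burst
#'   onset is available.
#' @return `trials` with `excluded`/`exclusion_reason` updated
#'   (`"tms_in_burst"`).
#' @export
exclude_tms_in_burst <- function(trials, motor_time_ms = 50) {
  stopifnot_cols(trials, c("trial_type", "tms_time_ms", "rt_ms", "responded",
                           "excluded", "exclusion_reason"), "`trials`")
  onset <- if ("burst_onset_ms" %in% names(trials)) {
    if_else(is.na(trials$burst_onset_ms),
            trials$rt_ms - motor_time_ms, trials$burst_onset_ms)
  } else {
    trials$rt_ms - motor_time_ms
  }
  bad <- trials$trial_type != "baseline" & trials$responded %in% TRUE &
    !is.na(onset) & !is.na(trials$tms_time_ms) &
    trials$tms_time_ms >= onset & !trials$excluded
  trials$excluded[bad] <- TRUE
  trials$exclusion_reason[bad] <- "tms_in_burst"
  trials
}

#' Normalize an amplitude to a baseline mean
#'
#' @param amplitude_mv MEP amplitude(s).
#' @param baseline_mean_mv Mean baseline MEP amplitude; must be > 0.
#' @return Dimensionless normalized value(s).
#' @export
#' @examples
#' normalize_to_baseline(1.0, 0.5) # 2
normalize_to_baseline <- function(amplitude_mv, baseline_mean_mv) {
  if (anyNA(baseline_mean_mv) || any(baseline_mean_mv <= 0)) {
    abort("`baseline_mean_mv` must be positive")
  }
  amplitude_mv / baseline_mean_mv
}

#' Baseline-normalize all MEPs in a trial table
#'
#' Computes each participant x coil baseline mean from non-excluded baseline
#' trials and divides every MEP by it, adding a `norm_mep` column.
#' Participant x coil cells without an elicitable baseline (no valid baseline
#' trials, or a non-positive mean) are dropped for that coil, mirroring the
#' handling of participants without measurable resting MEPs; dropped cells
#' are reported in a message and in the `"dropped"` attribute.
#'
#' @param trials Trial tibble with `mep_mv`.
#' @return `trials` (minus dropped cells) with `norm_mep` and
#'   `baseline_mean_mv` columns; attribute `"dropped"` lists removed cells.
#' @export
normalize_mep <- function(trials) {
  stopifnot_cols(trials, c("participant_id", "coil", "trial_type", "mep_mv",
                           "excluded"), "`trials`")
  base <- trials |>
    filter(.data$trial_type == "baseline", !.data$excluded, !is.na(.data$mep_mv)) |>
    group_by(.data$participant_id, .data$coil) |>
    summarise(baseline_mean_mv = mean(.data$mep_mv), .groups = "drop")

  cells <- distinct(trials, .data$participant_id, .data$coil)
  ok <- base |> filter(.data$baseline_mean_mv > 0)
  dropped <- anti_join(cells, ok, by = c("participant_id", "coil"))
  if (nrow(dropped) > 0) {
    inform(sprintf(
      "dropping %d participant x coil cell(s) without an elicitable baseline: %s",
      nrow(dropped),
      paste(sprintf("%s/%s", dropped$participant_id, dropped$coil), collapse = ", ")
    ))
  }
  out <- trials |>
    inner_join(ok, by = c("participant_id", "coil")) |>
    mutate(norm_mep = normalize_to_baseline(.data$mep_mv, .data$baseline_mean_mv))
  attr(out, "dropped") <- dropped
  out
}

#' Response-locked lead-time bin label
#'
#' Assigns a lead time (`rt - tms_time`, ms before movement) to one of the
#' six canonical 50-ms bins, lower-inclusive/upper-exclusive: 50--100 up to
#' 300--350 ms before movement. Lead times outside `[50, 350)` get `NA`
#' (out of range: closer than 50 ms implies TMS at or inside the EMG burst;
#' 350 ms or more precedes the analyzed execution epoch).
#'
#' @param lead_ms Numeric lead times.
#' @return Character bin labels or `NA`.
#' @export
#' @examples
#' response_bin_label(c(120, 150, 400)) # "100-150", "150-200", NA
response_bin_label <- function(lead_ms) {
  lower <- 50 * (lead_ms %/% 50)
  lab <- sprintf("%d-%d", lower, lower + 50)
  lab[!(lead_ms >= 50 & lead_ms < 350) | is.na(lead_ms)] <- NA_character_
  lab
}

#' Flag responding go trials with out-of-range lead times
#'
#' Responding, so-far-unexcluded go trials whose TMS-to-response lead time
#' falls outside `[50, 350)` ms are flagged `"out_of_range"`: they belong to
#' no response-locked bin.
#'
#' @param trials Trial tibble.
#' @return `trials` with flags updated.
#' @export
flag_out_of_range <- function(trials) {
  stopifnot_cols(trials, c("trial_type", "tms_time_ms", "rt_ms", "responded",
                           "excluded", "exclusion_reason"), "`trials`")
  lead <- trials$rt_ms - trials$tms_time_ms
  bad <- trials$trial_type == "go" & trials$responded %in% TRUE &
    !trials$excluded & !is.na(lead) & (lead < 50 | lead >= 350)
  trials$excluded[bad] <- TRUE
  trials$exclusion_reason[bad] <- "out_of_range"
  trials
}

#' Standard MEP preprocessing chain
#'
#' Applies, in order: omission flagging, TMS-in-burst exclusion, and
#' baseline normalization. This is the preprocessing assumed by
#' [bin_cue_locked()] and [bin_response_locked()]. Out-of-range lead-time
#' flagging is an alignment-specific rule applied inside
#' [bin_response_locked()] only: a slow trial probed at the cue is a valid
#' cue-locked observation even though its lead time exceeds 350 ms.
#'
#' @param trials Raw trial tibble.
#' @param omission_cutoff_ms Passed to [flag_omissions()].
#' @param motor_time_ms Passed to [exclude_tms_in_burst()].
#' @return Normalized, flagged trial tibble.
#' @export
#' @examples
#' trials <- simulate_dataset(2, seed = 1) |> prepare_mep()
prepare_mep <- function(trials, omission_cutoff_ms = 1000, motor_time_ms = 50) {
  trials |>
    flag_omissions(cutoff_ms = omission_cutoff_ms) |>
    exclude_tms_in_burst(motor_time_ms = motor_time_ms) |>
    normalize_mep()
}

binned_tibble <- function(x, alignment) {
  x$alignment <- alignment
  x <- x[, c("participant_id", "task", "coil", "alignment", "bin",
             "mean_norm_mep", "n_trials")]
  class(x) <- c("ss_binned", class(x))
  x
}

#' Cue-locked excitability bins
#'
#' Averages baseline-normalized MEPs of analyzable go trials by their
#' scheduled TMS timepoint (Cue, 50, ..., 300 ms after the go cue), per
#' participant x task x coil.
#'
#' @param trials Preprocessed trial tibble (see [prepare_mep()]) with
#'   `norm_mep`.
#' @param min_trials Minimum trials a bin needs to be retained (default 1;
#'   the distance analysis uses a stricter threshold, see [run_config()]).
#' @return A binned-excitability tibble: `participant_id`, `task`, `coil`,
#'   `alignment`, `bin` (factor in canonical order), `mean_norm_mep`,
#'   `n_trials`.
#' @export
bin_cue_locked <- function(trials, min_trials = 1) {
  stopifnot_cols(trials, c("participant_id", "task", "coil", "trial_type",
                           "tms_time_ms", "excluded", "norm_mep"), "`trials`")
  trials |>
    filter(.data$trial_type == "go", !.data$excluded, !is.na(.data$norm_mep)) |>
    mutate(bin = factor(cue_bin_label(.data$tms_time_ms),
                        levels = bin_levels("cue_locked"))) |>
    filter(!is.na(.data$bin)) |>
    group_by(.data$participant_id, .data$task, .data$coil, .data$bin) |>
    summarise(mean_norm_mep = mean(.data$norm_mep), n_trials = n(),
              .groups = "drop") |>
    filter(.data$n_trials >= min_trials) |>
    binned_tibble("cue_locked")
}

#' Response-locked excitability bins
#'
#' Computes each responding go trial's lead time (`rt - tms_time`), assigns
#' it to the canonical 50-ms bins before movement
#' (300--350 down to 50--100 ms), and averages normalized MEPs per
#' participant x task x coil x bin. Lead times outside `[50, 350)` are
#' excluded as out of range (see [flag_out_of_range()]); every analyzable
#' responding go trial therefore maps to exactly one bin or is flagged.
#'
#' @inheritParams bin_cue_locked
#' @return A binned-excitability tibble (see [bin_cue_locked()]).
#' @export
bin_response_locked <- function(trials, min_trials = 1) {
  stopifnot_cols(trials, c("participant_id", "task", "coil", "trial_type",
                           "tms_time_ms", "rt_ms", "responded", "excluded",
                           "norm_mep"), "`trials`")
  trials |>
    flag_out_of_range() |>
    filter(.data$trial_type == "go", .data$responded, !.data$excluded,
           !is.na(.data$norm_mep)) |>
    mutate(bin = factor(response_bin_label(.data$rt_ms - .data$tms_time_ms),
                        levels = bin_levels("response_locked"))) |>
    filter(!is.na(.data$bin)) |>
    group_by(.data$participant_id, .data$task, .data$coil, .data$bin) |>
    summarise(mean_norm_mep = mean(.data$norm_mep), n_trials = n(),
              .groups = "drop") |>
    filter(.data$n_trials >= min_trials) |>
    binned_tibble("response_locked")
}

#' Bin excitability under either alignment
#'
#' @param trials Preprocessed trial tibble.
#' @param alignment `"cue_locked"` or `"response_locked"`.
#' @return See [bin_cue_locked()] / [bin_response_locked()].
#' @export
bin_excitability <- function(trials,
                             alignment = c("cue_locked", "response_locked"),
                             min_trials = 1) {
  alignment <- arg_match(alignment)
  if (alignment == "cue_locked") {
    bin_cue_locked(trials, min_trials = min_trials)
  } else {
    bin_response_locked(trials, min_trials = min_trials)
  }
}
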