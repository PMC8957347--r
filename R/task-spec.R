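#' Define a task block
#'
#' Describes one block of the stop-signal task (SST) or the Go-only simple
#' reaction time task as delivered with TMS: trial counts, the cue-locked TMS
#' timepoints, and block timing. Defaults reproduce the published protocol:
#' 105 go trials (15 MEPs at each of 7 timepoints: go cue and 50--300 ms
#' after it), 35 stop trials (SST only, one in every four responding trials),
#' 15 catch/baseline trials with TMS 1,000 ms after fixation, a 500 ms
#' fixation-to-cue interval and a 1,750 ms intertrial interval.
#'
#' Catch trials double as the baseline-TMS trials: no go cue is shown and a
#' single pulse probes resting corticospinal excitability, so they appear in
#' generated trial tables as `trial_type = "baseline"`.
#'
#' @param task `"SST"` or `"GoOnly"`.
#' @param n_go Number of go trials.
#' @param n_stop Number of stop trials (forced to 0 for `"GoOnly"`).
#' @param n_catch Number of catch/baseline trials.
#' @param tms_timepoints_ms Strictly increasing TMS offsets from the go cue.
#' @param meps_per_timepoint MEPs collected at each timepoint; must satisfy
#'   `n_go == meps_per_timepoint * length(tms_timepoints_ms)`.
#' @param baseline_tms_offset_ms TMS time after fixation on baseline trials.
#' @param fixation_to_cue_ms Fixation-to-go-cue interval.
#' @param intertrial_interval_ms Intertrial interval.
#' @return A `task_spec` list.
#' @export
#' @examples
#' task_spec("SST")
#' task_spec("GoOnly")
task_spec <- function(task = c("SST", "GoOnly"),
                      n_go = 105,
                      n_stop = if (task == "SST") 35 else 0,
                      n_catch = 15,
                      tms_timepoints_ms = seq(0, 300, by = 50),
                      meps_per_timepoint = 15,
                      baseline_tms_offset_ms = 1000,
                      fixation_to_cue_ms = 500,
                      intertrial_interval_ms = 1750) {
  task <- arg_match(task)
  if (task == "GoOnly") n_stop <- 0L
  check_number(n_go, "n_go", min = 0)
  check_number(n_stop, "n_stop", min = 0)
  check_number(n_catch, "n_catch", min = 0)
  check_number(meps_per_timepoint, "meps_per_timepoint", min = 1)
  if (length(tms_timepoints_ms) < 1 || is.unsorted(tms_timepoints_ms, strictly = TRUE)) {
    abort("`tms_timepoints_ms` must be strictly increasing")
  }
  check_number(baseline_tms_offset_ms, "baseline_tms_offset_ms", min = 0)
  check_number(fixation_to_cue_ms, "fixation_to_cue_ms", min = 0)
  check_number(intertrial_interval_ms, "intertrial_interval_ms", min = 0)
  structure(
    list(
      task = task,
      n_go = as.integer(n_go),
      n_stop = as.integer(n_stop),
      n_catch = as.integer(n_catch),
      tms_timepoints_ms = as.numeric(tms_timepoints_ms),
      meps_per_timepoint = as.integer(meps_per_timepoint),
      baseline_tms_offset_ms = as.numeric(baseline_tms_offset_ms),
      fixation_to_cue_ms = as.numeric(fixation_to_cue_ms),
      intertrial_interval_ms = as.numeric(intertrial_interval_ms)
    ),
    class = "task_spec"
  )
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf(
    "<task_spec> %s: %d go, %d stop, %d catch/baseline; TMS at {%s} ms\n",
    x$task, x$n_go, x$n_stop, x$n_catch,
    paste(x$tms_timepoints_ms, collapse = ", ")
  ))
  invisible(x)
}

#' Dynamic stop-signal delay tracker
#'
#' One-up-one-down staircase on the stop-signal delay (SSD). After a
#' successful stop the next SSD moves one step later (stopping gets harder);
#' after a failed stop it moves one step earlier. The SSD is clipped to the
#' `[lower, upper]` range, so at the bounds an update in the outward
#' direction leaves it unchanged. Defaults follow the published tracking
#' rule: start 150 ms, step 50 ms, range 100--250 ms, which converges onto
#' ~50% successful inhibition.
#'
#' @param start_ssd_ms Initial SSD.
#' @param step_ms Step size.
#' @param lower_ms,upper_ms SSD bounds (inclusive).
#' @return A `staircase` object with fields `current_ssd_ms`, `step_ms`,
#'   `lower_ms`, `upper_ms` and a `history` list of parallel vectors
#'   (`ssd_ms`, `stop_success`).
#' @export
#' @examples
#' s <- staircase_new()
#' s <- staircase_update(s, stop_success = TRUE) # 150 -> 200
#' s$current_ssd_ms
staircase_new <- function(start_ssd_ms = 150, step_ms = 50,
                          lower_ms = 100, upper_ms = 250) {
  check_number(step_ms, "step_ms", min = 0, strict_min = TRUE)
  if (lower_ms > upper_ms) abort("`lower_ms` must be <= `upper_ms`")
  if (start_ssd_ms < lower_ms || start_ssd_ms > upper_ms) {
    abort("`start_ssd_ms` must lie within [lower_ms, upper_ms]")
  }
  if ((start_ssd_ms - lower_ms) %% step_ms != 0) {
    abort("`start_ssd_ms` must be `lower_ms` plus a multiple of `step_ms`")
  }
  structure(
    list(
      current_ssd_ms = start_ssd_ms,
      step_ms = step_ms,
      lower_ms = lower_ms,
      upper_ms = upper_ms,
      history = list(ssd_ms = numeric(), stop_success = logical())
    ),
    class = "staircase"
  )
}

#' Update the SSD staircase after a stop trial
#'
#' @param state A [staircase_new()] object.
#' @param stop_success `TRUE` if the response was successfully withheld.
#' @return The updated `staircase`; the SSD used on the trial and its outcome
#'   are appended to `history`.
#' @export
staircase_update <- function(state, stop_success) {
  if (!inherits(state, "staircase")) abort("`state` must be a staircase object")
  if (!is.logical(stop_success) || length(stop_success) != 1 || is.na(stop_success)) {
    abort("`stop_success` must be TRUE or FALSE")
  }
  used <- state$current_ssd_ms
  proposed <- used + if (stop_success) state$step_ms else -state$step_ms
  state$current_ssd_ms <- min(max(proposed, state$lower_ms), state$upper_ms)
  state$history$ssd_ms <- c(state$history$ssd_ms, used)
  state$history$stop_success <- c(state$history$stop_success, stop_success)
  state
}

#' @export
print.staircase <- function(x, ...) {
  cat(sprintf(
    "<staircase> SSD %g ms (range %g-%g, step %g); %d stop trials tracked\n",
    x$current_ssd_ms, x$lower_ms, x$upper_ms, x$step_ms,
    length(x$history$ssd_ms)
  ))
  invisible(x)
}
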