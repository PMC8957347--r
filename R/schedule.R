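#' Schedule one task block
#'
#' Lays out the trial sequence for a block: go trials each carrying one of
#' the cue-locked TMS timepoints (exactly `meps_per_timepoint` trials per
#' timepoint, in randomized order), stop trials inserted so that one in every
#' four responding (go or stop) trials is a stop trial, and catch/baseline
#' trials interspersed at random positions. With the strict one-in-four rule
#' every consecutive window of four responding trials contains exactly one
#' stop trial, which forces periodic stop placement; the phase of the period
#' and all other orderings are randomized.
#'
#' Stop trials are assigned a TMS timepoint too (TMS is delivered on every
#' trial) but their MEPs are never analyzed downstream.
#'
#' @param spec A [task_spec()].
#' @param seed Optional integer seed; when supplied the schedule is
#'   reproducible and the caller's RNG state is untouched.
#' @return A tibble of trial skeletons: `trial_index`, `task`, `trial_type`
#'   (`"go"`, `"stop"`, `"baseline"`), `tms_time_ms` and `tms_ref`
#'   (`"cue"` for go/stop trials, `"fixation"` for baseline trials).
#' @export
#' @examples
#' blk <- schedule_block(task_spec("SST"), seed = 1)
#' table(blk$trial_type)
schedule_block <- function(spec, seed = NULL) {
  if (!inherits(spec, "task_spec")) abort("`spec` must be a task_spec object")
  n_tp <- length(spec$tms_timepoints_ms)
  if (spec$n_go %% n_tp != 0 ||
      spec$n_go != spec$meps_per_timepoint * n_tp) {
    abort(sprintf(
      "unbalanced schedule: n_go (%d) must equal meps_per_timepoint (%d) x number of timepoints (%d)",
      spec$n_go, spec$meps_per_timepoint, n_tp
    ))
  }
  with_optional_seed(seed, {
    go_tms <- sample(rep(spec$tms_timepoints_ms, spec$meps_per_timepoint))
    n_resp <- spec$n_go + spec$n_stop

    if (spec$n_stop > 0) {
      if (n_resp %% 4 != 0 || spec$n_stop != n_resp %/% 4) {
        warn("stop trials are not one quarter of responding trials; placing stops at random")
        stop_pos <- sort(sample(n_resp, spec$n_stop))
      } else {
        phase <- sample(4, 1)
        stop_pos <- seq(phase, n_resp, by = 4)
      }
    } else {
      stop_pos <- integer()
    }
    resp_type <- rep("go", n_resp)
    resp_type[stop_pos] <- "stop"

    resp <- tibble(
      trial_type = resp_type,
      tms_time_ms = NA_real_,
      tms_ref = "cue"
    )
    resp$tms_time_ms[resp$trial_type == "go"] <- go_tms
    if (spec$n_stop > 0) {
      resp$tms_time_ms[resp$trial_type == "stop"] <-
        sample(spec$tms_timepoints_ms, spec$n_stop, replace = TRUE)
    }

    base <- tibble(
      trial_type = rep("baseline", spec$n_catch),
      tms_time_ms = rep(spec$baseline_tms_offset_ms, spec$n_catch),
      tms_ref = rep("fixation", spec$n_catch)
    )

    n_all <- n_resp + spec$n_catch
    is_base <- logical(n_all)
    is_base[sample(n_all, spec$n_catch)] <- TRUE
    cols <- c("trial_type", "tms_time_ms", "tms_ref")
    out <- tibble(
      trial_index = seq_len(n_all),
      task = spec$task,
      trial_type = NA_character_,
      tms_time_ms = NA_real_,
      tms_ref = NA_character_
    )
    out[is_base, cols] <- base
    out[!is_base, cols] <- resp
    out
  })
}
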