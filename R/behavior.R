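#' Flag omission errors on go trials
#'
#' Go trials with a reaction time strictly exceeding the cutoff, or with no
#' response at all (lapses), are flagged as omission errors and excluded from
#' reaction-time means downstream. The filter is idempotent: already-flagged
#' rows are left untouched.
#'
#' @param trials Trial tibble (see [simulate_dataset()] for the schema).
#' @param cutoff_ms Omission cutoff; the published rule is `rt > 1000` ms.
#' @return `trials` with `excluded`/`exclusion_reason` updated. Errors if any
#'   participant x coil x task cell is left with no analyzable go trials.
#' @export
#' @examples
#' trials <- simulate_dataset(2, seed = 1)
#' trials <- flag_omissions(trials)
#' table(trials$exclusion_reason, useNA = "ifany")
flag_omissions <- function(trials, cutoff_ms = 1000) {
  stopifnot_cols(trials, c("participant_id", "task", "coil", "trial_type",
                           "rt_ms", "responded", "excluded", "exclusion_reason"),
                 "`trials`")
  is_om <- trials$trial_type == "go" & !trials$excluded &
    (!trials$responded | (!is.na(trials$rt_ms) & trials$rt_ms > cutoff_ms))
  trials$excluded[is_om] <- TRUE
  trials$exclusion_reason[is_om] <- "omission"

  left <- trials |>
    filter(.data$trial_type == "go") |>
    group_by(.data$participant_id, .data$task, .data$coil) |>
    summarise(n_ok = sum(!.data$excluded), .groups = "drop") |>
    filter(.data$n_ok == 0)
  if (nrow(left) > 0) {
    abort(sprintf(
      "no analyzable go trials for %s",
      paste(sprintf("%s/%s/%s", left$participant_id, left$task, left$coil),
            collapse = "; ")
    ))
  }
  trials
}

#' Mean-method stop-signal reaction time
#'
#' `SSRT = mean go RT - mean SSD`. Because the difference of means equals the
#' mean of paired differences, this can be computed per participant and then
#' averaged, or directly on group means.
#'
#' @param mean_go_rt_ms Mean go reaction time(s), ms.
#' @param mean_ssd_ms Mean stop-signal delay(s), ms.
#' @return SSRT in ms (vectorized).
#' @export
#' @examples
#' ssrt_mean_method(391.55, 167.05) # 224.5
ssrt_mean_method <- function(mean_go_rt_ms, mean_ssd_ms) {
  if (length(mean_go_rt_ms) != length(mean_ssd_ms)) {
    abort("`mean_go_rt_ms` and `mean_ssd_ms` must have equal length")
  }
  if (anyNA(mean_ssd_ms) || any(!is.finite(mean_ssd_ms))) {
    abort("missing SSD record: `mean_ssd_ms` must be finite")
  }
  if (anyNA(mean_go_rt_ms) || any(!is.finite(mean_go_rt_ms))) {
    abort("`mean_go_rt_ms` must be finite")
  }
  mean_go_rt_ms - mean_ssd_ms
}

#' Response delay effect
#'
#' The behavioral signature of proactive inhibition: go-trial reaction time
#' in the stop-signal task minus go-trial reaction time in the Go-only task.
#' Positive values mean anticipatory slowing.
#'
#' @param mean_go_rt_sst,mean_go_rt_goonly Mean go RTs (ms) in the two tasks.
#' @return RDE in ms (vectorized).
#' @export
#' @examples
#' compute_rde(391.55, 288.31) # 103.24
compute_rde <- function(mean_go_rt_sst, mean_go_rt_goonly) {
  mean_go_rt_sst - mean_go_rt_goonly
}

#' Percentage of successful stop trials
#'
#' @param stop_trials Tibble of stop trials with a logical `stop_success`
#'   column (rows with `trial_type` other than `"stop"` are dropped if the
#'   column is present).
#' @return p(inhibit) as a percentage in \[0, 100\].
#' @export
#' @examples
#' compute_p_inhibit(tibble::tibble(stop_success = rep(c(TRUE, FALSE), c(17, 18))))
compute_p_inhibit <- function(stop_trials) {
  stopifnot_cols(stop_trials, "stop_success", "`stop_trials`")
  if ("trial_type" %in% names(stop_trials)) {
    stop_trials <- filter(stop_trials, .data$trial_type == "stop")
  }
  if (nrow(stop_trials) == 0) abort("zero stop trials: p(inhibit) is undefined")
  100 * mean(stop_trials$stop_success)
}

#' Behavioral summary table
#'
#' Computes, per participant x coil x task: the mean go reaction time
#' (omissions excluded), the omission percentage, and — for the stop-signal
#' task — p(inhibit), the mean RT on failed stop trials ("stop respond"),
#' the mean SSD over presented stop trials, and the mean-method SSRT. The
#' response delay effect (`rde_ms`, SST minus Go-only go RT) is attached per
#' participant x coil and repeated on both task rows.
#'
#' Mean SSD is averaged over all presented stop trials (the tracking
#' convention behind the mean method); set `drop_post_omission_ssd = TRUE` to
#' drop stop trials that immediately follow an omission go trial instead.
#'
#' @param trials Trial tibble.
#' @param omission_cutoff_ms Cutoff passed to [flag_omissions()].
#' @param drop_post_omission_ssd See above.
#' @return Tibble with one row per participant x coil x task.
#' @export
#' @examples
#' trials <- simulate_dataset(2, seed = 1)
#' summarize_behavior(trials)
summarize_behavior <- function(trials, omission_cutoff_ms = 1000,
                               drop_post_omission_ssd = FALSE) {
  trials <- flag_omissions(trials, cutoff_ms = omission_cutoff_ms)

  go <- trials |>
    filter(.data$trial_type == "go") |>
    group_by(.data$participant_id, .data$coil, .data$task) |>
    summarise(
      mean_go_rt_ms = mean(.data$rt_ms[!.data$excluded]),
      omission_pct = 100 * mean(.data$exclusion_reason %in% "omission"),
      .groups = "drop"
    )

  stops <- filter(trials, .data$trial_type == "stop")
  stops_ssd <- stops
  if (drop_post_omission_ssd && nrow(stops) > 0) {
    post_om <- trials |>
      group_by(.data$participant_id, .data$coil, .data$task) |>
      arrange(.data$trial_index, .by_group = TRUE) |>
      mutate(after_omission = lag(.data$exclusion_reason %in% "omission",
                                  default = FALSE)) |>
      ungroup() |>
      filter(.data$trial_type == "stop")
    stops_ssd <- filter(post_om, !.data$after_omission)
  }
  if (nrow(stops) > 0) {
    ssd_tbl <- stops_ssd |>
      group_by(.data$participant_id, .data$coil, .data$task) |>
      summarise(mean_ssd_ms = mean(.data$ssd_ms), .groups = "drop")
    sst <- stops |>
      group_by(.data$participant_id, .data$coil, .data$task) |>
      summarise(
        p_inhibit_pct = 100 * mean(.data$stop_success),
        stop_respond_rt_ms = mean(.data$rt_ms[.data$responded]),
        .groups = "drop"
      ) |>
      left_join(ssd_tbl, by = c("participant_id", "coil", "task")) |>
      mutate(ssrt_ms = ssrt_mean_method(
        go$mean_go_rt_ms[match(
          paste(.data$participant_id, .data$coil, .data$task),
          paste(go$participant_id, go$coil, go$task)
        )],
        .data$mean_ssd_ms
      ))
    out <- left_join(go, sst, by = c("participant_id", "coil", "task"))
  } else {
    out <- go |>
      mutate(p_inhibit_pct = NA_real_, stop_respond_rt_ms = NA_real_,
             mean_ssd_ms = NA_real_, ssrt_ms = NA_real_)
  }

  wide <- out |>
    select("participant_id", "coil", "task", "mean_go_rt_ms") |>
    pivot_wider(names_from = "task", values_from = "mean_go_rt_ms")
  wide$rde_ms <- if (all(c("SST", "GoOnly") %in% names(wide))) {
    compute_rde(wide$SST, wide$GoOnly)
  } else {
    NA_real_
  }
  rde <- select(wide, "participant_id", "coil", "rde_ms")

  out |>
    left_join(rde, by = c("participant_id", "coil")) |>
    arrange(.data$participant_id, .data$coil, .data$task)
}
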