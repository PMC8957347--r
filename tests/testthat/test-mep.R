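test_that("peak-to-peak amplitude is max minus min within the window", {
  tr <- emg_trace(c(0, 0.3, -0.2, 0, 5), sampling_rate_hz = 1000)
  expect_equal(peak_to_peak(tr, 0, 4), 0.5) # window excludes the 5 at t=4
  flat <- emg_trace(rep(0.1, 50), 1000)
  expect_equal(peak_to_peak(flat, 0, 50), 0)
  expect_error(peak_to_peak(tr, 10, 20), "empty window")
  expect_error(peak_to_peak(tr, 3, 3), "<")
})

test_that("synthetic biphasic MEP round-trips through peak_to_peak", {
  withr::with_seed(2, {
    tr <- simulate_emg_trace(amplitude_mv = 1.2, tms_time_ms = 100,
                             noise_sd_mv = 0.005)
  })
  # MEP occupies ~[120, 135); measure in the post-TMS window
  expect_equal(peak_to_peak(tr, 110, 160), 1.2, tolerance = 0.05)
})

test_that("threshold detector finds the EMG burst onset", {
  withr::with_seed(3, {
    tr <- simulate_emg_trace(0.8, tms_time_ms = 100, burst_onset_ms = 300)
    quiet <- simulate_emg_trace(0.8, tms_time_ms = 100)
  })
  expect_equal(detect_burst_onset(tr, tms_time_ms = 100), 300, tolerance = 5)
  expect_true(is.na(detect_burst_onset(quiet, tms_time_ms = 100)))
})

test_that("TMS during or after the EMG burst excludes the trial", {
  # burst onset = rt - 50 by default; rt 300 -> onset 250
  trials <- make_trials(
    rt_ms = c(300, 300, 300, NA),
    responded = c(TRUE, TRUE, TRUE, FALSE),
    trial_type = c("go", "go", "go", "baseline"),
    tms_time_ms = c(260, 210, 250, 1000), # 10 after, 40 before, at onset
    tms_ref = c("cue", "cue", "cue", "fixation")
  )
  out <- exclude_tms_in_burst(trials)
  expect_equal(out$excluded, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$exclusion_reason[1], "tms_in_burst")

  # a measured burst_onset_ms column takes precedence
  with_onset <- make_trials(rt_ms = 300, tms_time_ms = 260)
  with_onset$burst_onset_ms <- 270
  expect_false(exclude_tms_in_burst(with_onset)$excluded)
})

test_that("baseline normalization behaves and drops coil cells without baselines", {
  expect_equal(normalize_to_baseline(1.0, 0.5), 2)
  expect_error(normalize_to_baseline(1, 0), "positive")

  # 16 participants, 3 lacking AP30 baseline trials -> 13 retained for AP30
  ids <- sprintf("P%02d", 1:16)
  rows <- tidyr::crossing(participant_id = ids,
                          coil = c("PA120", "AP30"),
                          trial_type = c("baseline", "go"))
  rows <- rows[!(rows$participant_id %in% ids[1:3] &
                   rows$coil == "AP30" & rows$trial_type == "baseline"), ]
  trials <- make_trials(
    participant_id = rows$participant_id, coil = rows$coil,
    trial_type = rows$trial_type,
    tms_time_ms = ifelse(rows$trial_type == "baseline", 1000, 0),
    tms_ref = ifelse(rows$trial_type == "baseline", "fixation", "cue"),
    rt_ms = ifelse(rows$trial_type == "go", 400, NA),
    responded = rows$trial_type == "go",
    mep_mv = 0.5
  )
  out <- suppressMessages(normalize_mep(trials))
  kept <- dplyr::distinct(out, .data$participant_id, .data$coil)
  expect_equal(sum(kept$coil == "AP30"), 13)
  expect_equal(sum(kept$coil == "PA120"), 16)
  expect_equal(nrow(attr(out, "dropped")), 3)

  # self-normalization: baseline trials average to 1 within each cell
  base_norm <- out |>
    dplyr::filter(.data$trial_type == "baseline") |>
    dplyr::group_by(.data$participant_id, .data$coil) |>
    dplyr::summarise(m = mean(.data$norm_mep), .groups = "drop")
  expect_true(all(base_norm$m == 1))
})

test_that("cue-locked bins are the scheduled timepoint labels", {
  trials <- make_trials(
    tms_time_ms = c(0, 150, 300, 150),
    rt_ms = c(500, 500, 500, 500),
    mep_mv = c(1, 2, 3, 4)
  )
  trials <- rbind(trials, make_trials(trial_type = "baseline",
                                      tms_time_ms = 1000, tms_ref = "fixation",
                                      rt_ms = NA_real_, responded = FALSE,
                                      mep_mv = 0.5))
  prepped <- suppressMessages(prepare_mep(trials))
  bc <- bin_cue_locked(prepped)
  expect_equal(as.character(bc$bin), c("Cue", "150", "300"))
  expect_equal(bc$mean_norm_mep[bc$bin == "150"], mean(c(2, 4)) / 0.5)
  expect_equal(bc$n_trials[bc$bin == "150"], 2L)

  # excluded trials contribute to no bin
  prepped2 <- prepped
  prepped2$excluded[prepped2$tms_time_ms == 300 & prepped2$trial_type == "go"] <- TRUE
  expect_false("300" %in% as.character(bin_cue_locked(prepped2)$bin))
})

test_that("response-locked lead times map to the stated half-open 50 ms bins", {
  expect_equal(response_bin_label(320 - 200), "100-150")
  expect_equal(response_bin_label(150), "150-200") # lower-inclusive boundary
  expect_equal(response_bin_label(c(49.9, 50, 349.9, 350, 400)),
               c(NA, "50-100", "300-350", NA, NA))
})

test_that("every analyzable responding go trial lands in exactly one response bin or is out of range", {
  trials <- shared_trials()
  prepped <- suppressMessages(prepare_mep(trials))
  pool <- prepped[prepped$trial_type == "go" & prepped$responded &
                    !prepped$excluded, ]
  lead <- pool$rt_ms - pool$tms_time_ms
  labels <- response_bin_label(lead)
  in_range <- lead >= 50 & lead < 350
  # partition: labelled iff in range, one label each
  expect_equal(is.na(labels), !in_range)
  expect_true(all(labels[in_range] %in% bin_levels("response_locked")))
  # the binned table accounts for exactly the in-range trials
  br <- bin_response_locked(prepped)
  expect_equal(sum(br$n_trials), sum(in_range))
  # and flag_out_of_range flags exactly the complement
  flagged <- flag_out_of_range(prepped)
  expect_equal(sum(flagged$exclusion_reason %in% "out_of_range"),
               sum(!in_range))
})

test_that("a flat generator yields normalized means statistically equal to 1 in every bin", {
  flat <- simulate_dataset(8, seed = 31, rise_gain = c(PA120 = 1, AP30 = 1))
  prepped <- suppressMessages(prepare_mep(flat))
  bc <- bin_cue_locked(prepped)
  for (b in bin_levels("cue_locked")) {
    vals <- bc$mean_norm_mep[as.character(bc$bin) == b]
    p <- stats::t.test(vals, mu = 1)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("a response-locked ramp produces bin means rising toward movement", {
  trials <- shared_trials()
  prepped <- suppressMessages(prepare_mep(trials))
  br <- bin_response_locked(prepped)
  means <- br |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(m = mean(.data$mean_norm_mep), .groups = "drop") |>
    dplyr::arrange(.data$bin)
  # canonical order runs toward movement; allow tiny sampling slack
  expect_true(all(diff(means$m) > -0.05))
  expect_gt(means$m[nrow(means)], means$m[1] + 0.5)
})
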