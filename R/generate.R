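#' Sample go-process finishing times
#'
#' Draws ex-Gaussian go reaction times for a given task context and coil:
#' `Normal(mu + rde_shift * [task == "SST"] + coil penalty, sigma) +
#' Exponential(tau)`. Zero `sigma` or `tau` degenerate cleanly, so with both
#' at zero the draw equals the (shifted) `mu`. The expected RT is
#' `mu + shift + penalty + tau`.
#'
#' @param n Number of draws.
#' @param params A [participant_params()].
#' @param task `"SST"` or `"GoOnly"`.
#' @param coil `"PA120"` or `"AP30"`.
#' @return Numeric vector of reaction times (ms), strictly positive.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_go_rt(1e4, participant_params(), "GoOnly", "PA120")) # ~ 290
sample_go_rt <- function(n, params, task = c("SST", "GoOnly"),
                         coil = c("PA120", "AP30")) {
  task <- arg_match(task)
  coil <- arg_match(coil)
  if (!inherits(params, "participant_params")) {
    abort("`params` must be a participant_params object")
  }
  mu <- params$go_mu_ms +
    if (task == "SST") params$rde_shift_ms else 0
  mu <- mu + params$coil_rt_penalty_ms[[coil]]
  gaus <- if (params$go_sigma_ms > 0) rnorm(n, mu, params$go_sigma_ms) else rep(mu, n)
  expo <- if (params$go_tau_ms > 0) rexp(n, 1 / params$go_tau_ms) else 0
  pmax(gaus + expo, 1e-9)
}

#' Independent horse race on a stop trial
#'
#' The response escapes inhibition iff the go process finishes no later than
#' the stop process: `responded = go_rt <= ssd + ssrt` (ties, which have
#' measure zero under continuous RTs, are resolved as responses for
#' determinism). A successful stop is the complement.
#'
#' @param go_rt_ms Go finishing time(s), ms from the go cue.
#' @param ssd_ms Stop-signal delay(s), ms.
#' @param ssrt_ms Stop-process latency(ies), ms.
#' @return Tibble with logical columns `responded` and `stop_success`.
#' @export
#' @examples
#' race_stop_trial(c(300, 400), 150, 200) # failed stop, then successful stop
race_stop_trial <- function(go_rt_ms, ssd_ms, ssrt_ms) {
  if (any(!is.finite(go_rt_ms)) || any(!is.finite(ssd_ms)) || any(!is.finite(ssrt_ms))) {
    abort("race inputs must be finite")
  }
  responded <- go_rt_ms <= ssd_ms + ssrt_ms
  tibble(responded = responded, stop_success = !responded)
}

# Excitability ramp g(lead): 1 when TMS precedes the response by at least
# `onset` ms, rising linearly to `gain` at movement onset (lead = 0), and
# held at the plateau for TMS at/after the response. Vectorized over lead.
mep_gain <- function(lead_ms, onset_ms, gain) {
  frac <- pmin(pmax((onset_ms - lead_ms) / onset_ms, 0), 1)
  1 + (gain - 1) * frac
}

#' Generate MEP amplitudes for scheduled trials
#'
#' Adds a simulated MEP amplitude to every trial carrying a TMS pulse.
#' Amplitude is `baseline_mep[coil] * g(lead) * noise`, where
#' `lead = rt - tms_time` is the time from TMS to the response, `g` is a
#' linear-to-plateau ramp equal to 1 until `rise_onset_before_rt_ms[task]`
#' before the response and reaching `rise_gain[coil]` at movement onset, and
#' `noise` is lognormal with unit median and coefficient of variation
#' `mep_noise_cv`. Baseline trials and trials without a response stay at the
#' resting level (`g = 1`).
#'
#' @param trials Trial tibble with columns `task`, `coil`, `trial_type`,
#'   `tms_time_ms`, `responded`, `rt_ms`.
#' @param params A [participant_params()].
#' @param noise If `FALSE`, the lognormal noise is switched off (useful for
#'   exact checks).
#' @return `trials` with a `mep_mv` column added (or overwritten).
#' @export
generate_mep <- function(trials, params, noise = TRUE) {
  stopifnot_cols(trials, c("task", "coil", "trial_type", "tms_time_ms",
                           "responded", "rt_ms"), "`trials`")
  if (!inherits(params, "participant_params")) {
    abort("`params` must be a participant_params object")
  }
  n <- nrow(trials)
  gain <- unname(params$rise_gain[trials$coil])
  onset <- unname(params$rise_onset_before_rt_ms[trials$task])
  lead <- trials$rt_ms - trials$tms_time_ms
  g <- rep(1, n)
  ramped <- trials$trial_type != "baseline" & trials$responded %in% TRUE &
    !is.na(lead)
  g[ramped] <- mep_gain(lead[ramped], onset[ramped], gain[ramped])
  base <- unname(params$baseline_mep_mv[trials$coil])
  amp <- base * g
  if (noise && params$mep_noise_cv > 0) {
    sdlog <- sqrt(log(1 + params$mep_noise_cv^2))
    amp <- amp * rlnorm(n, meanlog = 0, sdlog = sdlog)
  }
  trials$mep_mv <- amp
  trials
}

#' Run a staircase-tracked stream of stop trials
#'
#' Simulates `n_stop` consecutive stop trials for one participant in the SST
#' context: each trial races a fresh ex-Gaussian go finishing time against
#' the stop process at the current SSD, then updates the one-up-one-down
#' tracker. This is the long-run engine behind the ~50% successful-inhibition
#' convergence property of the dynamic tracking algorithm.
#'
#' @param params A [participant_params()].
#' @param n_stop Number of stop trials.
#' @param coil Coil orientation context for the go RTs.
#' @param staircase A starting [staircase_new()] state.
#' @param seed Optional seed (local RNG).
#' @return Tibble with one row per stop trial: `ssd_ms`, `go_rt_ms`,
#'   `responded`, `stop_success`.
#' @export
#' @examples
#' run <- run_staircase(participant_params(), n_stop = 200, seed = 1)
#' mean(run$stop_success) # ~ 0.5
run_staircase <- function(params, n_stop, coil = "PA120",
                          staircase = staircase_new(), seed = NULL) {
  check_number(n_stop, "n_stop", min = 1)
  with_optional_seed(seed, {
    go_rt <- sample_go_rt(n_stop, params, task = "SST", coil = coil)
    ssrt <- if (params$ssrt_sd_ms > 0) {
      pmax(rnorm(n_stop, params$ssrt_true_ms, params$ssrt_sd_ms), 1)
    } else {
      rep(params$ssrt_true_ms, n_stop)
    }
    ssd <- numeric(n_stop)
    success <- logical(n_stop)
    for (i in seq_len(n_stop)) {
      ssd[i] <- staircase$current_ssd_ms
      success[i] <- go_rt[i] > ssd[i] + ssrt[i]
      staircase <- staircase_update(staircase, success[i])
    }
    tibble(
      ssd_ms = ssd, go_rt_ms = go_rt,
      responded = !success, stop_success = success
    )
  })
}

# Simulate one participant x task x coil block: schedule, race, MEPs.
simulate_block <- function(participant_id, spec, coil, params) {
  blk <- schedule_block(spec)
  n <- nrow(blk)
  blk$participant_id <- participant_id
  blk$coil <- coil
  blk$ssd_ms <- NA_real_
  blk$rt_ms <- NA_real_
  blk$responded <- FALSE
  blk$stop_success <- NA

  is_go <- blk$trial_type == "go"
  is_stop <- blk$trial_type == "stop"

  # Go trials: ex-Gaussian finishing times, with lapses at omission_rate.
  n_go <- sum(is_go)
  go_rt <- sample_go_rt(n_go, params, task = spec$task, coil = coil)
  lapse <- runif(n_go) < params$omission_rate
  blk$rt_ms[is_go] <- if_else(lapse, NA_real_, go_rt)
  blk$responded[is_go] <- !lapse

  # Stop trials: race at the tracked SSD, in presented order.
  if (any(is_stop)) {
    idx <- which(is_stop)
    run <- run_staircase(params, n_stop = length(idx), coil = coil)
    blk$ssd_ms[idx] <- run$ssd_ms
    blk$stop_success[idx] <- run$stop_success
    blk$responded[idx] <- run$responded
    blk$rt_ms[idx] <- if_else(run$responded, run$go_rt_ms, NA_real_)
  }

  blk <- generate_mep(blk, params)
  blk$excluded <- FALSE
  blk$exclusion_reason <- NA_character_
  blk
}

#' Simulate a complete synthetic experiment
#'
#' Generates the full trial table for `n_participants` participants, each
#' completing one block per task x coil combination (the published protocol:
#' SST and Go-only, under PA120 and AP30 TMS). Every stage — scheduling,
#' staircase tracking, the go/stop horse race, lapses and MEP generation — is
#' driven by one seed, so identical calls return byte-identical tables.
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed (required: the generated experiment is defined by
#'   it).
#' @param params Either a single [participant_params()] used for everyone, a
#'   named list of per-participant params, or `NULL` to draw a heterogeneous
#'   sample with [draw_participants()] (forwarding `...`).
#' @param specs List of [task_spec()]s, one per task block type.
#' @param coils Coil orientations delivered.
#' @param ... Passed to [draw_participants()] when `params` is `NULL`.
#' @return Trial tibble, one row per trial. Columns: `participant_id`,
#'   `task`, `coil`, `trial_type`, `trial_index`, `tms_time_ms`, `tms_ref`,
#'   `ssd_ms`, `rt_ms`, `responded`, `stop_success`, `mep_mv`, `excluded`,
#'   `exclusion_reason`. The per-participant parameter list is attached as
#'   attribute `"params"`.
#' @export
#' @examples
#' trials <- simulate_dataset(n_participants = 2, seed = 1)
#' dplyr::count(trials, task, trial_type)
simulate_dataset <- function(n_participants = 16, seed,
                             params = NULL,
                             specs = list(task_spec("SST"), task_spec("GoOnly")),
                             coils = c("PA120", "AP30"),
                             ...) {
  if (missing(seed)) abort("`seed` is required: the dataset is defined by it")
  coils <- match.arg(coils, .coils, several.ok = TRUE)
  withr::with_seed(as.integer(seed), {
    if (is.null(params)) {
      params <- draw_participants(n_participants, ...)
    } else if (inherits(params, "participant_params")) {
      params <- setNames(
        rep(list(params), n_participants),
        sprintf("P%02d", seq_len(n_participants))
      )
    } else if (length(params) != n_participants) {
      abort("`params` list must have one element per participant")
    }
    if (is.null(names(params)) || anyNA(names(params)) || any(names(params) == "")) {
      names(params) <- sprintf("P%02d", seq_len(n_participants))
    }

    combos <- crossing(
      participant_id = names(params),
      spec_i = seq_along(specs),
      coil = coils
    )
    rows <- pmap(combos, function(participant_id, spec_i, coil) {
      simulate_block(participant_id, specs[[spec_i]], coil, params[[participant_id]])
    })
    out <- list_rbind(rows)
    out <- out[, c("participant_id", "task", "coil", "trial_type", "trial_index",
                   "tms_time_ms", "tms_ref", "ssd_ms", "rt_ms", "responded",
                   "stop_success", "mep_mv", "excluded", "exclusion_reason")]
    attr(out, "params") <- params
    out
  })
}
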