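#' Generator parameters for one simulated participant
#'
#' Parameterizes the horse-race + excitability model behind the synthetic
#' data generator. Go finishing times are ex-Gaussian
#' (Normal(`go_mu_ms`, `go_sigma_ms`) + Exponential(`go_tau_ms`)), shifted by
#' `rde_shift_ms` in the stop-signal task (proactive slowing, the response
#' delay effect) and by a per-coil reaction-time penalty. The stop process
#' finishes a constant `ssrt_true_ms` after the stop signal (optionally with
#' Gaussian jitter `ssrt_sd_ms`), and the trial's response is decided by an
#' independent horse race. MEP amplitude is
#' `baseline_mep * g(lead) * lognormal noise`, where `lead` is the time from
#' TMS to the response and `g` ramps from 1 (more than
#' `rise_onset_before_rt_ms` before the response) up to the per-coil plateau
#' `rise_gain` at movement onset; the lognormal noise has unit median and
#' coefficient of variation `mep_noise_cv`.
#'
#' Defaults describe a realistic participant in this protocol: simple-RT
#' ex-Gaussian parameters (mu 250, sigma 25, tau 40 ms), ~100 ms proactive
#' slowing, a 220 ms stop-signal reaction time, a 23 ms AP30 reaction-time
#' penalty, 0.5 mV baseline MEPs, an excitability ramp starting 150 ms before
#' the response with larger PA120 than AP30 gain, 40% MEP amplitude CV and a
#' 0.4% lapse rate.
#'
#' @param go_mu_ms,go_sigma_ms,go_tau_ms Ex-Gaussian parameters of the go
#'   finishing time (ms). `go_sigma_ms`/`go_tau_ms` of 0 degenerate cleanly.
#' @param rde_shift_ms Additive slowing of `go_mu_ms` in the SST context.
#' @param ssrt_true_ms True stop-process latency (ms).
#' @param ssrt_sd_ms Optional Gaussian jitter of the stop latency (default 0:
#'   constant stop process, so mean-method recovery is testable).
#' @param coil_rt_penalty_ms Named numeric, additive RT offset per coil.
#' @param baseline_mep_mv Named numeric, resting MEP amplitude per coil (mV).
#' @param rise_onset_before_rt_ms Named numeric per task: lead time (ms
#'   before the response) at which the excitability ramp leaves baseline.
#' @param rise_gain Named numeric per coil: plateau gain of the ramp at
#'   movement onset (relative PA/AP weighting of the rise).
#' @param mep_noise_cv Lognormal coefficient of variation of MEP amplitude.
#' @param omission_rate Probability that a go trial is a lapse (no response).
#' @param motor_time_ms Electromechanical delay: the EMG burst starts this
#'   long before the registered response.
#' @return A `participant_params` list.
#' @export
#' @examples
#' participant_params()
#' participant_params(rde_shift_ms = 0) # no proactive slowing
participant_params <- function(go_mu_ms = 250,
                               go_sigma_ms = 25,
                               go_tau_ms = 40,
                               rde_shift_ms = 100,
                               ssrt_true_ms = 220,
                               ssrt_sd_ms = 0,
                               coil_rt_penalty_ms = c(PA120 = 0, AP30 = 23),
                               baseline_mep_mv = c(PA120 = 0.5, AP30 = 0.5),
                               rise_onset_before_rt_ms = c(SST = 150, GoOnly = 150),
                               rise_gain = c(PA120 = 3, AP30 = 2.5),
                               mep_noise_cv = 0.4,
                               omission_rate = 0.004) {
  check_number(go_mu_ms, "go_mu_ms", min = 0, strict_min = TRUE)
  check_number(go_sigma_ms, "go_sigma_ms", min = 0)
  check_number(go_tau_ms, "go_tau_ms", min = 0)
  check_number(rde_shift_ms, "rde_shift_ms")
  check_number(ssrt_true_ms, "ssrt_true_ms", min = 0, strict_min = TRUE)
  check_number(ssrt_sd_ms, "ssrt_sd_ms", min = 0)
  check_number(mep_noise_cv, "mep_noise_cv", min = 0)
  check_number(omission_rate, "omission_rate", min = 0, max = 1 - 1e-12)
  for (nm in c("coil_rt_penalty_ms", "baseline_mep_mv", "rise_gain")) {
    v <- get(nm)
    if (!all(.coils %in% names(v))) {
      abort(sprintf("`%s` must be named with coils %s", nm, paste(.coils, collapse = ", ")))
    }
  }
  if (!all(.tasks %in% names(rise_onset_before_rt_ms))) {
    abort("`rise_onset_before_rt_ms` must be named with tasks SST, GoOnly")
  }
  if (any(baseline_mep_mv <= 0)) abort("`baseline_mep_mv` must be > 0")
  if (any(rise_gain <= 0)) abort("`rise_gain` must be > 0")
  if (any(rise_onset_before_rt_ms <= 0)) abort("`rise_onset_before_rt_ms` must be > 0")
  structure(
    list(
      go_mu_ms = go_mu_ms, go_sigma_ms = go_sigma_ms, go_tau_ms = go_tau_ms,
      rde_shift_ms = rde_shift_ms,
      ssrt_true_ms = ssrt_true_ms, ssrt_sd_ms = ssrt_sd_ms,
      coil_rt_penalty_ms = coil_rt_penalty_ms[.coils],
      baseline_mep_mv = baseline_mep_mv[.coils],
      rise_onset_before_rt_ms = rise_onset_before_rt_ms[.tasks],
      rise_gain = rise_gain[.coils],
      mep_noise_cv = mep_noise_cv,
      omission_rate = omission_rate
    ),
    class = "participant_params"
  )
}

#' Draw a heterogeneous participant sample
#'
#' Draws `n` participants whose key parameters vary around the
#' [participant_params()] defaults (or around any override passed through
#' `...`): between-participant Gaussian variation in mean go speed, proactive
#' slowing, stop latency and baseline MEP amplitude, at spreads matching the
#' between-participant standard deviations printed for the behavioral
#' measures of this protocol.
#'
#' @param n_participants Number of participants.
#' @param mu_sd,rde_sd,ssrt_sd,baseline_sd Between-participant SDs of
#'   `go_mu_ms`, `rde_shift_ms`, `ssrt_true_ms` and `baseline_mep_mv`.
#' @param seed Optional seed (local RNG).
#' @param ... Overrides forwarded to [participant_params()] as the
#'   population-mean values.
#' @return Named list of `participant_params`, one per participant
#'   (`"P01"`, `"P02"`, ...).
#' @export
#' @examples
#' pop <- draw_participants(4, seed = 1)
#' names(pop)
draw_participants <- function(n_participants = 16,
                              mu_sd = 25, rde_sd = 20, ssrt_sd = 25,
                              baseline_sd = 0.1,
                              seed = NULL, ...) {
  check_number(n_participants, "n_participants", min = 1)
  base <- participant_params(...)
  with_optional_seed(seed, {
    ids <- sprintf("P%02d", seq_len(n_participants))
    out <- map(seq_len(n_participants), function(i) {
      p <- base
      p$go_mu_ms <- max(50, rnorm(1, base$go_mu_ms, mu_sd))
      p$rde_shift_ms <- rnorm(1, base$rde_shift_ms, rde_sd)
      p$ssrt_true_ms <- max(50, rnorm(1, base$ssrt_true_ms, ssrt_sd))
      p$baseline_mep_mv <- pmax(0.1, rnorm(2, base$baseline_mep_mv, baseline_sd))
      names(p$baseline_mep_mv) <- .coils
      p
    })
    setNames(out, ids)
  })
}
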