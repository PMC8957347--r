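# Shared fixtures: small deterministic worlds used across test files.

# Noise-free, lapse-free single participant with no proactive slowing.
quiet_params <- function(...) {
  args <- utils::modifyList(
    list(go_sigma_ms = 0, go_tau_ms = 0, rde_shift_ms = 0,
         coil_rt_penalty_ms = c(PA120 = 0, AP30 = 0),
         mep_noise_cv = 0, omission_rate = 0),
    list(...)
  )
  do.call(stopstate::participant_params, args)
}

# Hand-built trial rows with sensible defaults for unit tests.
make_trials <- function(...) {
  defaults <- tibble::tibble(
    participant_id = "P01", task = "GoOnly", coil = "PA120",
    trial_type = "go", trial_index = NA_integer_, tms_time_ms = 0,
    tms_ref = "cue", ssd_ms = NA_real_, rt_ms = 300, responded = TRUE,
    stop_success = NA, mep_mv = 0.5, excluded = FALSE,
    exclusion_reason = NA_character_
  )
  over <- tibble::tibble(...)
  out <- defaults[rep(1, max(nrow(over), 1)), ]
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out$trial_index <- seq_len(nrow(out))
  out
}

# A small simulated experiment reused by several files (cached per session).
shared_trials <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- stopstate::simulate_dataset(6, seed = 42)
    cache
  }
})
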