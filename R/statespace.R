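as_point_matrix <- function(p, name) {
  if (is.numeric(p) && is.null(dim(p))) {
    if (length(p) %% 2 != 0 && length(p) != 2) {
      abort(sprintf("`%s` must be a length-2 vector or a 2-column matrix", name))
    }
    p <- matrix(p, ncol = 2, byrow = length(p) > 2)
  }
  p <- as.matrix(p)
  if (ncol(p) != 2) abort(sprintf("`%s` must have 2 columns (pa, ap)", name))
  p
}

#' Euclidean distance between state points
#'
#' The magnitude difference between two points of the PA x AP excitability
#' plane at matched time bins. Vectorized: `p` and `q` may be length-2
#' vectors or 2-column matrices of (pa, ap) rows.
#'
#' @param p,q State points.
#' @return Numeric distances, one per row.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
euclidean_distance <- function(p, q) {
  p <- as_point_matrix(p, "p")
  q <- as_point_matrix(q, "q")
  if (nrow(p) != nrow(q)) abort("`p` and `q` must have the same number of points")
  sqrt(rowSums((p - q)^2))
}

#' Cosine distance between state points
#'
#' `1 - cos(theta)`, where `theta` is the angle between the vectors drawn
#' from the origin to each point: 0 for collinear points (any positive
#' scaling), 1 for orthogonal, 2 for antiparallel. Insensitive to magnitude,
#' it captures the relative PA/AP weighting. The angle itself (radians) is
#' available via [cosine_angle()].
#'
#' @param p,q State points (length-2 vectors or 2-column matrices); neither
#'   may be the zero vector.
#' @return Numeric values in \[0, 2\].
#' @export
#' @examples
#' cosine_distance(c(1, 0), c(0, 1)) # 1
#' cosine_distance(c(2, 2), c(5, 5)) # 0
cosine_distance <- function(p, q) {
  1 - cosine_similarity(p, q)
}

cosine_similarity <- function(p, q) {
  p <- as_point_matrix(p, "p")
  q <- as_point_matrix(q, "q")
  if (nrow(p) != nrow(q)) abort("`p` and `q` must have the same number of points")
  np <- sqrt(rowSums(p^2))
  nq <- sqrt(rowSums(q^2))
  if (any(np == 0) || any(nq == 0)) {
    abort("zero vector: cosine distance is undefined at the origin")
  }
  pmin(pmax(rowSums(p * q) / (np * nq), -1), 1)
}

#' Angle between state-point vectors
#'
#' @inheritParams cosine_distance
#' @return Angle in radians, in \[0, pi\].
#' @export
cosine_angle <- function(p, q) {
  acos(cosine_similarity(p, q))
}

#' Build PA x AP state-space trajectories
#'
#' Pairs the PA120 and AP30 binned excitability series into ordered (pa, ap)
#' state points across the canonical bin sequence, per participant x task
#' (scope `"participant"`) or averaged over participants per task (scope
#' `"group"`, the form used for trajectory plots).
#'
#' @param binned A binned-excitability tibble from [bin_cue_locked()] /
#'   [bin_response_locked()], containing both coils.
#' @param scope `"participant"` or `"group"`.
#' @param incomplete `"error"` (default): fail if any participant x task
#'   lacks a coil or a bin, listing the missing cells; `"drop"`: silently
#'   drop those bins for that participant x task, as late cue-locked
#'   timepoints can legitimately lose all their trials to the TMS-in-burst
#'   rule on fast-responding participants.
#' @return A trajectory tibble: `participant_id` (`"group"` for group
#'   scope), `task`, `alignment`, `bin` (ordered factor), `pa`, `ap`.
#' @export
build_trajectories <- function(binned, scope = c("participant", "group"),
                               incomplete = c("error", "drop")) {
  scope <- arg_match(scope)
  incomplete <- arg_match(incomplete)
  stopifnot_cols(binned, c("participant_id", "task", "coil", "alignment",
                           "bin", "mean_norm_mep"), "`binned`")
  alignment <- unique(binned$alignment)
  if (length(alignment) != 1) abort("`binned` must contain a single alignment")
  levels <- bin_levels(alignment)

  wide <- binned |>
    mutate(bin = as.character(.data$bin)) |>
    select("participant_id", "task", "bin", "coil", "mean_norm_mep") |>
    pivot_wider(names_from = "coil", values_from = "mean_norm_mep")

  # coverage is judged against the bins observed anywhere in the input:
  # a deliberately shorter bin sequence is fine, a cell missing for one
  # coil or one participant is not
  levels_obs <- levels[levels %in% wide$bin]
  expected <- crossing(
    distinct(wide, .data$participant_id, .data$task),
    bin = levels_obs
  )
  full <- left_join(expected, wide, by = c("participant_id", "task", "bin"))
  for (coil in .coils) if (!coil %in% names(full)) full[[coil]] <- NA_real_
  bad <- filter(full, is.na(.data$PA120) | is.na(.data$AP30))
  if (nrow(bad) > 0) {
    if (incomplete == "error") {
      abort(sprintf(
        "mismatched bin coverage; missing coil x bin cells: %s",
        paste(sprintf("%s/%s[%s]", bad$participant_id, bad$task, bad$bin),
              collapse = ", ")
      ))
    }
    full <- filter(full, !is.na(.data$PA120) & !is.na(.data$AP30))
  }
  out <- full |>
    rename(pa = "PA120", ap = "AP30") |>
    mutate(alignment = alignment,
           bin = factor(.data$bin, levels = levels)) |>
    select("participant_id", "task", "alignment", "bin", "pa", "ap") |>
    arrange(.data$participant_id, .data$task, .data$bin)

  if (scope == "group") {
    out <- out |>
      group_by(.data$task, .data$alignment, .data$bin) |>
      summarise(pa = mean(.data$pa), ap = mean(.data$ap), .groups = "drop") |>
      mutate(participant_id = "group") |>
      select("participant_id", "task", "alignment", "bin", "pa", "ap")
  }
  class(out) <- c("ss_trajectory", class(out))
  out
}

#' Per-bin distance series between two tasks' trajectories
#'
#' Matches the two tasks' trajectories bin by bin (within participant and
#' alignment) and computes the Euclidean and cosine distances, plus the
#' auxiliary angle, at every time bin.
#'
#' @param trajectories A trajectory tibble from [build_trajectories()]
#'   containing both tasks.
#' @param task_a,task_b Tasks compared; distances are between `task_a`'s and
#'   `task_b`'s state points.
#' @param strict If `TRUE` (default), error unless the two tasks cover
#'   exactly the same participant x bin cells; if `FALSE`, unmatched bins
#'   are dropped.
#' @return A distance tibble: `participant_id`, `alignment`, `bin`,
#'   `analysis_type = "real"`, `replicate = NA`, `euclidean_d`, `cosine_d`,
#'   `angle_rad`.
#' @export
distance_series <- function(trajectories, task_a = "SST", task_b = "GoOnly",
                            strict = TRUE) {
  stopifnot_cols(trajectories, c("participant_id", "task", "alignment", "bin",
                                 "pa", "ap"), "`trajectories`")
  a <- filter(trajectories, .data$task == task_a)
  b <- filter(trajectories, .data$task == task_b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort(sprintf("both tasks (%s, %s) must be present", task_a, task_b))
  }
  m <- inner_join(a, b, by = c("participant_id", "alignment", "bin"),
                  suffix = c("_a", "_b"))
  if (strict && (nrow(m) != nrow(a) || nrow(m) != nrow(b))) {
    abort("trajectories must share alignment and bin coverage across tasks")
  }
  if (nrow(m) == 0) abort("no matched bins between the two tasks")
  pa_ <- cbind(m$pa_a, m$ap_a)
  pb_ <- cbind(m$pa_b, m$ap_b)
  out <- tibble(
    participant_id = m$participant_id,
    alignment = m$alignment,
    bin = m$bin,
    analysis_type = "real",
    replicate = NA_integer_,
    euclidean_d = euclidean_distance(pa_, pb_),
    cosine_d = cosine_distance(pa_, pb_),
    angle_rad = cosine_angle(pa_, pb_)
  )
  class(out) <- c("ss_distances", class(out))
  out
}

#' Bootstrap null of simulated Go-only trajectories
#'
#' Constructs the chance-level distance distribution for the trajectory
#' comparison: trajectories are resampled (with replacement, within
#' participant x coil x bin, preserving each bin's trial count) from the
#' Go-only trials, and distances between simulated trajectories are computed
#' at every bin. These are the distances expected if proactive inhibition
#' had no effect.
#'
#' Two null constructions are available. `compare = "pair"` (default) draws
#' two independent resampled trajectories per replicate and measures their
#' distance; its sampling variance matches the real SST-vs-Go-only
#' comparison, where both trajectories are noisy. `compare = "original"`
#' measures each resampled trajectory against the observed Go-only
#' trajectory (the literal description of the source method); it carries
#' half the variance and makes the real-vs-simulated test anticonservative.
#'
#' @param goonly_trials Preprocessed trials (see [prepare_mep()]); only
#'   non-excluded Go-only go trials with `norm_mep` are used.
#' @param alignment `"cue_locked"` or `"response_locked"`.
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Optional seed (local RNG).
#' @param compare `"pair"` or `"original"` (see above).
#' @param summarize If `TRUE` (default), replicate distances are averaged
#'   per participant x bin so the simulated arm is balanced with the real
#'   arm in the mixed model; if `FALSE`, one row per replicate is returned.
#' @param missing_bins `"error"` (default): fail, naming the bin, if any
#'   participant x coil lacks trials for a canonical bin; `"drop"`: build
#'   that participant's simulated trajectory from the bins it has.
#' @param min_trials Minimum pool size for a bin to be resampled; smaller
#'   pools are treated like missing bins (a bootstrap of a near-empty pool
#'   cannot represent the sampling noise the real trajectory carries).
#' @param n_template Optional binned-excitability tibble (e.g. the SST arm
#'   of [bin_cue_locked()]) whose `n_trials` set the resample size of the
#'   second trajectory in `"pair"` mode. The real comparison pits an SST
#'   trajectory (with the SST per-bin trial counts) against a Go-only one,
#'   so a variance-matched null resamples one trajectory at the Go-only
#'   counts and the other at the SST counts — both still drawn from the
#'   Go-only pools, which is the null hypothesis. Cells absent from the
#'   template fall back to the pool size.
#' @return A distance tibble (see [distance_series()]) with
#'   `analysis_type = "simulated"`.
#' @export
bootstrap_simulated_trajectories <- function(goonly_trials,
                                             alignment = c("cue_locked", "response_locked"),
                                             n_boot = 1000, seed = NULL,
                                             compare = c("pair", "original"),
                                             summarize = TRUE,
                                             missing_bins = c("error", "drop"),
                                             min_trials = 1,
                                             n_template = NULL) {
  alignment <- arg_match(alignment)
  compare <- arg_match(compare)
  missing_bins <- arg_match(missing_bins)
  check_number(min_trials, "min_trials", min = 1)
  check_number(n_boot, "n_boot", min = 1)
  stopifnot_cols(goonly_trials, c("participant_id", "task", "coil",
                                  "trial_type", "tms_time_ms", "rt_ms",
                                  "responded", "excluded", "norm_mep"),
                 "`goonly_trials`")
  levels <- bin_levels(alignment)

  pool <- goonly_trials |>
    filter(.data$task == "GoOnly", .data$trial_type == "go", !.data$excluded,
           !is.na(.data$norm_mep))
  if (alignment == "cue_locked") {
    pool <- mutate(pool, bin = cue_bin_label(.data$tms_time_ms))
  } else {
    pool <- pool |>
      filter(.data$responded) |>
      mutate(bin = response_bin_label(.data$rt_ms - .data$tms_time_ms)) |>
      filter(!is.na(.data$bin))
  }

  groups <- pool |>
    group_by(.data$participant_id, .data$coil, .data$bin) |>
    summarise(values = list(.data$norm_mep), .groups = "drop") |>
    filter(lengths(.data$values) >= min_trials)
  groups$n_b <- lengths(groups$values)
  if (!is.null(n_template)) {
    stopifnot_cols(n_template, c("participant_id", "coil", "bin", "n_trials"),
                   "`n_template`")
    tmpl <- n_template |>
      mutate(bin = as.character(.data$bin)) |>
      select("participant_id", "coil", "bin", tmpl_n = "n_trials")
    groups <- left_join(groups, tmpl,
                        by = c("participant_id", "coil", "bin"))
    groups$n_b <- if_else(is.na(groups$tmpl_n), groups$n_b,
                          as.integer(groups$tmpl_n))
    groups$tmpl_n <- NULL
  }
  expected <- crossing(
    distinct(pool, .data$participant_id),
    coil = .coils, bin = levels
  )
  missing <- anti_join(expected, groups, by = c("participant_id", "coil", "bin"))
  if (nrow(missing) > 0 && missing_bins == "error") {
    abort(sprintf(
      "empty bin pool for %s",
      paste(sprintf("%s/%s[%s]", missing$participant_id, missing$coil,
                    missing$bin), collapse = ", ")
    ))
  }

  with_optional_seed(seed, {
    # Resampled bin means (resample size m, pool size n), with small-sample
    # corrections on the deviations from the pool mean. A plain
    # with-replacement bootstrap under-disperses the mean by a factor
    # (n-1)/n (degenerating entirely at n = 1), and the implied SD estimate
    # is itself biased low (E[s] = c4(n) * sigma under normality). Distances
    # are linear in the sampling SD, so deviations are scaled by
    # sqrt(n/(n-1)) / c4(n): the simulated trajectory then carries
    # (approximately) the same expected sampling SD as a real one measured
    # with m trials.
    c4 <- function(n) {
      sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
    }
    resample_means <- function(v, m_draw) {
      n <- length(v)
      m <- mean(v)
      raw <- colMeans(matrix(sample(v, m_draw * n_boot, replace = TRUE),
                             nrow = m_draw))
      if (n < 2) return(rep(m, n_boot))
      m + (raw - m) * sqrt(n / (n - 1)) / c4(n)
    }
    groups$mean_a <- map(groups$values, function(v) {
      resample_means(v, length(v))
    })
    groups$mean_b <- if (compare == "pair") {
      map2(groups$values, groups$n_b, resample_means)
    } else {
      map(groups$values, function(v) rep(mean(v), n_boot))
    }

    k <- nrow(groups)
    long <- tibble(
      participant_id = rep(groups$participant_id, each = n_boot),
      coil = rep(groups$coil, each = n_boot),
      bin = rep(groups$bin, each = n_boot),
      replicate = rep(seq_len(n_boot), times = k),
      mean_a = unlist(groups$mean_a),
      mean_b = unlist(groups$mean_b)
    )
    wide <- long |>
      pivot_wider(names_from = "coil", values_from = c("mean_a", "mean_b"))
    for (col in c("mean_a_PA120", "mean_a_AP30", "mean_b_PA120", "mean_b_AP30")) {
      if (!col %in% names(wide)) wide[[col]] <- NA_real_
    }
    wide <- wide[complete.cases(wide[, c("mean_a_PA120", "mean_a_AP30",
                                         "mean_b_PA120", "mean_b_AP30")]), ]
    pa_ <- cbind(wide$mean_a_PA120, wide$mean_a_AP30)
    pb_ <- cbind(wide$mean_b_PA120, wide$mean_b_AP30)
    out <- tibble(
      participant_id = wide$participant_id,
      alignment = alignment,
      bin = factor(wide$bin, levels = levels),
      analysis_type = "simulated",
      replicate = wide$replicate,
      euclidean_d = euclidean_distance(pa_, pb_),
      cosine_d = cosine_distance(pa_, pb_),
      angle_rad = cosine_angle(pa_, pb_)
    )
    if (summarize) {
      out <- out |>
        group_by(.data$participant_id, .data$alignment, .data$bin,
                 .data$analysis_type) |>
        summarise(euclidean_d = mean(.data$euclidean_d),
                  cosine_d = mean(.data$cosine_d),
                  angle_rad = mean(.data$angle_rad),
                  .groups = "drop") |>
        mutate(replicate = NA_integer_) |>
        select("participant_id", "alignment", "bin", "analysis_type",
               "replicate", "euclidean_d", "cosine_d", "angle_rad")
    }
    out <- arrange(out, .data$participant_id, .data$bin, .data$replicate)
    class(out) <- c("ss_distances", class(out))
    out
  })
}

#' Participant-level test of real vs simulated distances
#'
#' The calibrated decision rule for whether the real (SST vs Go-only)
#' trajectory distances exceed the bootstrap null: for each metric, each
#' participant's distances are averaged across time bins within each
#' analysis type, and the two arms are compared with a paired t test across
#' participants. This respects the within-subject design exactly — the
#' factorial mixed model of [fit_mixed()] reports the full TIME x
#' ANALYSIS TYPE table, but its ANALYSIS TYPE test is anticonservative
#' whenever the participant x analysis-type variance component is estimated
#' at the zero boundary, which is common at n = 16.
#'
#' @param comparison Long table from [assemble_comparison_table()].
#' @return Tibble, one row per metric (x alignment if several):
#'   `estimate` (mean real minus simulated distance), `t`, `df`, `p.value`,
#'   `n_participants`.
#' @export
compare_real_simulated <- function(comparison) {
  stopifnot_cols(comparison, c("participant_id", "bin", "analysis_type",
                               "metric", "distance"), "`comparison`")
  has_align <- "alignment" %in% names(comparison)
  grouping <- if (has_align) c("alignment", "metric") else "metric"
  comparison |>
    group_by(across(dplyr::all_of(c(grouping, "participant_id",
                                    "analysis_type")))) |>
    summarise(d = mean(.data$distance), .groups = "drop") |>
    pivot_wider(names_from = "analysis_type", values_from = "d") |>
    group_by(across(dplyr::all_of(grouping))) |>
    summarise({
      ok <- is.finite(.data$real) & is.finite(.data$simulated)
      if (sum(ok) < 2) {
        abort("need at least 2 participants with both analysis types")
      }
      diffs <- .data$real[ok] - .data$simulated[ok]
      tt <- stats::t.test(diffs)
      tibble(estimate = mean(diffs), t = unname(tt$statistic),
             df = unname(tt$parameter), p.value = tt$p.value,
             n_participants = sum(ok))
    }, .groups = "drop")
}

#' Assemble the real-vs-simulated comparison table
#'
#' Stacks the real (SST vs Go-only) and simulated (bootstrap null) distance
#' series into the long format expected by [fit_mixed()]: one row per
#' observation, with columns `distance`, `metric` (`"euclidean"`,
#' `"cosine"`), `bin`, `analysis_type` and `participant_id`.
#'
#' @param real,simulated Distance tibbles from [distance_series()] and
#'   [bootstrap_simulated_trajectories()].
#' @param common_bins If `TRUE` (default), keep only time bins observed in
#'   both analysis types, so the TIME x ANALYSIS TYPE factorial has no empty
#'   cells.
#' @return Long comparison tibble.
#' @export
assemble_comparison_table <- function(real, simulated, common_bins = TRUE) {
  if (is.null(simulated) || nrow(simulated) == 0) {
    abort("`simulated` distance series is empty")
  }
  if (is.null(real) || nrow(real) == 0) abort("`real` distance series is empty")
  if (common_bins) {
    shared <- intersect(as.character(unique(real$bin)),
                        as.character(unique(simulated$bin)))
    real <- filter(real, as.character(.data$bin) %in% shared)
    simulated <- filter(simulated, as.character(.data$bin) %in% shared)
  }
  bind_rows(as_tibble(real), as_tibble(simulated)) |>
    pivot_longer(c("euclidean_d", "cosine_d"),
                 names_to = "metric", values_to = "distance") |>
    mutate(metric = sub("_d$", "", .data$metric)) |>
    select("participant_id", "alignment", "bin", "analysis_type",
           "replicate", "metric", "distance")
}
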