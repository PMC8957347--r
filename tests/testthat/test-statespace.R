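# Small helper: a binned table from explicit values for both coils.
binned_from <- function(values, bins = c("Cue", "50", "100"),
                        participants = "P01", task = "GoOnly") {
  grid <- tidyr::crossing(participant_id = participants, task = task,
                          coil = c("PA120", "AP30"), bin = bins)
  grid$mean_norm_mep <- values
  grid$n_trials <- 10L
  grid$alignment <- "cue_locked"
  grid[, c("participant_id", "task", "coil", "alignment", "bin",
           "mean_norm_mep", "n_trials")]
}

test_that("euclidean distance satisfies its definition and axioms", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1.2, 0.8), c(1.2, 0.8)), 0)

  withr::with_seed(11, {
    P <- matrix(runif(600, -5, 5), ncol = 2)
    Q <- matrix(runif(600, -5, 5), ncol = 2)
    R <- matrix(runif(600, -5, 5), ncol = 2)
  })
  d_pq <- euclidean_distance(P, Q)
  expect_true(all(d_pq >= 0)) # non-negativity
  expect_equal(d_pq, euclidean_distance(Q, P)) # symmetry
  expect_true(all(d_pq <= euclidean_distance(P, R) +
                    euclidean_distance(R, Q) + 1e-12)) # triangle
  expect_equal(euclidean_distance(P, P), rep(0, nrow(P))) # identity
})

test_that("cosine distance measures angle only, in [0, 2]", {
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1) # orthogonal
  expect_equal(cosine_distance(c(2, 2), c(5, 5)), 0) # collinear
  expect_equal(cosine_distance(c(1, 1), c(-1, -1)), 2) # antiparallel
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero vector")

  withr::with_seed(12, {
    P <- matrix(runif(400, 0.1, 5), ncol = 2)
    Q <- matrix(runif(400, 0.1, 5), ncol = 2)
    a <- runif(200, 0.1, 10)
    b <- runif(200, 0.1, 10)
  })
  d <- cosine_distance(P, Q)
  expect_true(all(d >= 0 & d <= 2))
  # positive-scale invariance: D(a p, b q) = D(p, q)
  expect_equal(cosine_distance(P * a, Q * b), d, tolerance = 1e-12)
  # auxiliary angle is consistent: d = 1 - cos(theta)
  expect_equal(1 - cos(cosine_angle(P, Q)), d, tolerance = 1e-12)
})

test_that("trajectories pair PA and AP series in canonical bin order", {
  b <- binned_from(rep(1, 6))
  tr <- build_trajectories(b)
  expect_equal(nrow(tr), 3)
  expect_equal(as.character(tr$bin), c("Cue", "50", "100"))
  expect_equal(tr$pa[tr$bin == "Cue"], 1)
  expect_equal(tr$ap[tr$bin == "Cue"], 1)

  # group trajectory of identical participants equals any participant's
  b2 <- binned_from(rep(c(2, 3), each = 6),
                    participants = c("P01", "P02"))
  g <- build_trajectories(b2, scope = "group")
  p1 <- build_trajectories(b2)
  expect_equal(g$pa, (p1$pa[1:3] + p1$pa[4:6]) / 2)

  # a missing coil x bin cell is an error naming the bin, unless dropped
  b3 <- binned_from(rep(1, 6))[-2, ]
  expect_error(build_trajectories(b3), "missing coil x bin")
  expect_equal(nrow(build_trajectories(b3, incomplete = "drop")), 2)
})

test_that("distance series match hand-computed values on a 3-bin toy table", {
  # trajectory A: (1,1), (2,1), (1,2); trajectory B: (1,1), (1,1), (4,2)
  traj <- tibble::tibble(
    participant_id = "P01",
    task = rep(c("SST", "GoOnly"), each = 3),
    alignment = "cue_locked",
    bin = factor(rep(c("Cue", "50", "100"), 2),
                 levels = bin_levels("cue_locked")),
    pa = c(1, 2, 1, 1, 1, 4),
    ap = c(1, 1, 2, 1, 1, 2)
  )
  d <- distance_series(traj)
  expect_equal(d$euclidean_d, c(0, 1, 3))
  expect_equal(d$cosine_d, c(0, 1 - 3 / sqrt(10), 1 - 8 / 10))
  expect_equal(d$analysis_type, rep("real", 3))

  # identical trajectories: all distances zero
  same <- traj
  same$pa <- rep(c(1, 2, 3), 2)
  same$ap <- rep(c(2, 1, 3), 2)
  d0 <- distance_series(same)
  expect_equal(d0$euclidean_d, rep(0, 3))
  expect_equal(d0$cosine_d, rep(0, 3))

  # pointwise doubling: cosine blind, euclidean not
  scaled <- traj
  scaled$pa <- c(1, 2, 3, 2, 4, 6)
  scaled$ap <- c(2, 1, 3, 4, 2, 6)
  ds <- distance_series(scaled)
  expect_equal(ds$cosine_d, rep(0, 3), tolerance = 1e-12)
  expect_true(all(ds$euclidean_d > 0))
})

test_that("bootstrap null is reproducible and degenerates correctly", {
  trials <- shared_trials()
  prepped <- suppressMessages(prepare_mep(trials))

  a <- bootstrap_simulated_trajectories(prepped, "cue_locked", n_boot = 20,
                                        seed = 5, missing_bins = "drop")
  b <- bootstrap_simulated_trajectories(prepped, "cue_locked", n_boot = 20,
                                        seed = 5, missing_bins = "drop")
  expect_identical(a, b)
  expect_true(all(a$analysis_type == "simulated"))
  expect_true(all(a$euclidean_d >= 0))
  expect_true(all(a$cosine_d >= 0 & a$cosine_d <= 2))

  # a noise-free flat generator gives all-equal pools: distances all zero
  flat <- simulate_dataset(2, seed = 9,
                           params = quiet_params(rise_gain = c(PA120 = 1, AP30 = 1)))
  fp <- suppressMessages(prepare_mep(flat))
  sim0 <- bootstrap_simulated_trajectories(fp, "cue_locked", n_boot = 10,
                                           seed = 2, missing_bins = "drop")
  expect_equal(max(sim0$euclidean_d), 0)
  expect_equal(max(sim0$cosine_d), 0)

  # empty pools are an error naming the bin under the strict contract
  thin <- prepped[!(prepped$tms_time_ms %in% 300 & prepped$trial_type == "go"), ]
  expect_error(
    bootstrap_simulated_trajectories(thin, "cue_locked", n_boot = 5),
    "empty bin pool"
  )
})

test_that("comparison table stacks both arms in long format with matched bins", {
  trials <- shared_trials()
  prepped <- suppressMessages(prepare_mep(trials))
  bc <- bin_cue_locked(prepped, min_trials = 5)
  tr <- build_trajectories(bc, incomplete = "drop")
  real <- distance_series(tr, strict = FALSE)
  sim <- bootstrap_simulated_trajectories(prepped, "cue_locked", n_boot = 15,
                                          seed = 3, summarize = TRUE,
                                          missing_bins = "drop", min_trials = 5)
  cmp <- assemble_comparison_table(real, sim)
  expect_setequal(unique(cmp$metric), c("euclidean", "cosine"))
  expect_setequal(unique(cmp$analysis_type), c("real", "simulated"))
  # replicate-averaged: one row per participant x bin x arm x metric
  shared_bins <- intersect(as.character(unique(real$bin)),
                           as.character(unique(sim$bin)))
  n_real <- nrow(dplyr::filter(real, as.character(bin) %in% shared_bins))
  n_sim <- nrow(dplyr::filter(sim, as.character(bin) %in% shared_bins))
  expect_equal(nrow(cmp), 2 * (n_real + n_sim))
  expect_error(assemble_comparison_table(real, real[0, ]), "empty")

  # full-replicate mode keeps one row per replicate
  sim_full <- bootstrap_simulated_trajectories(prepped, "cue_locked",
                                               n_boot = 4, seed = 3,
                                               summarize = FALSE,
                                               missing_bins = "drop",
                                               min_trials = 5)
  expect_equal(dplyr::n_distinct(sim_full$replicate), 4)
})

test_that("pair-mode null matches the real comparison's per-bin trial counts", {
  trials <- shared_trials()
  prepped <- suppressMessages(prepare_mep(trials))
  bc <- bin_cue_locked(prepped, min_trials = 5)
  tmpl <- dplyr::filter(bc, .data$task == "SST")
  # with a template of larger counts, simulated spread shrinks
  sim_small <- bootstrap_simulated_trajectories(
    prepped, "cue_locked", n_boot = 100, seed = 8, summarize = TRUE,
    missing_bins = "drop", min_trials = 5
  )
  tmpl_big <- dplyr::mutate(tmpl, n_trials = .data$n_trials * 20L)
  sim_big_n <- bootstrap_simulated_trajectories(
    prepped, "cue_locked", n_boot = 100, seed = 8, summarize = TRUE,
    missing_bins = "drop", min_trials = 5, n_template = tmpl_big
  )
  expect_lt(mean(sim_big_n$euclidean_d), mean(sim_small$euclidean_d))
})
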