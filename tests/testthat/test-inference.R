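# Factorial test table with known structure: 2 x 2 design, optional
# participant intercepts, Gaussian noise.
make_factorial <- function(n_per_cell = 10, n_participants = 8,
                           a_eff = 2, b_eff = 0, sd_participant = 0,
                           sd_noise = 1, seed = 1, positive_shift = 10) {
  withr::with_seed(seed, {
    d <- tidyr::crossing(
      participant_id = sprintf("P%02d", seq_len(n_participants)),
      A = c("a1", "a2"), B = c("b1", "b2"),
      rep = seq_len(n_per_cell)
    )
    u <- stats::setNames(rnorm(n_participants, 0, sd_participant),
                         sprintf("P%02d", seq_len(n_participants)))
    d$y <- positive_shift +
      a_eff * (d$A == "a2") + b_eff * (d$B == "b2") +
      u[d$participant_id] + rnorm(nrow(d), 0, sd_noise)
    d
  })
}

test_that("log-transform decision follows the residual-skewness rule", {
  sym <- make_factorial(seed = 2)
  ct <- check_and_transform(sym, "y", c("A", "B"))
  expect_equal(ct$transform, "none")
  expect_lt(abs(ct$skewness), 1)

  skewed <- sym
  withr::with_seed(3, {
    skewed$y <- exp(rnorm(nrow(skewed), 0, 1.2)) # lognormal response
  })
  ct2 <- check_and_transform(skewed, "y", c("A", "B"))
  expect_equal(ct2$transform, "log")
  expect_gt(ct2$skewness, 1)
  # post-transform residuals are far less skewed
  post <- check_and_transform(ct2$data, "y", c("A", "B"))
  expect_lt(abs(post$skewness), abs(ct2$skewness))

  withzero <- sym
  withzero$y[1] <- 0
  expect_error(
    check_and_transform(withzero, "y", c("A", "B"), transform = "log"),
    "strictly positive"
  )
})

test_that("zero-variance mixed fit reproduces the fixed-effects factorial fit", {
  d <- make_factorial(a_eff = 2, b_eff = -1, sd_participant = 0, seed = 4)
  # remove even the sampling noise between participant means, so the
  # random-intercept variance is exactly zero by construction
  d <- d |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(y = .data$y - mean(.data$y) + 10.35) |>
    dplyr::ungroup()
  fit <- suppressWarnings(fit_mixed(d, "y", c("A", "B"), transform = "none"))
  expect_true(fit$singular) # no participant variance to find

  ols <- lm(y ~ A * B, data = d,
            contrasts = list(A = stats::contr.sum, B = stats::contr.sum))
  # fixed-effect estimates agree to 4 significant figures
  expect_equal(unname(lme4::fixef(fit$model)), unname(coef(ols)),
               tolerance = 1e-4)
  # and the balanced-design F statistics match the classical ANOVA
  aov_tab <- anova(ols)
  mine <- tidy(fit)
  expect_equal(mine$statistic[mine$term == "A"], aov_tab["A", "F value"],
               tolerance = 1e-4)
  expect_equal(mine$statistic[mine$term == "B"], aov_tab["B", "F value"],
               tolerance = 1e-4)
  expect_equal(mine$statistic[mine$term == "A:B"], aov_tab["A:B", "F value"],
               tolerance = 1e-4)
  expect_equal(mine$df2[1], stats::df.residual(ols))
})

test_that("planted participant variance and effects are recovered", {
  d <- make_factorial(a_eff = 3, sd_participant = 2, sd_noise = 1,
                      n_participants = 16, seed = 5)
  fit <- fit_mixed(d, "y", c("A", "B"), transform = "none")
  expect_true(fit$converged)
  expect_false(fit$fallback)
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  sd_u <- vc$sdcor[vc$grp == "participant_id"]
  expect_gt(sd_u, 1)
  expect_lt(sd_u, 3.5)
  # the A effect is detected, the null B effect is not
  tt <- tidy(fit)
  expect_lt(tt$p.value[tt$term == "A"], 1e-6)
  expect_gt(tt$p.value[tt$term == "B"], 0.01)
  # glance reports the bookkeeping
  g <- glance(fit)
  expect_equal(g$nobs, nrow(d))
  expect_equal(g$n_groups, 16L)
  expect_equal(g$transform, "none")
})

test_that("term p-values are calibrated under permutation of the response", {
  d <- make_factorial(a_eff = 0, b_eff = 0, sd_participant = 0,
                      n_participants = 6, n_per_cell = 4, seed = 6)
  ps <- withr::with_seed(7, {
    vapply(1:60, function(i) {
      d$y <- sample(d$y)
      fit <- suppressWarnings(fit_mixed(d, "y", c("A", "B"),
                                        transform = "none"))
      tt <- tidy(fit)
      tt$p.value[tt$term == "A"]
    }, numeric(1))
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lte(sum(ps < 0.05), 8) # ~3 expected of 60
})

test_that("fit_mixed rejects degenerate inputs", {
  d <- make_factorial()
  expect_error(fit_mixed(d[d$participant_id == "P01", ], "y", c("A", "B")),
               "single-participant")
  d1 <- d
  d1$A <- "a1"
  expect_error(fit_mixed(d1, "y", c("A", "B")), "< 2 levels")
  expect_error(fit_mixed(d, "missing", c("A", "B")), "missing")
})

test_that("rise onset is the earliest timepoint significantly above the cue", {
  # planted world: proactive slowing delays the cue-locked rise in the SST
  trials <- simulate_dataset(10, seed = 17)
  prepped <- suppressMessages(prepare_mep(trials))
  bc <- bin_cue_locked(prepped)
  po <- posthoc_rise_onset(bc)
  onset <- stats::setNames(po$onset$onset_bin, po$onset$task)
  lv <- bin_levels("cue_locked")
  expect_false(anyNA(onset))
  expect_gt(match(onset["SST"], lv), match(onset["GoOnly"], lv))
  # contrasts table is complete and self-consistent
  expect_equal(nrow(po$contrasts), 2 * 6)
  expect_true(all(po$contrasts$p_adj >= 0 & po$contrasts$p_adj <= 1))
  sig <- po$contrasts[po$contrasts$significant, ]
  expect_true(all(sig$estimate > 0))

  # adjustment methods agree on the strong effects
  po_b <- posthoc_rise_onset(bc, adjust = "bonferroni")
  expect_equal(po_b$onset$onset_bin, po$onset$onset_bin)
})

test_that("a flat generator produces no rise onset", {
  flat <- simulate_dataset(8, seed = 23,
                           rise_gain = c(PA120 = 1, AP30 = 1))
  prepped <- suppressMessages(prepare_mep(flat))
  po <- posthoc_rise_onset(bin_cue_locked(prepped))
  expect_true(all(is.na(po$onset$onset_bin)))
})

test_that("single-participant rise-onset tables are rejected", {
  trials <- simulate_dataset(2, seed = 3)
  prepped <- suppressMessages(prepare_mep(trials))
  bc <- bin_cue_locked(prepped)
  one <- bc[bc$participant_id == bc$participant_id[1], ]
  expect_error(posthoc_rise_onset(one), "single-participant")
})
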