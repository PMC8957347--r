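---
title: "Models and methods: simulating and analysing proactive inhibition with directional TMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analysing proactive inhibition with directional TMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stopstate` packages two things: a synthetic-data generator that emulates a
stop-signal/Go-only experiment probed with directional TMS, and the
analysis chain that turns trial tables into behavioral measures,
excitability time courses, state-space trajectories and statistical
inferences. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and what a green test suite does and
does not establish.

## 1. The behavioral model

### Horse race with a tracked stop-signal delay

Each stop trial races two independent processes: the go process, whose
finishing time is the trial's would-be reaction time, and a stop process
that finishes `ssrt_true_ms` after the stop signal. The response escapes
inhibition iff

```
RT_go <= SSD + SSRT
```

with ties (measure zero under continuous RTs) resolved as responses so the
rule is deterministic. The stop-signal delay follows a one-up-one-down
staircase: +50 ms after a successful stop, −50 ms after a failed one,
starting at 150 ms and clipped to [100, 250] ms. We clip rather than wrap
or terminate at the bounds: the tracker stays well-defined and the SSD
always remains on the designed four-value grid. Because the staircase is a
random walk whose drift reverses at the 50% point of
`P(RT_go <= SSD + SSRT)`, the long-run proportion of successful stops
converges to ~0.5 for any continuous go-RT distribution — the property the
acceptance suite verifies over 2,000 stop trials per simulated participant.

### Go finishing times

Go RTs are ex-Gaussian:

```
RT_go = Normal(mu + rde_shift * [task = SST] + coil_penalty, sigma) + Exp(tau)
```

Defaults, chosen once from the simple-RT literature and from the published
behavioral table of this protocol, then frozen: `mu = 250`, `sigma = 25`,
`tau = 40` ms, so the Go-only mean is 290 ms; `rde_shift = 100` ms of
proactive slowing puts the SST mean at 390 ms; `ssrt_true = 220` ms; and an
AP30 penalty of 23 ms (the midpoint of the two task-specific AP−PA RT
differences printed for the real data, whose text and table disagree about
which task carries the larger difference). Between-participant
heterogeneity is Gaussian around these means (SDs 25, 20, 25 ms and 0.1 mV,
matching the printed between-participant SDs).

A useful pre-registration check run before any package test: under these
defaults the implied stationary mean SSD is ~166 ms (printed value:
167.05), the group p(inhibit) is 50.0%, and the mean-method SSRT carries a
+3 ms bias (see below), all before any parameter was fitted to anything.

### Mean-method SSRT and its bias

`SSRT = mean go RT − mean SSD` is exact arithmetic (the acceptance anchor
224.50 = 391.55 − 167.05 must hold to machine precision). As an *estimator*
of the true stop latency it carries a known bias: the staircase converges
on the *median*-based 50% point while the formula uses the *mean* go RT, so
the bias is approximately `mean(RT_go) − median(RT_go)` — about +7 ms for
the default ex-Gaussian, partly offset by the staircase's start-at-150
transient. With constant per-participant stop latencies the group-mean
estimate recovers truth within ±10 ms at the published trial counts (16
participants, 35 stop trials), which the acceptance suite checks against
the planted values. Heavier right tails (larger `tau`) would enlarge this
bias; that is a property of the mean method itself, not of the
implementation.

### Omissions

Go trials with RT > 1,000 ms (strict inequality) or no response at all are
omission errors, excluded from all RT means. The generator plants lapses at
rate 0.4%, matching the printed omission percentages. Mean SSD is averaged
over all presented stop trials — the tracking convention the mean method
assumes; `summarize_behavior(drop_post_omission_ssd = TRUE)` instead drops
stop trials immediately following an omission, since the source leaves this
unstated. The default never changes p(inhibit) or stop-respond RT, only the
SSD mean.

## 2. The excitability model

MEP amplitude on a trial probed at time `t` is

```
MEP = baseline_mep[coil] * g(rt − t) * LogNormal(median = 1, cv)
```

`g` is a linear-to-plateau ramp on the *lead time* before the response:
1 until `rise_onset_before_rt_ms` (default 150 ms, the published
"sharp rise" latency), rising linearly to the per-coil plateau `rise_gain`
at movement onset (defaults PA120 = 3.0, AP30 = 2.5 — the rise weights the
two inputs differently, which is what gives cosine distances something to
measure). A sigmoid would also be defensible; the source specifies only "a
rise", and the piecewise-linear form makes the expected bin means available
in closed form for tests. Baseline/catch trials (TMS 1,000 ms after
fixation, no go cue) and non-responding trials stay at `g = 1`. Noise is
lognormal with unit median (CV default 0.4, a typical MEP amplitude CV), so
baseline normalization is exact in expectation: the lognormal mean factor
cancels in the ratio, and the expected normalized amplitude at movement
onset is the plateau gain itself.

Cue-locked structure is *emergent*: because the ramp is yoked to the
response, a 100 ms proactive slowing of RTs delays the cue-locked rise by
100 ms while leaving the response-locked profile identical — exactly the
dissociation reported for the real data, and the basis of the
planted-effect acceptance check (a 50 ms planted shift must move the
significant rise one 50-ms bin later in the SST, with no response-locked
TASK effect).

## 3. Preprocessing and binning

* **TMS-in-burst exclusion**: a MEP is a clean probe only if the pulse
  precedes voluntary EMG. The generator has no traces, so burst onset is
  `rt − motor_time_ms` (default 50 ms electromechanical delay); for real
  traces `detect_burst_onset()` provides a threshold detector (rectified
  signal > k·baseline SD for ≥ 5 ms, k = 3) as a documented stand-in for
  the source's visual inspection, which cannot be codified.
* **Cue-locked bins** are the seven scheduled timepoints. **Response-locked
  bins** are lead times in 50-ms windows, lower-inclusive/upper-exclusive
  (the source lists bins without boundary rules); leads outside [50, 350)
  are `out_of_range` — below 50 ms TMS sits at or inside the burst given
  the electromechanical delay. This rule lives inside the response-locked
  path only: a slow trial probed at the cue is a perfectly good cue-locked
  observation.
* **Late-bin sparsity**: on fast trials the burst exclusion removes the
  250/300 ms cue-locked probes, so those bins survive only on slow trials
  and can be empty for fast participants. The excitability models and
  rise-onset post hocs use every surviving bin (`min_trials = 1`); the
  distance analysis requires `min_bin_trials = 5` per cell (the usual
  minimum MEP count for a stable conditional mean) because a bootstrap of a
  near-empty pool cannot represent sampling noise at all.
* Participant x coil cells without an elicitable baseline are dropped for
  that coil with a logged reason, mirroring the real dataset's 16 PA120 /
  13 AP30 participants.

## 4. State space, distances, and the bootstrap null

Trajectories are ordered (PA120, AP30) points over the bin sequence,
participant-scope for inference (the participant random intercept implies
participant-level observations) and group-scope for figures. Euclidean
distance measures magnitude differences; cosine distance
`1 − cos θ` (with the angle exposed separately) measures the relative
PA/AP weighting and is invariant to positive rescaling of either point.

The null asks: how large would those distances be if proactive inhibition
did nothing? Simulated Go-only trajectories are drawn by resampling trials
with replacement within participant x coil x bin, preserving each bin's
trial count, and distances involving them are computed per bin. Three
numerical choices matter, all fixed a priori and verified by a 200-run
Monte-Carlo calibration in the acceptance suite:

1. **Pairs, not originals.** The real comparison involves *two* noisy
   trajectories (SST and Go-only), so the default null measures the
   distance between two independent resamples (`compare = "pair"`).
   Measuring each resample against the observed Go-only trajectory
   (`compare = "original"`, the literal description of the source method)
   yields a null with half the sampling variance and an anticonservative
   test; it is retained as an option.
2. **Deviation scaling.** Resampled-mean deviations are scaled by
   `sqrt(n/(n−1)) / c4(n)`: plain with-replacement resampling
   under-disperses the mean by `(n−1)/n`, and the implied SD estimate is
   itself biased low by the Gaussian constant `c4(n)`. Distances are linear
   in the sampling SD, so without both corrections the simulated arm runs
   systematically below the real one under the null. The residual bias from
   the lognormal noise's excess kurtosis is not corrected and is part of
   what the calibration run measures.
3. **Trial-count templates.** The real comparison pits SST bin means (SST
   per-bin counts) against Go-only means; with proactive slowing those
   counts differ systematically, especially response-locked. The pipeline
   therefore resamples the second trajectory of each pair at the SST arm's
   per-bin counts (`n_template`), still drawing from Go-only pools — the
   null hypothesis concerns the law, not the design.

Replicate distances are averaged per participant x bin by default
(`summarize = TRUE`) so the two arms enter the model balanced; the
full-replicate mode is available.

### Testing the real-vs-simulated difference

Two results are reported. The factorial mixed model
(`distance ~ bin * analysis_type + (1 | participant)`) reproduces the
published model's shape and its TIME effects. For the ANALYSIS TYPE
decision itself the package uses `compare_real_simulated()`: each
participant's distances are averaged over bins within each arm and the
arms compared by a paired t test. The reason is empirical and structural: a
participant's real distance series carries trajectory-level noise shared
across bins — a participant x analysis-type random component that the
random-intercept-only model must estimate from 16 groups and usually pins
at the zero boundary, collapsing the standard error (observed type-I error
~17% at the nominal 5%). The paired participant-level contrast respects the
within-subject design exactly and calibrates to ~2.5% in the same
simulations. This is also the spirit of the source's own paired post hoc
tests.

## 5. Mixed models and post hocs

`fit_mixed()` builds `response ~ f1 * f2 * ... + (1 | participant)` with
sum-to-zero contrasts and REML, and tests each fixed term with a Type-III
Wald F. Denominator degrees of freedom are fixed at `n − rank(X)` (the
residual convention) so runs are reproducible; Satterthwaite or
Kenward-Roger approximations would need packages not available here, and
the choice is deliberately simple and documented rather than silently
approximate. If the mixed fit fails outright the model falls back to the
fixed-effects factorial (flagged in the result); singular fits are flagged
but kept. With zero group variance the mixed fit collapses onto ordinary
least squares — the acceptance suite requires agreement with the classical
ANOVA to four significant figures.

Normality is assessed by an automated surrogate for QQ inspection: the log
transform is applied iff the residual skewness of a provisional fit exceeds
1.0 in absolute value and the response is strictly positive. The threshold
is configurable; the decision is logged in the result and the manifest.

The excitability **rise onset** is the earliest cue-locked timepoint whose
CSE significantly exceeds the cue level, per task: paired contrasts of each
timepoint against the cue across participant x coil units, family-corrected
over the six contrasts with the multivariate-t distribution at the
estimated contrast correlation (the exact analogue of a Tukey-style family
adjustment for a vs-control family; studentized-range and Bonferroni
fallbacks are provided). The quasi-Monte-Carlo evaluation of the
multivariate-t integral runs under a fixed internal seed with tolerance
1e-6, so p-values are reproducible to well below any decision threshold.

## 6. What the synthetic world does and does not establish

The generator reproduces the *structure* the analysis assumes: race-model
stopping held at 50% by the staircase, ~100 ms proactive slowing, an
execution-locked excitability rise with coil-specific weighting, realistic
MEP noise, omission lapses, and the published trial counts and timing. It
does not emulate: fatigue or learning across blocks, trial-history effects
(post-stop slowing), genuine EMG waveforms (only their bookkeeping),
between-coil differences in baseline stimulator intensity, or
visual-inspection artifact rejection. Green tests therefore establish that
the pipeline measures what the model plants at realistic noise levels — not
that the published effect sizes are correct, and the published
real-data F statistics are out of reach by construction (the raw
distributions were never deposited).

Degenerate inputs are first-class: zero-variance RTs, flat excitability,
all-equal bin pools, single participants, missing baselines and empty bins
all have defined behavior (exact values, errors naming the offending cell,
or documented drops), and the exclusion accounting
(`rows_in = retained + Σ excluded-by-reason`) is checked at pipeline level.

## 7. Reproducibility

Every random stage — scheduling, RT and MEP draws, lapses, bootstrap
resampling — descends from one seed; identical configurations produce
byte-identical tables, and the pipeline manifest records the seed, package
version, thresholds, transform decisions and exclusion counts alongside
every exported CSV.
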