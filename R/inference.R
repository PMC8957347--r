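#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Residual-normality check and log-transform decision
#'
#' Automated surrogate for QQ-plot inspection: the response is
#' log-transformed iff the residual skewness of a provisional fixed-effects
#' fit (the fixed factors plus the grouping factor) exceeds
#' `skew_threshold` in absolute value and the response is strictly positive.
#'
#' @param data Long-format tibble.
#' @param response Response column name.
#' @param fixed Character vector of fixed-factor column names.
#' @param random Grouping column name (participant).
#' @param skew_threshold Absolute skewness above which the log is applied.
#' @param transform `"auto"` (decide by the rule), `"none"` or `"log"`
#'   (forced; errors if the response is not strictly positive).
#' @return List with `data` (response transformed in place when decided),
#'   `transform` (`"none"`/`"log"`), and `skewness` (pre-transform residual
#'   skewness).
#' @export
check_and_transform <- function(data, response, fixed,
                                random = "participant_id",
                                skew_threshold = 1,
                                transform = c("auto", "none", "log")) {
  transform <- arg_match(transform)
  stopifnot_cols(data, c(response, fixed, random), "`data`")
  y <- data[[response]]
  if (!is.numeric(y)) abort(sprintf("`%s` must be numeric", response))

  fml <- as.formula(paste(
    response, "~",
    paste(c(sprintf("`%s`", fixed), sprintf("`%s`", random)), collapse = " + ")
  ))
  res <- resid(lm(fml, data = data))
  skew <- skewness(res)

  decided <- switch(transform,
    none = "none",
    log = "log",
    auto = if (is.finite(skew) && abs(skew) > skew_threshold && all(y > 0)) "log" else "none"
  )
  if (decided == "log") {
    if (any(y <= 0)) {
      abort(sprintf("log transform requires a strictly positive `%s`", response))
    }
    data[[response]] <- log(y)
  }
  list(data = data, transform = decided, skewness = skew)
}

#' Fit the factorial linear mixed model
#'
#' Fits `response ~ fixed factors with all interactions + (1 | participant)`
#' with `lme4::lmer`, after the residual-normality/log-transform check of
#' [check_and_transform()]. Each fixed term is tested with a Type-III Wald
#' F statistic (sum-to-zero contrasts; denominator degrees of freedom fixed
#' at `n_obs - rank(X)`, the residual convention, so runs are reproducible).
#' If the mixed fit fails the model falls back to an ordinary fixed-effects
#' fit without the random intercept, and the result is flagged.
#'
#' @inheritParams check_and_transform
#' @param data Long-format tibble; rows with missing values in the used
#'   columns are dropped.
#' @return An object of class `ss_lmm`: list with `model`, `terms` (tibble
#'   of per-term F tests), `transform`, `skewness`, `singular`, `converged`,
#'   `fallback`, `formula`. Use [tidy()] / [glance()] to extract results.
#' @export
#' @examples
#' trials <- simulate_dataset(4, seed = 1) |> prepare_mep()
#' binned <- bin_cue_locked(trials)
#' fit <- fit_mixed(binned, "mean_norm_mep", c("coil", "task", "bin"))
#' tidy(fit)
fit_mixed <- function(data, response, fixed, random = "participant_id",
                      transform = c("auto", "none", "log"),
                      skew_threshold = 1) {
  stopifnot_cols(data, c(response, fixed, random), "`data`")
  data <- as_tibble(data)
  used <- c(response, fixed, random)
  data <- data[complete.cases(data[, used]), used]
  for (f in c(fixed, random)) data[[f]] <- factor(data[[f]])
  if (nlevels(data[[random]]) < 2) {
    abort("grouping column must have >= 2 levels (single-participant table)")
  }
  dropped <- fixed[vapply(fixed, function(f) nlevels(data[[f]]) < 2, logical(1))]
  if (length(dropped) > 0) {
    abort(sprintf("fixed factor(s) with < 2 levels: %s",
                  paste(dropped, collapse = ", ")))
  }

  ct <- check_and_transform(data, response, fixed, random,
                            skew_threshold = skew_threshold,
                            transform = transform)
  data <- ct$data

  contrasts <- setNames(rep(list(contr.sum), length(fixed)), fixed)
  fml <- as.formula(paste(
    response, "~", paste(sprintf("`%s`", fixed), collapse = " * "),
    "+ (1 |", random, ")"
  ))

  converged <- TRUE
  singular <- FALSE
  fallback <- FALSE
  model <- withCallingHandlers(
    tryCatch(
      lme4::lmer(fml, data = data, REML = TRUE,
                 contrasts = contrasts,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) {
        warn(sprintf("mixed fit failed (%s); falling back to a fixed-effects fit without the random intercept",
                     conditionMessage(e)))
        NULL
      }
    ),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  if (is.null(model)) {
    fallback <- TRUE
    converged <- TRUE
    fml_lm <- as.formula(paste(
      response, "~", paste(sprintf("`%s`", fixed), collapse = " * ")
    ))
    model <- lm(fml_lm, data = data, contrasts = contrasts)
  } else {
    singular <- lme4::isSingular(model)
  }

  terms_tbl <- wald_term_tests(model)
  structure(
    list(model = model, terms = terms_tbl, transform = ct$transform,
         skewness = ct$skewness, singular = singular, converged = converged,
         fallback = fallback, formula = fml, response = response,
         fixed = fixed, random = random),
    class = "ss_lmm"
  )
}

# Type-III Wald F tests on the fixed terms of an lmerMod or lm fit.
wald_term_tests <- function(model) {
  X <- model.matrix(model)
  asg <- attr(X, "assign")
  labels <- attr(terms(model), "term.labels")
  if (inherits(model, "merMod")) {
    # keep only fixed-effect term labels (random terms carry a "|")
    labels <- labels[!grepl("\\|", labels)]
    beta <- lme4::fixef(model)
  } else {
    beta <- coef(model)
  }
  beta <- beta[!is.na(beta)]
  # rank-deficient fits drop columns: align assign with estimated coefficients
  keep <- colnames(X) %in% names(beta)
  asg <- asg[keep]
  V <- as.matrix(vcov(model))
  n <- nrow(X)
  df2 <- n - qr(X)$rank
  rows <- map(seq_along(labels), function(j) {
    idx <- which(asg == j)
    b <- beta[idx]
    Fv <- drop(t(b) %*% solve(V[idx, idx, drop = FALSE], b)) / length(idx)
    tibble(term = gsub("`", "", labels[j]),
           statistic = Fv, df1 = length(idx), df2 = df2,
           p.value = pf(Fv, length(idx), df2, lower.tail = FALSE))
  })
  list_rbind(rows)
}

#' @export
print.ss_lmm <- function(x, ...) {
  cat(sprintf("<ss_lmm> %s\n", deparse(x$formula)))
  cat(sprintf("  transform: %s (residual skewness %.2f)%s%s\n",
              x$transform, x$skewness,
              if (x$singular) "; singular random effect" else "",
              if (x$fallback) "; FIXED-EFFECTS FALLBACK" else ""))
  print(as.data.frame(x$terms), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @rdname fit_mixed
#' @param x An `ss_lmm` object.
#' @param ... Unused.
#' @export
tidy.ss_lmm <- function(x, ...) {
  x$terms
}

#' @rdname fit_mixed
#' @export
glance.ss_lmm <- function(x, ...) {
  m <- x$model
  mixed <- inherits(m, "merMod")
  tibble(
    nobs = if (mixed) stats::nobs(m) else length(resid(m)),
    n_groups = if (mixed) lme4::ngrps(m)[[1]] else NA_integer_,
    sigma = stats::sigma(m),
    transform = x$transform,
    skewness = x$skewness,
    singular = x$singular,
    converged = x$converged,
    fallback = x$fallback
  )
}

# Family-wise adjusted p-values for paired contrasts given the raw paired
# t statistics and the contrast correlation matrix.
adjust_family <- function(t_stats, df, R, n_means,
                          method = c("mvt", "tukey", "bonferroni")) {
  method <- arg_match(method)
  k <- length(t_stats)
  switch(method,
    mvt = vapply(abs(t_stats), function(q) {
      p <- tryCatch(
        withr::with_seed(1L, {
          1 - mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k),
                            df = as.integer(df), corr = R, type = "shifted",
                            algorithm = mvtnorm::GenzBretz(abseps = 1e-6))
        }),
        error = function(e) NA_real_
      )
      if (is.na(p)) min(1, k * 2 * pt(q, df, lower.tail = FALSE)) else max(0, min(1, p))
    }, numeric(1)),
    tukey = ptukey(abs(t_stats) * sqrt(2), nmeans = n_means, df = df,
                   lower.tail = FALSE),
    bonferroni = pmin(1, k * 2 * pt(abs(t_stats), df, lower.tail = FALSE))
  )
}

#' Rise onset of corticospinal excitability
#'
#' Indexes the main rise in excitability per task as the earliest cue-locked
#' timepoint at which CSE becomes significantly greater than CSE at the go
#' cue. Within each task, every post-cue timepoint is compared with the cue
#' by a paired contrast across participant x coil units, with a family-wise
#' correction over the six contrasts: `"mvt"` (default) uses the
#' multivariate-t distribution at the estimated contrast correlation,
#' `"tukey"` the studentized range, `"bonferroni"` the Bonferroni bound.
#'
#' @param binned Cue-locked binned excitability (see [bin_cue_locked()]).
#' @param alpha Family-wise significance level.
#' @param adjust Correction method.
#' @return An `ss_posthoc` list: `onset` (tibble of task and earliest
#'   significant bin, `NA` when no timepoint clears the cue level) and
#'   `contrasts` (per task x timepoint estimates, t, adjusted p).
#' @export
posthoc_rise_onset <- function(binned, alpha = 0.05,
                               adjust = c("mvt", "tukey", "bonferroni")) {
  adjust <- arg_match(adjust)
  stopifnot_cols(binned, c("participant_id", "task", "coil", "alignment",
                           "bin", "mean_norm_mep"), "`binned`")
  if (!all(binned$alignment == "cue_locked")) {
    abort("`binned` must be cue-locked (the onset is defined vs the cue)")
  }
  if (n_distinct(binned$participant_id) < 2) {
    abort("single-participant table: no random-effect variance estimable")
  }
  levels <- bin_levels("cue_locked")
  tasks <- unique(as.character(binned$task))

  all_contrasts <- map(tasks, function(tk) {
    wide <- binned |>
      filter(.data$task == tk) |>
      mutate(unit = paste(.data$participant_id, .data$coil, sep = ":"),
             bin = factor(as.character(.data$bin), levels = levels)) |>
      select("unit", "bin", "mean_norm_mep") |>
      pivot_wider(names_from = "bin", values_from = "mean_norm_mep")
    miss <- setdiff(levels, names(wide))
    if (length(miss) > 0) {
      abort(sprintf("task %s is missing bin(s): %s", tk,
                    paste(miss, collapse = ", ")))
    }
    wide <- wide[complete.cases(wide), ]
    n_units <- nrow(wide)
    if (n_units < 3) abort(sprintf("task %s has too few complete units", tk))
    D <- as.matrix(wide[, levels[-1]]) - wide[[levels[1]]]
    est <- colMeans(D)
    se <- apply(D, 2, sd) / sqrt(n_units)
    t_stats <- est / se
    df <- n_units - 1
    R <- suppressWarnings(stats::cor(D))
    if (anyNA(R)) R <- diag(ncol(D))
    p_adj <- adjust_family(t_stats, df, R, n_means = length(levels),
                           method = adjust)
    tibble(task = tk, bin = factor(levels[-1], levels = levels[-1]),
           estimate = est, t = t_stats, df = df, p_adj = p_adj,
           significant = p_adj < alpha & est > 0)
  })
  contrasts <- list_rbind(all_contrasts)

  onset <- contrasts |>
    group_by(.data$task) |>
    summarise(
      onset_bin = if (any(.data$significant)) {
        as.character(.data$bin[which(.data$significant)[1]])
      } else {
        NA_character_
      },
      .groups = "drop"
    )
  structure(list(onset = onset, contrasts = contrasts, alpha = alpha,
                 adjust = adjust),
            class = "ss_posthoc")
}

#' @export
print.ss_posthoc <- function(x, ...) {
  cat(sprintf("<ss_posthoc> rise onset vs cue (%s-adjusted, alpha = %g)\n",
              x$adjust, x$alpha))
  print(as.data.frame(x$onset), row.names = FALSE)
  invisible(x)
}
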