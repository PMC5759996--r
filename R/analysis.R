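#' Per-participant accuracy by phase
#'
#' One row per participant and phase, with timed-out trials counted as
#' incorrect (they are part of the denominator).
#'
#' @param dataset A trial-level dataset with `participant_id`, `group`,
#'   `phase`, `correct`.
#' @return A tibble with `participant_id`, `group`, `phase`, `n_trials`,
#'   `n_correct`, `proportion_correct`.
#' @export
#' @examples
#' ds <- simulate_experiment(experiment_config(n_per_group = 3, seed = 7))
#' summarize_accuracy(ds)
summarize_accuracy <- function(dataset) {
  stopifnot(is.data.frame(dataset))
  out <- dplyr::summarise(
    dplyr::group_by(
      tibble::as_tibble(dataset),
      .data$participant_id, .data$group, .data$phase
    ),
    n_trials = dplyr::n(),
    n_correct = sum(.data$correct),
    proportion_correct = mean(.data$correct),
    .groups = "drop"
  )
  out$phase <- factor(out$phase, levels = PHASES)
  dplyr::arrange(out, .data$participant_id, .data$phase)
}

#' One-sample t-tests of accuracy against chance
#'
#' Tests, separately for each group (and phase, when a `phase` column is
#' present), whether mean accuracy differs from chance-level responding.
#' A group whose accuracies have zero variance is flagged degenerate: the
#' t statistic is 0 (p = 1) when its mean equals chance and signed-infinite
#' otherwise.
#'
#' @param accuracy A data frame with columns `group` and
#'   `proportion_correct` (and optionally `phase`), e.g. from
#'   [summarize_accuracy()].
#' @param chance Chance-level proportion correct for the two-choice task.
#' @return A tibble with one row per group (x phase): `n`, `mean`,
#'   `t`, `df`, `p`, `degenerate`.
#' @export
chance_test <- function(accuracy, chance = 0.5) {
  stopifnot(is.data.frame(accuracy))
  grp_cols <- intersect(c("group", "phase"), names(accuracy))
  one <- function(d, key) {
    v <- d$proportion_correct
    if (length(v) < 2) abort("need >= 2 participants per group")
    if (sd(v) == 0) {
      delta <- mean(v) - chance
      return(tibble::tibble(
        n = length(v), mean = mean(v),
        t = if (delta == 0) 0 else sign(delta) * Inf,
        df = length(v) - 1,
        p = if (delta == 0) 1 else 0,
        degenerate = TRUE
      ))
    }
    tt <- stats::t.test(v, mu = chance)
    tibble::tibble(
      n = length(v), mean = mean(v),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, degenerate = FALSE
    )
  }
  out <- dplyr::group_modify(
    dplyr::group_by(tibble::as_tibble(accuracy), dplyr::across(dplyr::all_of(grp_cols))),
    one
  )
  dplyr::ungroup(out)
}

#' One-way ANCOVA with covariate-adjusted group means
#'
#' Fits the standard one-factor, one-covariate analysis of covariance with
#' the sequential (covariate-first) decomposition: the group effect is the
#' F-ratio comparing the covariate-only linear model against the
#' covariate-plus-group model. Covariate-adjusted group means are
#' `ybar_g - b_w * (xbar_g - xbar)` where `b_w` is the pooled within-group
#' slope, i.e. each group's mean outcome moved along the common regression
#' line to the grand covariate mean. The effect size is
#' `eta^2 = SS_group / SS_total`.
#'
#' @param data A data frame holding the outcome, covariate and group
#'   columns.
#' @param outcome,covariate,group Column names (strings) of the outcome,
#'   baseline covariate, and grouping factor.
#' @return An object of class `ancova_fit` with per-group raw and adjusted
#'   means, `b_w`, the group F test (`statistic`, `df1`, `df2`,
#'   `p_value`), and `eta_sq`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
#' @examples
#' d <- data.frame(
#'   g = rep(c("g1", "g2"), each = 2),
#'   x = c(1, 2, 3, 4), y = c(2, 4, 5, 7)
#' )
#' ancova_adjusted_means(d, outcome = "y", covariate = "x", group = "g")
ancova_adjusted_means <- function(data, outcome, covariate, group) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(outcome, covariate, group), names(data))
  if (length(miss) > 0) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  y <- data[[outcome]]
  x <- data[[covariate]]
  g <- factor(data[[group]])
  ok <- stats::complete.cases(y, x, g)
  y <- y[ok]; x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("need at least 2 participants per group")
  ss_within_x <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  if (ss_within_x <= .Machine$double.eps * sum(x^2)) {
    abort("zero within-group covariate variance: pooled slope inestimable")
  }

  fit_cov <- lm(y ~ x)
  fit_full <- lm(y ~ x + g)
  cmp <- anova(fit_cov, fit_full)
  b_w <- unname(coef(fit_full)["x"])

  xbar_g <- as.vector(tapply(x, g, mean))
  ybar_g <- as.vector(tapply(y, g, mean))
  adjusted <- ybar_g - b_w * (xbar_g - mean(x))

  ss_group <- cmp$`Sum of Sq`[2]
  ss_total <- sum((y - mean(y))^2)

  structure(
    list(
      groups = levels(g),
      n = as.integer(table(g)),
      raw_means = ybar_g,
      covariate_means = xbar_g,
      adjusted_means = adjusted,
      b_w = b_w,
      statistic = cmp$F[2],
      df1 = cmp$Df[2],
      df2 = cmp$Res.Df[2],
      p_value = cmp$`Pr(>F)`[2],
      eta_sq = ss_group / ss_total,
      outcome = outcome, covariate = covariate, group = group
    ),
    class = "ancova_fit"
  )
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf(
    "<ancova_fit> %s ~ %s + %s\nGroup effect: F(%d, %d) = %.3f, p = %.4g, eta^2 = %.3f, b_w = %.4f\n",
    x$outcome, x$covariate, x$group, x$df1, x$df2, x$statistic, x$p_value, x$eta_sq, x$b_w
  ))
  print(tidy.ancova_fit(x))
  invisible(x)
}

#' Per-group summary of an ANCOVA fit
#'
#' @param x An `ancova_fit`.
#' @param ... Unused.
#' @return A tibble with one row per group: `group`, `n`, `raw_mean`,
#'   `covariate_mean`, `adjusted_mean`.
#' @export
tidy.ancova_fit <- function(x, ...) {
  tibble::tibble(
    group = x$groups, n = x$n,
    raw_mean = x$raw_means,
    covariate_mean = x$covariate_means,
    adjusted_mean = x$adjusted_means
  )
}

#' One-row summary of an ANCOVA fit
#'
#' @param x An `ancova_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `b_w`, `statistic`, `df1`, `df2`, `p_value`,
#'   `eta_sq`.
#' @export
glance.ancova_fit <- function(x, ...) {
  tibble::tibble(
    b_w = x$b_w, statistic = x$statistic, df1 = x$df1, df2 = x$df2,
    p_value = x$p_value, eta_sq = x$eta_sq
  )
}

#' ANCOVA of a test phase's accuracy with test-1 accuracy as covariate
#'
#' Convenience wrapper reproducing the study's covariate-adjusted group
#' comparison on simulated data: per-participant accuracy in `phase` is the
#' outcome, accuracy in test 1 the baseline covariate, and delay group the
#' factor.
#'
#' @param dataset An `experiment_dataset` (or its [summarize_accuracy()]
#'   output).
#' @param phase Outcome phase, e.g. `"test3"`.
#' @param covariate_phase Baseline phase, by default `"test1"`.
#' @return An `ancova_fit`.
#' @export
ancova_by_phase <- function(dataset, phase, covariate_phase = "test1") {
  acc <- if (all(c("proportion_correct", "phase") %in% names(dataset))) {
    tibble::as_tibble(dataset)
  } else {
    summarize_accuracy(dataset)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(acc, "participant_id", "group", "phase", "proportion_correct"),
    names_from = "phase", values_from = "proportion_correct"
  )
  for (ph in c(phase, covariate_phase)) {
    if (!ph %in% names(wide)) abort(paste0("phase not in dataset: ", ph))
  }
  ancova_adjusted_means(wide, outcome = phase, covariate = covariate_phase,
                        group = "group")
}

#' Shifts in GLC-strategy prevalence across the tests
#'
#' Tabulates, per group, the proportion of participants classified as using
#' the general linear classifier at each categorization test and the changes
#' from test 1 — the descriptive surface for asking whether integrative
#' strategy use grows more after sleep-filled delays.
#'
#' @param x An `experiment_dataset`, or a precomputed
#'   [classification_table()].
#' @param options A [db_fit_options()], used when `x` is a dataset.
#' @return A tibble with one row per group: `glc_test1`, `glc_test2`,
#'   `glc_test3`, `delta_t2_t1`, `delta_t3_t1`.
#' @export
strategy_shift_summary <- function(x, options = db_fit_options()) {
  tab <- if (is.data.frame(x) && all(c("family", "proportion") %in% names(x))) {
    x
  } else {
    classification_table(x, phases = c("test1", "test2", "test3"), options = options)
  }
  glc <- dplyr::filter(tab, .data$family == "glc",
                       .data$phase %in% c("test1", "test2", "test3"))
  wide <- tidyr::pivot_wider(
    dplyr::select(glc, "group", "phase", "proportion"),
    names_from = "phase", values_from = "proportion", names_prefix = "glc_"
  )
  dplyr::mutate(wide,
    delta_t2_t1 = .data$glc_test2 - .data$glc_test1,
    delta_t3_t1 = .data$glc_test3 - .data$glc_test1
  )
}
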