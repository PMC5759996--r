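#' Strategy-recovery confusion matrix
#'
#' Simulates observers of known strategy family, classifies each with
#' [classify_strategy()], and tabulates generated-versus-classified
#' proportions. Generating observers use canonical task-appropriate
#' parameters: criteria at level 50 (both 1D dimensions, alternating;
#' likewise the conjunction criteria) and the optimal diagonal boundary for
#' the GLC; each observer responds to a fresh normalized exemplar set.
#'
#' @param n_per_family Observers simulated per generating family.
#' @param n_trials Trials per observer (half per category).
#' @param noise_sd Internal noise SD of the generating observers.
#' @param seed Integer seed.
#' @param struct Generative [category_structure()].
#' @param families Generating families, labelled as in the classification
#'   (`"1D"` pools both unidimensional dimensions).
#' @param options [db_fit_options()] for the classification fits.
#' @return A tibble with columns `generated`, `classified`, `n`,
#'   `proportion`; `proportion` sums to 1 within each generating family.
#' @export
#' @examples
#' strategy_recovery(n_per_family = 3, n_trials = 60, seed = 1,
#'                   options = db_fit_options(n_starts = 5))
strategy_recovery <- function(n_per_family = 50, n_trials = 120,
                              noise_sd = 10, seed = 1,
                              struct = ii_structure(),
                              families = c("1D", "conjunction", "glc", "random"),
                              options = db_fit_options()) {
  stopifnot(n_per_family >= 1, n_trials >= 2)
  opt <- optimal_boundary(struct)
  gen_spec <- function(family, i) {
    switch(family,
      `1D` = {
        dim_i <- if (i %% 2 == 1) "unidimensional_x" else "unidimensional_y"
        observer_spec(dim_i, criterion = 50, noise_sd = noise_sd)
      },
      conjunction = observer_spec("conjunction", criterion_x = 50,
                                  criterion_y = 50, noise_sd = noise_sd),
      glc = observer_spec("glc", angle = opt$angle, offset = opt$offset,
                          noise_sd = noise_sd),
      random = observer_spec("random")
    )
  }
  rows <- list()
  for (family in families) {
    for (i in seq_len(n_per_family)) {
      s <- derive_seed(seed, match(family, families) * 1000 + i)
      ex <- sample_exemplars(struct, n_trials %/% 2, seed = s)
      tr <- simulate_responses(ex, gen_spec(family, i), seed = s + 1)
      cl <- classify_strategy(tr, options)
      rows[[length(rows) + 1]] <- tibble::tibble(
        generated = family, classified = cl$best_family
      )
    }
  }
  per <- dplyr::bind_rows(rows)
  fams <- c("1D", "glc", "conjunction", "random")
  counts <- dplyr::count(
    per,
    generated = factor(.data$generated, levels = families),
    classified = factor(.data$classified, levels = fams),
    .drop = FALSE
  )
  out <- dplyr::mutate(
    dplyr::group_by(counts, .data$generated),
    proportion = .data$n / sum(.data$n)
  )
  out <- dplyr::ungroup(out)
  out$generated <- as.character(out$generated)
  out$classified <- as.character(out$classified)
  out
}

#' Diagonal of a strategy-recovery confusion matrix
#'
#' @param confusion Output of [strategy_recovery()].
#' @return A named numeric vector of per-family correct-recovery rates.
#' @export
recovery_diagonal <- function(confusion) {
  d <- dplyr::filter(confusion, .data$generated == .data$classified)
  stats::setNames(d$proportion, d$generated)
}

#' Simulate-and-analyze recovery harness for the group analysis
#'
#' Repeatedly simulates the experiment under `config`, runs the test-3
#' ANCOVA (covariate test 1, factor group) on each replicate, and reports
#' the rejection rate of the group effect at level `alpha` — the type-I
#' error rate under a null configuration, power under an effect
#' configuration. Optionally appends a strategy-recovery confusion matrix
#' so one report covers both halves of the pipeline.
#'
#' @param config An [experiment_config()]; its group-effect parameters are
#'   the injected ground truth.
#' @param replicates Number of simulated experiments.
#' @param alpha Two-sided significance level.
#' @param seed Integer seed; replicate r uses a seed derived from it.
#' @param phase,covariate_phase Outcome and covariate phases of the ANCOVA.
#' @param strategy_recovery_n Observers per family for the confusion
#'   matrix; 0 (default) skips it.
#' @param options [db_fit_options()] for the confusion-matrix fits.
#' @return An object of class `recovery_report`: `rejection_rate`,
#'   `n_reject`, `replicates`, `alpha`, per-replicate results
#'   (`replicate_results`, a tibble of F and p values), the injected group
#'   effects, and optionally `confusion`.
#' @export
#' @examples
#' run_recovery(null_experiment_config(n_per_group = 8), replicates = 3,
#'              seed = 1)
run_recovery <- function(config, replicates = 100, alpha = 0.05, seed = 1,
                         phase = "test3", covariate_phase = "test1",
                         strategy_recovery_n = 0,
                         options = db_fit_options()) {
  stopifnot(inherits(config, "experiment_config"), replicates >= 1)
  res <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg_r <- config
    cfg_r$seed <- derive_seed(seed, r)
    ds <- simulate_experiment(cfg_r)
    fit <- ancova_by_phase(ds, phase = phase, covariate_phase = covariate_phase)
    res[[r]] <- tibble::tibble(
      replicate = r, statistic = fit$statistic, df1 = fit$df1,
      df2 = fit$df2, p_value = fit$p_value
    )
  }
  res <- dplyr::bind_rows(res)
  confusion <- NULL
  if (strategy_recovery_n > 0) {
    confusion <- strategy_recovery(
      n_per_family = strategy_recovery_n,
      seed = derive_seed(seed, 0, 1), struct = config$struct,
      options = options
    )
  }
  structure(
    list(
      rejection_rate = mean(res$p_value < alpha),
      n_reject = sum(res$p_value < alpha),
      replicates = replicates, alpha = alpha, seed = seed,
      phase = phase, covariate_phase = covariate_phase,
      replicate_results = res,
      injected_effects = list(
        group_noise_mult = config$group_noise_mult,
        group_switch_prob = config$group_switch_prob
      ),
      confusion = confusion
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> %s ANCOVA (covariate %s): rejected %d/%d (rate %.3f) at alpha = %.2f\n",
    x$phase, x$covariate_phase, x$n_reject, x$replicates,
    x$rejection_rate, x$alpha
  ))
  if (!is.null(x$confusion)) {
    cat("strategy recovery diagonal:\n")
    print(round(recovery_diagonal(x$confusion), 3))
  }
  invisible(x)
}
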