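#' Options controlling maximum-likelihood decision-bound fits
#'
#' Fits minimize the negative log-likelihood by multi-start bounded local
#' optimization: `n_starts - 1` stratified-random starting points inside the
#' parameter bounds plus one data-driven start (criteria at the midpoint of
#' the per-response means; the GLC start from the difference of the response
#' class means). Given a `seed` the whole procedure is deterministic.
#'
#' @param n_starts Total number of optimizer starts.
#' @param seed Integer seed for the random starts.
#' @param tol Relative convergence tolerance of each local optimization.
#' @param criterion_bounds Length-2 bounds for 1D/conjunction criteria
#'   (level units).
#' @param offset_bounds Length-2 bounds for the GLC offset (level units).
#' @param noise_bounds Length-2 bounds for `noise_sd`.
#' @param min_trials Minimum labeled trials required to fit.
#' @param conjunction_orientations Orientations tried for the conjunction
#'   family; the best-fitting one is kept (the parameter count stays 3, the
#'   orientation being a discrete rule choice, not a fitted parameter). The
#'   default fits only the canonical "low pixel density AND high tone
#'   frequency" rule.
#' @return A list of class `db_fit_options`.
#' @export
db_fit_options <- function(n_starts = 20, seed = 1, tol = 1e-6,
                           criterion_bounds = c(-25, 125),
                           offset_bounds = c(-200, 200),
                           noise_bounds = c(0.01, 200),
                           min_trials = 10,
                           conjunction_orientations = "low_x_high_y") {
  structure(
    list(
      n_starts = as.integer(n_starts), seed = seed, tol = tol,
      criterion_bounds = criterion_bounds, offset_bounds = offset_bounds,
      noise_bounds = noise_bounds, min_trials = min_trials,
      conjunction_orientations = conjunction_orientations
    ),
    class = "db_fit_options"
  )
}

# Parameter-space description per family: names, lower, upper.
db_param_space <- function(family, options) {
  cb <- options$criterion_bounds
  nb <- options$noise_bounds
  ob <- options$offset_bounds
  switch(family,
    unidimensional_x = ,
    unidimensional_y = list(
      names = c("criterion", "noise_sd"),
      lower = c(cb[1], nb[1]), upper = c(cb[2], nb[2])
    ),
    conjunction = list(
      names = c("criterion_x", "criterion_y", "noise_sd"),
      lower = c(cb[1], cb[1], nb[1]), upper = c(cb[2], cb[2], nb[2])
    ),
    glc = list(
      names = c("angle", "offset", "noise_sd"),
      lower = c(0, ob[1], nb[1]), upper = c(pi - 1e-8, ob[2], nb[2])
    )
  )
}

# Stratified-random starts: each parameter is sampled once per stratum of an
# equal partition of its range, strata independently permuted per parameter.
db_random_starts <- function(space, n) {
  d <- length(space$names)
  m <- matrix(0, nrow = n, ncol = d)
  for (j in seq_len(d)) {
    u <- (sample.int(n) - runif(n)) / n
    m[, j] <- space$lower[j] + u * (space$upper[j] - space$lower[j])
  }
  colnames(m) <- space$names
  m
}

# One start informed by the data: put criteria between the response-class
# means; point the GLC normal from the B-response mean toward the A mean.
db_data_start <- function(family, trials, space) {
  a <- trials$response == "A"
  mx <- c(mean(trials$x_level[a]), mean(trials$x_level[!a]))
  my <- c(mean(trials$y_level[a]), mean(trials$y_level[!a]))
  mx[is.na(mx)] <- mean(trials$x_level)
  my[is.na(my)] <- mean(trials$y_level)
  s <- max(sd(trials$x_level), sd(trials$y_level), 1)
  start <- switch(family,
    unidimensional_x = c(criterion = mean(mx), noise_sd = s),
    unidimensional_y = c(criterion = mean(my), noise_sd = s),
    conjunction = c(criterion_x = mean(mx), criterion_y = mean(my), noise_sd = s),
    glc = {
      v <- c(mx[1] - mx[2], my[1] - my[2])
      if (sum(v^2) < 1e-12) v <- c(-1, 1)
      ang <- atan2(v[2], v[1]) %% (2 * pi)
      if (ang >= pi) ang <- ang - pi # bounds keep the normal in [0, pi)
      mid <- c(mean(trials$x_level), mean(trials$y_level))
      c(angle = ang, offset = cos(ang) * mid[1] + sin(ang) * mid[2], noise_sd = s)
    }
  )
  pmin(pmax(start, space$lower + 1e-9), space$upper - 1e-9)
}

#' Fit one decision-bound model family by maximum likelihood
#'
#' Minimizes [neg_log_lik()] over the family's parameter space with
#' multi-start bounded optimization (`nlminb`); the `random` family has a
#' closed-form likelihood (`n * log(0.5)`) and needs no optimization.
#' Timed-out (`NA`-response) trials are dropped before fitting.
#'
#' @param trials A data frame with columns `x_level`, `y_level`, `response`.
#' @param family One of the five families of [db_model()].
#' @param options A [db_fit_options()] list.
#' @return An object of class `db_fit`: the fitted [db_model()] plus
#'   `log_lik`, `n_params`, `aic`, `n_trials`, `converged` and `n_starts`.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' ex <- sample_exemplars(ii_structure(), 30, seed = 2)
#' obs <- observer_spec("glc", angle = 3 * pi / 4, offset = 0, noise_sd = 10)
#' tr <- simulate_responses(ex, obs, seed = 3)
#' fit_db_model(tr, "glc", db_fit_options(n_starts = 5))
fit_db_model <- function(trials, family, options = db_fit_options()) {
  family <- match.arg(family, DB_FAMILIES)
  stopifnot(inherits(options, "db_fit_options"))
  trials <- trials[!is.na(trials$response), , drop = FALSE]
  n <- nrow(trials)
  if (n < options$min_trials) {
    abort(paste0("need at least ", options$min_trials, " labeled trials; got ", n))
  }

  if (family == "random") {
    ll <- n * log(0.5)
    return(new_db_fit(db_model("random"), ll, n, TRUE, 0L))
  }

  orientations <- if (family == "conjunction") options$conjunction_orientations else "low_x_high_y"
  space <- db_param_space(family, options)

  best <- NULL
  with_seed(options$seed, {
    starts <- rbind(
      db_random_starts(space, options$n_starts - 1L),
      db_data_start(family, trials, space)
    )
    for (orient in orientations) {
      obj <- nll_objective(family, orient, trials)
      for (i in seq_len(nrow(starts))) {
        res <- tryCatch(
          nlminb(starts[i, ], obj,
                 lower = space$lower, upper = space$upper,
                 control = list(rel.tol = options$tol, iter.max = 500)),
          error = function(e) NULL
        )
        if (is.null(res)) next
        cand <- list(par = res$par, nll = res$objective,
                     conv = res$convergence == 0, orient = orient)
        if (is.null(best) || cand$nll < best$nll ||
            (cand$nll == best$nll && cand$conv && !best$conv)) {
          best <- cand
        }
      }
    }
  })
  if (is.null(best)) abort("all optimizer starts failed")
  par <- best$par
  names(par) <- space$names
  model <- make_db_model(family, par, best$orient)
  # report the likelihood through the public evaluator, not the optimizer's
  # last objective value, so fit and evaluator can never drift apart
  new_db_fit(model, -neg_log_lik(model, trials), n, best$conv, options$n_starts)
}

make_db_model <- function(family, par, orientation) {
  do.call(db_model, c(as.list(par), list(family = family, orientation = orientation)))
}

# Fast closure evaluating the negative log-likelihood for an unnamed
# parameter vector in the family's canonical order; algebraically identical
# to neg_log_lik(make_db_model(...), trials).
nll_objective <- function(family, orient, trials, eps = 1e-10) {
  x <- trials$x_level
  y <- trials$y_level
  is_a <- trials$response == "A"
  finish <- function(p_a) {
    p_a <- pmin(pmax(p_a, eps), 1 - eps)
    -(sum(log(p_a[is_a])) + sum(log1p(-p_a[!is_a])))
  }
  switch(family,
    unidimensional_x = function(p) finish(pnorm((p[1] - x) / p[2])),
    unidimensional_y = function(p) finish(pnorm((y - p[1]) / p[2])),
    glc = function(p) finish(pnorm((cos(p[1]) * x + sin(p[1]) * y - p[2]) / p[3])),
    conjunction = {
      sx <- if (orient %in% c("low_x_high_y", "low_x_low_y")) 1 else -1
      sy <- if (orient %in% c("low_x_high_y", "high_x_high_y")) 1 else -1
      function(p) {
        finish(pnorm(sx * (p[1] - x) / p[3]) * pnorm(sy * (y - p[2]) / p[3]))
      }
    }
  )
}

new_db_fit <- function(model, log_lik, n_trials, converged, n_starts) {
  structure(
    list(
      model = model, family = model$family,
      log_lik = log_lik, n_params = model$n_params,
      aic = aic(log_lik, model$n_params),
      n_trials = n_trials, converged = converged, n_starts = n_starts
    ),
    class = "db_fit"
  )
}

#' @export
print.db_fit <- function(x, ...) {
  cat(sprintf(
    "<db_fit> %s: logLik = %.3f, k = %d, AIC = %.3f, n = %d%s\n",
    x$family, x$log_lik, x$n_params, x$aic, x$n_trials,
    if (!x$converged) " (not converged)" else ""
  ))
  if (length(x$model$params)) print(round(x$model$params, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted parameters of a decision-bound fit
#'
#' One row per parameter. For the GLC the derived `intercept` and
#' `gradient`, and for every noisy family `noise_var` (the variance of
#' internal noise), are appended as derived rows.
#'
#' @param x A `db_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `derived`.
#' @export
tidy.db_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = names(x$model$params) %||% character(0),
    estimate = unname(x$model$params),
    derived = FALSE
  )
  if (x$family == "glc" && abs(sin(x$model$params[["angle"]])) > 1e-12) {
    ig <- as_intercept_gradient(
      linear_boundary(x$model$params[["angle"]], x$model$params[["offset"]])
    )
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = c("intercept", "gradient"),
      estimate = c(ig$intercept, ig$gradient), derived = TRUE
    ))
  }
  if ("noise_sd" %in% out$term) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "noise_var",
      estimate = out$estimate[out$term == "noise_sd"]^2, derived = TRUE
    ))
  }
  out
}

#' One-row model-level summary of a decision-bound fit
#'
#' @param x A `db_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `log_lik`, `n_params`, `aic`,
#'   `n_trials`, `converged`, `n_starts`.
#' @export
glance.db_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, log_lik = x$log_lik, n_params = x$n_params,
    aic = x$aic, n_trials = x$n_trials, converged = x$converged,
    n_starts = x$n_starts
  )
}

#' Classify one participant's response strategy by AIC
#'
#' Fits all model families to the trials (both unidimensional dimensions;
#' the better of the two represents the pooled "1D" family) and selects the
#' family with the minimum AIC. Ties are broken toward fewer parameters,
#' then by the fixed order random, 1D, conjunction, glc.
#'
#' @param trials A data frame with `x_level`, `y_level`, `response`.
#' @param options A [db_fit_options()].
#' @return An object of class `strategy_classification`: `best_family` (one
#'   of `"1D"`, `"conjunction"`, `"glc"`, `"random"`), `best_sub_family`
#'   (which 1D dimension, where relevant), `aic_table` (a tibble), and the
#'   underlying `fits`.
#' @export
#' @examples
#' ex <- sample_exemplars(ii_structure(), 30, seed = 4)
#' tr <- simulate_responses(ex, observer_spec("random"), seed = 5)
#' classify_strategy(tr, db_fit_options(n_starts = 5))$best_family
classify_strategy <- function(trials, options = db_fit_options()) {
  fits <- lapply(stats::setNames(DB_FAMILIES, DB_FAMILIES), function(f) {
    fit_db_model(trials, f, options)
  })
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  oned_sub <- if (aics[["unidimensional_x"]] <= aics[["unidimensional_y"]]) {
    "unidimensional_x"
  } else {
    "unidimensional_y"
  }
  pooled <- c(
    random = aics[["random"]],
    `1D` = aics[[oned_sub]],
    conjunction = aics[["conjunction"]],
    glc = aics[["glc"]]
  )
  k <- c(random = 0L, `1D` = 2L, conjunction = 3L, glc = 3L)
  ord <- order(pooled, k, seq_along(pooled)) # AIC, then fewer params, then fixed order
  best <- names(pooled)[ord[1]]
  structure(
    list(
      best_family = best,
      best_sub_family = if (best == "1D") oned_sub else best,
      aic_table = tibble::tibble(
        family = names(pooled), aic = unname(pooled), k = unname(k)
      ),
      fits = fits
    ),
    class = "strategy_classification"
  )
}

#' @export
print.strategy_classification <- function(x, ...) {
  cat("<strategy_classification> best:", x$best_family,
      if (x$best_family == "1D") paste0("(", x$best_sub_family, ")"), "\n")
  print(x$aic_table)
  invisible(x)
}

#' Strategy-classification proportions by group and phase
#'
#' Classifies every participant's strategy in each requested phase and
#' tabulates, per group and phase, the proportion of participants best
#' described by each model family (columns `1D`, `glc`, `conjunction`,
#' `random`, summing to 1 across families within a group-phase cell).
#'
#' @param dataset A trial-level experiment dataset (see
#'   [simulate_experiment()]) or any data frame with `participant_id`,
#'   `group`, `phase`, `x_level`, `y_level`, `response`.
#' @param phases Phases to classify; defaults to the three tests.
#' @param options A [db_fit_options()].
#' @return A tibble with columns `group`, `phase`, `family`, `n`,
#'   `proportion`, plus attribute `"classifications"` holding the
#'   per-participant best families.
#' @export
classification_table <- function(dataset, phases = c("test1", "test2", "test3"),
                                 options = db_fit_options()) {
  stopifnot(is.data.frame(dataset))
  missing_ph <- setdiff(phases, unique(dataset$phase))
  if (length(missing_ph) > 0) {
    abort(paste0("dataset lacks phase(s): ", paste(missing_ph, collapse = ", ")))
  }
  sub <- dataset[dataset$phase %in% phases, , drop = FALSE]
  per <- dplyr::group_modify(
    dplyr::group_by(sub, .data$group, .data$phase, .data$participant_id),
    function(tr, key) {
      cl <- classify_strategy(tr, options)
      tibble::tibble(best_family = cl$best_family)
    }
  )
  per <- dplyr::ungroup(per)
  fams <- c("1D", "glc", "conjunction", "random")
  counts <- dplyr::count(per, .data$group, .data$phase,
                         best_family = factor(.data$best_family, levels = fams),
                         .drop = FALSE)
  out <- dplyr::mutate(
    dplyr::group_by(counts, .data$group, .data$phase),
    proportion = .data$n / sum(.data$n)
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::rename(out, family = "best_family")
  out$family <- as.character(out$family)
  attr(out, "classifications") <- per
  out
}
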