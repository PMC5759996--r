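#' Specify a synthetic observer
#'
#' A synthetic participant responds to category trials through a noisy
#' decision-bound strategy — the same probabilistic rule the fitting module
#' assumes ([response_prob_a()]) — mixed with occasional lapses (uniformly
#' random responses) and, optionally, timeouts (no response within the
#' response window; scored incorrect).
#'
#' @param strategy One of `"unidimensional_x"`, `"unidimensional_y"`,
#'   `"conjunction"`, `"glc"`, `"random"`.
#' @param ... Strategy parameters passed to [db_model()] (for non-random
#'   strategies this includes `noise_sd`).
#' @param lapse_rate Probability a trial's response is a fair coin flip
#'   regardless of the stimulus; in `[0, 1]` (1 makes any strategy behave
#'   like a random responder).
#' @param timeout_rate Probability a trial times out with no response;
#'   in `[0, 1)`.
#' @param orientation Conjunction-rule orientation, see [db_model()].
#' @return An object of class `observer_spec`.
#' @export
#' @examples
#' observer_spec("glc", angle = 3 * pi / 4, offset = 0, noise_sd = 10)
#' observer_spec("random", lapse_rate = 0)
observer_spec <- function(strategy, ..., lapse_rate = 0, timeout_rate = 0,
                          orientation = "low_x_high_y") {
  if (lapse_rate < 0 || lapse_rate > 1) {
    abort("`lapse_rate` must lie in [0, 1]")
  }
  if (timeout_rate < 0 || timeout_rate >= 1) {
    abort("`timeout_rate` must lie in [0, 1)")
  }
  model <- db_model(strategy, ..., orientation = orientation)
  structure(
    list(model = model, strategy = model$family,
         lapse_rate = lapse_rate, timeout_rate = timeout_rate),
    class = "observer_spec"
  )
}

#' @export
print.observer_spec <- function(x, ...) {
  cat("<observer_spec> strategy:", x$strategy,
      sprintf("(lapse %.2f, timeout %.2f)\n", x$lapse_rate, x$timeout_rate))
  if (length(x$model$params)) print(round(x$model$params, 4))
  invisible(x)
}

# P(respond A) for an observer, including the lapse mixture.
observer_prob_a <- function(spec, x, y) {
  p <- response_prob_a(spec$model, x, y)
  (1 - spec$lapse_rate) * p + spec$lapse_rate * 0.5
}

#' Simulate an observer's responses to a set of stimuli
#'
#' Each trial independently times out with probability `timeout_rate`
#' (response `NA`, scored incorrect); otherwise the response is `"A"` with
#' the observer's lapse-mixed response probability.
#'
#' @param stimuli A data frame with columns `x_level` and `y_level`;
#'   a `category` column, if present, is used to score correctness.
#' @param spec An [observer_spec()].
#' @param seed Optional integer seed; the global RNG stream is unaffected.
#' @return The input tibble with columns `response`, `timed_out` and (when
#'   the true category is available) `correct` appended.
#' @export
#' @examples
#' ex <- sample_exemplars(ii_structure(), 30, seed = 1)
#' obs <- observer_spec("unidimensional_y", criterion = 50, noise_sd = 10)
#' mean(simulate_responses(ex, obs, seed = 2)$correct)
simulate_responses <- function(stimuli, spec, seed = NULL) {
  stopifnot(is.data.frame(stimuli), inherits(spec, "observer_spec"))
  if (nrow(stimuli) == 0) abort("`stimuli` is empty")
  n <- nrow(stimuli)
  with_seed(seed, {
    p_a <- observer_prob_a(spec, stimuli$x_level, stimuli$y_level)
    resp <- ifelse(runif(n) < p_a, "A", "B")
    timed_out <- runif(n) < spec$timeout_rate
    resp[timed_out] <- NA_character_
    out <- tibble::as_tibble(stimuli)
    out$response <- resp
    out$timed_out <- timed_out
    if ("category" %in% names(stimuli)) {
      out$correct <- !timed_out & !is.na(resp) & resp == stimuli$category
    } else if ("true_category" %in% names(stimuli)) {
      out$correct <- !timed_out & !is.na(resp) & resp == stimuli$true_category
    }
    out
  })
}
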