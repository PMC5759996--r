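DB_FAMILIES <- c("unidimensional_x", "unidimensional_y", "conjunction", "glc", "random")

DB_N_PARAMS <- c(
  unidimensional_x = 2L, unidimensional_y = 2L,
  conjunction = 3L, glc = 3L, random = 0L
)

#' Construct a decision-bound model
#'
#' Four model families describe how an observer partitions the
#' two-dimensional stimulus space into category-A and category-B response
#' regions, each perturbed by Gaussian internal noise of standard deviation
#' `noise_sd` (perceptual and criterial noise combined in a single term):
#'
#' * `unidimensional_x` — a single criterion on the pixel-density dimension;
#'   respond A when the (noisy) density falls below the criterion.
#'   Parameters: `criterion`, `noise_sd` (2).
#' * `unidimensional_y` — a single criterion on the tone-frequency
#'   dimension; respond A for high tones. Parameters: `criterion`,
#'   `noise_sd` (2).
#' * `conjunction` — independent criteria on both dimensions combined by a
#'   logical rule, by default "low pixel density AND high tone frequency is
#'   A". Parameters: `criterion_x`, `criterion_y`, `noise_sd` (3; one shared
#'   noise term keeps the count at three).
#' * `glc` — the general linear classifier: an arbitrary straight boundary,
#'   parametrized here by the normal `angle` and `offset` of a
#'   [linear_boundary()] (which avoids the vertical-line singularity of the
#'   intercept/gradient form; use [as_intercept_gradient()] to report the
#'   conventional description). Parameters: `angle`, `offset`, `noise_sd`
#'   (3).
#' * `random` — category labels are guessed with probability 0.5 each; no
#'   parameters.
#'
#' @param family One of `"unidimensional_x"`, `"unidimensional_y"`,
#'   `"conjunction"`, `"glc"`, `"random"`.
#' @param ... Named numeric parameters for the family, as listed above.
#' @param orientation For `conjunction` only: which quadrant maps to A, as
#'   `"low_x_high_y"` (default), `"low_x_low_y"`, `"high_x_high_y"`, or
#'   `"high_x_low_y"`.
#' @return An object of class `db_model`.
#' @export
#' @examples
#' db_model("glc", angle = 3 * pi / 4, offset = 0, noise_sd = 10)
#' db_model("unidimensional_y", criterion = 50, noise_sd = 12)
db_model <- function(family, ..., orientation = "low_x_high_y") {
  family <- match.arg(family, DB_FAMILIES)
  params <- c(...)
  needed <- switch(family,
    unidimensional_x = ,
    unidimensional_y = c("criterion", "noise_sd"),
    conjunction = c("criterion_x", "criterion_y", "noise_sd"),
    glc = c("angle", "offset", "noise_sd"),
    random = character(0)
  )
  if (!setequal(names(params) %||% character(0), needed)) {
    abort(paste0(
      "family \"", family, "\" needs parameters: ",
      if (length(needed)) paste(needed, collapse = ", ") else "(none)"
    ))
  }
  params <- params[needed]
  if ("noise_sd" %in% needed && params[["noise_sd"]] <= 0) {
    abort("`noise_sd` must be positive")
  }
  orientation <- match.arg(
    orientation,
    c("low_x_high_y", "low_x_low_y", "high_x_high_y", "high_x_low_y")
  )
  structure(
    list(
      family = family, params = params,
      n_params = DB_N_PARAMS[[family]],
      orientation = if (family == "conjunction") orientation else NULL
    ),
    class = "db_model"
  )
}

#' @export
print.db_model <- function(x, ...) {
  cat("<db_model>", x$family,
      if (!is.null(x$orientation)) paste0("[", x$orientation, "]"), "\n")
  if (length(x$params)) print(round(x$params, 4)) else cat("(no parameters)\n")
  invisible(x)
}

#' Probability of a category-A response
#'
#' The response rule shared by the simulator and the likelihood: the
#' observer's noisy percept is compared against the model's partition, so
#' the probability of responding A is the Gaussian CDF of the (signed)
#' margin in units of `noise_sd`. For `unidimensional_x` this is
#' `pnorm((criterion - x) / noise_sd)` (A for low pixel density); for
#' `unidimensional_y`, `pnorm((y - criterion) / noise_sd)` (A for high
#' tones); for `glc`, `pnorm(d / noise_sd)` with `d` the signed distance to
#' the boundary (A positive); for `conjunction`, the product of the two
#' marginal judgment probabilities; for `random`, 0.5. Probabilities are
#' clamped to `[eps, 1 - eps]` so log-likelihoods stay finite.
#'
#' @param model A [db_model()].
#' @param x,y Numeric vectors of stimulus levels.
#' @param eps Clamp width.
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' m <- db_model("glc", angle = 3 * pi / 4, offset = 0, noise_sd = 10)
#' response_prob_a(m, x = 40, y = 50) # 10 / sqrt(2) levels inside A
response_prob_a <- function(model, x, y, eps = 1e-10) {
  stopifnot(inherits(model, "db_model"))
  p <- model$params
  pr <- switch(model$family,
    unidimensional_x = pnorm((p[["criterion"]] - x) / p[["noise_sd"]]),
    unidimensional_y = pnorm((y - p[["criterion"]]) / p[["noise_sd"]]),
    glc = {
      b <- linear_boundary(p[["angle"]], p[["offset"]])
      pnorm(boundary_distance(b, x, y) / p[["noise_sd"]])
    },
    conjunction = {
      zx <- (p[["criterion_x"]] - x) / p[["noise_sd"]]
      zy <- (y - p[["criterion_y"]]) / p[["noise_sd"]]
      sx <- if (model$orientation %in% c("low_x_high_y", "low_x_low_y")) 1 else -1
      sy <- if (model$orientation %in% c("low_x_high_y", "high_x_high_y")) 1 else -1
      pnorm(sx * zx) * pnorm(sy * zy)
    },
    random = rep(0.5, length(x))
  )
  pmin(pmax(pr, eps), 1 - eps)
}

#' Negative log-likelihood of a decision-bound model
#'
#' `-sum(log p_i)` over trials, where `p_i` is [response_prob_a()] for
#' A responses and its complement for B responses. Timed-out trials carry no
#' response label (`NA`) and are excluded.
#'
#' @param model A [db_model()].
#' @param trials A data frame with columns `x_level`, `y_level`, `response`
#'   (values `"A"`/`"B"`, `NA` allowed for timeouts).
#' @param eps Likelihood clamp passed to [response_prob_a()].
#' @return Negative log-likelihood in nats (a single non-negative number).
#' @export
#' @examples
#' tr <- data.frame(x_level = c(30, 60), y_level = c(60, 40),
#'                  response = c("A", "B"))
#' neg_log_lik(db_model("random"), tr) # 2 * log(2)
neg_log_lik <- function(model, trials, eps = 1e-10) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0) abort("`trials` is empty")
  resp <- trials$response
  keep <- !is.na(resp)
  bad <- setdiff(unique(resp[keep]), c("A", "B"))
  if (length(bad) > 0) {
    abort(paste0("unknown response label(s): ", paste(bad, collapse = ", ")))
  }
  if (!any(keep)) abort("`trials` has no labeled responses")
  p_a <- response_prob_a(model, trials$x_level[keep], trials$y_level[keep], eps = eps)
  p <- ifelse(resp[keep] == "A", p_a, 1 - p_a)
  -sum(log(p))
}

#' Akaike's information criterion
#'
#' `2 * k - 2 * log_lik`; lower is better, penalizing each free parameter by
#' 2 nats. For the zero-parameter random-responder model on `n` trials the
#' log-likelihood is `n * log(0.5)` exactly, so its AIC is `2 * n * log(2)`.
#'
#' @param log_lik Log-likelihood in nats.
#' @param k Number of free parameters (non-negative integer).
#' @return The AIC value.
#' @export
#' @examples
#' aic(-50, 3)
aic <- function(log_lik, k) {
  stopifnot(is.numeric(log_lik), is.numeric(k), k >= 0)
  2 * k - 2 * log_lik
}
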