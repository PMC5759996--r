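#' Linear decision boundary in stimulus space
#'
#' A line in the two-dimensional level space parametrized by the direction of
#' its unit normal, `(cos(angle), sin(angle))`, and its signed `offset` from
#' the origin along that normal. The line is the locus
#' `cos(angle) * x + sin(angle) * y = offset`; category A responses lie on
#' the positive-normal side. `(angle + pi, -offset)` denotes the same line
#' with category labels flipped, so the angle is kept in `[0, 2*pi)` and the
#' label orientation is part of the parametrization.
#'
#' @param angle Direction of the unit normal, radians; wrapped into
#'   `[0, 2*pi)`.
#' @param offset Signed distance from the origin to the line, level units.
#' @return An object of class `linear_boundary`.
#' @seealso [boundary_accuracy()], [optimal_boundary()],
#'   [as_intercept_gradient()].
#' @export
#' @examples
#' # the main diagonal x = y, with A on the low-x / high-y side
#' linear_boundary(3 * pi / 4, 0)
linear_boundary <- function(angle, offset) {
  stopifnot(is.numeric(angle), length(angle) == 1, is.finite(angle),
            is.numeric(offset), length(offset) == 1, is.finite(offset))
  structure(list(angle = unname(angle) %% (2 * pi), offset = unname(offset)),
            class = "linear_boundary")
}

#' @export
print.linear_boundary <- function(x, ...) {
  cat(sprintf(
    "<linear_boundary> angle = %.4f rad (%.1f deg), offset = %.4f\n",
    x$angle, x$angle * 180 / pi, x$offset
  ))
  invisible(x)
}

#' Signed distance from stimuli to a linear boundary
#'
#' Positive on the category-A side.
#'
#' @param boundary A [linear_boundary()].
#' @param x,y Numeric vectors of stimulus levels.
#' @return Numeric vector of signed distances, level units.
#' @export
boundary_distance <- function(boundary, x, y) {
  stopifnot(inherits(boundary, "linear_boundary"))
  cos(boundary$angle) * x + sin(boundary$angle) * y - boundary$offset
}

#' Express a boundary as intercept and gradient
#'
#' Converts the (angle, offset) normal form to the `y = intercept +
#' gradient * x` description conventional in general-linear-classifier
#' reports. Undefined for vertical boundaries (normal along the y axis is
#' required to be nonzero).
#'
#' @param boundary A [linear_boundary()].
#' @return A named list with `intercept` and `gradient`.
#' @export
as_intercept_gradient <- function(boundary) {
  s <- sin(boundary$angle)
  if (abs(s) < 1e-12) {
    abort("vertical boundary: intercept/gradient form is undefined")
  }
  list(
    intercept = boundary$offset / s,
    gradient = -cos(boundary$angle) / s
  )
}

#' Analytic expected accuracy of a linear boundary
#'
#' For a mixture of axis-aligned bivariate-Gaussian components the
#' probability that an exemplar falls on its category's side of a linear
#' boundary has a closed form: for each component, project onto the boundary
#' normal — the projection is univariate Gaussian with SD
#' `sqrt((sigma_x * cos a)^2 + (sigma_y * sin a)^2)` — and take the Gaussian
#' CDF of the component mean's signed distance (negated for category B,
#' which should fall on the negative side). Components are weighted by their
#' category prior split equally within category.
#'
#' @param struct A [category_structure()].
#' @param boundary A [linear_boundary()].
#' @return Expected proportion correct, in \[0, 1\].
#' @export
#' @examples
#' boundary_accuracy(ii_structure(), linear_boundary(3 * pi / 4, 0))
boundary_accuracy <- function(struct, boundary) {
  stopifnot(inherits(struct, "category_structure"),
            inherits(boundary, "linear_boundary"))
  comp <- struct$components
  a <- boundary$angle
  sd_n <- sqrt((comp$sigma_x * cos(a))^2 + (comp$sigma_y * sin(a))^2)
  d <- boundary_distance(boundary, comp$mu_x, comp$mu_y)
  signed <- ifelse(comp$category == "A", d, -d)
  p_comp <- ifelse(sd_n > 0, pnorm(signed / sd_n), as.numeric(signed >= 0))
  prior <- ifelse(comp$category == "A", struct$prior_a, 1 - struct$prior_a)
  w <- prior / stats::ave(rep(1, nrow(comp)), comp$category, FUN = sum)
  sum(w * p_comp)
}

#' Find the accuracy-maximizing linear boundary
#'
#' Deterministic two-stage search: a coarse grid over normal angles (default
#' 1 degree, covering both label orientations) and offsets (default 1 level,
#' spanning the projections of all component means padded by 4 SD), followed
#' by Nelder-Mead refinement of the best grid cell.
#'
#' @param struct A [category_structure()].
#' @param angle_step Grid resolution in radians.
#' @param offset_step Grid resolution in level units.
#' @param tol Relative convergence tolerance of the local refinement.
#' @return The optimal [linear_boundary()], with the achieved expected
#'   accuracy attached as attribute `"accuracy"`.
#' @export
#' @examples
#' b <- optimal_boundary(ii_structure())
#' attr(b, "accuracy")
optimal_boundary <- function(struct, angle_step = pi / 180, offset_step = 1,
                             tol = 1e-6) {
  stopifnot(inherits(struct, "category_structure"))
  comp <- struct$components
  angles <- seq(0, 2 * pi, by = angle_step)
  pad <- 4 * max(comp$sigma_x, comp$sigma_y)
  lo <- min(comp$mu_x, comp$mu_y) - pad
  hi <- max(comp$mu_x, comp$mu_y) + pad
  span <- sqrt(2) * max(abs(lo), abs(hi))
  offsets <- seq(-span, span, by = offset_step)

  acc_fun <- function(a, o) boundary_accuracy(struct, linear_boundary(a, o))
  best <- c(acc = -Inf, angle = 0, offset = 0)
  for (a in angles) {
    # vectorized over offsets for speed
    sd_n <- sqrt((comp$sigma_x * cos(a))^2 + (comp$sigma_y * sin(a))^2)
    proj <- cos(a) * comp$mu_x + sin(a) * comp$mu_y
    prior <- ifelse(comp$category == "A", struct$prior_a, 1 - struct$prior_a)
    w <- prior / stats::ave(rep(1, nrow(comp)), comp$category, FUN = sum)
    sgn <- ifelse(comp$category == "A", 1, -1)
    acc <- vapply(offsets, function(o) {
      z <- sgn * (proj - o) / sd_n
      sum(w * pnorm(z))
    }, numeric(1))
    i <- which.max(acc)
    if (acc[i] > best["acc"]) best <- c(acc = acc[i], angle = a, offset = offsets[i])
  }
  ref <- stats::optim(
    c(best["angle"], best["offset"]),
    function(p) -acc_fun(p[1], p[2]),
    method = "Nelder-Mead",
    control = list(reltol = tol^2, maxit = 2000)
  )
  out <- linear_boundary(ref$par[1], ref$par[2])
  attr(out, "accuracy") <- -ref$value
  out
}
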