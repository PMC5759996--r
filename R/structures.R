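#' Define a two-category bivariate-Gaussian category structure
#'
#' An information-integration category structure places two categories in a
#' two-dimensional stimulus space (abstract "level" units on each dimension),
#' each category a mixture of axis-aligned bivariate-Gaussian components.
#' Neither dimension alone separates the categories; accurate classification
#' requires integrating both.
#'
#' @param components A data frame with one row per mixture component and
#'   columns `category` (`"A"` or `"B"`), `mu_x`, `mu_y`, `sigma_x`, `sigma_y`
#'   (means and standard deviations in level units).
#' @param prior_a Prior probability of category A; strictly inside (0, 1).
#'
#' @return An object of class `category_structure`: a list with elements
#'   `components` (a tibble) and `prior_a`.
#' @seealso [ii_structure()] for the packaged default structure,
#'   [sample_exemplars()], [optimal_boundary()], [boundary_accuracy()].
#' @export
#' @examples
#' category_structure(
#'   data.frame(
#'     category = c("A", "B"),
#'     mu_x = c(30, 70), mu_y = c(50, 50),
#'     sigma_x = 10, sigma_y = 10
#'   )
#' )
category_structure <- function(components, prior_a = 0.5) {
  components <- tibble::as_tibble(components)
  req <- c("category", "mu_x", "mu_y", "sigma_x", "sigma_y")
  missing_cols <- setdiff(req, names(components))
  if (length(missing_cols) > 0) {
    abort(paste0("`components` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(components$category %in% c("A", "B"))) {
    abort("`category` must be \"A\" or \"B\"")
  }
  if (!all(c("A", "B") %in% components$category)) {
    abort("each category needs at least one component")
  }
  if (any(components$sigma_x < 0) || any(components$sigma_y < 0)) {
    abort("component standard deviations must be non-negative")
  }
  if (!is.numeric(prior_a) || length(prior_a) != 1 || prior_a <= 0 || prior_a >= 1) {
    abort("`prior_a` must be a single probability in (0, 1)")
  }
  components <- dplyr::mutate(components,
    dplyr::across(dplyr::all_of(req[-1]), as.numeric),
    component = stats::ave(seq_along(.data$category), .data$category, FUN = seq_along)
  )
  structure(
    list(components = components[, c("category", "component", req[-1])], prior_a = prior_a),
    class = "category_structure"
  )
}

#' The default cross-modal information-integration structure
#'
#' Each category is an equal mixture of two isotropic bivariate-Gaussian
#' components (SD 10 on both dimensions) arranged so that category A occupies
#' the low-pixel-density / high-tone-frequency diagonal band and category B
#' the opposite band: A components at (26.67, 50.00) and (50.00, 73.33),
#' B components at (50.00, 26.67) and (73.33, 50.00), with equal priors.
#' The optimal linear decision boundary is the main diagonal `x = y` and
#' attains 95% expected accuracy (a 5% category overlap).
#'
#' @return A [category_structure()].
#' @export
#' @examples
#' ii_structure()
ii_structure <- function() {
  category_structure(
    tibble::tibble(
      category = c("A", "A", "B", "B"),
      mu_x = c(26.67, 50.00, 50.00, 73.33),
      mu_y = c(50.00, 73.33, 26.67, 50.00),
      sigma_x = 10,
      sigma_y = 10
    )
  )
}

#' @export
print.category_structure <- function(x, ...) {
  cat("<category_structure> prior A =", format(x$prior_a), "\n")
  print(x$components)
  invisible(x)
}

#' Physical realization constants for the cross-modal stimuli
#'
#' Abstract stimulus levels are realized physically as (a) the number of lit
#' pixels in a square visual pixel box, growing geometrically with level, and
#' (b) the frequency of a pure tone, rising by one octave every
#' `freq_octave_div` levels.
#'
#' @param pixel_base Lit pixels at level 0.
#' @param pixel_growth Multiplicative growth in lit pixels per level.
#' @param freq_base Tone frequency (Hz) at level 0.
#' @param freq_octave_div Number of levels per octave.
#' @param box_edge Edge length of the square pixel box, in pixels; the box
#'   contains `box_edge^2` addressable pixels (22,500 at the default 150).
#' @return An object of class `realization_params`.
#' @export
#' @examples
#' p <- realization_params()
#' p$box_edge^2 # total addressable pixels
realization_params <- function(pixel_base = 850, pixel_growth = 1.0181,
                               freq_base = 220, freq_octave_div = 120,
                               box_edge = 150) {
  vals <- c(pixel_base, pixel_growth, freq_base, freq_octave_div, box_edge)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all realization parameters must be positive and finite")
  }
  structure(
    list(
      pixel_base = as.numeric(pixel_base), pixel_growth = as.numeric(pixel_growth),
      freq_base = as.numeric(freq_base), freq_octave_div = as.numeric(freq_octave_div),
      box_edge = as.numeric(box_edge)
    ),
    class = "realization_params"
  )
}

#' Realize an abstract level as a lit-pixel count
#'
#' Computes `round(pixel_base * pixel_growth^level)` with half-up rounding
#' (0.5 always rounds toward +Inf), the convention for counting lit pixels.
#'
#' @param level Numeric vector of abstract levels (may lie outside 0–100).
#' @param params A [realization_params()] object.
#' @return Integer-valued numeric vector of lit-pixel counts.
#' @export
#' @examples
#' realize_pixels(c(0, 1, 100))
realize_pixels <- function(level, params = realization_params()) {
  stopifnot(is.numeric(level), all(is.finite(level)))
  floor(params$pixel_base * params$pixel_growth^level + 0.5)
}

#' Realize an abstract level as a tone frequency
#'
#' Computes `freq_base * 2^(level / freq_octave_div)`, left unrounded;
#' round only for display.
#'
#' @inheritParams realize_pixels
#' @return Numeric vector of frequencies in Hz.
#' @export
#' @examples
#' realize_frequency(c(0, 100, 120))
realize_frequency <- function(level, params = realization_params()) {
  stopifnot(is.numeric(level), all(is.finite(level)))
  params$freq_base * 2^(level / params$freq_octave_div)
}

#' Assign the on-screen presentation side of a stimulus
#'
#' Stimuli are presented on the left or right side of the screen according to
#' their position relative to a line orthogonal to the category boundary, so
#' screen side is systematic but carries no category information for a
#' structure symmetric about the main diagonal. The default rule puts
#' `x + y >= threshold` on the left (ties inclusive-left); which half-space
#' maps to which side is a display convention, exposed via `polarity`.
#'
#' @param x,y Numeric vectors of stimulus levels.
#' @param threshold Sum of levels at the dividing line.
#' @param polarity `"high_left"` (default) presents the high `x + y`
#'   half-space on the left; `"high_right"` flips the mapping.
#' @return Character vector, `"left"` or `"right"`.
#' @export
#' @examples
#' assign_screen_side(c(26.67, 73.33, 50), c(50, 50, 50))
assign_screen_side <- function(x, y, threshold = 100,
                               polarity = c("high_left", "high_right")) {
  polarity <- match.arg(polarity)
  high <- (x + y) >= threshold
  if (polarity == "high_left") ifelse(high, "left", "right") else ifelse(high, "right", "left")
}

#' Sample a normalized exemplar set from a category structure
#'
#' Draws `n_per_category` exemplars per category, each category's draw split
#' equally across its mixture components (odd remainders allocated by a
#' seeded draw). With `normalize = TRUE` (the default) each component's
#' sample is affinely standardized per dimension so that its sample mean and
#' SD equal the component parameters exactly — every simulated participant
#' then sees the same statistical category structure through their own unique
#' exemplars, which is how per-participant stimulus sets are equated in this
#' paradigm.
#'
#' @param struct A [category_structure()].
#' @param n_per_category Number of exemplars per category.
#' @param seed Optional integer seed; the global RNG stream is unaffected.
#' @param normalize Standardize each component's sample moments to its
#'   parameters. Requires at least 2 draws per component.
#' @param params A [realization_params()] used for the physical columns.
#' @return A tibble with one row per exemplar: `exemplar_id`, `category`,
#'   `component`, `x_level`, `y_level`, `pixels`, `freq_hz`, `side`.
#' @export
#' @examples
#' ex <- sample_exemplars(ii_structure(), 60, seed = 1)
#' dplyr::count(ex, category, component)
sample_exemplars <- function(struct, n_per_category, seed = NULL,
                             normalize = TRUE, params = realization_params()) {
  stopifnot(inherits(struct, "category_structure"))
  if (!is.numeric(n_per_category) || n_per_category < 1) {
    abort("`n_per_category` must be at least 1")
  }
  n_per_category <- as.integer(n_per_category)
  with_seed(seed, {
    comp <- struct$components
    out <- vector("list", nrow(comp))
    for (cat_lab in c("A", "B")) {
      rows <- which(comp$category == cat_lab)
      k <- length(rows)
      n_each <- rep(n_per_category %/% k, k)
      rem <- n_per_category %% k
      if (rem > 0) {
        extra <- sample.int(k, rem)
        n_each[extra] <- n_each[extra] + 1
      }
      for (j in seq_len(k)) {
        i <- rows[j]
        n <- n_each[j]
        if (normalize && n < 2) {
          abort(paste0(
            "normalization needs >= 2 exemplars per component; component ",
            comp$component[i], " of category ", cat_lab, " has ", n
          ))
        }
        zx <- rnorm(n)
        zy <- rnorm(n)
        if (normalize) {
          zx <- (zx - mean(zx)) / sd(zx)
          zy <- (zy - mean(zy)) / sd(zy)
        }
        out[[i]] <- tibble::tibble(
          category = cat_lab,
          component = comp$component[i],
          x_level = comp$mu_x[i] + comp$sigma_x[i] * zx,
          y_level = comp$mu_y[i] + comp$sigma_y[i] * zy
        )
      }
    }
    res <- dplyr::bind_rows(out)
    res <- dplyr::mutate(res,
      exemplar_id = dplyr::row_number(),
      pixels = realize_pixels(.data$x_level, params),
      freq_hz = realize_frequency(.data$y_level, params),
      side = assign_screen_side(.data$x_level, .data$y_level),
      .before = 1
    )
    res[, c(
      "exemplar_id", "category", "component", "x_level", "y_level",
      "pixels", "freq_hz", "side"
    )]
  })
}
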