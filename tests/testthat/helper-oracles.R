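# Independent oracles used across the suite. These re-derive quantities from
# first principles (different code paths from the package) so agreement is
# evidence, not tautology.

# Standard normal CDF via the complementary error function (pracma), not
# stats::pnorm.
phi_erfc <- function(z) 0.5 * pracma::erfc(-z / sqrt(2))

# Trial-by-trial negative log-likelihood, re-implemented per family with
# explicit formulas and a scalar loop.
oracle_nll <- function(family, par, trials, orientation = "low_x_high_y",
                       eps = 1e-10) {
  total <- 0
  for (i in seq_len(nrow(trials))) {
    x <- trials$x_level[i]
    y <- trials$y_level[i]
    p_a <- switch(family,
      unidimensional_x = phi_erfc((par[["criterion"]] - x) / par[["noise_sd"]]),
      unidimensional_y = phi_erfc((y - par[["criterion"]]) / par[["noise_sd"]]),
      glc = {
        d <- cos(par[["angle"]]) * x + sin(par[["angle"]]) * y - par[["offset"]]
        phi_erfc(d / par[["noise_sd"]])
      },
      conjunction = {
        sx <- if (orientation %in% c("low_x_high_y", "low_x_low_y")) 1 else -1
        sy <- if (orientation %in% c("low_x_high_y", "high_x_high_y")) 1 else -1
        phi_erfc(sx * (par[["criterion_x"]] - x) / par[["noise_sd"]]) *
          phi_erfc(sy * (y - par[["criterion_y"]]) / par[["noise_sd"]])
      },
      random = 0.5
    )
    p_a <- min(max(p_a, eps), 1 - eps)
    p <- if (trials$response[i] == "A") p_a else 1 - p_a
    total <- total - log(p)
  }
  total
}

# Draw one random small likelihood instance (family, parameters, trials).
random_nll_instance <- function() {
  family <- sample(c("unidimensional_x", "unidimensional_y", "conjunction",
                     "glc", "random"), 1)
  par <- switch(family,
    unidimensional_x = ,
    unidimensional_y = c(criterion = runif(1, -25, 125), noise_sd = runif(1, 0.5, 60)),
    conjunction = c(criterion_x = runif(1, -25, 125),
                    criterion_y = runif(1, -25, 125),
                    noise_sd = runif(1, 0.5, 60)),
    glc = c(angle = runif(1, 0, 2 * pi), offset = runif(1, -100, 100),
            noise_sd = runif(1, 0.5, 60)),
    random = numeric(0)
  )
  n <- sample(5:30, 1)
  trials <- data.frame(
    x_level = runif(n, -20, 120),
    y_level = runif(n, -20, 120),
    response = sample(c("A", "B"), n, replace = TRUE)
  )
  list(family = family, par = par, trials = trials)
}

# One-way, one-covariate ANCOVA via explicit normal equations (dummy-coded
# design matrix, base solve()), independent of lm().
oracle_ancova <- function(y, x, g) {
  g <- factor(g)
  n <- length(y)
  lev <- levels(g)
  dummies <- sapply(lev[-1], function(l) as.numeric(g == l))
  X_full <- cbind(1, x, dummies)
  X_cov <- cbind(1, x)
  beta_full <- solve(crossprod(X_full), crossprod(X_full, y))
  beta_cov <- solve(crossprod(X_cov), crossprod(X_cov, y))
  rss_full <- sum((y - X_full %*% beta_full)^2)
  rss_cov <- sum((y - X_cov %*% beta_cov)^2)
  df1 <- length(lev) - 1
  df2 <- n - length(lev) - 1
  f_stat <- ((rss_cov - rss_full) / df1) / (rss_full / df2)
  b_w <- beta_full[2]
  xbar_g <- as.vector(tapply(x, g, mean))
  ybar_g <- as.vector(tapply(y, g, mean))
  list(
    b_w = b_w,
    adjusted = ybar_g - b_w * (xbar_g - mean(x)),
    statistic = f_stat, df1 = df1, df2 = df2,
    p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
    eta_sq = (rss_cov - rss_full) / sum((y - mean(y))^2)
  )
}

# Cheap fit options for tests where full multi-start depth is not the point.
fast_opts <- function(n_starts = 6, seed = 1) {
  db_fit_options(n_starts = n_starts, seed = seed)
}

# Small handmade trial table.
toy_trials <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(
    x_level = runif(n, 0, 100),
    y_level = runif(n, 0, 100),
    response = sample(c("A", "B"), n, replace = TRUE)
  )
}
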