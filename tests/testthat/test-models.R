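test_that("response probabilities follow the Gaussian margin rule", {
  glc <- db_model("glc", angle = 3 * pi / 4, offset = 0, noise_sd = 10)
  expect_equal(response_prob_a(glc, 50, 50), 0.5)
  # one noise-SD inside the A region: d = 10, sd = 10
  d <- 10 / sqrt(2)
  expect_equal(response_prob_a(glc, 50 - d, 50 + d), pnorm(1), tolerance = 1e-10)
  cj <- db_model("conjunction", criterion_x = 50, criterion_y = 50, noise_sd = 5)
  expect_gte(response_prob_a(cj, -100, 200), 1 - 1e-9)
  expect_equal(response_prob_a(db_model("random"), c(1, 2), c(3, 4)), c(0.5, 0.5))
})

test_that("response probabilities are monotone in the model's margin", {
  xs <- seq(-20, 120, by = 5)
  ux <- db_model("unidimensional_x", criterion = 50, noise_sd = 12)
  expect_true(all(diff(response_prob_a(ux, xs, rep(50, length(xs)))) <= 0))
  uy <- db_model("unidimensional_y", criterion = 50, noise_sd = 12)
  expect_true(all(diff(response_prob_a(uy, rep(50, length(xs)), xs)) >= 0))
  cj <- db_model("conjunction", criterion_x = 40, criterion_y = 60, noise_sd = 8)
  expect_true(all(diff(response_prob_a(cj, xs, rep(70, length(xs)))) <= 0))
  expect_true(all(diff(response_prob_a(cj, rep(30, length(xs)), xs)) >= 0))
  glc <- db_model("glc", angle = 3 * pi / 4, offset = 0, noise_sd = 7)
  dists <- seq(-30, 30, by = 2)
  p <- response_prob_a(glc, 50 - dists / sqrt(2), 50 + dists / sqrt(2))
  expect_true(all(diff(p) >= 0))
})

test_that("conjunction orientations carve the four quadrants", {
  for (orient in c("low_x_high_y", "low_x_low_y", "high_x_high_y", "high_x_low_y")) {
    m <- db_model("conjunction", criterion_x = 50, criterion_y = 50,
                  noise_sd = 2, orientation = orient)
    corner <- switch(orient,
      low_x_high_y = c(20, 80), low_x_low_y = c(20, 20),
      high_x_high_y = c(80, 80), high_x_low_y = c(80, 20)
    )
    expect_gt(response_prob_a(m, corner[1], corner[2]), 0.99)
    expect_lt(response_prob_a(m, 100 - corner[1], 100 - corner[2]), 0.01)
  }
})

test_that("closed-form likelihood values hold", {
  tr60 <- data.frame(x_level = runif(60), y_level = runif(60),
                     response = sample(c("A", "B"), 60, replace = TRUE))
  expect_equal(neg_log_lik(db_model("random"), tr60), 60 * log(2), tolerance = 1e-12)
  one <- data.frame(x_level = 50, y_level = 50, response = "A")
  glc <- db_model("glc", angle = 3 * pi / 4, offset = 0, noise_sd = 10)
  expect_equal(neg_log_lik(glc, one), log(2), tolerance = 1e-12)
  # near-noiseless model on correctly labeled separable data: NLL -> 0
  sep <- data.frame(x_level = c(20, 80), y_level = c(80, 20),
                    response = c("A", "B"))
  tight <- db_model("glc", angle = 3 * pi / 4, offset = 0, noise_sd = 0.01)
  expect_lt(neg_log_lik(tight, sep), 1e-8)
  expect_gte(neg_log_lik(tight, sep), 0)
})

test_that("likelihood rejects unknown labels and skips timeouts", {
  bad <- data.frame(x_level = 1, y_level = 1, response = "C")
  expect_error(neg_log_lik(db_model("random"), bad), "unknown response")
  mixed <- data.frame(x_level = c(1, 2), y_level = c(1, 2),
                      response = c("A", NA))
  expect_equal(neg_log_lik(db_model("random"), mixed), log(2), tolerance = 1e-12)
  expect_error(neg_log_lik(db_model("random"),
                           data.frame(x_level = 1, y_level = 1,
                                      response = NA_character_)),
               "no labeled")
})

test_that("negative log-likelihood matches the independent oracle", {
  skip_if_not_installed("pracma")
  set.seed(1234)
  for (i in 1:25) {
    inst <- random_nll_instance()
    m <- do.call(db_model, c(list(family = inst$family), as.list(inst$par)))
    expect_equal(neg_log_lik(m, inst$trials),
                 oracle_nll(inst$family, inst$par, inst$trials),
                 tolerance = 1e-8)
  }
})

test_that("AIC is 2k minus twice the log-likelihood", {
  expect_identical(aic(-50, 3), 106)
  expect_identical(aic(0, 0), 0)
  # random-model AIC is exactly 2 n log 2
  for (n in c(1, 10, 60, 137)) {
    expect_equal(aic(n * log(0.5), 0), 2 * n * log(2), tolerance = 1e-12)
  }
})

test_that("model constructors validate their parameter sets", {
  expect_error(db_model("glc", angle = 1), "needs parameters")
  expect_error(db_model("unidimensional_x", criterion = 50, noise_sd = -1),
               "positive")
  expect_identical(db_model("random")$n_params, 0L)
  expect_identical(db_model("conjunction", criterion_x = 1, criterion_y = 2,
                            noise_sd = 3)$n_params, 3L)
})
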