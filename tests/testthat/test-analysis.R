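make_acc_dataset <- function() {
  # 2 participants x 2 phases, hand-countable
  tibble::tibble(
    participant_id = rep(1:2, each = 8),
    group = rep(c("g1", "g2"), each = 8),
    phase = rep(rep(c("test1", "test2"), each = 4), 2),
    correct = c(rep(TRUE, 8), c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)),
    timed_out = FALSE,
    response = "A", true_category = "A"
  )
}

test_that("accuracy summaries count correct trials per participant and phase", {
  acc <- summarize_accuracy(make_acc_dataset())
  expect_identical(nrow(acc), 4L)
  expect_equal(acc$proportion_correct[acc$participant_id == 1], c(1, 1))
  expect_equal(acc$proportion_correct[acc$participant_id == 2 &
                                        acc$phase == "test2"], 0.25)
  # totals are conserved
  expect_identical(sum(acc$n_correct) + sum(acc$n_trials - acc$n_correct),
                   sum(acc$n_trials))
  # 45 of 60 correct gives 0.75
  ds60 <- tibble::tibble(
    participant_id = 1, group = "g", phase = "test1",
    correct = rep(c(TRUE, FALSE), c(45, 15))
  )
  expect_equal(summarize_accuracy(ds60)$proportion_correct, 0.75)
})

test_that("chance tests match hand-computed t statistics and flag degeneracy", {
  d <- tibble::tibble(group = "g1", proportion_correct = c(0.6, 0.7, 0.8))
  res <- chance_test(d)
  expect_equal(res$t, 3.4641016, tolerance = 1e-6) # mean .7, SE .05774
  expect_identical(res$df, 2)
  expect_false(res$degenerate)
  flat <- tibble::tibble(group = "g1", proportion_correct = rep(0.5, 4))
  res_flat <- chance_test(flat)
  expect_identical(res_flat$t, 0)
  expect_identical(res_flat$p, 1)
  expect_true(res_flat$degenerate)
  up <- tibble::tibble(group = "g1", proportion_correct = rep(0.7, 4))
  res_up <- chance_test(up)
  expect_true(res_up$degenerate)
  expect_identical(res_up$t, Inf)
  expect_error(chance_test(tibble::tibble(group = "g", proportion_correct = 0.6)),
               ">= 2 participants")
})

test_that("the ANCOVA toy table gives the pooled slope and adjusted means", {
  d <- data.frame(g = c("g1", "g1", "g2", "g2"), x = c(1, 2, 3, 4),
                  y = c(2, 4, 5, 7))
  fit <- ancova_adjusted_means(d, outcome = "y", covariate = "x", group = "g")
  expect_equal(fit$b_w, 2.0, tolerance = 1e-12)
  # ybar_g - b_w (xbar_g - xbar): (3 - 2(1.5-2.5), 6 - 2(3.5-2.5)) = (5, 4)
  expect_equal(fit$adjusted_means, c(5, 4), tolerance = 1e-12)
})

test_that("ANCOVA matches the normal-equations oracle on random instances", {
  set.seed(77)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    n_g <- sample(3:8, k, replace = TRUE)
    g <- rep(paste0("g", seq_len(k)), n_g)
    x <- rnorm(length(g), 50, 10)
    y <- 0.3 * x + rnorm(length(g), as.numeric(factor(g)), 2)
    fit <- ancova_adjusted_means(data.frame(y = y, x = x, g = g), "y", "x", "g")
    orc <- oracle_ancova(y, x, g)
    expect_equal(fit$b_w, orc$b_w, tolerance = 1e-8)
    expect_equal(fit$adjusted_means, orc$adjusted, tolerance = 1e-8)
    expect_equal(fit$statistic, orc$statistic, tolerance = 1e-8)
    expect_equal(fit$p_value, orc$p_value, tolerance = 1e-8)
    expect_equal(fit$eta_sq, orc$eta_sq, tolerance = 1e-8)
    expect_equal(fit$df1, k - 1)
    expect_equal(fit$df2, length(g) - k - 1)
  }
})

test_that("adjusted means reduce to raw means in the degenerate directions", {
  # identical covariate distribution across groups: xbar_g == xbar
  d <- data.frame(
    g = rep(c("g1", "g2"), each = 4),
    x = rep(c(1, 2, 3, 4), 2),
    y = c(1, 3, 2, 4, 5, 6, 7, 8)
  )
  fit <- ancova_adjusted_means(d, "y", "x", "g")
  expect_equal(fit$adjusted_means, fit$raw_means, tolerance = 1e-12)
  # outcome orthogonal to the covariate within groups: b_w == 0 exactly
  d2 <- data.frame(
    g = rep(c("g1", "g2"), each = 4),
    x = c(1, 2, 3, 4, 11, 12, 13, 14),
    y = rep(c(2, 2, 2, 2), 2) + rep(c(0, 1), each = 4)
  )
  fit2 <- ancova_adjusted_means(d2, "y", "x", "g")
  expect_equal(fit2$b_w, 0, tolerance = 1e-12)
  expect_equal(fit2$adjusted_means, fit2$raw_means, tolerance = 1e-12)
  # constant covariate within groups is inestimable
  d3 <- data.frame(g = rep(c("g1", "g2"), each = 3), x = rep(c(1, 5), each = 3),
                   y = rnorm(6))
  expect_error(ancova_adjusted_means(d3, "y", "x", "g"), "covariate variance")
})

test_that("tidy and glance summarize ANCOVA fits", {
  ds <- simulate_experiment(experiment_config(n_per_group = 8, seed = 33))
  fit <- ancova_by_phase(ds, "test3")
  td <- tidy(fit)
  expect_identical(nrow(td), 4L)
  expect_true(all(td$adjusted_mean > 0 & td$adjusted_mean < 1))
  gl <- glance(fit)
  expect_gte(gl$eta_sq, 0)
  expect_lte(gl$eta_sq, 1)
  expect_equal(gl$df1, 3)
  expect_error(ancova_by_phase(ds, "test9"), "phase not in dataset")
})

test_that("strategy-shift summaries report GLC prevalence deltas", {
  tab <- tidyr::expand_grid(
    group = c("sleep", "wake"),
    phase = c("test1", "test2", "test3"),
    family = c("1D", "glc", "conjunction", "random")
  )
  tab$proportion <- 0
  # sleep rises 0.2 -> 0.7 -> 0.7; wake flat at 0.3
  tab$proportion[tab$family == "glc" & tab$group == "sleep"] <- c(0.2, 0.7, 0.7)
  tab$proportion[tab$family == "glc" & tab$group == "wake"] <- c(0.3, 0.3, 0.3)
  out <- strategy_shift_summary(tab)
  sleep <- out[out$group == "sleep", ]
  expect_equal(sleep$delta_t2_t1, 0.5)
  expect_equal(sleep$delta_t3_t1, 0.5)
  wake <- out[out$group == "wake", ]
  expect_equal(wake$delta_t2_t1, 0)
  expect_true(all(out$delta_t2_t1 >= -1 & out$delta_t2_t1 <= 1))
})
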