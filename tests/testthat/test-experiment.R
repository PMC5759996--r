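small_config <- function(n = 3, seed = 101, ...) {
  experiment_config(n_per_group = n, seed = seed, ...)
}

test_that("a simulated experiment has the full design schema", {
  cfg <- small_config()
  ds <- simulate_experiment(cfg)
  expect_s3_class(ds, "experiment_dataset")
  expect_identical(nrow(ds), 4L * 3L * 7L * 60L)
  counts <- dplyr::count(ds, participant_id, phase)
  expect_true(all(counts$n == 60))
  expect_setequal(unique(ds$phase), experiment_phases())
  # correctness flag consistency; timeouts scored incorrect
  expect_identical(
    ds$correct,
    !ds$timed_out & !is.na(ds$response) & ds$response == ds$true_category
  )
  # each 60-trial block is 30 A + 30 B
  comp <- dplyr::count(ds, participant_id, phase, true_category)
  expect_true(all(comp$n == 30))
  # physical columns consistent with the level columns
  expect_identical(ds$pixels, realize_pixels(ds$x_level))
  expect_identical(ds$side, assign_screen_side(ds$x_level, ds$y_level))
})

test_that("ground-truth observer paths are attached and well formed", {
  ds <- simulate_experiment(small_config())
  obs <- attr(ds, "observers")
  expect_identical(nrow(obs), 12L * 7L)
  expect_setequal(unique(obs$phase), experiment_phases())
  expect_true(all(obs$strategy %in% c(
    "random", "unidimensional_x", "unidimensional_y", "conjunction", "glc"
  )))
  expect_true(all(is.na(obs$noise_sd[obs$strategy == "random"])))
  expect_true(all(obs$noise_sd[obs$strategy != "random"] > 0))
})

test_that("identical seeds give identical datasets; participants regenerate in isolation", {
  cfg <- small_config()
  ds1 <- simulate_experiment(cfg)
  ds2 <- simulate_experiment(cfg)
  expect_identical(as.data.frame(ds1), as.data.frame(ds2))
  p7 <- simulate_participant(cfg, 7)
  full7 <- ds1[ds1$participant_id == 7, ]
  expect_equal(as.data.frame(p7), as.data.frame(full7), ignore_attr = TRUE)
  obs7 <- attr(p7, "observers")
  full_obs7 <- dplyr::filter(attr(ds1, "observers"), participant_id == 7)
  expect_equal(as.data.frame(obs7), as.data.frame(full_obs7), ignore_attr = TRUE)
})

test_that("an empty cohort yields an empty dataset with a valid schema", {
  ds <- simulate_experiment(small_config(n = 0))
  expect_identical(nrow(ds), 0L)
  expect_true(all(c(
    "participant_id", "group", "phase", "block", "trial_index", "x_level",
    "y_level", "pixels", "freq_hz", "side", "true_category", "response",
    "correct", "timed_out"
  ) %in% names(ds)))
  expect_identical(nrow(attr(ds, "observers")), 0L)
})

test_that("with null group effects the groups stay exchangeable", {
  ds <- simulate_experiment(null_experiment_config(n_per_group = 20, seed = 55))
  acc <- summarize_accuracy(ds)
  t3 <- acc[acc$phase == "test3", ]
  means <- tapply(t3$proportion_correct, t3$group, mean)
  expect_lt(max(means) - min(means), 0.12)
})

test_that("the default configuration produces a learning trajectory in the working band", {
  ds <- simulate_experiment(experiment_config(seed = 2024))
  acc <- summarize_accuracy(ds)
  phase_means <- tapply(acc$proportion_correct, acc$phase, mean)
  tests <- phase_means[c("test1", "test2", "test3")]
  expect_true(all(tests > 0.65 & tests < 0.80))
  expect_gt(phase_means[["test3"]], phase_means[["learn1_block1"]])
})

test_that("datasets round-trip through CSV/JSON serialization", {
  dir <- withr::local_tempdir()
  cfg <- small_config(n = 2)
  ds <- simulate_experiment(cfg)
  write_experiment(ds, dir)
  back <- read_experiment(dir)
  expect_equal(as.data.frame(back)[, c("participant_id", "group", "phase",
                                       "response", "correct", "timed_out")],
               as.data.frame(ds)[, c("participant_id", "group", "phase",
                                     "response", "correct", "timed_out")])
  expect_equal(back$x_level, ds$x_level, tolerance = 1e-12)
  # ground-truth specs round-trip unchanged
  expect_equal(as.data.frame(attr(back, "observers")),
               as.data.frame(attr(ds, "observers")), tolerance = 1e-14)
  # restored config regenerates the identical dataset
  ds_again <- simulate_experiment(attr(back, "config"))
  expect_identical(as.data.frame(ds_again), as.data.frame(ds))
})

test_that("serialization is byte-identical across repeated writes", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds <- simulate_experiment(small_config(n = 2))
  write_experiment(ds, d1)
  write_experiment(ds, d2)
  for (f in c("trials.csv", "observers.json", "config.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6))
  }
})

test_that("experiment configs validate and round-trip through YAML", {
  expect_error(experiment_config(n_per_group = -1), "non-negative")
  expect_error(experiment_config(trials_per_block = 61), "even")
  expect_error(experiment_config(group_noise_mult = c(a = 1)), "named for every group")
  cfg <- small_config(n = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(catbound:::config_to_list(cfg), path)
  cfg2 <- read_experiment_config(path)
  expect_identical(as.data.frame(cfg2$struct$components),
                   as.data.frame(cfg$struct$components))
  expect_identical(
    as.data.frame(simulate_experiment(cfg2)),
    as.data.frame(simulate_experiment(cfg))
  )
})
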