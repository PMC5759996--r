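PHASES <- c(
  "learn1_block1", "learn1_block2", "test1", "test2",
  "learn2_block1", "learn2_block2", "test3"
)
POST_DELAY_PHASES <- c("test2", "learn2_block1", "learn2_block2", "test3")
DEFAULT_GROUPS <- c("15min", "PSG", "12h_sleep", "12h_wake")

#' Phase labels of the simulated experiment design
#'
#' The design has two sessions separated by a consolidation delay: Session 1
#' holds two 60-trial learning blocks and an immediate test (test 1); after
#' the delay, Session 2 opens with a retention test (test 2), continues with
#' two further learning blocks, and ends with a final test (test 3).
#'
#' @return Character vector of the seven phase labels, in design order.
#' @export
experiment_phases <- function() PHASES

#' Configure a simulated category-learning experiment
#'
#' Defines the study conditions for [simulate_experiment()]: four delay
#' groups (15-min, overnight-lab (PSG), 12-h sleep, 12-h wake), a population
#' of decision-bound observers whose strategies and internal noise evolve
#' across the seven phases, and the group-dependent effects applied across
#' the consolidation delay (i.e. to every phase after test 1).
#'
#' Learning is modeled as between-phase parameter change only: internal
#' noise shrinks along `phase_noise_mult`, random guessers may adopt a rule
#' at each phase transition (`p_upgrade_random`), and rule users may switch
#' to the integrative GLC strategy (`p_integrate` per transition, plus the
#' one-shot `group_switch_prob` across the delay). Group effects enter only
#' after test 1, mirroring a consolidation manipulation: `group_noise_mult`
#' rescales post-delay noise and `group_switch_prob` raises the
#' rule-to-GLC switch probability across the delay.
#'
#' @param n_per_group Participants per delay group.
#' @param groups Group labels; defaults to the four delay conditions.
#' @param trials_per_block Trials per learning block and per test (half
#'   category A, half category B, randomized order).
#' @param struct The generative [category_structure()].
#' @param params [realization_params()] for the physical stimulus columns.
#' @param strategy_probs Baseline strategy mix at the first learning block;
#'   named probabilities over `random`, `unidimensional`, `conjunction`,
#'   `glc` (the unidimensional mass splits equally between dimensions).
#' @param noise_base Population median internal-noise SD (level units) at
#'   the first learning block.
#' @param noise_cv SD of the participant-level log-normal noise multiplier.
#' @param phase_noise_mult Named per-phase multipliers on the baseline noise
#'   describing within-experiment learning.
#' @param p_upgrade_random Per-transition probability that a random guesser
#'   adopts a rule (then unidimensional with probability 0.7, GLC 0.3).
#' @param p_integrate Baseline per-transition probability that a
#'   unidimensional or conjunction user switches to GLC.
#' @param group_noise_mult Named per-group noise multiplier applied to all
#'   post-delay phases.
#' @param group_switch_prob Named per-group extra rule-to-GLC switch
#'   probability applied once, across the delay.
#' @param lapse_rate,timeout_rate Observer lapse/timeout probabilities.
#' @param seed Master seed; all per-participant and per-phase substreams are
#'   derived deterministically from it.
#' @return An object of class `experiment_config`.
#' @seealso [null_experiment_config()] for the no-group-effect control.
#' @export
experiment_config <- function(n_per_group = 23,
                              groups = DEFAULT_GROUPS,
                              trials_per_block = 60,
                              struct = ii_structure(),
                              params = realization_params(),
                              strategy_probs = c(
                                random = 0.15, unidimensional = 0.45,
                                conjunction = 0.05, glc = 0.35
                              ),
                              noise_base = 25,
                              noise_cv = 0.15,
                              phase_noise_mult = c(
                                learn1_block1 = 1.00, learn1_block2 = 0.85,
                                test1 = 0.78, test2 = 0.78,
                                learn2_block1 = 0.70, learn2_block2 = 0.66,
                                test3 = 0.62
                              ),
                              p_upgrade_random = 0.3,
                              p_integrate = 0.05,
                              group_noise_mult = c(
                                "15min" = 1.00, "PSG" = 0.92,
                                "12h_sleep" = 0.92, "12h_wake" = 1.05
                              ),
                              group_switch_prob = c(
                                "15min" = 0.05, "PSG" = 0.25,
                                "12h_sleep" = 0.25, "12h_wake" = 0.00
                              ),
                              lapse_rate = 0.02,
                              timeout_rate = 0,
                              seed = 1) {
  if (!is.numeric(n_per_group) || n_per_group < 0) {
    abort("`n_per_group` must be a non-negative count")
  }
  if (length(groups) < 1 || anyDuplicated(groups)) {
    abort("`groups` must be distinct labels")
  }
  if (trials_per_block < 2 || trials_per_block %% 2 != 0) {
    abort("`trials_per_block` must be an even count >= 2")
  }
  strategy_probs <- strategy_probs[c("random", "unidimensional", "conjunction", "glc")]
  if (anyNA(strategy_probs) || any(strategy_probs < 0)) {
    abort("`strategy_probs` must name random, unidimensional, conjunction, glc")
  }
  strategy_probs <- strategy_probs / sum(strategy_probs)
  if (!all(groups %in% names(group_noise_mult)) ||
      !all(groups %in% names(group_switch_prob))) {
    abort("group effect parameters must be named for every group")
  }
  if (!all(PHASES %in% names(phase_noise_mult))) {
    abort("`phase_noise_mult` must name every phase")
  }
  stopifnot(
    is.finite(noise_base), noise_base > 0, is.finite(noise_cv), noise_cv >= 0,
    all(is.finite(group_noise_mult)), all(group_noise_mult > 0),
    all(is.finite(group_switch_prob)), all(group_switch_prob >= 0),
    all(group_switch_prob <= 1)
  )
  structure(
    list(
      n_per_group = as.integer(n_per_group), groups = groups,
      trials_per_block = as.integer(trials_per_block),
      struct = struct, params = params,
      strategy_probs = strategy_probs, noise_base = as.numeric(noise_base),
      noise_cv = as.numeric(noise_cv),
      phase_noise_mult = vapply(phase_noise_mult[PHASES], as.numeric, 0),
      p_upgrade_random = as.numeric(p_upgrade_random),
      p_integrate = as.numeric(p_integrate),
      group_noise_mult = vapply(group_noise_mult[groups], as.numeric, 0),
      group_switch_prob = vapply(group_switch_prob[groups], as.numeric, 0),
      lapse_rate = as.numeric(lapse_rate), timeout_rate = as.numeric(timeout_rate),
      seed = as.numeric(seed)
    ),
    class = "experiment_config"
  )
}

#' Null-effect experiment configuration
#'
#' The default [experiment_config()] with all group-dependent effects
#' equalized (noise multiplier 1 and a common delay switch probability for
#' every group), making the four groups exchangeable. Used for type-I-error
#' calibration of the analysis pipeline.
#'
#' @param ... Overrides passed to [experiment_config()].
#' @param switch_prob Common rule-to-GLC delay switch probability.
#' @return An `experiment_config`.
#' @export
null_experiment_config <- function(..., switch_prob = 0.05) {
  groups <- list(...)$groups %||% DEFAULT_GROUPS
  experiment_config(
    ...,
    group_noise_mult = stats::setNames(rep(1, length(groups)), groups),
    group_switch_prob = stats::setNames(rep(switch_prob, length(groups)), groups)
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>", length(x$groups), "groups x", x$n_per_group,
      "participants;", x$trials_per_block, "trials/block; seed", x$seed, "\n")
  invisible(x)
}

# Lean exemplar sampler used inside the simulator: plain vectors, balanced
# components, per-component moment normalization (exact mean/SD).
sample_levels_core <- function(comp, n_per_category, normalize) {
  nr <- length(comp$category)
  xs <- vector("list", nr); ys <- vector("list", nr)
  cats <- vector("list", nr); comps <- vector("list", nr)
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
      i <- rows[j]; n <- n_each[j]
      zx <- rnorm(n); zy <- rnorm(n)
      if (normalize) {
        zx <- (zx - mean(zx)) / sd(zx)
        zy <- (zy - mean(zy)) / sd(zy)
      }
      xs[[i]] <- comp$mu_x[i] + comp$sigma_x[i] * zx
      ys[[i]] <- comp$mu_y[i] + comp$sigma_y[i] * zy
      cats[[i]] <- rep(cat_lab, n)
      comps[[i]] <- rep(comp$component[i], n)
    }
  }
  list(
    x = unlist(xs), y = unlist(ys),
    category = unlist(cats), component = unlist(comps)
  )
}

# Draw strategy parameters for a newly adopted strategy. Criteria and the
# GLC boundary are centered on the task-appropriate values with individual
# jitter, reflecting imperfect rule placement.
draw_strategy_params <- function(strategy) {
  jitter5 <- function() rnorm(1, 0, 5)
  switch(strategy,
    random = list(),
    unidimensional_x = list(criterion = 50 + jitter5()),
    unidimensional_y = list(criterion = 50 + jitter5()),
    conjunction = list(criterion_x = 50 + jitter5(), criterion_y = 50 + jitter5()),
    glc = list(
      angle = min(max(3 * pi / 4 + rnorm(1, 0, 5 * pi / 180), 1e-6), pi - 1e-6),
      offset = rnorm(1, 0, 5)
    )
  )
}

# Build the ground-truth per-phase observer path for one participant.
# Drawn under the participant substream so a participant is reproducible in
# isolation.
draw_observer_path <- function(config, group) {
  sp <- config$strategy_probs
  pick <- sample(names(sp), 1, prob = sp)
  strategy <- if (pick == "unidimensional") {
    sample(c("unidimensional_x", "unidimensional_y"), 1)
  } else {
    pick
  }
  params <- draw_strategy_params(strategy)
  noise_mult <- exp(rnorm(1, 0, config$noise_cv))

  path <- vector("list", length(PHASES))
  for (pi in seq_along(PHASES)) {
    phase <- PHASES[pi]
    if (pi > 1) {
      # phase-transition dynamics
      if (strategy == "random") {
        if (runif(1) < config$p_upgrade_random) {
          strategy <- if (runif(1) < 0.7) {
            sample(c("unidimensional_x", "unidimensional_y"), 1)
          } else {
            "glc"
          }
          params <- draw_strategy_params(strategy)
        }
      } else if (strategy != "glc") {
        p_switch <- config$p_integrate +
          if (PHASES[pi - 1] == "test1") config$group_switch_prob[[group]] else 0
        if (runif(1) < p_switch) {
          strategy <- "glc"
          params <- draw_strategy_params(strategy)
        }
      }
    }
    noise <- config$noise_base * noise_mult * config$phase_noise_mult[[phase]]
    if (phase %in% POST_DELAY_PHASES) {
      noise <- noise * config$group_noise_mult[[group]]
    }
    path[[pi]] <- list(
      phase = phase, strategy = strategy, params = params,
      noise_sd = noise,
      lapse_rate = config$lapse_rate, timeout_rate = config$timeout_rate
    )
  }
  path
}

path_entry_spec <- function(entry) {
  if (entry$strategy == "random") {
    observer_spec("random",
      lapse_rate = entry$lapse_rate, timeout_rate = entry$timeout_rate
    )
  } else {
    do.call(observer_spec, c(
      list(strategy = entry$strategy),
      entry$params, list(noise_sd = entry$noise_sd),
      list(lapse_rate = entry$lapse_rate, timeout_rate = entry$timeout_rate)
    ))
  }
}

# Simulate all phases of one participant; returns plain vectors.
sim_one_participant <- function(config, idx, group) {
  pseed <- derive_seed(config$seed, idx)
  path <- with_seed(pseed, draw_observer_path(config, group))

  tpb <- config$trials_per_block
  npc <- tpb %/% 2L
  comp <- as.list(config$struct$components)
  n_total <- length(PHASES) * tpb
  x <- numeric(n_total); y <- numeric(n_total)
  cat_v <- character(n_total); comp_v <- integer(n_total)
  resp <- character(n_total); tout <- logical(n_total)
  phase_v <- character(n_total)

  for (pi in seq_along(PHASES)) {
    entry <- path[[pi]]
    spec <- path_entry_spec(entry)
    rows <- ((pi - 1) * tpb + 1):(pi * tpb)
    with_seed(derive_seed(config$seed, idx, pi), {
      lv <- sample_levels_core(comp, npc, normalize = TRUE)
      ord <- sample.int(tpb)
      xi <- lv$x[ord]; yi <- lv$y[ord]
      p_a <- observer_prob_a(spec, xi, yi)
      ri <- ifelse(runif(tpb) < p_a, "A", "B")
      ti <- runif(tpb) < spec$timeout_rate
      ri[ti] <- NA_character_
      x[rows] <- xi; y[rows] <- yi
      cat_v[rows] <- lv$category[ord]; comp_v[rows] <- lv$component[ord]
      resp[rows] <- ri; tout[rows] <- ti
      phase_v[rows] <- entry$phase
    })
  }
  list(
    x = x, y = y, category = cat_v, component = comp_v,
    response = resp, timed_out = tout, phase = phase_v, path = path
  )
}

#' Simulate a full category-learning experiment
#'
#' Generates one trial-level dataset for all groups and participants across
#' the seven phases of the design. Every participant receives a fresh,
#' per-component moment-normalized exemplar set in every phase (half
#' category A, half B, randomized order) and responds through their
#' phase-specific noisy decision-bound strategy. All randomness derives from
#' the master seed via per-participant, per-phase substreams, so any
#' participant can be regenerated in isolation ([simulate_participant()]).
#'
#' @param config An [experiment_config()].
#' @return A tibble of class `experiment_dataset` with columns
#'   `participant_id`, `group`, `phase`, `block`, `trial_index`, `x_level`,
#'   `y_level`, `pixels`, `freq_hz`, `side`, `true_category`, `response`,
#'   `correct`, `timed_out`. Timed-out trials have `response = NA` and are
#'   scored incorrect. The injected ground truth is attached as attributes:
#'   `"observers"` (a per-participant-phase spec tibble) and `"config"`.
#' @export
#' @examples
#' ds <- simulate_experiment(experiment_config(n_per_group = 2, seed = 42))
#' dplyr::count(ds, group, phase)
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  n_g <- length(config$groups)
  n_p <- n_g * config$n_per_group
  tpb <- config$trials_per_block
  npp <- length(PHASES) * tpb

  parts <- vector("list", max(n_p, 0))
  groups_of <- rep(config$groups, each = config$n_per_group)
  for (i in seq_len(n_p)) {
    parts[[i]] <- sim_one_participant(config, i, groups_of[i])
  }

  pull <- function(field, mode) {
    if (n_p == 0) return(vector(mode, 0))
    unlist(lapply(parts, `[[`, field), use.names = FALSE)
  }
  x <- pull("x", "numeric"); y <- pull("y", "numeric")
  ds <- tibble::tibble(
    participant_id = rep(seq_len(n_p), each = npp)[seq_along(x)],
    group = rep(groups_of, each = npp)[seq_along(x)],
    phase = pull("phase", "character"),
    block = dplyr::case_when(
      grepl("block1$", pull("phase", "character")) ~ 1L,
      grepl("block2$", pull("phase", "character")) ~ 2L,
      TRUE ~ NA_integer_
    ),
    trial_index = rep(rep(seq_len(tpb), length(PHASES)), n_p)[seq_along(x)],
    x_level = x,
    y_level = y,
    pixels = realize_pixels(x, config$params),
    freq_hz = realize_frequency(y, config$params),
    side = assign_screen_side(x, y),
    true_category = pull("category", "character"),
    response = pull("response", "character"),
    timed_out = pull("timed_out", "logical")
  )
  ds$correct <- !ds$timed_out & !is.na(ds$response) &
    ds$response == ds$true_category
  ds <- ds[, c(
    "participant_id", "group", "phase", "block", "trial_index",
    "x_level", "y_level", "pixels", "freq_hz", "side",
    "true_category", "response", "correct", "timed_out"
  )]

  obs <- observer_truth_table(parts, groups_of)
  attr(ds, "observers") <- obs
  attr(ds, "config") <- config
  class(ds) <- c("experiment_dataset", class(ds))
  ds
}

observer_truth_table <- function(parts, groups_of, ids = seq_along(parts)) {
  entries <- unlist(lapply(parts, `[[`, "path"), recursive = FALSE)
  n <- length(entries)
  n_phase <- length(PHASES)
  num_field <- function(e, f) e$params[[f]] %||% NA_real_
  tibble::tibble(
    participant_id = if (n) rep(as.integer(ids), each = n_phase) else integer(0),
    group = if (n) rep(groups_of, each = n_phase) else character(0),
    phase = vapply(entries, `[[`, "", "phase"),
    strategy = vapply(entries, `[[`, "", "strategy"),
    criterion = vapply(entries, num_field, 0, "criterion"),
    criterion_x = vapply(entries, num_field, 0, "criterion_x"),
    criterion_y = vapply(entries, num_field, 0, "criterion_y"),
    angle = vapply(entries, num_field, 0, "angle"),
    offset = vapply(entries, num_field, 0, "offset"),
    noise_sd = vapply(entries, function(e) {
      if (e$strategy == "random") NA_real_ else e$noise_sd
    }, 0),
    lapse_rate = vapply(entries, `[[`, 0, "lapse_rate"),
    timeout_rate = vapply(entries, `[[`, 0, "timeout_rate")
  )
}

#' Regenerate a single simulated participant in isolation
#'
#' Because all randomness in [simulate_experiment()] flows through
#' deterministic per-participant, per-phase substreams of the master seed,
#' any participant's trials and ground-truth observer path can be
#' reconstructed without simulating the rest of the cohort.
#'
#' @param config The same [experiment_config()] used for the full dataset.
#' @param participant_id Participant index (participants are numbered
#'   consecutively within groups, in group order).
#' @return A tibble of that participant's trials, with the ground-truth
#'   observer path attached as attribute `"observers"`.
#' @export
simulate_participant <- function(config, participant_id) {
  stopifnot(inherits(config, "experiment_config"))
  n_p <- length(config$groups) * config$n_per_group
  if (participant_id < 1 || participant_id > n_p) {
    abort("`participant_id` out of range for this config")
  }
  groups_of <- rep(config$groups, each = config$n_per_group)
  one <- sim_one_participant(config, participant_id, groups_of[participant_id])
  tpb <- config$trials_per_block
  ds <- tibble::tibble(
    participant_id = as.integer(participant_id),
    group = groups_of[participant_id],
    phase = one$phase,
    block = dplyr::case_when(
      grepl("block1$", one$phase) ~ 1L,
      grepl("block2$", one$phase) ~ 2L,
      TRUE ~ NA_integer_
    ),
    trial_index = rep(seq_len(tpb), length(PHASES)),
    x_level = one$x, y_level = one$y,
    pixels = realize_pixels(one$x, config$params),
    freq_hz = realize_frequency(one$y, config$params),
    side = assign_screen_side(one$x, one$y),
    true_category = one$category,
    response = one$response,
    timed_out = one$timed_out
  )
  ds$correct <- !ds$timed_out & !is.na(ds$response) & ds$response == ds$true_category
  ds <- ds[, c(
    "participant_id", "group", "phase", "block", "trial_index",
    "x_level", "y_level", "pixels", "freq_hz", "side",
    "true_category", "response", "correct", "timed_out"
  )]
  attr(ds, "observers") <- observer_truth_table(
    list(one), groups_of[participant_id], ids = participant_id
  )
  ds
}

#' Write / read an experiment dataset as tidy CSV plus JSON sidecars
#'
#' `write_experiment()` writes `trials.csv` (the trial table),
#' `observers.json` (the ground-truth observer specs) and `config.json`
#' (the generating configuration) into `dir`. `read_experiment()` restores
#' the dataset with both attributes re-attached.
#'
#' @param dataset An `experiment_dataset` from [simulate_experiment()].
#' @param dir Directory to write into (created if needed).
#' @return `write_experiment()` returns `dir` invisibly;
#'   `read_experiment()` returns the restored dataset.
#' @export
write_experiment <- function(dataset, dir) {
  stopifnot(is.data.frame(dataset))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(as.data.frame(dataset), file.path(dir, "trials.csv"), row.names = FALSE)
  obs <- attr(dataset, "observers")
  if (!is.null(obs)) {
    jsonlite::write_json(obs, file.path(dir, "observers.json"),
                         digits = NA, na = "null")
  }
  config <- attr(dataset, "config")
  if (!is.null(config)) {
    jsonlite::write_json(config_to_list(config), file.path(dir, "config.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  ds <- tibble::as_tibble(read.csv(file.path(dir, "trials.csv"),
                                   stringsAsFactors = FALSE))
  ds$response[ds$response == ""] <- NA_character_
  obs_path <- file.path(dir, "observers.json")
  if (file.exists(obs_path)) {
    obs <- tibble::as_tibble(jsonlite::read_json(obs_path, simplifyVector = TRUE))
    num_cols <- c("criterion", "criterion_x", "criterion_y", "angle",
                  "offset", "noise_sd", "lapse_rate", "timeout_rate")
    for (col in intersect(num_cols, names(obs))) {
      obs[[col]] <- as.numeric(obs[[col]]) # all-NA columns parse as logical
    }
    obs$participant_id <- as.integer(obs$participant_id)
    attr(ds, "observers") <- obs
  }
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    attr(ds, "config") <- config_from_list(jsonlite::read_json(cfg_path, simplifyVector = TRUE))
  }
  class(ds) <- c("experiment_dataset", class(ds))
  ds
}

config_to_list <- function(config) {
  list(
    n_per_group = config$n_per_group, groups = config$groups,
    trials_per_block = config$trials_per_block,
    structure = list(
      components = as.data.frame(config$struct$components),
      prior_a = config$struct$prior_a
    ),
    realization = unclass(config$params),
    strategy_probs = as.list(config$strategy_probs),
    noise_base = config$noise_base, noise_cv = config$noise_cv,
    phase_noise_mult = as.list(config$phase_noise_mult),
    p_upgrade_random = config$p_upgrade_random,
    p_integrate = config$p_integrate,
    group_noise_mult = as.list(config$group_noise_mult),
    group_switch_prob = as.list(config$group_switch_prob),
    lapse_rate = config$lapse_rate, timeout_rate = config$timeout_rate,
    seed = config$seed
  )
}

config_from_list <- function(lst) {
  experiment_config(
    n_per_group = lst$n_per_group, groups = lst$groups,
    trials_per_block = lst$trials_per_block,
    struct = category_structure(
      lst$structure$components[, c("category", "mu_x", "mu_y", "sigma_x", "sigma_y")],
      prior_a = lst$structure$prior_a
    ),
    params = do.call(realization_params, lst$realization),
    strategy_probs = unlist(lst$strategy_probs),
    noise_base = lst$noise_base, noise_cv = lst$noise_cv,
    phase_noise_mult = unlist(lst$phase_noise_mult),
    p_upgrade_random = lst$p_upgrade_random, p_integrate = lst$p_integrate,
    group_noise_mult = unlist(lst$group_noise_mult),
    group_switch_prob = unlist(lst$group_switch_prob),
    lapse_rate = lst$lapse_rate, timeout_rate = lst$timeout_rate,
    seed = lst$seed
  )
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON configuration file
#'   with the fields of [experiment_config()].
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(lst$structure$components) && !is.data.frame(lst$structure$components)) {
    lst$structure$components <- as.data.frame(lst$structure$components)
  }
  config_from_list(lst)
}

#' Read a category structure and realization constants from a config file
#'
#' Reads a JSON or YAML file with a `components` table (fields `category`,
#' `mu_x`, `mu_y`, `sigma_x`, `sigma_y`), an optional `prior_a`, and an
#' optional `realization` block of [realization_params()] fields. The
#' packaged default (`system.file("extdata", "ii_structure.json", package =
#' "catbound")`) reproduces the default cross-modal structure and stimulus
#' constants exactly.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `structure` (a [category_structure()]) and
#'   `params` (a [realization_params()]).
#' @export
#' @examples
#' cfg <- read_structure_config(
#'   system.file("extdata", "ii_structure.json", package = "catbound")
#' )
#' boundary_accuracy(cfg$structure, linear_boundary(3 * pi / 4, 0))
read_structure_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  comps <- as.data.frame(lst$components)
  list(
    structure = category_structure(comps, prior_a = lst$prior_a %||% 0.5),
    params = do.call(realization_params, as.list(lst$realization %||% list()))
  )
}
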