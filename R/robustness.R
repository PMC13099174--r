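# Controls: stochastic corruption of the encounter seed set (drop / swap /
# add), component ablations, and the placebo co-occurrence experiments.

#' Corrupt an encounter seed set
#'
#' Perturbs the initial membership set before inference, deterministically
#' given the seed (key it by (global seed, encounter_id) via
#' [encounter_seed()] for order-independent reproducibility):
#' * `drop` — each seed identity is independently removed with probability p
#'   (missing/withheld membership);
#' * `swap` — each seed identity is independently marked with probability p
#'   and replaced by a uniform draw from the label universe, rejecting draws
#'   already present in the corrupted set (incorrect membership);
#' * `add` — `k ~ Binomial(n_init, p)` decoy identities drawn uniformly from
#'   the universe excluding current members are inserted (spurious
#'   membership).
#'
#' @param initial character seed identity set.
#' @param mode "drop", "swap" or "add".
#' @param p corruption probability in `[0, 1]`.
#' @param n_init binomial size for `add` (default: number of seeds, floor 1).
#' @param universe full identity universe.
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap for `swap`.
#' @return corrupted character set (unique, subset of the universe).
#' @export
corrupt_seed_set <- function(initial, mode = c("drop", "swap", "add"), p,
                             n_init = max(1L, length(initial)), universe,
                             seed, max_tries = 1000L) {
  mode <- match.arg(mode)
  if (!is.numeric(p) || p < 0 || p > 1) {
    stop_encontext("corruption probability p must lie in [0, 1]",
                   class = "encontext_parameter_error")
  }
  initial <- unique(as.character(initial))
  if (length(setdiff(initial, universe)) > 0L) {
    stop_encontext("seed identities outside the universe",
                   class = "encontext_validation_error")
  }
  withr::with_seed(as.integer(seed), {
    out <- initial
    if (mode == "drop") {
      keep <- stats::runif(length(out)) >= p
      out <- out[keep]
    } else if (mode == "swap") {
      marked <- stats::runif(length(out)) < p
      for (i in which(marked)) {
        replaced <- FALSE
        for (try in seq_len(max_tries)) {
          draw <- sample(universe, 1L)
          if (!(draw %in% out)) {
            out[i] <- draw
            replaced <- TRUE
            break
          }
        }
        if (!replaced) {
          stop_encontext("swap rejection sampling exhausted (universe too small)",
                         class = "encontext_validation_error")
        }
      }
    } else {
      k <- stats::rbinom(1L, size = n_init, prob = p)
      pool <- setdiff(universe, out)
      if (k > 0L) {
        if (length(pool) < k) {
          stop_encontext("universe too small to draw %d decoys", k,
                         class = "encontext_validation_error")
        }
        out <- c(out, sample(pool, k))
      }
    }
    out
  })
}

#' Run one ablation configuration
#'
#' Identical pipeline to headline inference except for the specified weight
#' zeroing and/or initialization override. The ML-only ablation
#' `(alpha, beta, gamma) = (1, 0, 0)` reproduces baseline metrics exactly.
#'
#' @param weights `fusion_weights` with the ablated components zeroed.
#' @param strategy_override optional strategy (e.g. "oracle") replacing the
#'   base config's strategy.
#' @param posteriors,artifacts,config,encounters,baseline_accuracy as in
#'   [evaluate_strategy()].
#' @return a `metrics_report`.
#' @export
run_ablation <- function(weights, posteriors, artifacts, config,
                         encounters = NULL, strategy_override = NULL,
                         baseline_accuracy = NULL) {
  if (!is.null(strategy_override)) {
    config <- inference_config(strategy = strategy_override,
                               n_init = config$n_init, tau = config$tau,
                               seed = config$seed, n_seeds = config$n_seeds)
  }
  evaluate_strategy(posteriors, artifacts, weights, config,
                    encounters = encounters,
                    baseline_accuracy = baseline_accuracy)
}

#' Fixed-weight placebo co-occurrence experiment
#'
#' Builds real and placebo context artifacts from the same training block
#' (the placebo table preserves encounter sizes and per-identity marginals,
#' destroying only the pairing structure) and evaluates the identical
#' inference pipeline under both log-lift matrices at fixed weights.
#'
#' @param train_encounters training-block `encounter_table`.
#' @param test_encounters test-block `encounter_table` (truth for seeding and
#'   coverage).
#' @param posteriors `posterior_set` for the test images.
#' @param seed placebo shuffle / inference seed.
#' @param weights fixed fusion weights (default `(1.0, 0.5, 1.0)`).
#' @param strategies named list of `inference_config`s to evaluate.
#' @param epsilon,clip log-lift parameters.
#' @return data.frame with one row per strategy: real and placebo macro-F1
#'   (and accuracy), and their difference.
#' @export
run_placebo_experiment <- function(train_encounters, test_encounters,
                                   posteriors, seed,
                                   weights = fusion_weights(1.0, 0.5, 1.0),
                                   strategies = NULL,
                                   epsilon = 1e-6, clip = 6) {
  strategies <- strategies %||% list(
    null_set = inference_config("null_set", seed = seed),
    top_unknown = inference_config("top_unknown", n_init = 1, seed = seed),
    random_known = inference_config("random_known", n_init = 1, seed = seed)
  )
  art_real <- build_context(train_encounters, epsilon = epsilon, clip = clip)
  placebo_tbl <- make_placebo_encounters(train_encounters, seed = seed)
  art_placebo <- build_context(placebo_tbl, epsilon = epsilon, clip = clip,
                               allow_any_source = TRUE)
  rows <- lapply(names(strategies), function(nm) {
    cfg <- strategies[[nm]]
    real <- evaluate_strategy(posteriors, art_real, weights, cfg,
                              encounters = test_encounters)
    plac <- evaluate_strategy(posteriors, art_placebo, weights, cfg,
                              encounters = test_encounters)
    data.frame(strategy = nm,
               macro_f1_real = real$macro_f1,
               macro_f1_placebo = plac$macro_f1,
               macro_f1_gap = real$macro_f1 - plac$macro_f1,
               accuracy_real = real$accuracy,
               accuracy_placebo = plac$accuracy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Seed-corruption sensitivity suite
#'
#' One metrics row per (strategy, corruption mode, p): inference with the
#' seed set perturbed by [corrupt_seed_set()], all other settings fixed. The
#' `p = 0` rows reproduce the uncorrupted runs bit-for-bit.
#'
#' @param posteriors,artifacts,encounters as in [evaluate_strategy()].
#' @param weights fixed fusion weights.
#' @param strategies named list of `inference_config`s.
#' @param modes corruption modes to sweep.
#' @param p_grid corruption probabilities (default `{0, 0.1, 0.2, 0.4, 0.6}`).
#' @param n_init binomial size for `add` corruption (default 1).
#' @param seed corruption seed.
#' @return long data.frame (strategy, mode, p, metric columns, sd columns).
#' @export
run_sensitivity_suite <- function(posteriors, artifacts, encounters, weights,
                                  strategies, modes = c("drop", "swap", "add"),
                                  p_grid = c(0, 0.1, 0.2, 0.4, 0.6),
                                  n_init = 1L, seed = 1L) {
  rows <- list()
  for (nm in names(strategies)) {
    cfg <- strategies[[nm]]
    for (mode in modes) {
      for (p in p_grid) {
        corruption <- if (p > 0) {
          list(mode = mode, p = p, n_init = n_init, seed = seed)
        }  # p = 0: no-op, run the uncorrupted pipeline itself
        rep <- evaluate_strategy(posteriors, artifacts, weights, cfg,
                                 encounters = encounters,
                                 corruption = corruption)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = nm, mode = mode, p = p,
          macro_f1 = rep$macro_f1, accuracy = rep$accuracy,
          log_loss = rep$log_loss, brier = rep$brier,
          coverage = rep$coverage,
          macro_f1_sd = rep$sd[["macro_f1"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
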