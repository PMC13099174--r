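# Single-pass encounter-level inference: seed the membership set Y, order
# images easy-first (or shuffled), fuse each image's posterior with priors and
# the co-occurrence term conditioned on the evolving Y, and grow Y when the
# fused confidence clears the threshold tau.

#' Inference configuration
#'
#' @param strategy membership seeding strategy: `"null_set"` (Y starts
#'   empty), `"random_known"` (n ground-truth members, expert-assisted),
#'   `"top_unknown"` (identities of the n most confident baseline
#'   predictions, self-seeding), `"random_unknown"` (n identities sampled
#'   from the baseline argmax predictions occurring in the encounter), or
#'   `"oracle"` (full ground-truth membership).
#' @param n_init number of seed identities for strategies requiring n.
#' @param tau fused-confidence threshold in (0, 1] for adding a prediction to
#'   Y (strict ">", so `tau = 1` disables growth). Default 0.95.
#' @param ordering image processing order: `"confidence_desc"` (easy-first)
#'   or `"shuffled"`; `NULL` selects per strategy (shuffled for
#'   random_unknown, easy-first otherwise).
#' @param seed global seed; per-encounter streams are derived from
#'   (seed, encounter_id) so results do not depend on processing order.
#' @param n_seeds seeds to average for stochastic strategies (`NULL`: 10 for
#'   random_known / random_unknown, 1 otherwise).
#' @return list of class `inference_config`.
#' @export
inference_config <- function(strategy = c("null_set", "random_known",
                                          "top_unknown", "random_unknown",
                                          "oracle"),
                             n_init = 1L, tau = 0.95, ordering = NULL,
                             seed = 1L, n_seeds = NULL) {
  strategy <- match.arg(strategy)
  if (!is.numeric(tau) || tau <= 0 || tau > 1) {
    stop_encontext("tau must lie in (0, 1]", class = "encontext_parameter_error")
  }
  needs_n <- strategy %in% c("random_known", "top_unknown", "random_unknown")
  if (needs_n && n_init < 1L) {
    stop_encontext("n_init must be >= 1 for strategy '%s'", strategy,
                   class = "encontext_parameter_error")
  }
  if (is.null(ordering)) {
    ordering <- if (strategy == "random_unknown") "shuffled" else "confidence_desc"
  }
  ordering <- match.arg(ordering, c("confidence_desc", "shuffled"))
  stochastic <- strategy %in% c("random_known", "random_unknown")
  n_seeds <- n_seeds %||% if (stochastic) 10L else 1L
  structure(list(strategy = strategy, n_init = as.integer(n_init), tau = tau,
                 ordering = ordering, seed = as.integer(seed),
                 n_seeds = as.integer(n_seeds), stochastic = stochastic),
            class = "inference_config")
}

#' Stable per-encounter seed derived from (global seed, encounter id)
#'
#' Polynomial string hash folded with the global seed, kept below 2^31 so it
#' is a valid R seed. Makes every encounter's random stream reproducible
#' independently of processing order.
#'
#' @param seed integer global seed.
#' @param encounter_id encounter identifier string.
#' @return integer seed.
#' @export
encounter_seed <- function(seed, encounter_id) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(as.character(encounter_id))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

#' Seed the encounter membership set
#'
#' Implements the representative initialization strategies (see
#' [inference_config()]). Sampling strategies draw from a stream seeded by
#' (seed, encounter_id).
#'
#' @param strategy strategy name.
#' @param posteriors `posterior_set` restricted to the encounter's images.
#' @param truth character vector of ground-truth members (required for
#'   random_known / oracle).
#' @param n number of seed identities where applicable.
#' @param seed integer seed for the sampling strategies.
#' @return character vector of unique seed identities (possibly empty).
#' @export
initialize_context <- function(strategy, posteriors, truth = NULL, n = 1L,
                               seed = 1L) {
  switch(strategy,
    null_set = character(0),
    oracle = {
      if (is.null(truth)) {
        stop_encontext("oracle initialization requires ground truth",
                       class = "encontext_parameter_error")
      }
      unique(truth)
    },
    random_known = {
      if (is.null(truth) || length(truth) == 0L) {
        stop_encontext("random_known initialization requires ground truth",
                       class = "encontext_parameter_error")
      }
      truth <- unique(truth)
      k <- min(n, length(truth))
      withr::with_seed(seed, sample(truth, k))
    },
    top_unknown = {
      conf <- apply(posteriors$prob, 1, max)
      preds <- apply(posteriors$prob, 1, argmax_identity)
      preds <- preds[order(-conf, posteriors$image_id)]
      utils::head(unique(preds), n)
    },
    random_unknown = {
      pool <- unique(apply(posteriors$prob, 1, argmax_identity))
      k <- min(n, length(pool))
      withr::with_seed(seed, sample(pool, k))
    },
    stop_encontext("unknown strategy '%s'", strategy,
                   class = "encontext_parameter_error")
  )
}

#' Image processing order within an encounter
#'
#' `confidence_desc` mimics the expert easy-first workflow: descending
#' baseline confidence `max_y P_ML(y|x)`, ties broken by image id.
#' `shuffled` is a seeded uniform permutation.
#'
#' @param posteriors `posterior_set` for the encounter (>= 1 image).
#' @param mode `"confidence_desc"` or `"shuffled"`.
#' @param seed integer seed (shuffled mode).
#' @return integer permutation of image indices.
#' @export
order_images <- function(posteriors, mode = c("confidence_desc", "shuffled"),
                         seed = 1L) {
  mode <- match.arg(mode)
  m <- n_images(posteriors)
  if (mode == "confidence_desc") {
    conf <- apply(posteriors$prob, 1, max)
    order(-conf, posteriors$image_id)
  } else {
    withr::with_seed(seed, sample.int(m))
  }
}

#' Coverage of the inferred membership set
#'
#' Fraction of ground-truth encounter members contained in the final inferred
#' set Y.
#'
#' @param final_members inferred identity set.
#' @param true_members ground-truth member set (non-empty).
#' @return real in `[0, 1]`.
#' @export
compute_coverage <- function(final_members, true_members) {
  if (length(true_members) == 0L) {
    stop_encontext("coverage undefined for empty ground truth",
                   class = "encontext_validation_error")
  }
  true_members <- unique(true_members)
  length(intersect(unique(final_members), true_members)) / length(true_members)
}

#' Run single-pass inference on one encounter
#'
#' Seeds Y by the configured strategy (seeded identities condition the
#' context term immediately), processes each image exactly once in the chosen
#' order, records the fused posterior and prediction, and adds the predicted
#' identity to Y when its fused probability strictly exceeds `tau`. No
#' re-processing of earlier images (single pass, to limit reinforcement).
#'
#' @param encounter_id the encounter to process.
#' @param posteriors a `posterior_set` (full set or encounter subset).
#' @param artifacts train-derived `context_artifacts`.
#' @param weights fusion weight triple.
#' @param config an `inference_config`.
#' @param truth optional ground-truth member set (needed by expert-seeded
#'   strategies and for coverage).
#' @param init_members optional explicit seed set overriding the strategy
#'   (used by the seed-corruption suite).
#' @return list of class `encounter_result`: `image_id`, `fused` (matrix),
#'   `predicted`, `baseline` (raw argmax), `members_init`, `members_final`,
#'   `coverage` (NA without truth), `order_used`.
#' @export
run_encounter <- function(encounter_id, posteriors, artifacts, weights,
                          config, truth = NULL, init_members = NULL) {
  w <- as_fusion_weights(weights)
  ids <- artifacts$identities
  enc_post <- posterior_subset(posteriors, encounter_id)
  if (!identical(colnames(enc_post$prob), ids)) {
    stop_encontext("posterior universe does not match the artifacts",
                   class = "encontext_validation_error")
  }
  eseed <- encounter_seed(config$seed, encounter_id)
  m <- n_images(enc_post)

  members <- init_members %||%
    initialize_context(config$strategy, enc_post, truth = truth,
                       n = config$n_init, seed = eseed)
  members <- unique(as.character(members))
  members_init <- members

  if (m == 0L) {
    return(structure(list(image_id = character(0),
                          fused = matrix(numeric(0), 0, length(ids),
                                         dimnames = list(NULL, ids)),
                          predicted = character(0), baseline = character(0),
                          members_init = members_init, members_final = members,
                          coverage = if (!is.null(truth)) compute_coverage(members, truth) else NA_real_,
                          order_used = integer(0)),
                     class = "encounter_result"))
  }

  ord <- order_images(enc_post, config$ordering, seed = eseed)
  fused <- matrix(NA_real_, m, length(ids),
                  dimnames = list(enc_post$image_id[ord], ids))
  predicted <- character(m)
  baseline <- character(m)
  for (k in seq_len(m)) {
    i <- ord[k]
    p <- enc_post$prob[i, ]
    f <- fuse_posterior(p, artifacts$global_prior, artifacts$loglift,
                        members, w)
    fused[k, ] <- f
    predicted[k] <- argmax_identity(f)
    baseline[k] <- argmax_identity(p)
    if (f[[predicted[k]]] > config$tau && !(predicted[k] %in% members)) {
      members <- c(members, predicted[k])
    }
  }
  structure(list(image_id = enc_post$image_id[ord], fused = fused,
                 predicted = predicted, baseline = baseline,
                 members_init = members_init, members_final = members,
                 coverage = if (!is.null(truth)) compute_coverage(members, truth) else NA_real_,
                 order_used = ord),
            class = "encounter_result")
}

#' Run inference over every encounter of a posterior set
#'
#' @param encounters `encounter_table` holding ground-truth membership of the
#'   evaluated encounters (used for expert seeding and coverage); may be
#'   `NULL` for fully automated strategies, in which case coverage is NA.
#' @inheritParams run_encounter
#' @param corruption optional list(mode, p, n_init, seed) — after seeding,
#'   each encounter's seed set is perturbed by [corrupt_seed_set()] keyed by
#'   (corruption seed, encounter_id).
#' @return list of class `inference_run`: `results` (per-encounter), plus
#'   flattened `image_id`, `predicted`, `baseline`, `truth`, `fused`,
#'   `coverage` (mean over encounters with truth).
#' @export
run_inference <- function(posteriors, artifacts, weights, config,
                          encounters = NULL, corruption = NULL) {
  enc_ids <- unique(posteriors$encounter_id)
  results <- lapply(enc_ids, function(eid) {
    truth <- if (!is.null(encounters)) encounter_members(encounters, eid)
    init <- NULL
    if (!is.null(corruption)) {
      eseed <- encounter_seed(config$seed, eid)
      seeded <- initialize_context(config$strategy,
                                   posterior_subset(posteriors, eid),
                                   truth = truth, n = config$n_init,
                                   seed = eseed)
      init <- corrupt_seed_set(seeded, mode = corruption$mode,
                               p = corruption$p,
                               n_init = corruption$n_init %||% config$n_init,
                               universe = artifacts$identities,
                               seed = encounter_seed(corruption$seed, eid))
    }
    run_encounter(eid, posteriors, artifacts, weights, config,
                  truth = truth, init_members = init)
  })
  names(results) <- enc_ids
  image_id <- unlist(lapply(results, `[[`, "image_id"), use.names = FALSE)
  fused <- do.call(rbind, lapply(results, `[[`, "fused"))
  truth_map <- stats::setNames(posteriors$true_identity, posteriors$image_id)
  cov <- vapply(results, `[[`, numeric(1), "coverage")
  structure(list(results = results,
                 image_id = image_id,
                 predicted = unlist(lapply(results, `[[`, "predicted"), use.names = FALSE),
                 baseline = unlist(lapply(results, `[[`, "baseline"), use.names = FALSE),
                 truth = unname(truth_map[image_id]),
                 fused = fused,
                 coverage = if (all(is.na(cov))) NA_real_ else mean(cov, na.rm = TRUE)),
            class = "inference_run")
}

#' Evaluate one strategy: inference + scoring, averaged over seeds
#'
#' Runs [run_inference()] with `config$n_seeds` consecutive global seeds
#' (stochastic strategies) or once (deterministic), scores each run against
#' the image-level truth, and aggregates mean and SD.
#'
#' @inheritParams run_inference
#' @param baseline_accuracy optional ML-only reference accuracy for rAER.
#' @return a `metrics_report` (mean over seeds, SD fields populated when
#'   `n_seeds > 1`).
#' @export
evaluate_strategy <- function(posteriors, artifacts, weights, config,
                              encounters = NULL, corruption = NULL,
                              baseline_accuracy = NULL) {
  w <- as_fusion_weights(weights)
  # with gamma = 0 the membership set cannot influence any prediction, so
  # stochastic seeding is irrelevant: one seed suffices (identical results)
  n_seeds <- if (config$stochastic && (w[["gamma"]] > 0 || !is.null(corruption)))
    config$n_seeds else 1L
  reports <- lapply(seq_len(n_seeds), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    run <- run_inference(posteriors, artifacts, weights, cfg,
                         encounters = encounters, corruption = corruption)
    rep <- score_predictions(run$predicted, run$fused, run$truth)
    rep$coverage <- run$coverage
    if (!is.null(baseline_accuracy)) {
      rep$raer <- raer(baseline_accuracy, rep$accuracy)
    }
    rep
  })
  aggregate_seeds(reports)
}
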