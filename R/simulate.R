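# Synthetic encounter archives and classifier posteriors with the structure
# the fusion method assumes: matriline-like social units that generate
# non-random co-occurrence, heterogeneous per-individual sighting rates,
# uncertain-ID flags, and softmax posteriors with controllable cross-unit
# confusability. Everything is deterministic under (config, seed).

#' Simulate a closed population partitioned into social units
#'
#' Individuals get catalog-style labels ("I01", "I02", ...), are dealt
#' round-robin into `n_units` units (every unit non-empty), and receive a
#' log-normal sighting-rate multiplier capturing heterogeneous encounter
#' frequencies (`rate_sdlog = 0` makes all individuals equally sighted).
#' Rates are normalized to mean 1.
#'
#' @param n_individuals population size.
#' @param n_units number of social units (<= n_individuals).
#' @param rate_meanlog,rate_sdlog log-normal parameters of the sighting-rate
#'   multipliers (defaults: meanlog 0, sdlog 0.5).
#' @param seed integer seed.
#' @return list of class `sim_population`: `identities`, `unit` (named unit
#'   index per identity), `rate` (named multiplier per identity).
#' @export
simulate_population <- function(n_individuals = 20L, n_units = 5L,
                                rate_meanlog = 0, rate_sdlog = 0.5, seed = 1L) {
  if (n_units > n_individuals || n_units < 1L || n_individuals < 1L) {
    stop_encontext("need 1 <= n_units <= n_individuals",
                   class = "encontext_parameter_error")
  }
  if (rate_sdlog < 0) {
    stop_encontext("rate_sdlog must be >= 0", class = "encontext_parameter_error")
  }
  ids <- sprintf("I%02d", seq_len(n_individuals))
  withr::with_seed(as.integer(seed), {
    unit <- stats::setNames(rep(seq_len(n_units), length.out = n_individuals)[
      sample.int(n_individuals)], ids)
    rate <- if (rate_sdlog == 0) {
      stats::setNames(rep(1, n_individuals), ids)
    } else {
      r <- stats::rlnorm(n_individuals, rate_meanlog, rate_sdlog)
      stats::setNames(r / mean(r), ids)
    }
  })
  structure(list(identities = ids, unit = unit, rate = rate,
                 n_units = as.integer(n_units)),
            class = "sim_population")
}

#' Simulate an encounter archive from a unit-structured population
#'
#' Each encounter picks a focal unit uniformly; unit-mates join independently
#' with probability `within_unit_join_prob` and non-mates with
#' `cross_unit_join_prob`, both scaled by the individual sighting-rate
#' multiplier (clamped to 1). Members are flagged uncertain with probability
#' `uncertain_flag_prob`. Empty draws are retried (bounded); encounter order
#' is the generation index.
#'
#' @param population a `sim_population`.
#' @param n_encounters number of encounters (>= 1).
#' @param within_unit_join_prob,cross_unit_join_prob join probabilities
#'   (defaults 0.9 / 0.05).
#' @param uncertain_flag_prob probability a member is recorded as uncertain
#'   (default 0.1).
#' @param seed integer seed.
#' @param source split tag for the resulting table.
#' @param max_retries retry cap per encounter before erroring.
#' @return an `encounter_table` over the full population universe.
#' @export
simulate_encounters <- function(population, n_encounters,
                                within_unit_join_prob = 0.9,
                                cross_unit_join_prob = 0.05,
                                uncertain_flag_prob = 0.1,
                                seed = 1L, source = "unspecified",
                                max_retries = 100L) {
  if (n_encounters < 1L) {
    stop_encontext("n_encounters must be >= 1", class = "encontext_parameter_error")
  }
  probs <- c(within_unit_join_prob, cross_unit_join_prob, uncertain_flag_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_encontext("join/flag probabilities must lie in [0, 1]",
                   class = "encontext_parameter_error")
  }
  ids <- population$identities
  withr::with_seed(as.integer(seed), {
    rows <- vector("list", n_encounters)
    for (e in seq_len(n_encounters)) {
      members <- character(0)
      for (try in seq_len(max_retries)) {
        focal <- sample.int(population$n_units, 1L)
        p_join <- ifelse(population$unit[ids] == focal,
                         within_unit_join_prob, cross_unit_join_prob)
        p_join <- pmin(1, p_join * population$rate[ids])
        members <- ids[stats::runif(length(ids)) < p_join]
        if (length(members) > 0L) break
      }
      if (length(members) == 0L) {
        stop_encontext("simulated encounters systematically empty",
                       class = "encontext_validation_error")
      }
      uncertain <- stats::runif(length(members)) < uncertain_flag_prob
      rows[[e]] <- data.frame(
        encounter_id = sprintf("E%05d", e), order = e - 1L,
        identity = members,
        certainty = ifelse(uncertain, "uncertain", "confirmed"),
        stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  encounter_table(df$encounter_id, df$order, df$identity, df$certainty,
                  identities = ids, source = source)
}

#' Designate confusable (lookalike) identity pairs across units
#'
#' Pairs individuals from different units so that visual ambiguity occurs
#' exactly where co-occurrence context is informative. Pairs are disjoint.
#'
#' @param population a `sim_population`.
#' @param n_pairs number of lookalike pairs.
#' @param seed integer seed.
#' @return 2-column character matrix, one row per pair.
#' @export
make_confusable_pairs <- function(population, n_pairs = 5L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    pool <- sample(population$identities)
    pairs <- matrix(character(0), 0, 2)
    while (nrow(pairs) < n_pairs && length(pool) >= 2L) {
      a <- pool[1]
      partner <- pool[population$unit[pool] != population$unit[a]][1]
      if (is.na(partner)) break
      pairs <- rbind(pairs, c(a, partner))
      pool <- setdiff(pool, c(a, partner))
    }
  })
  if (nrow(pairs) < n_pairs) {
    stop_encontext("could not form %d cross-unit pairs", n_pairs,
                   class = "encontext_parameter_error")
  }
  pairs
}

#' Posterior generator configuration
#'
#' @param base_correct_mass probability mass placed on the true identity of a
#'   typical image before noise (default 0.55 for confusable individuals —
#'   the ambiguous regime the method targets).
#' @param confusable_mass mass placed on the designated lookalike (default
#'   0.40); identities without a lookalike absorb this mass into the truth.
#' @param confusable_pairs 2-column matrix of lookalike pairs (or NULL).
#' @param noise_temperature SD of Gaussian perturbation added to the log
#'   probabilities before re-normalization (0 = noiseless).
#' @param images_per_member_mean Poisson mean; each member yields
#'   `Poisson(mean) + 1` images.
#' @return list of class `posterior_config`.
#' @export
posterior_config <- function(base_correct_mass = 0.55, confusable_mass = 0.40,
                             confusable_pairs = NULL, noise_temperature = 0.5,
                             images_per_member_mean = 2) {
  if (base_correct_mass <= 0 || base_correct_mass > 1) {
    stop_encontext("base_correct_mass must lie in (0, 1]",
                   class = "encontext_parameter_error")
  }
  if (confusable_mass < 0 || base_correct_mass + confusable_mass > 1) {
    stop_encontext("base_correct_mass + confusable_mass must not exceed 1",
                   class = "encontext_parameter_error")
  }
  if (noise_temperature < 0 || images_per_member_mean <= 0) {
    stop_encontext("invalid noise/image-count parameters",
                   class = "encontext_parameter_error")
  }
  structure(list(base_correct_mass = base_correct_mass,
                 confusable_mass = confusable_mass,
                 confusable_pairs = confusable_pairs,
                 noise_temperature = noise_temperature,
                 images_per_member_mean = images_per_member_mean),
            class = "posterior_config")
}

#' Simulate per-image classifier posteriors for an encounter archive
#'
#' For every encounter member, `Poisson(images_per_member_mean) + 1` images.
#' Each image's base distribution places `base_correct_mass` on the truth,
#' `confusable_mass` on its designated lookalike (if any, else on the truth),
#' and the remainder uniformly over the other identities; log probabilities
#' are then perturbed with Gaussian noise of SD `noise_temperature` and
#' re-normalized by softmax.
#'
#' @param encounters an `encounter_table`.
#' @param config a `posterior_config`.
#' @param seed integer seed.
#' @return a `posterior_set` with `true_identity` filled.
#' @export
simulate_posteriors <- function(encounters, config = posterior_config(),
                                seed = 1L) {
  ids <- identity_universe(encounters)
  n <- length(ids)
  lookalike <- stats::setNames(rep(NA_character_, n), ids)
  if (!is.null(config$confusable_pairs)) {
    for (r in seq_len(nrow(config$confusable_pairs))) {
      a <- config$confusable_pairs[r, 1]; b <- config$confusable_pairs[r, 2]
      lookalike[a] <- b
      lookalike[b] <- a
    }
  }
  base_rows <- lapply(ids, function(id) {
    p <- numeric(n)
    names(p) <- ids
    if (is.na(lookalike[id])) {
      p[id] <- config$base_correct_mass + config$confusable_mass
    } else {
      p[id] <- config$base_correct_mass
      p[lookalike[id]] <- config$confusable_mass
    }
    rest <- 1 - sum(p)
    others <- p == 0
    if (any(others)) p[others] <- rest / sum(others)
    p
  })
  names(base_rows) <- ids

  withr::with_seed(as.integer(seed), {
    img_rows <- list()
    meta <- list()
    counter <- 0L
    for (eid in encounter_ids(encounters)) {
      for (member in encounter_members(encounters, eid)) {
        k <- stats::rpois(1L, config$images_per_member_mean) + 1L
        for (j in seq_len(k)) {
          counter <- counter + 1L
          logp <- log(base_rows[[member]])
          if (config$noise_temperature > 0) {
            logp <- logp + stats::rnorm(n, 0, config$noise_temperature)
          }
          p <- exp(logp - logsumexp(logp))
          img_rows[[counter]] <- p
          meta[[counter]] <- c(sprintf("IMG%06d", counter), eid, member)
        }
      }
    }
  })
  meta <- do.call(rbind, meta)
  prob <- do.call(rbind, img_rows)
  colnames(prob) <- ids
  posterior_set(meta[, 1], meta[, 2], prob, true_identity = meta[, 3],
                identities = ids)
}

#' Simulate a complete archive: population, encounters, unit map
#'
#' Convenience wrapper used by the tests, the acceptance experiments, and the
#' CLI `simulate` command. Logs (but does not assert) the mean encounter
#' size, whose realistic range for the target systems is roughly 3-6.
#'
#' @param n_individuals,n_units,rate_meanlog,rate_sdlog population settings.
#' @param n_encounters archive length.
#' @param within_unit_join_prob,cross_unit_join_prob,uncertain_flag_prob
#'   encounter settings.
#' @param seed integer master seed (population, encounters and pairs derive
#'   sub-seeds from it).
#' @param n_confusable_pairs lookalike pairs to designate (0 for none).
#' @param quiet suppress the calibration message.
#' @return list of class `sim_archive`: `population`, `encounters`,
#'   `confusable_pairs`.
#' @export
simulate_archive <- function(n_individuals = 20L, n_units = 5L,
                             n_encounters = 500L,
                             within_unit_join_prob = 0.9,
                             cross_unit_join_prob = 0.05,
                             uncertain_flag_prob = 0.1,
                             rate_meanlog = 0, rate_sdlog = 0.5,
                             n_confusable_pairs = 5L, seed = 1L,
                             quiet = FALSE) {
  pop <- simulate_population(n_individuals, n_units, rate_meanlog, rate_sdlog,
                             seed = seed)
  enc <- simulate_encounters(pop, n_encounters,
                             within_unit_join_prob = within_unit_join_prob,
                             cross_unit_join_prob = cross_unit_join_prob,
                             uncertain_flag_prob = uncertain_flag_prob,
                             seed = seed + 1L)
  pairs <- if (n_confusable_pairs > 0L) {
    make_confusable_pairs(pop, n_confusable_pairs, seed = seed + 2L)
  }
  if (!quiet) {
    mean_size <- nrow(enc) / n_encounters(enc)
    message(sprintf("simulated archive: mean encounter size %.2f", mean_size))
  }
  structure(list(population = pop, encounters = enc,
                 confusable_pairs = pairs),
            class = "sim_archive")
}
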