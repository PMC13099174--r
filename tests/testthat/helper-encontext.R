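# Shared fixtures, built in code.

# Four-encounter toy archive: E1={A,B}, E2={A,B?}, E3={A?,C}, E4={C}
# ("?" marks an uncertain sighting, weight 0.5).
toy_encounters <- function(source = "train") {
  encounter_table(
    encounter_id = c("E1", "E1", "E2", "E2", "E3", "E3", "E4"),
    order = c(0, 0, 1, 1, 2, 2, 3),
    identity = c("A", "B", "A", "B", "A", "C", "C"),
    certainty = c("confirmed", "confirmed", "confirmed", "?", "?",
                  "confirmed", "confirmed"),
    source = source)
}

toy_artifacts <- function() build_context(toy_encounters())

# Posterior set over an explicit universe from a plain matrix.
make_post <- function(prob, encounter_id = "E1", truth = NULL,
                      image_id = sprintf("img%02d", seq_len(nrow(prob)))) {
  posterior_set(image_id,
                rep(encounter_id, length.out = nrow(prob)),
                prob, true_identity = truth)
}

# Independent fusion oracle: exponentiate and normalize term by term, no
# log-space shortcuts. Mirrors the documented clamps (1e-12 on the image
# probability, +1e-6 on the prior).
brute_fuse <- function(posterior, priors, loglift, members, w) {
  ids <- rownames(loglift)
  unnorm <- vapply(ids, function(y) {
    v <- max(posterior[[y]], 1e-12)^w[1] * (priors[[y]] + 1e-6)^w[2]
    if (length(members) > 0) {
      a <- mean(vapply(members, function(i) loglift[i, y], numeric(1)))
      v <- v * exp(w[3] * a)
    }
    v
  }, numeric(1))
  unnorm / sum(unnorm)
}

# Small synthetic world shared by inference-level tests: 12 ids, 3 units,
# strong unit structure, confusable cross-unit pairs.
small_world <- function(seed = 42, n_encounters = 300) {
  sim <- simulate_archive(n_individuals = 12, n_units = 3,
                          n_encounters = n_encounters,
                          within_unit_join_prob = 0.9,
                          cross_unit_join_prob = 0.02,
                          rate_sdlog = 0, n_confusable_pairs = 3,
                          seed = seed, quiet = TRUE)
  split <- temporal_split(sim$encounters, t = 0.7)
  train <- split_block(sim$encounters, split, "train")
  test <- split_block(sim$encounters, split, "test")
  post <- simulate_posteriors(
    test, posterior_config(confusable_pairs = sim$confusable_pairs),
    seed = seed + 10)
  list(sim = sim, split = split, train = train, test = test, post = post,
       artifacts = build_context(train))
}
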