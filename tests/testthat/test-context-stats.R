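test_that("global priors: weighted hand tally on the toy archive", {
  pr <- compute_global_priors(toy_encounters())
  # n_A = 1 + 1 + 0.5 = 2.5 over |E| = 4
  expect_equal(unname(pr[c("A", "B", "C")]), c(0.625, 0.375, 0.5))

  # identity confirmed in every encounter -> prior 1; absent -> 0
  enc <- encounter_table(c("E1", "E2"), c(0, 1), c("A", "A"),
                         rep("confirmed", 2), identities = c("A", "Z"),
                         source = "train")
  pr2 <- compute_global_priors(enc)
  expect_equal(unname(pr2[c("A", "Z")]), c(1, 0))

  expect_error(compute_global_priors(toy_encounters(source = "test")),
               class = "encontext_leakage_error")
})

test_that("pair counts: product weighting, symmetry, diagonal", {
  pc <- compute_pair_counts(toy_encounters())
  expect_equal(pc["A", "B"], 1.5)   # 1*1 + 1*0.5
  expect_equal(pc["A", "C"], 0.5)   # 0.5*1
  expect_equal(pc["B", "C"], 0)
  expect_identical(pc, t(pc))
  # diagonal carries n_i
  expect_equal(diag(pc), c(A = 2.5, B = 1.5, C = 2))

  # both members uncertain -> the pair gains 0.25
  enc <- encounter_table(c("E1", "E1"), c(0, 0), c("A", "B"), c("?", "?"),
                         source = "train")
  expect_equal(compute_pair_counts(enc)["A", "B"], 0.25)

  # singleton encounter contributes to no off-diagonal cell
  single <- encounter_table("E1", 0, "A", "confirmed",
                            identities = c("A", "B"), source = "train")
  pcs <- compute_pair_counts(single)
  expect_equal(pcs["A", "B"], 0)
  expect_equal(pcs["A", "A"], 1)
})

test_that("log lift: formula, clipping, independence, parameter errors", {
  enc <- toy_encounters()
  pr <- compute_global_priors(enc)
  pc <- compute_pair_counts(enc)
  ll <- compute_log_lift(pc, pr, 4)
  # direct evaluation of the printed formula (epsilon negligible)
  expect_equal(ll["A", "B"], log(0.375 / (0.625 * 0.375)), tolerance = 1e-4)
  expect_equal(ll["A", "C"], log(0.4), tolerance = 1e-4)
  # never-co-occurring pair: raw lift ~ log(1e-6 / 0.1875) ~ -12.1, clipped
  expect_equal(ll["B", "C"], -6)
  expect_true(max(abs(ll)) <= 6)
  expect_identical(ll, t(ll))
  # self-association is neutral (see vignette: placebo-compatibility)
  expect_equal(unname(diag(ll)), rep(0, 3))

  # independence: P(i,j) = P(i) P(j) exactly -> lift ~ 0
  pr0 <- c(A = 0.5, B = 0.4)
  pc0 <- matrix(c(0.5 * 100, 0.2 * 100, 0.2 * 100, 0.4 * 100), 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  ll0 <- compute_log_lift(pc0, pr0, 100)
  expect_equal(ll0["A", "B"], 0, tolerance = 1e-4)

  expect_error(compute_log_lift(pc, pr, 4, epsilon = 0),
               class = "encontext_parameter_error")
  expect_error(compute_log_lift(pc, pr, 4, clip = -1),
               class = "encontext_parameter_error")
})

test_that("placebo shuffle preserves sizes and marginals exactly", {
  enc <- small_world()$train
  plac <- make_placebo_encounters(enc, seed = 7)
  expect_equal(n_encounters(plac), n_encounters(enc))
  # encounter-size multiset preserved exactly
  expect_equal(sort(table(plac$encounter_id)), sort(table(enc$encounter_id)),
               ignore_attr = TRUE)
  # per-identity weighted counts identical to machine precision
  w_real <- tapply(enc$weight, enc$identity, sum)
  w_plac <- tapply(plac$weight, plac$identity, sum)
  expect_equal(w_plac[names(w_real)], w_real, tolerance = 1e-15)
  # hence global priors bit-identical
  expect_identical(compute_global_priors(plac, allow_any_source = TRUE),
                   compute_global_priors(enc))
  # within-encounter uniqueness holds
  expect_false(any(duplicated(paste(plac$encounter_id, plac$identity))))
  # deterministic given seed, different across seeds
  expect_identical(as.data.frame(make_placebo_encounters(enc, seed = 7)),
                   as.data.frame(plac))
  expect_false(identical(as.data.frame(make_placebo_encounters(enc, seed = 8)),
                         as.data.frame(plac)))
})

test_that("placebo of two disjoint pairs is a perfect pairing of the tokens", {
  enc <- encounter_table(c("E1", "E1", "E2", "E2"), c(0, 0, 1, 1),
                         c("A", "B", "C", "D"), rep("confirmed", 4),
                         source = "train")
  for (seed in 1:10) {
    plac <- make_placebo_encounters(enc, seed = seed)
    sizes <- table(plac$encounter_id)
    expect_equal(unname(sort(sizes)), c(2L, 2L), ignore_attr = TRUE)
    expect_equal(sort(plac$identity), c("A", "B", "C", "D"))
    expect_false(any(duplicated(paste(plac$encounter_id, plac$identity))))
  }
})

test_that("graph diagnostics: density, mean degree, support fraction", {
  ids <- c("A", "B", "C")
  pc <- matrix(0, 3, 3, dimnames = list(ids, ids))
  pc["A", "B"] <- pc["B", "A"] <- 6
  pc["A", "C"] <- pc["C", "A"] <- 1
  d <- graph_diagnostics(pc, support_threshold = 5)
  expect_equal(d$density, 2 / 3)
  expect_equal(d$mean_degree, (2 + 1 + 1) / 3)
  expect_equal(d$frac_dyads_at_support, 1 / 3)

  full <- matrix(1, 3, 3, dimnames = list(ids, ids))
  expect_equal(graph_diagnostics(full)$density, 1)
  none <- matrix(0, 3, 3, dimnames = list(ids, ids))
  expect_equal(graph_diagnostics(none)$density, 0)
  expect_equal(graph_diagnostics(none)$mean_degree, 0)
  expect_error(graph_diagnostics(matrix(0, 1, 1)),
               class = "encontext_validation_error")
})

test_that("independence null: log lift vanishes without unit structure", {
  # members drawn independently with fixed marginals (within == cross);
  # mean off-diagonal lift over supported dyads approaches 0
  pop <- simulate_population(20, 5, rate_sdlog = 0, seed = 3)
  means <- vapply(1:3, function(s) {
    enc <- simulate_encounters(pop, 5000, within_unit_join_prob = 0.2,
                               cross_unit_join_prob = 0.2, seed = s,
                               source = "train")
    art <- build_context(enc)
    off <- upper.tri(art$loglift)
    supported <- off & art$pair_counts >= 5
    mean(art$loglift[supported])
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.1)
})
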