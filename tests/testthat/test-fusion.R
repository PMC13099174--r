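test_that("association score: empty set, single member, mean", {
  art <- toy_artifacts()
  ll <- art$loglift
  # empty membership contributes exactly 0 for every candidate
  expect_equal(unname(association_matrix(members = character(0), loglift = ll)),
               rep(0, 3))
  # single member: the raw lift entry
  expect_equal(association_score("B", "A", ll), ll["A", "B"])
  # mean over members
  expect_equal(association_score("C", c("A", "B"), ll),
               mean(c(ll["A", "C"], ll["B", "C"])))
  expect_error(association_score("C", "Z", ll),
               class = "encontext_validation_error")
})

test_that("association score on the spec-style toy lift", {
  ids <- c("A", "B", "C")
  ll <- matrix(0, 3, 3, dimnames = list(ids, ids))
  ll["A", "C"] <- ll["C", "A"] <- -0.9163
  ll["B", "C"] <- ll["C", "B"] <- -6
  expect_equal(association_score("C", c("A", "B"), ll), -3.45815)
})

test_that("fused posterior: identity configuration and two-candidate case", {
  ids <- c("A", "B", "C")
  ll <- matrix(0, 3, 3, dimnames = list(ids, ids))
  ll["C", "A"] <- ll["A", "C"] <- 1
  ll["C", "B"] <- ll["B", "C"] <- -1
  priors <- c(A = 0.3, B = 0.3, C = 0.4)

  p <- c(A = 0.6, B = 0.4, C = 0)
  # alpha = 1, beta = gamma = 0: fused equals the raw posterior
  f0 <- fuse_posterior(p, priors, ll, c("C"), fusion_weights(1, 0, 0))
  expect_equal(unname(f0), unname(p), tolerance = 1e-9)

  # beta = 0, Y = {C}, alpha = gamma = 1: hand-derived log-sum-exp value
  f1 <- fuse_posterior(p, priors, ll, "C", fusion_weights(1, 0, 1))
  expect_equal(unname(f1[c("A", "B")]),
               c(0.6 * exp(1), 0.4 * exp(-1)) / (0.6 * exp(1) + 0.4 * exp(-1)),
               tolerance = 1e-6)
  expect_equal(round(unname(f1["A"]), 4), 0.9172)

  # empty Y with beta = 0: fused == P_ML for any gamma
  f2 <- fuse_posterior(p, priors, ll, character(0), fusion_weights(1, 0, 7))
  expect_equal(unname(f2), unname(p), tolerance = 1e-9)

  expect_error(fuse_posterior(p, priors, ll, "C", c(1, -1, 0)),
               class = "encontext_parameter_error")
})

test_that("fusion invariants: normalization, ranking, monotone context", {
  art <- small_world(seed = 5, n_encounters = 120)$artifacts
  ids <- art$identities
  withr::with_seed(99, {
    for (rep in 1:25) {
      x <- stats::rexp(length(ids))
      p <- stats::setNames(x / sum(x), ids)
      members <- sample(ids, sample(0:3, 1))
      w <- fusion_weights(stats::runif(1, 0, 2), stats::runif(1, 0, 2),
                          stats::runif(1, 0, 2))
      f <- fuse_posterior(p, art$global_prior, art$loglift, members, w)
      expect_equal(sum(f), 1, tolerance = 1e-9)
      expect_true(all(f >= 0))
      # ranking preserved at beta = gamma = 0, alpha > 0
      f_id <- fuse_posterior(p, art$global_prior, art$loglift, members,
                             fusion_weights(1.7, 0, 0))
      expect_equal(order(f_id), order(p))
    }
  })

  # monotone context: increasing gamma raises the probability ratio of the
  # better-associated candidate (two-candidate instance)
  ids2 <- c("A", "B", "C")
  ll <- matrix(0, 3, 3, dimnames = list(ids2, ids2))
  ll["C", "A"] <- ll["A", "C"] <- 1
  ll["C", "B"] <- ll["B", "C"] <- -1
  p <- c(A = 0.3, B = 0.6, C = 0.1)
  ratios <- vapply(c(0, 0.5, 1, 2), function(g) {
    f <- fuse_posterior(p, c(A = 1, B = 1, C = 1) / 3, ll, "C",
                        fusion_weights(1, 0, g))
    f[["A"]] / f[["B"]]
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("oracle equivalence: brute-force term-by-term fusion to 1e-12", {
  art <- toy_artifacts()  # N = 3
  withr::with_seed(7, {
    for (rep in 1:50) {
      x <- stats::rexp(3)
      p <- stats::setNames(x / sum(x), art$identities)
      members <- sample(art$identities, sample(0:2, 1))
      w <- c(stats::runif(1, 0, 2), stats::runif(1, 0, 2), stats::runif(1, 0, 2))
      f <- fuse_posterior(p, art$global_prior, art$loglift, members,
                          fusion_weights(w[1], w[2], w[3]))
      expect_equal(unname(f),
                   unname(brute_fuse(p, art$global_prior, art$loglift,
                                     members, w)),
                   tolerance = 1e-12)
    }
  })
})

test_that("zero-prior and zero-posterior safety", {
  ids <- c("A", "B")
  ll <- matrix(0, 2, 2, dimnames = list(ids, ids))
  # unseen identity (prior 0) is floored, not -Inf
  f <- fuse_posterior(c(A = 0.5, B = 0.5), c(A = 1, B = 0), ll,
                      character(0), fusion_weights(1, 1, 0))
  expect_true(all(is.finite(f)) && f[["B"]] > 0)
  # an image probability serialized as exactly 0 is clamped, not -Inf
  f2 <- fuse_posterior(c(A = 1, B = 0), c(A = 0.5, B = 0.5), ll,
                       character(0), fusion_weights(1, 0, 0))
  expect_true(all(is.finite(f2)))
  expect_equal(f2[["A"]], 1, tolerance = 1e-9)
  # no evidence at all: uniform over the universe
  f3 <- fuse_posterior(c(A = 1, B = 0), c(A = 0.5, B = 0.5), ll,
                       character(0), fusion_weights(0, 0, 0))
  expect_equal(unname(f3), c(0.5, 0.5))
})
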