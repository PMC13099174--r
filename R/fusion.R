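# Log-linear fusion of image evidence, global sighting priors, and the
# encounter-conditioned co-occurrence association term. All arithmetic is in
# log space with log-sum-exp normalization.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf
  m + log(sum(exp(x - m)))
}

#' Encounter-conditioned association score
#'
#' For candidate identity `y` and the current encounter membership set `Y`,
#' the mean log lift between the candidate and the members:
#' `a(y; Y) = (1/|Y|) * sum_{i in Y} L(i, y)`, and exactly 0 when `Y` is
#' empty (no contextual information).
#'
#' @param candidate identity label.
#' @param members character vector of member identities (may be empty).
#' @param loglift clipped log-lift matrix with identity dimnames.
#' @return scalar association score, bounded by the clip bound.
#' @export
association_score <- function(candidate, members, loglift) {
  as.numeric(association_matrix(candidate, members, loglift))
}

#' Association scores for every candidate at once
#'
#' Vectorized form of [association_score()]: one score per universe identity.
#'
#' @param candidates identity labels to score (default: all rows of
#'   `loglift`).
#' @inheritParams association_score
#' @return named numeric vector over `candidates`.
#' @export
association_matrix <- function(candidates = rownames(loglift), members, loglift) {
  ids <- rownames(loglift)
  if (length(bad <- setdiff(c(candidates, members), ids)) > 0L) {
    stop_encontext("identities outside the log-lift universe: %s",
                   paste(bad, collapse = ", "),
                   class = "encontext_validation_error")
  }
  if (length(members) == 0L) {
    return(stats::setNames(numeric(length(candidates)), candidates))
  }
  colMeans(loglift[members, candidates, drop = FALSE])
}

#' Log-linear fused posterior
#'
#' `log P_fuse(y | x, Y) = alpha log P_ML(y|x) + beta log P_global(y)
#'  + gamma a(y; Y) - log Z(x, Y)`, normalized over the whole closed identity
#' set by log-sum-exp. With weights (1, 0, 0) the output equals the input
#' posterior to float precision; with `Y` empty the association term vanishes
#' for every candidate.
#'
#' Numerical guards: image probabilities are clamped at 1e-12 before the log
#' (serialized softmax outputs may round to exactly 0), and the prior enters
#' as `log(P_global + 1e-6)` so unseen identities are floored rather than
#' driven to -Inf.
#'
#' @param posterior numeric image posterior over the universe (named or in
#'   universe order).
#' @param priors global sighting priors over the same universe.
#' @param loglift clipped log-lift matrix.
#' @param members current encounter membership set `Y` (character, possibly
#'   empty).
#' @param weights a [fusion_weights()] triple (or length-3 numeric).
#' @return fused probability vector summing to 1 within 1e-9.
#' @export
fuse_posterior <- function(posterior, priors, loglift, members, weights) {
  w <- as_fusion_weights(weights)
  score <- fuse_log_scores(posterior, priors, loglift, members, w)
  z <- logsumexp(score)
  if (!is.finite(z)) {
    stop_encontext("all fused log scores are -Inf (degenerate evidence)",
                   class = "encontext_validation_error")
  }
  exp(score - z)
}

# unnormalized fused log scores over all candidates
fuse_log_scores <- function(posterior, priors, loglift, members, w) {
  p <- pmax(as.numeric(posterior), 1e-12)
  score <- w[["alpha"]] * log(p) + w[["beta"]] * log(as.numeric(priors) + 1e-6)
  if (w[["gamma"]] > 0 && length(members) > 0L) {
    score <- score + w[["gamma"]] *
      as.numeric(association_matrix(rownames(loglift), members, loglift))
  }
  names(score) <- rownames(loglift)
  score
}

#' Deterministic argmax over identities
#'
#' Ties resolve to the lowest identity index (first in the sorted universe).
#'
#' @param p named probability (or score) vector.
#' @return the winning identity label.
#' @keywords internal
argmax_identity <- function(p) {
  names(p)[which.max(p)]  # which.max takes the first maximum
}
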