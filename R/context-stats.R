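# Social-context statistics built from training encounters only.
#
# All quantities use the certainty weighting: a confirmed sighting contributes
# weight 1 to every count it enters, an uncertain sighting weight 0.5, and a
# pair contribution is the product of the two member weights (0.25 when both
# are uncertain).

assert_train_source <- function(encounters, allow_any) {
  src <- attr(encounters, "source") %||% "unspecified"
  if (!allow_any && !grepl("train", src, fixed = TRUE)) {
    stop_encontext(paste0("context statistics must be built from a train block ",
                          "(source is '%s'); pass allow_any_source = TRUE to ",
                          "override deliberately"), src,
                   class = "encontext_leakage_error")
  }
  invisible(src)
}

#' Global sighting priors
#'
#' For each individual `i`, the weighted count `n_i` of training encounters in
#' which it appears (confirmed = 1, uncertain = 0.5) divided by the number of
#' training encounters `|E|`: `P_global(i) = n_i / |E|`.
#'
#' @param encounters an `encounter_table` tagged as a training block.
#' @param allow_any_source bypass the train-source leakage guard (tests only).
#' @return named numeric vector over the identity universe, entries in `[0,1]`.
#' @export
compute_global_priors <- function(encounters, allow_any_source = FALSE) {
  assert_train_source(encounters, allow_any_source)
  nE <- n_encounters(encounters)
  if (nE == 0L) {
    stop_encontext("no encounters: global priors undefined",
                   class = "encontext_validation_error")
  }
  ids <- identity_universe(encounters)
  counts <- stats::setNames(numeric(length(ids)), ids)
  agg <- tapply(encounters$weight, encounters$identity, sum)
  counts[names(agg)] <- agg
  counts / nE
}

#' Weighted co-occurrence pair counts
#'
#' For each encounter and each unordered pair of distinct members the pair
#' cell gains the product of the two sighting weights. The diagonal is set to
#' the weighted per-identity encounter count `n_i` (an individual trivially
#' co-occurs with itself), which keeps the within-encounter association term
#' from penalizing an already-confirmed member when it reappears.
#'
#' @inheritParams compute_global_priors
#' @return symmetric numeric matrix over the identity universe.
#' @export
compute_pair_counts <- function(encounters, allow_any_source = FALSE) {
  assert_train_source(encounters, allow_any_source)
  if (n_encounters(encounters) == 0L) {
    stop_encontext("no encounters", class = "encontext_validation_error")
  }
  ids <- identity_universe(encounters)
  n <- length(ids)
  counts <- matrix(0, n, n, dimnames = list(ids, ids))
  for (members in encounter_member_list(encounters)) {
    idx <- match(members$identity, ids)
    w <- members$weight
    if (length(idx) >= 2L) {
      # rank-1 outer product restricted to off-diagonal pairs
      block <- outer(w, w)
      diag(block) <- 0
      counts[idx, idx] <- counts[idx, idx] + block
    }
    counts[cbind(idx, idx)] <- counts[cbind(idx, idx)] + w
  }
  counts
}

#' Clipped co-occurrence log-lift matrix
#'
#' `L(i,j) = log((P(i,j) + eps) / ((P(i) + eps) (P(j) + eps)))` with
#' `P(i,j) = n_ij / |E|`, natural log, element-wise clipped to
#' `[-clip, clip]`. Positive values mark above-chance association, negative
#' avoidance; the clip bounds the influence of rarely observed pairs.
#'
#' The diagonal is set to 0: self-association is neutral. A positive
#' diagonal (e.g. `-log P_i`) would make the association term encode each
#' identity's marginal prevalence, a signal that survives the
#' marginal-preserving placebo shuffle by construction and therefore defeats
#' the placebo control (see the methods vignette).
#'
#' @param pair_counts symmetric weighted co-occurrence counts (`n_ij`).
#' @param priors global sighting priors (`P(i)`), same universe.
#' @param n_encounters number of encounters both were computed from.
#' @param epsilon smoothing constant (> 0), default 1e-6.
#' @param clip clip bound in nats (> 0), default 6.
#' @return symmetric matrix with all entries in `[-clip, clip]`.
#' @export
compute_log_lift <- function(pair_counts, priors, n_encounters,
                             epsilon = 1e-6, clip = 6) {
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop_encontext("epsilon must be > 0", class = "encontext_parameter_error")
  }
  if (!is.numeric(clip) || clip <= 0) {
    stop_encontext("clip must be > 0", class = "encontext_parameter_error")
  }
  p_pair <- pair_counts / n_encounters
  denom <- outer(priors + epsilon, priors + epsilon)
  lift <- log((p_pair + epsilon) / denom)
  lift <- pmin(pmax(lift, -clip), clip)
  diag(lift) <- 0
  lift
}

#' Build the full context artifact bundle from training encounters
#'
#' Convenience wrapper: priors, pair counts, clipped log lift, packaged with
#' provenance metadata.
#'
#' @inheritParams compute_global_priors
#' @inheritParams compute_log_lift
#' @return a `context_artifacts` object.
#' @export
build_context <- function(encounters, epsilon = 1e-6, clip = 6,
                          allow_any_source = FALSE) {
  src <- assert_train_source(encounters, allow_any_source)
  priors <- compute_global_priors(encounters, allow_any_source = TRUE)
  counts <- compute_pair_counts(encounters, allow_any_source = TRUE)
  nE <- n_encounters(encounters)
  lift <- compute_log_lift(counts, priors, nE, epsilon = epsilon, clip = clip)
  context_artifacts(identity_universe(encounters), priors, counts, lift,
                    epsilon = epsilon, clip = clip, n_encounters = nE,
                    source = src)
}

#' Placebo encounter table (association-destroying shuffle)
#'
#' Shuffles identity membership across encounters while preserving exactly
#' (i) the multiset of encounter sizes and (ii) the multiset of
#' (identity, certainty) sighting tokens — hence per-identity weighted counts
#' and global priors are bit-identical to the real condition. Only the
#' pairing structure is randomized, so a log lift rebuilt from the placebo
#' table has comparable scale but no genuine association signal.
#'
#' Tokens are dealt into the original size multiset after a seeded shuffle;
#' within-encounter duplicate identities are then repaired by swapping tokens
#' between encounters (bounded number of passes).
#'
#' @param encounters an `encounter_table` (>= 2 encounters).
#' @param seed integer seed; same seed, same placebo table.
#' @param max_passes repair pass cap before giving up.
#' @return an `encounter_table` with source tag `"<source>-placebo"`.
#' @export
make_placebo_encounters <- function(encounters, seed, max_passes = 1000L) {
  ids <- encounter_ids(encounters)
  if (length(ids) < 2L) {
    stop_encontext("placebo shuffle needs >= 2 encounters",
                   class = "encontext_validation_error")
  }
  members <- encounter_member_list(encounters)
  sizes <- vapply(members, nrow, integer(1))
  tokens <- do.call(rbind, members)  # identity + certainty + weight rows
  enc_of <- rep(seq_along(sizes), sizes)

  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    perm <- sample.int(nrow(tokens))
    tokens <- tokens[perm, , drop = FALSE]

    has_dup <- function(e) {
      anyDuplicated(tokens$identity[enc_of == e]) > 0L
    }
    repair_one <- function(e) {
      slots <- which(enc_of == e)
      dup <- slots[duplicated(tokens$identity[slots])]
      for (s in dup) {
        present <- tokens$identity[setdiff(slots, s)]
        # candidate partner slots, scanned in random order
        others <- which(enc_of != e)
        others <- others[sample.int(length(others))]
        for (t in others) {
          f <- enc_of[t]
          f_slots <- which(enc_of == f)
          if (tokens$identity[t] %in% present) next
          if (tokens$identity[s] %in% tokens$identity[setdiff(f_slots, t)]) next
          tmp <- tokens[s, ]; tokens[s, ] <<- tokens[t, ]; tokens[t, ] <<- tmp
          return(TRUE)
        }
      }
      FALSE
    }
    for (pass in seq_len(max_passes)) {
      bad <- which(vapply(seq_along(sizes), has_dup, logical(1)))
      if (length(bad) == 0L) break
      progressed <- any(vapply(bad, repair_one, logical(1)))
      if (!progressed) {
        stop_encontext("placebo shuffle could not repair duplicate identities",
                       class = "encontext_validation_error")
      }
    }
    if (any(vapply(seq_along(sizes), has_dup, logical(1)))) {
      stop_encontext("placebo shuffle exceeded the repair pass cap",
                     class = "encontext_validation_error")
    }
  })

  orders <- stats::setNames(
    unique(encounters[, c("encounter_id", "order")])$order,
    unique(encounters[, c("encounter_id", "order")])$encounter_id)
  encounter_table(ids[enc_of], orders[ids[enc_of]], tokens$identity,
                  tokens$certainty,
                  identities = identity_universe(encounters),
                  source = paste0(attr(encounters, "source"), "-placebo"))
}

#' Co-occurrence graph maturity diagnostics
#'
#' Simple checklist statistics indicating whether enough repeated association
#' history exists for the context term to be informative: graph density
#' (fraction of possible dyads ever observed together), mean number of
#' distinct companions, and the fraction of dyads observed at least
#' `support_threshold` times.
#'
#' @param pair_counts symmetric weighted co-occurrence counts.
#' @param support_threshold dyad support cutoff (default 5).
#' @return list of class `graph_diagnostics` with `density`, `mean_degree`,
#'   `frac_dyads_at_support`, `support_threshold`.
#' @export
graph_diagnostics <- function(pair_counts, support_threshold = 5) {
  n <- nrow(pair_counts)
  if (is.null(n) || n < 2L) {
    stop_encontext("graph diagnostics need >= 2 identities",
                   class = "encontext_validation_error")
  }
  off <- pair_counts[upper.tri(pair_counts)]
  n_dyads <- length(off)
  degree <- vapply(seq_len(n), function(i) {
    sum(pair_counts[i, -i] > 0)
  }, numeric(1))
  structure(list(density = sum(off > 0) / n_dyads,
                 mean_degree = mean(degree),
                 frac_dyads_at_support = sum(off >= support_threshold) / n_dyads,
                 support_threshold = support_threshold),
            class = "graph_diagnostics")
}

#' @export
print.graph_diagnostics <- function(x, ...) {
  cat(sprintf(paste0("<graph_diagnostics> density %.3f, mean degree %.1f, ",
                     "dyads at support >= %g: %.1f%%\n"),
              x$density, x$mean_degree, x$support_threshold,
              100 * x$frac_dyads_at_support))
  invisible(x)
}
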