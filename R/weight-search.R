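# Validation-split selection of the fusion weights (alpha, beta, gamma):
# staged lexicographic search (Stage A over alpha/beta with gamma = 0, Stage B
# over a small gamma grid), optional coordinate-wise hill-climb refinement,
# and Pareto-frontier reporting of all evaluated candidates.

#' Lexicographic comparison of two metric reports
#'
#' `a` beats `b` iff it has higher macro-F1; ties are broken by lower log
#' loss, then lower Brier score. Exact float comparison — residual ties mean
#' "not better", so the earlier-evaluated candidate is retained.
#'
#' @param a,b `metrics_report` objects (macro_f1, log_loss, brier required).
#' @return logical.
#' @export
lexicographic_better <- function(a, b) {
  for (r in list(a, b)) {
    if (is.null(r$macro_f1) || is.null(r$log_loss) || is.null(r$brier) ||
        is.na(r$macro_f1) || is.na(r$log_loss) || is.na(r$brier)) {
      stop_encontext("metrics report missing macro_f1 / log_loss / brier",
                     class = "encontext_validation_error")
    }
  }
  if (a$macro_f1 != b$macro_f1) return(a$macro_f1 > b$macro_f1)
  if (a$log_loss != b$log_loss) return(a$log_loss < b$log_loss)
  a$brier < b$brier
}

#' Default coarse grid for alpha and beta
#' @export
default_weight_grid <- function() seq(0, 2, by = 0.25)

new_candidate <- function(weights, metrics, stage) {
  list(weights = as_fusion_weights(weights), metrics = metrics, stage = stage)
}

candidate_frame <- function(candidates) {
  do.call(rbind, lapply(candidates, function(cr) {
    data.frame(alpha = cr$weights[["alpha"]], beta = cr$weights[["beta"]],
               gamma = cr$weights[["gamma"]], stage = cr$stage,
               macro_f1 = cr$metrics$macro_f1, accuracy = cr$metrics$accuracy,
               log_loss = cr$metrics$log_loss, brier = cr$metrics$brier,
               stringsAsFactors = FALSE)
  }))
}

#' Stage A: select (alpha, beta) with the co-occurrence term disabled
#'
#' Evaluates `eval_fn(fusion_weights(alpha, beta, 0))` over the Cartesian
#' grid (beta varying fastest, ascending, so the prior-free configuration is
#' preferred on exact ties) and keeps the lexicographic best. In
#' `"hillclimb"` mode the best coarse point is refined coordinate-wise with
#' halving steps (start 0.25, stop below 0.0625 or after 20 evaluations per
#' coordinate), weights floored at 0.
#'
#' @param eval_fn deterministic callable: `fusion_weights` -> `metrics_report`
#'   on the validation block.
#' @param grid numeric grid of candidate values for both alpha and beta.
#' @param mode `"grid"` or `"hillclimb"`.
#' @return list: `alpha`, `beta`, `candidates` (list of candidate records).
#' @export
stage_a <- function(eval_fn, grid = default_weight_grid(),
                    mode = c("grid", "hillclimb")) {
  mode <- match.arg(mode)
  if (length(grid) == 0L) {
    stop_encontext("empty stage A grid", class = "encontext_parameter_error")
  }
  grid <- sort(unique(grid))
  candidates <- list()
  best <- NULL
  for (alpha in grid) {
    for (beta in grid) {
      w <- fusion_weights(alpha, beta, 0)
      m <- eval_fn(w)
      candidates[[length(candidates) + 1L]] <- new_candidate(w, m, "A")
      if (is.null(best) || lexicographic_better(m, best$metrics)) {
        best <- new_candidate(w, m, "A")
      }
    }
  }
  if (mode == "hillclimb") {
    current <- best
    for (coord in c("alpha", "beta")) {
      step <- 0.25
      evals <- 0L
      while (step >= 0.0625 && evals < 20L) {
        improved <- FALSE
        for (dir in c(1, -1)) {
          v <- unclass(current$weights)
          v[[coord]] <- max(0, v[[coord]] + dir * step)
          w <- fusion_weights(v[["alpha"]], v[["beta"]], 0)
          if (identical(unclass(w), unclass(current$weights))) next
          m <- eval_fn(w)
          evals <- evals + 1L
          candidates[[length(candidates) + 1L]] <- new_candidate(w, m, "A")
          if (lexicographic_better(m, current$metrics)) {
            current <- new_candidate(w, m, "A")
            improved <- TRUE
            break
          }
        }
        if (!improved) step <- step / 2
      }
    }
    best <- current
  }
  list(alpha = best$weights[["alpha"]], beta = best$weights[["beta"]],
       best = best, candidates = candidates)
}

#' Stage B: select gamma with (alpha, beta) fixed
#'
#' Sweeps the gamma grid (default `{0, 0.5, 1, 2}`) under the same
#' lexicographic criterion; on exact ties the earlier grid value wins, so
#' gamma stays 0 unless a positive value strictly improves.
#'
#' @param eval_fn callable: `fusion_weights` -> `metrics_report`.
#' @param alpha,beta fixed Stage A optimum.
#' @param gamma_grid candidate gamma values.
#' @return list: `gamma`, `best`, `candidates`.
#' @export
stage_b <- function(eval_fn, alpha, beta, gamma_grid = c(0, 0.5, 1, 2)) {
  candidates <- list()
  best <- NULL
  for (gamma in gamma_grid) {
    w <- fusion_weights(alpha, beta, gamma)
    m <- eval_fn(w)
    candidates[[length(candidates) + 1L]] <- new_candidate(w, m, "B")
    if (is.null(best) || lexicographic_better(m, best$metrics)) {
      best <- new_candidate(w, m, "B")
    }
  }
  list(gamma = best$weights[["gamma"]], best = best, candidates = candidates)
}

#' Staged selection of the full weight triple on the validation block
#'
#' Stage A then Stage B; returns the selected weights plus every evaluated
#' candidate record (for Pareto-frontier reporting).
#'
#' @inheritParams stage_a
#' @inheritParams stage_b
#' @return list of class `weight_selection`: `weights` (`fusion_weights`),
#'   `metrics` (validation report of the selected triple), `candidates`
#'   (data.frame of all evaluations).
#' @export
select_weights <- function(eval_fn, grid = default_weight_grid(),
                           gamma_grid = c(0, 0.5, 1, 2),
                           mode = c("grid", "hillclimb")) {
  a <- stage_a(eval_fn, grid = grid, mode = mode)
  b <- stage_b(eval_fn, a$alpha, a$beta, gamma_grid = gamma_grid)
  structure(list(weights = b$best$weights, metrics = b$best$metrics,
                 candidates = candidate_frame(c(a$candidates, b$candidates))),
            class = "weight_selection")
}

#' @export
print.weight_selection <- function(x, ...) {
  cat(sprintf("<weight_selection> alpha=%g beta=%g gamma=%g (validation macro-F1 %.3f)\n",
              x$weights[["alpha"]], x$weights[["beta"]], x$weights[["gamma"]],
              x$metrics$macro_f1))
  invisible(x)
}

#' Pareto frontier over (macro-F1 up, log loss down, Brier down)
#'
#' A record dominates another if it is at least as good on all three
#' objectives and strictly better on at least one. Duplicated objective
#' points keep one representative.
#'
#' @param records data.frame with columns macro_f1, log_loss, brier (e.g.
#'   `weight_selection$candidates`).
#' @return the non-dominated rows of `records`.
#' @export
pareto_front <- function(records) {
  if (nrow(records) == 0L) {
    stop_encontext("no candidate records", class = "encontext_validation_error")
  }
  obj <- cbind(-records$macro_f1, records$log_loss, records$brier)
  dup <- duplicated(obj)
  dominated <- vapply(seq_len(nrow(obj)), function(i) {
    any(vapply(seq_len(nrow(obj)), function(j) {
      j != i && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])
    }, logical(1)))
  }, logical(1))
  records[!dominated & !dup, , drop = FALSE]
}
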