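# Leakage-safe temporal splitting and every reported metric.

#' Temporal block split of a chronologically ordered encounter archive
#'
#' Contiguous blocks over the ordered encounters: training = earliest
#' `floor(t |E|)`, validation = next `floor((1 - t)/2 |E|)`, holdout = the
#' remainder (monitoring only), and a fixed "future" test block = the last
#' `ceiling(test_fraction |E|)` encounters, identical across all `t`. The
#' holdout may overlap the test block; the training block never does for
#' `t <= 1 - test_fraction`.
#'
#' @param encounters an `encounter_table`.
#' @param t training fraction in (0, 1).
#' @param test_fraction fixed future test fraction (default 0.10).
#' @return list of class `split_spec` with encounter-id vectors `train`,
#'   `validation`, `holdout`, `test` and the fraction `t`.
#' @export
temporal_split <- function(encounters, t, test_fraction = 0.10) {
  ids <- encounter_ids(encounters)
  nE <- length(ids)
  if (!is.numeric(t) || t <= 0 || t >= 1) {
    stop_encontext("t must lie in (0, 1)", class = "encontext_parameter_error")
  }
  n_train <- floor(t * nE)
  if (n_train < 1L) {
    stop_encontext("t * |E| < 1: training block empty",
                   class = "encontext_validation_error")
  }
  n_val <- floor((1 - t) / 2 * nE)
  n_test <- ceiling(test_fraction * nE)
  structure(list(train = ids[seq_len(n_train)],
                 validation = ids[n_train + seq_len(n_val)],
                 holdout = ids[(n_train + n_val + 1):nE],
                 test = ids[(nE - n_test + 1):nE],
                 t = t, test_fraction = test_fraction),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> t=%.2f: train %d | validation %d | holdout %d | test %d\n",
              x$t, length(x$train), length(x$validation), length(x$holdout),
              length(x$test)))
  invisible(x)
}

#' Extract one split block as a tagged encounter table
#' @param encounters the full `encounter_table`.
#' @param split a `split_spec`.
#' @param which one of "train", "validation", "holdout", "test".
#' @return an `encounter_table` tagged with the block name as its source.
#' @export
split_block <- function(encounters, split,
                        which = c("train", "validation", "holdout", "test")) {
  which <- match.arg(which)
  encounter_subset(encounters, split[[which]], source = which)
}

#' Construct a metrics report
#' @param accuracy,macro_f1,macro_precision,macro_recall,log_loss,brier
#'   scalar metrics.
#' @param raer,coverage optional scalars.
#' @param n_seeds number of seeds aggregated.
#' @param sd named numeric vector of per-metric SDs (when `n_seeds > 1`).
#' @return list of class `metrics_report`.
#' @export
metrics_report <- function(accuracy, macro_f1, macro_precision, macro_recall,
                           log_loss, brier, raer = NA_real_,
                           coverage = NA_real_, n_seeds = 1L, sd = NULL) {
  structure(list(accuracy = accuracy, macro_f1 = macro_f1,
                 macro_precision = macro_precision, macro_recall = macro_recall,
                 log_loss = log_loss, brier = brier, raer = raer,
                 coverage = coverage, n_seeds = as.integer(n_seeds), sd = sd),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> acc %.3f | macro-F1 %.3f | logloss %.3f",
                     " | Brier %.3f%s%s (n_seeds=%d)\n"),
              x$accuracy, x$macro_f1, x$log_loss, x$brier,
              if (is.na(x$raer)) "" else sprintf(" | rAER %.3f", x$raer),
              if (is.na(x$coverage)) "" else sprintf(" | coverage %.3f", x$coverage),
              x$n_seeds))
  invisible(x)
}

metric_names <- c("accuracy", "macro_f1", "macro_precision", "macro_recall",
                  "log_loss", "brier", "raer", "coverage")

#' Score predictions against image-level truth
#'
#' Top-1 accuracy; macro-averaged one-vs-rest precision/recall/F1 over the
#' classes present in the truth set (a class with no predicted positives
#' scores precision 0, not skipped); multi-class log loss (natural log,
#' true-class probability clamped at 1e-15); multi-class Brier score (squared
#' distance to the one-hot truth summed over classes, averaged over images).
#'
#' @param predicted character predictions per image.
#' @param fused probability matrix, one row per image, identity columns.
#' @param truth character true identities per image.
#' @return a `metrics_report`.
#' @export
score_predictions <- function(predicted, fused, truth) {
  if (length(predicted) == 0L) {
    stop_encontext("no predictions to score", class = "encontext_validation_error")
  }
  if (length(predicted) != length(truth) || nrow(fused) != length(truth)) {
    stop_encontext("predictions, posteriors and truths must align",
                   class = "encontext_validation_error")
  }
  if (anyNA(truth)) {
    stop_encontext("missing true identities in scoring",
                   class = "encontext_validation_error")
  }
  accuracy <- mean(predicted == truth)

  classes <- sort(unique(truth))
  prf <- vapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- tp / (tp + fn)  # tp + fn >= 1 since cl occurs in truth
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }, numeric(3))

  truth_col <- match(truth, colnames(fused))
  if (anyNA(truth_col)) {
    stop_encontext("true identities outside the posterior universe",
                   class = "encontext_validation_error")
  }
  p_true <- fused[cbind(seq_along(truth), truth_col)]
  log_loss <- mean(-log(pmax(p_true, 1e-15)))
  onehot_sq <- rowSums(fused^2) - 2 * p_true + 1
  brier <- mean(onehot_sq)

  metrics_report(accuracy = accuracy,
                 macro_f1 = mean(prf[3, ]),
                 macro_precision = mean(prf[1, ]),
                 macro_recall = mean(prf[2, ]),
                 log_loss = log_loss, brier = brier)
}

#' Relative accuracy error reduction
#'
#' `rAER = (A_method - A_baseline) / (1 - A_baseline)`: the fraction of the
#' baseline's top-1 error removed by the method. 0 when accuracies are equal,
#' 1 when the method is perfect.
#'
#' @param accuracy_baseline baseline top-1 accuracy (< 1).
#' @param accuracy_method method top-1 accuracy.
#' @return real in `(-Inf, 1]`.
#' @export
raer <- function(accuracy_baseline, accuracy_method) {
  if (accuracy_baseline >= 1) {
    stop_encontext("rAER undefined for a perfect baseline",
                   class = "encontext_parameter_error")
  }
  (accuracy_method - accuracy_baseline) / (1 - accuracy_baseline)
}

#' Aggregate per-seed metric reports into mean and SD
#'
#' Arithmetic mean per metric; sample SD (n-1 denominator) when two or more
#' reports are given, 0 otherwise.
#'
#' @param reports list of `metrics_report` objects.
#' @return a `metrics_report` with `n_seeds` and `sd` populated.
#' @export
aggregate_seeds <- function(reports) {
  if (length(reports) == 0L) {
    stop_encontext("no reports to aggregate", class = "encontext_validation_error")
  }
  vals <- vapply(reports, function(r) {
    unlist(r[metric_names])
  }, numeric(length(metric_names)))
  vals <- matrix(vals, nrow = length(metric_names),
                 dimnames = list(metric_names, NULL))
  mu <- rowMeans(vals)
  sdv <- if (length(reports) >= 2L) apply(vals, 1, stats::sd) else
    stats::setNames(rep(0, length(metric_names)), metric_names)
  metrics_report(accuracy = mu[["accuracy"]], macro_f1 = mu[["macro_f1"]],
                 macro_precision = mu[["macro_precision"]],
                 macro_recall = mu[["macro_recall"]],
                 log_loss = mu[["log_loss"]], brier = mu[["brier"]],
                 raer = mu[["raer"]], coverage = mu[["coverage"]],
                 n_seeds = length(reports), sd = sdv)
}
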