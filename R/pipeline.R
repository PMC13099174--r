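# End-to-end experiment orchestration: for each training fraction, split the
# archive, build context artifacts from the training block only, select
# fusion weights on validation, and score baseline and fused inference on the
# fixed future test block. A manifest records seeds, weights and block
# boundaries for exact re-runs.

#' Run the full experiment grid on one archive
#'
#' @param encounters full chronologically ordered `encounter_table`.
#' @param posteriors `posterior_set` covering at least the validation and
#'   test encounters (image-level truth required).
#' @param t_values training fractions to sweep.
#' @param strategies named list of `inference_config` templates (their `seed`
#'   is replaced by `seed`).
#' @param weights either `"staged"` (validation weight selection per
#'   strategy) or a fixed `fusion_weights` triple applied everywhere.
#' @param grid,gamma_grid,search_mode forwarded to [select_weights()] when
#'   `weights = "staged"`.
#' @param seed master seed.
#' @param epsilon,clip log-lift parameters.
#' @param test_fraction fixed future test fraction.
#' @return list of class `experiment_report`: `report` (one data.frame row
#'   per (t, strategy) with baseline and fused metrics) and `manifest`.
#' @export
run_experiment <- function(encounters, posteriors,
                           t_values = c(0.1, 0.3, 0.5, 0.7),
                           strategies = list(
                             null_set = inference_config("null_set"),
                             top_unknown = inference_config("top_unknown")),
                           weights = "staged",
                           grid = default_weight_grid(),
                           gamma_grid = c(0, 0.5, 1, 2),
                           search_mode = "grid",
                           seed = 1L, epsilon = 1e-6, clip = 6,
                           test_fraction = 0.10) {
  rows <- list()
  manifest <- list(seed = seed, epsilon = epsilon, clip = clip,
                   weights_mode = if (is.character(weights)) weights else "fixed",
                   t = list())
  for (t in t_values) {
    split <- temporal_split(encounters, t, test_fraction = test_fraction)
    train_tbl <- split_block(encounters, split, "train")
    test_tbl <- split_block(encounters, split, "test")
    artifacts <- build_context(train_tbl, epsilon = epsilon, clip = clip)
    test_post <- posterior_subset(posteriors, split$test)
    val_post <- posterior_subset(posteriors, split$validation)
    val_tbl <- split_block(encounters, split, "validation")

    baseline <- score_predictions(
      apply(test_post$prob, 1, argmax_identity), test_post$prob,
      test_post$true_identity)

    for (nm in names(strategies)) {
      cfg <- strategies[[nm]]
      cfg$seed <- as.integer(seed)
      if (is.character(weights) && weights == "staged") {
        eval_fn <- function(w) {
          evaluate_strategy(val_post, artifacts, w, cfg, encounters = val_tbl)
        }
        sel <- select_weights(eval_fn, grid = grid, gamma_grid = gamma_grid,
                              mode = search_mode)
        w_use <- sel$weights
      } else {
        w_use <- as_fusion_weights(weights)
      }
      fused <- evaluate_strategy(test_post, artifacts, w_use, cfg,
                                 encounters = test_tbl,
                                 baseline_accuracy = baseline$accuracy)
      rows[[length(rows) + 1L]] <- data.frame(
        t = t, strategy = nm,
        alpha = w_use[["alpha"]], beta = w_use[["beta"]], gamma = w_use[["gamma"]],
        baseline_accuracy = baseline$accuracy,
        baseline_macro_f1 = baseline$macro_f1,
        accuracy = fused$accuracy, macro_f1 = fused$macro_f1,
        log_loss = fused$log_loss, brier = fused$brier,
        raer = fused$raer, coverage = fused$coverage,
        macro_f1_sd = fused$sd[["macro_f1"]], n_seeds = fused$n_seeds,
        stringsAsFactors = FALSE)
      manifest$t[[as.character(t)]][[nm]] <-
        list(weights = unclass(w_use), n_train = length(split$train),
             n_validation = length(split$validation),
             n_test = length(split$test),
             artifact_source = artifacts$source)
    }
  }
  structure(list(report = do.call(rbind, rows), manifest = manifest),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  print(x$report)
  invisible(x)
}

# ---- command line interface -------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: encontext <command> [options]",
    "commands:",
    "  simulate       --out DIR [--seed N] [--n-encounters N] [--n-individuals N]",
    "  build-context  --train-table FILE --out FILE [--epsilon X] [--clip X]",
    "  placebo        --train-table FILE --out FILE --seed N",
    "  infer          --artifacts FILE --posteriors FILE --encounters FILE",
    "                 --out FILE [--strategy S] [--n N] [--tau X]",
    "                 [--weights a,b,g] [--seed N]",
    "  evaluate       --results FILE --out FILE",
    sep = "\n")
}

cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    out[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  out
}

cli_get <- function(opts, key, default = NULL) {
  v <- opts[[key]] %||% default
  if (is.null(v)) {
    stop_encontext("missing required option --%s", key,
                   class = "encontext_parameter_error")
  }
  v
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `build-context`, `placebo`, `infer` and
#' `evaluate` subcommands (see `inst/cli/encontext`). Exposed as a function
#' so it can be driven in-process.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the main artifact produced by the subcommand.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat(cli_usage(), "\n")
    return(invisible(NULL))
  }
  cmd <- args[[1L]]
  opts <- cli_args(args[-1L])
  seed <- as.integer(cli_get(opts, "seed", "1"))
  switch(cmd,
    "simulate" = {
      dir.create(out <- cli_get(opts, "out"), showWarnings = FALSE,
                 recursive = TRUE)
      sim <- simulate_archive(
        n_individuals = as.integer(cli_get(opts, "n-individuals", "20")),
        n_encounters = as.integer(cli_get(opts, "n-encounters", "500")),
        seed = seed, quiet = TRUE)
      post <- simulate_posteriors(
        sim$encounters,
        posterior_config(confusable_pairs = sim$confusable_pairs),
        seed = seed)
      write_encounter_table(sim$encounters, file.path(out, "encounters.csv"))
      write_posteriors(post, file.path(out, "posteriors.csv"))
      jsonlite::write_json(as.list(sim$population$unit),
                           file.path(out, "units.json"), auto_unbox = TRUE)
      invisible(out)
    },
    "build-context" = {
      tbl <- read_encounter_table(cli_get(opts, "train-table"), source = "train")
      art <- build_context(tbl,
                           epsilon = as.numeric(cli_get(opts, "epsilon", "1e-6")),
                           clip = as.numeric(cli_get(opts, "clip", "6")))
      write_context_artifacts(art, cli_get(opts, "out"))
      invisible(art)
    },
    "placebo" = {
      tbl <- read_encounter_table(cli_get(opts, "train-table"), source = "train")
      plac <- make_placebo_encounters(tbl, seed = seed)
      write_encounter_table(plac, cli_get(opts, "out"))
      invisible(plac)
    },
    "infer" = {
      art <- read_context_artifacts(cli_get(opts, "artifacts"))
      enc <- read_encounter_table(cli_get(opts, "encounters"), source = "test")
      post <- read_posteriors(cli_get(opts, "posteriors"), art$identities)
      w <- as_fusion_weights(as.numeric(strsplit(
        cli_get(opts, "weights", "1,0,1"), ",")[[1]]))
      cfg <- inference_config(cli_get(opts, "strategy", "null_set"),
                              n_init = as.integer(cli_get(opts, "n", "1")),
                              tau = as.numeric(cli_get(opts, "tau", "0.95")),
                              seed = seed)
      run <- run_inference(post, art, w, cfg, encounters = enc)
      res <- data.frame(image_id = run$image_id, predicted = run$predicted,
                        baseline = run$baseline,
                        truth = ifelse(is.na(run$truth), "", run$truth),
                        p_fused = run$fused[cbind(seq_along(run$image_id),
                                                  match(run$predicted,
                                                        colnames(run$fused)))],
                        stringsAsFactors = FALSE)
      utils::write.csv(res, cli_get(opts, "out"), row.names = FALSE)
      invisible(run)
    },
    "evaluate" = {
      res <- utils::read.csv(cli_get(opts, "results"),
                             stringsAsFactors = FALSE)
      if (!all(c("predicted", "truth") %in% names(res))) {
        stop_encontext("results file needs predicted and truth columns",
                       class = "encontext_format_error")
      }
      acc_base <- mean(res$baseline == res$truth)
      acc <- mean(res$predicted == res$truth)
      out <- list(accuracy_baseline = acc_base, accuracy = acc,
                  raer = raer(acc_base, acc), n_images = nrow(res))
      jsonlite::write_json(out, cli_get(opts, "out"), auto_unbox = TRUE,
                           digits = NA)
      invisible(out)
    },
    stop_encontext("unknown command '%s'\n%s", cmd, cli_usage(),
                   class = "encontext_parameter_error")
  )
}
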