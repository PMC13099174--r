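# ---- internal helpers -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_encontext <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "encontext_error")))
}

#' Certainty flag to sighting weight
#'
#' Confirmed sightings carry weight 1, uncertain sightings (flagged "?" by
#' experts) carry weight 0.5. All context statistics use these weights.
#'
#' @param certainty character vector of "confirmed" / "uncertain".
#' @return numeric weights.
#' @keywords internal
certainty_weight <- function(certainty) {
  ifelse(certainty == "confirmed", 1.0, 0.5)
}

normalize_certainty <- function(x) {
  x <- trimws(as.character(x))
  out <- ifelse(x %in% c("?", "uncertain"), "uncertain",
                ifelse(x == "confirmed", "confirmed", NA_character_))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop_encontext("unrecognized certainty value(s): %s",
                   paste(bad, collapse = ", "), class = "encontext_format_error")
  }
  out
}

# ---- encounter tables -------------------------------------------------------

#' Construct an encounter table
#'
#' The central observational unit: one row per (encounter, individual)
#' sighting. Encounters carry an explicit integer chronological `order`
#' (dates are not modeled); individuals carry a confirmed/uncertain flag from
#' which the sighting weight (1 / 0.5) is derived. Duplicate
#' (encounter, identity) rows are collapsed keeping the higher-certainty flag.
#'
#' @param encounter_id character encounter identifiers.
#' @param order integer chronological rank of each row's encounter; every
#'   encounter must map to exactly one order value and order values are unique
#'   across encounters.
#' @param identity character individual catalog labels (e.g. "T055B").
#' @param certainty "confirmed", "uncertain" or "?" per row.
#' @param identities optional fixed identity universe (character); defaults to
#'   the sorted unique labels observed. Labels outside a supplied universe are
#'   an error (closed-set assumption).
#' @param source split provenance tag ("train", "validation", "test", ...);
#'   context statistics refuse non-train sources unless overridden.
#' @return data.frame of class `encounter_table` with columns
#'   encounter_id, order, identity, certainty, weight; attributes
#'   `identities` and `source`.
#' @export
encounter_table <- function(encounter_id, order, identity, certainty,
                            identities = NULL, source = "unspecified") {
  if (length(encounter_id) == 0L) {
    stop_encontext("encounter table is empty", class = "encontext_validation_error")
  }
  certainty <- normalize_certainty(certainty)
  df <- data.frame(
    encounter_id = as.character(encounter_id),
    order = as.integer(order),
    identity = as.character(identity),
    certainty = certainty,
    stringsAsFactors = FALSE
  )
  # each encounter must have a single, globally unique order value
  ord_map <- unique(df[, c("encounter_id", "order")])
  if (anyDuplicated(ord_map$encounter_id)) {
    stop_encontext("encounter(s) with conflicting order values",
                   class = "encontext_validation_error")
  }
  if (anyDuplicated(ord_map$order)) {
    stop_encontext("order values are not unique across encounters",
                   class = "encontext_validation_error")
  }
  # collapse duplicate (encounter, identity) rows, keeping confirmed over uncertain
  key <- paste(df$encounter_id, df$identity, sep = "\r")
  if (anyDuplicated(key)) {
    conf_rank <- ifelse(df$certainty == "confirmed", 0L, 1L)
    df <- df[order(key, conf_rank), , drop = FALSE]
    df <- df[!duplicated(paste(df$encounter_id, df$identity, sep = "\r")), , drop = FALSE]
  }
  df$weight <- certainty_weight(df$certainty)
  df <- df[order(df$order, df$identity), , drop = FALSE]
  rownames(df) <- NULL

  observed <- sort(unique(df$identity))
  if (is.null(identities)) {
    identities <- observed
  } else {
    identities <- sort(unique(as.character(identities)))
    missing <- setdiff(observed, identities)
    if (length(missing) > 0L) {
      stop_encontext("identities outside the closed universe: %s",
                     paste(missing, collapse = ", "),
                     class = "encontext_validation_error")
    }
  }
  structure(df,
            identities = identities,
            source = source,
            class = c("encounter_table", "data.frame"))
}

#' @export
print.encounter_table <- function(x, ...) {
  cat(sprintf("<encounter_table> %d encounters, %d sightings, %d identities (source: %s)\n",
              n_encounters(x), nrow(x), length(attr(x, "identities")),
              attr(x, "source")))
  invisible(x)
}

#' Number of encounters in a table
#' @param encounters an `encounter_table`.
#' @return integer count of distinct encounters.
#' @export
n_encounters <- function(encounters) {
  length(unique(encounters$encounter_id))
}

#' Identity universe of an object
#' @param x an `encounter_table`, `posterior_set` or `context_artifacts`.
#' @return character vector of identity labels (sorted).
#' @export
identity_universe <- function(x) {
  if (inherits(x, "context_artifacts")) return(x$identities)
  attr(x, "identities")
}

#' Split encounter members by encounter, in chronological order
#' @keywords internal
encounter_member_list <- function(encounters) {
  ids <- unique(encounters$encounter_id[order(encounters$order)])
  split(encounters[, c("identity", "weight", "certainty")],
        factor(encounters$encounter_id, levels = ids))
}

#' Chronologically ordered encounter ids
#' @param encounters an `encounter_table`.
#' @return character vector of encounter ids sorted by `order`.
#' @export
encounter_ids <- function(encounters) {
  unique(encounters$encounter_id[order(encounters$order)])
}

#' Subset an encounter table by encounter id, retagging its split provenance
#'
#' @param encounters an `encounter_table`.
#' @param ids encounter ids to keep.
#' @param source split tag for the subset (e.g. "train").
#' @return an `encounter_table` restricted to `ids`, preserving the full
#'   identity universe (closed set).
#' @export
encounter_subset <- function(encounters, ids, source = attr(encounters, "source")) {
  keep <- encounters$encounter_id %in% ids
  if (!any(keep)) {
    stop_encontext("encounter subset is empty", class = "encontext_validation_error")
  }
  df <- encounters[keep, , drop = FALSE]
  encounter_table(df$encounter_id, df$order, df$identity, df$certainty,
                  identities = attr(encounters, "identities"), source = source)
}

#' True membership of one encounter
#' @param encounters an `encounter_table`.
#' @param id one encounter id.
#' @return character vector of member identities.
#' @export
encounter_members <- function(encounters, id) {
  unique(encounters$identity[encounters$encounter_id == id])
}

#' Read an encounter table from delimited text
#'
#' Expects columns `encounter_id`, `order`, `identity`, `certainty` (values
#' "confirmed", "uncertain" or "?"). Delimiter is inferred from the file
#' extension (`.tsv` = tab) unless given.
#'
#' @param path file path.
#' @param sep field delimiter; default inferred.
#' @param identities optional fixed identity universe.
#' @param source split provenance tag.
#' @return an `encounter_table`.
#' @export
read_encounter_table <- function(path, sep = NULL, identities = NULL,
                                 source = "unspecified") {
  if (!file.exists(path)) {
    stop_encontext("file not found: %s", path, class = "encontext_format_error")
  }
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("encounter_id", "order", "identity", "certainty")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_encontext("encounter table missing column(s): %s",
                   paste(missing, collapse = ", "),
                   class = "encontext_format_error")
  }
  if (nrow(df) == 0L) {
    stop_encontext("encounter table is empty", class = "encontext_validation_error")
  }
  encounter_table(df$encounter_id, as.integer(df$order), df$identity,
                  df$certainty, identities = identities, source = source)
}

#' Write an encounter table to delimited text
#' @param encounters an `encounter_table`.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_encounter_table <- function(encounters, path, sep = ",") {
  utils::write.table(
    encounters[, c("encounter_id", "order", "identity", "certainty")],
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- posterior sets ---------------------------------------------------------

#' Construct a set of per-image classifier posteriors
#'
#' One row per image: softmax posterior over the closed identity set, the
#' encounter the image belongs to, and (when known) the true identity. Rows
#' with a strictly positive sum are renormalized on ingestion (logged when
#' the raw sum deviates from 1 by more than 1e-6); non-positive rows error.
#'
#' @param image_id character image identifiers (unique).
#' @param encounter_id character encounter id per image.
#' @param prob numeric matrix, one row per image, columns named by identity.
#' @param true_identity optional character truth per image (NA allowed).
#' @param identities identity universe; defaults to sorted column names.
#' @return object of class `posterior_set`: list with `image_id`,
#'   `encounter_id`, `true_identity`, `prob` (rows summing to 1).
#' @export
posterior_set <- function(image_id, encounter_id, prob, true_identity = NULL,
                          identities = NULL) {
  prob <- as.matrix(prob)
  if (is.null(colnames(prob))) {
    stop_encontext("posterior matrix must have identity column names",
                   class = "encontext_format_error")
  }
  identities <- identities %||% sort(colnames(prob))
  unknown <- setdiff(colnames(prob), identities)
  if (length(unknown) > 0L) {
    stop_encontext("posterior column(s) outside the identity universe: %s",
                   paste(unknown, collapse = ", "),
                   class = "encontext_validation_error")
  }
  missing <- setdiff(identities, colnames(prob))
  if (length(missing) > 0L) {
    stop_encontext("posterior matrix missing identity column(s): %s",
                   paste(missing, collapse = ", "),
                   class = "encontext_validation_error")
  }
  prob <- prob[, identities, drop = FALSE]
  storage.mode(prob) <- "double"
  if (any(prob < 0)) {
    stop_encontext("negative posterior entries", class = "encontext_validation_error")
  }
  s <- rowSums(prob)
  image_id <- as.character(image_id)
  if (any(s <= 0)) {
    stop_encontext("posterior row(s) with non-positive sum: %s",
                   paste(image_id[s <= 0], collapse = ", "),
                   class = "encontext_validation_error")
  }
  if (any(abs(s - 1) > 1e-6)) {
    message(sprintf("renormalized %d posterior row(s) with |sum - 1| > 1e-6",
                    sum(abs(s - 1) > 1e-6)))
  }
  prob <- prob / s
  rownames(prob) <- image_id
  true_identity <- if (is.null(true_identity)) {
    rep(NA_character_, length(image_id))
  } else {
    ti <- as.character(true_identity)
    ti[!is.na(ti) & ti == ""] <- NA_character_
    ti
  }
  bad <- !is.na(true_identity) & !(true_identity %in% identities)
  if (any(bad)) {
    stop_encontext("true identities outside the universe: %s",
                   paste(unique(true_identity[bad]), collapse = ", "),
                   class = "encontext_validation_error")
  }
  structure(list(image_id = image_id,
                 encounter_id = as.character(encounter_id),
                 true_identity = true_identity,
                 prob = prob),
            identities = identities,
            class = "posterior_set")
}

#' @export
print.posterior_set <- function(x, ...) {
  cat(sprintf("<posterior_set> %d images over %d identities, %d encounters\n",
              length(x$image_id), ncol(x$prob), length(unique(x$encounter_id))))
  invisible(x)
}

#' Number of images in a posterior set
#' @param posteriors a `posterior_set`.
#' @export
n_images <- function(posteriors) length(posteriors$image_id)

#' Restrict a posterior set to one encounter
#' @param posteriors a `posterior_set`.
#' @param id encounter id.
#' @return a `posterior_set` with only that encounter's images.
#' @export
posterior_subset <- function(posteriors, id) {
  keep <- posteriors$encounter_id %in% id
  structure(list(image_id = posteriors$image_id[keep],
                 encounter_id = posteriors$encounter_id[keep],
                 true_identity = posteriors$true_identity[keep],
                 prob = posteriors$prob[keep, , drop = FALSE]),
            identities = attr(posteriors, "identities"),
            class = "posterior_set")
}

#' Read per-image posterior records from CSV
#'
#' Layout: columns `image_id`, `encounter_id`, `true_identity` (may be empty),
#' then one probability column per identity label. Columns are aligned to the
#' supplied universe by label, so file column order is free.
#'
#' @param path file path.
#' @param identities the identity universe the probabilities must cover.
#' @return a `posterior_set`.
#' @export
read_posteriors <- function(path, identities) {
  if (!file.exists(path)) {
    stop_encontext("file not found: %s", path, class = "encontext_format_error")
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("image_id", "encounter_id", "true_identity")
  missing <- setdiff(c("image_id", "encounter_id"), names(df))
  if (length(missing) > 0L) {
    stop_encontext("posterior file missing column(s): %s",
                   paste(missing, collapse = ", "),
                   class = "encontext_format_error")
  }
  prob_cols <- setdiff(names(df), meta_cols)
  prob <- as.matrix(df[, prob_cols, drop = FALSE])
  posterior_set(df$image_id, df$encounter_id, prob,
                true_identity = if ("true_identity" %in% names(df)) df$true_identity,
                identities = sort(identities))
}

#' Write a posterior set to CSV
#' @param posteriors a `posterior_set`.
#' @param path output file path.
#' @export
write_posteriors <- function(posteriors, path) {
  df <- data.frame(image_id = posteriors$image_id,
                   encounter_id = posteriors$encounter_id,
                   true_identity = ifelse(is.na(posteriors$true_identity), "",
                                          posteriors$true_identity),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(posteriors$prob, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- fusion weights ---------------------------------------------------------

#' Fusion weight triple
#'
#' Non-negative weights on the three evidence channels of log-linear fusion:
#' `alpha` (image posterior), `beta` (global sighting prior), `gamma`
#' (co-occurrence association term).
#'
#' @param alpha,beta,gamma non-negative reals.
#' @return named numeric vector of class `fusion_weights`.
#' @export
fusion_weights <- function(alpha, beta, gamma) {
  w <- c(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma))
  if (any(!is.finite(w)) || any(w < 0)) {
    stop_encontext("fusion weights must be finite and non-negative",
                   class = "encontext_parameter_error")
  }
  structure(w, class = "fusion_weights")
}

as_fusion_weights <- function(w) {
  if (inherits(w, "fusion_weights")) return(w)
  w <- as.numeric(w)
  if (length(w) != 3L) {
    stop_encontext("fusion weights must have length 3 (alpha, beta, gamma)",
                   class = "encontext_parameter_error")
  }
  fusion_weights(w[1], w[2], w[3])
}

# ---- context artifact serialization ----------------------------------------

#' Construct deployable social-context artifacts
#'
#' Bundles the train-derived global sighting prior vector and the clipped
#' co-occurrence log-lift matrix together with the provenance metadata
#' (smoothing epsilon, clip bound, number of source encounters, split tag)
#' without which they are not interpretable.
#'
#' @param identities ordered identity universe.
#' @param global_prior named numeric vector in `[0,1]` over `identities`.
#' @param pair_counts symmetric weighted co-occurrence count matrix.
#' @param loglift symmetric log-lift matrix clipped to `[-clip, clip]`.
#' @param epsilon smoothing constant used in the lift.
#' @param clip clip bound (nats).
#' @param n_encounters number of source encounters.
#' @param source split provenance tag.
#' @return object of class `context_artifacts`.
#' @export
context_artifacts <- function(identities, global_prior, pair_counts, loglift,
                              epsilon, clip, n_encounters, source) {
  identities <- as.character(identities)
  n <- length(identities)
  stopifnot(length(global_prior) == n, all(dim(pair_counts) == n),
            all(dim(loglift) == n))
  if (any(global_prior < 0 | global_prior > 1)) {
    stop_encontext("global prior outside [0,1]", class = "encontext_validation_error")
  }
  if (max(abs(pair_counts - t(pair_counts))) > 1e-12) {
    stop_encontext("pair counts not symmetric", class = "encontext_validation_error")
  }
  if (max(abs(loglift)) > clip + 1e-12) {
    stop_encontext("log lift exceeds the clip bound", class = "encontext_validation_error")
  }
  global_prior <- stats::setNames(as.numeric(global_prior), identities)
  dimnames(pair_counts) <- dimnames(loglift) <- list(identities, identities)
  structure(list(identities = identities,
                 global_prior = global_prior,
                 pair_counts = pair_counts,
                 loglift = loglift,
                 epsilon = as.numeric(epsilon),
                 clip = as.numeric(clip),
                 n_encounters = as.integer(n_encounters),
                 source = as.character(source)),
            class = "context_artifacts")
}

#' @export
print.context_artifacts <- function(x, ...) {
  cat(sprintf(paste0("<context_artifacts> %d identities from %d encounters ",
                     "(source: %s, epsilon: %g, clip: %g)\n"),
              length(x$identities), x$n_encounters, x$source, x$epsilon, x$clip))
  invisible(x)
}

#' Write context artifacts to JSON
#'
#' Single-file JSON: metadata, the prior as a label-to-probability map, and
#' dense matrix payloads. Numeric values are serialized at full precision so
#' the round trip is bit-identical for finite values.
#'
#' @param artifacts a `context_artifacts` object.
#' @param path output path (.json).
#' @export
write_context_artifacts <- function(artifacts, path) {
  # doubles are stored as %.17g strings: JSON writers round at 15
  # significant digits, which would break the bit-identical round trip
  fmt <- function(x) sprintf("%.17g", x)
  payload <- list(
    identities = artifacts$identities,
    epsilon = fmt(artifacts$epsilon),
    clip = fmt(artifacts$clip),
    n_encounters = artifacts$n_encounters,
    source = artifacts$source,
    global_prior = as.list(stats::setNames(fmt(artifacts$global_prior),
                                           artifacts$identities)),
    pair_counts = matrix(fmt(artifacts$pair_counts), nrow(artifacts$pair_counts)),
    loglift = matrix(fmt(artifacts$loglift), nrow(artifacts$loglift))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read context artifacts from JSON
#' @param path path written by [write_context_artifacts()].
#' @return a `context_artifacts` object.
#' @export
read_context_artifacts <- function(path) {
  if (!file.exists(path)) {
    stop_encontext("file not found: %s", path, class = "encontext_format_error")
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("epsilon", "clip", "identities", "n_encounters", "source")) {
    if (is.null(payload[[field]])) {
      stop_encontext("context artifact file missing field '%s'", field,
                     class = "encontext_validation_error")
    }
  }
  ids <- payload$identities
  prior <- as.numeric(unlist(payload$global_prior)[ids])
  context_artifacts(ids, prior,
                    matrix(as.numeric(payload$pair_counts), length(ids)),
                    matrix(as.numeric(payload$loglift), length(ids)),
                    epsilon = as.numeric(payload$epsilon),
                    clip = as.numeric(payload$clip),
                    n_encounters = payload$n_encounters, source = payload$source)
}
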