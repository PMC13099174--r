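test_that("encounter table ingestion: weights, dedup, ordering, errors", {
  enc <- toy_encounters()
  expect_s3_class(enc, "encounter_table")
  expect_equal(n_encounters(enc), 4L)
  expect_equal(identity_universe(enc), c("A", "B", "C"))
  # "?" parses as uncertain with weight 0.5
  expect_equal(enc$weight[enc$encounter_id == "E2" & enc$identity == "B"], 0.5)
  expect_equal(enc$weight[enc$encounter_id == "E1" & enc$identity == "A"], 1.0)

  # duplicate (encounter, identity) rows collapse keeping confirmed
  dup <- encounter_table(c("E1", "E1"), c(0, 0), c("A", "A"),
                         c("confirmed", "?"))
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$certainty, "confirmed")

  # single confirmed sighting: minimal valid table
  one <- encounter_table("E1", 0, "A", "confirmed")
  expect_equal(one$weight, 1.0)

  expect_error(encounter_table(character(0), integer(0), character(0),
                               character(0)), class = "encontext_validation_error")
  expect_error(encounter_table(c("E1", "E2"), c(0, 0), c("A", "B"),
                               c("confirmed", "confirmed")),
               class = "encontext_validation_error")  # non-unique order
  expect_error(encounter_table("E1", 0, "A", "maybe"),
               class = "encontext_format_error")
  # closed-set violation is an error, never a silent drop
  expect_error(encounter_table("E1", 0, "Z", "confirmed",
                               identities = c("A", "B")),
               class = "encontext_validation_error")
})

test_that("encounter table round-trips through CSV/TSV and is row-order free", {
  enc <- toy_encounters()
  for (ext in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_encounter_table(enc, path, sep = if (ext == "tsv") "\t" else ",")
    back <- read_encounter_table(path, source = "train")
    expect_equal(as.data.frame(back), as.data.frame(enc))
  }
  # shuffled row order yields identical structure (member sets are order-free)
  perm <- c(7, 2, 5, 1, 3, 6, 4)
  shuf <- encounter_table(enc$encounter_id[perm], enc$order[perm],
                          enc$identity[perm], enc$certainty[perm],
                          source = "train")
  expect_equal(as.data.frame(shuf), as.data.frame(enc))

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("encounter_id,identity\nE1,A", path)
  expect_error(read_encounter_table(path), class = "encontext_format_error",
               regexp = "order")
})

test_that("posterior ingestion renormalizes, aligns columns, rejects garbage", {
  p <- matrix(c(0.5, 0.5, 0.2, 0.2), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("A", "B")))
  expect_message(ps <- make_post(p), "renormalized")
  expect_equal(unname(ps$prob[2, ]), c(0.5, 0.5))
  expect_equal(unname(ps$prob[1, ]), c(0.5, 0.5))

  expect_error(make_post(matrix(c(0, 0), 1, dimnames = list(NULL, c("A", "B")))),
               class = "encontext_validation_error", regexp = "img01")
  expect_error(make_post(matrix(c(0.9, -0.1), 1,
                                dimnames = list(NULL, c("A", "B")))),
               class = "encontext_validation_error")
  # any strictly positive row is renormalized (and logged)
  expect_message(ps3 <- make_post(matrix(c(0.3, 0.1), 1,
                                         dimnames = list(NULL, c("A", "B")))),
                 "renormalized")
  expect_equal(unname(ps3$prob[1, ]), c(0.75, 0.25))

  # CSV round trip with permuted identity columns aligns by label
  ids <- c("A", "B", "C")
  prob <- matrix(c(0.7, 0.2, 0.1, 0.1, 0.6, 0.3), 2, 3, byrow = TRUE,
                 dimnames = list(NULL, ids))
  ps <- posterior_set(c("i1", "i2"), c("E1", "E1"), prob,
                      true_identity = c("A", NA), identities = ids)
  path <- withr::local_tempfile(fileext = ".csv")
  write_posteriors(ps, path)
  back <- read_posteriors(path, identities = ids)
  expect_equal(back$prob, ps$prob, tolerance = 1e-12)
  expect_equal(back$true_identity, c("A", NA))
  # unknown identity column is an error
  expect_error(read_posteriors(path, identities = c("A", "B")),
               class = "encontext_validation_error")
})

test_that("context artifacts round-trip bit-identically with metadata", {
  art <- toy_artifacts()
  path <- withr::local_tempfile(fileext = ".json")
  write_context_artifacts(art, path)
  back <- read_context_artifacts(path)
  expect_identical(back$loglift, art$loglift)
  expect_identical(back$global_prior, art$global_prior)
  expect_identical(back$pair_counts, art$pair_counts)
  expect_equal(back$epsilon, art$epsilon)
  expect_equal(back$clip, art$clip)
  expect_equal(back$n_encounters, art$n_encounters)
  expect_equal(back$source, "train")
  # an entry exactly at the clip bound survives
  expect_true(any(back$loglift == -6))

  # files without epsilon are uninterpretable
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$epsilon <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(payload, path2, auto_unbox = TRUE, digits = NA)
  expect_error(read_context_artifacts(path2),
               class = "encontext_validation_error", regexp = "epsilon")
})

test_that("fusion weights reject negatives and wrong shapes", {
  expect_error(fusion_weights(1, -0.1, 0), class = "encontext_parameter_error")
  w <- fusion_weights(1, 0.5, 2)
  expect_equal(unclass(w), c(alpha = 1, beta = 0.5, gamma = 2))
})
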