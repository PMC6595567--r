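# The central dataset and its queries.

central_from_corpus <- function(tc, created = "2020-06-01T00:00:00Z") {
  batch <- read_batch(tc$dir)
  build_central(batch, normalize_studies(batch), created = created)
}

test_that("central dataset conserves every study and outcome row", {
  tc <- test_corpus(42, 10)
  ds <- central_from_corpus(tc)
  expect_equal(ds$source_count, 10)
  expect_equal(nrow(ds$studies), tc$manifest$totals$n_studies)
  expect_equal(nrow(ds$outcome_rows), tc$manifest$totals$n_outcome_rows)
  # raw free text preserved alongside normalized labels
  expect_true(all(c("methods", "blinding", "allocation") %in% names(ds$studies)))
  expect_false(any(grepl("<P>", ds$studies$methods, fixed = TRUE)))  # plain projection
})

test_that("an empty batch builds a valid zero-record dataset", {
  ds <- build_central(list(), created = "2020-06-01T00:00:00Z")
  expect_equal(ds$source_count, 0)
  expect_equal(nrow(ds$studies), 0)
  expect_equal(nrow(ds$outcome_rows), 0)
  f <- tempfile(fileext = ".xml")
  write_central_xml(ds, f)
  expect_true(file.exists(f))
})

test_that("rebuilding from shuffled input order is byte-identical", {
  tc <- test_corpus(42, 10)
  batch <- read_batch(tc$dir)
  recs <- normalize_studies(batch)
  f1 <- tempfile(fileext = ".xml"); f2 <- tempfile(fileext = ".xml")
  write_central_xml(build_central(batch, recs, created = "2020-06-01T00:00:00Z"), f1)
  set.seed(11)
  shuffled <- batch[sample(length(batch))]
  write_central_xml(build_central(shuffled, recs, created = "2020-06-01T00:00:00Z"), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("duplicate (review_id, study_id) collisions are hard errors", {
  rev <- make_demo_review()
  err <- tryCatch(build_central(list(rev, rev)), error = conditionMessage)
  expect_match(err, "DEMO01 Smith 1999", fixed = TRUE)
})

test_that("exports produce loadable tables with stable columns", {
  tc <- test_corpus(42, 10)
  ds <- central_from_corpus(tc)
  d <- file.path(tempdir(), "exports")
  files <- export_tables(ds, d, "csv")
  st <- readr::read_csv(file.path(d, "studies.csv"), col_types = readr::cols())
  orows <- readr::read_csv(file.path(d, "outcome_rows.csv"), col_types = readr::cols())
  expect_equal(nrow(st), nrow(ds$studies))
  expect_equal(nrow(orows), nrow(ds$outcome_rows))
  expect_equal(names(orows), names(ds$outcome_rows))
  # JSON mirrors the dataset
  export_tables(ds, d, "json")
  j <- jsonlite::read_json(file.path(d, "central.json"), simplifyVector = TRUE)
  expect_equal(j$source_count, ds$source_count)
  expect_equal(nrow(j$studies), nrow(ds$studies))
  expect_equal(j$outcome_rows$study_id, ds$outcome_rows$study_id)
  expect_equal(j$outcome_rows$events_1, ds$outcome_rows$events_1)
})

test_that("study years come from the id, then earliest reference, else excluded", {
  expect_equal(parse_study_year("Smith 1999"), 1999L)
  expect_equal(parse_study_year("Chen 2010a"), 2010L)
  expect_true(is.na(parse_study_year("NIMH Cooperative")))
  rev <- rm5_review(
    review_id = "YR1", title = "t",
    studies = tibble::tibble(study_id = c("Smith 1999", "Anon Study", "Lost Trial")),
    references = tibble::tibble(
      study_id = c("Smith 1999", "Anon Study", "Anon Study", "Lost Trial"),
      citation_id = paste0("R", 1:4),
      year = c(NA_integer_, 1988L, 1985L, NA_integer_),
      title = "r", journal = NA))
  ds <- build_central(rev, created = "x")
  yrs <- ds$studies$year[match(c("Smith 1999", "Anon Study", "Lost Trial"),
                               ds$studies$study_id)]
  expect_equal(yrs[1], 1999L)   # parsed from id, NA reference year ignored
  expect_equal(yrs[2], 1985L)   # earliest reference year
  expect_true(is.na(yrs[3]))    # excluded
  ys <- publication_year_histogram(ds, reference_year = 2019)
  expect_equal(ys$n_dated, 2)
  expect_equal(ys$n_excluded, 1)
  expect_equal(sum(tidy(ys)$n), ys$n_dated)
})

test_that("the year histogram over a corpus equals the manifest exactly", {
  tc <- test_corpus(42, 10)
  ds <- central_from_corpus(tc)
  ys <- publication_year_histogram(ds, reference_year = 2019)
  expect_equal(as.data.frame(tidy(ys)),
               as.data.frame(tc$manifest$totals$year_histogram))
  expect_equal(ys$n_dated + ys$n_excluded, nrow(ds$studies))
})

test_that("a corpus with half its studies older than 20 years reports 0.5", {
  old <- review_with_years("OLD1", c(1990, 1992, 1994, 1996, 1998))
  new <- review_with_years("NEW1", c(1999, 2004, 2008, 2012, 2016))
  ds <- build_central(list(old, new), created = "x")
  ys <- publication_year_histogram(ds, age_years = 20, reference_year = 2019)
  expect_identical(ys$fraction_older, 0.5)
})

test_that("participant totals sum parsed counts and count the missing", {
  revs <- purrr::imap(c(60L, 120L, 40L), function(n, i) {
    sid <- sprintf("Trial %d 200%d", i, i)
    rm5_review(
      review_id = "PT1x", title = "t",
      studies = tibble::tibble(study_id = sid),
      references = tibble::tibble(study_id = sid, citation_id = paste0("R", i),
                                  year = 2000L + i, title = "r", journal = NA),
      characteristics = tibble::tibble(
        study_id = sid, methods = "", interventions = "", outcomes = "", notes = "",
        participants = sprintf("<P>N=%d inpatients.</P>", n)))
  })
  merged <- revs[[1]]
  merged$studies <- dplyr::bind_rows(lapply(revs, `[[`, "studies"))
  merged$references <- dplyr::bind_rows(lapply(revs, `[[`, "references"))
  merged$characteristics <- dplyr::bind_rows(lapply(revs, `[[`, "characteristics"))
  ds <- build_central(merged, created = "x")
  sp <- sum_participants(ds)
  expect_equal(sp$total_participants, 220L)
  expect_equal(sp$n_missing, 0L)
  # adding a study with no parsable N leaves the total unchanged, missing+1
  merged$studies <- dplyr::bind_rows(merged$studies,
                                     tibble::tibble(study_id = "Extra 2009"))
  merged$references <- dplyr::bind_rows(
    merged$references,
    tibble::tibble(study_id = "Extra 2009", citation_id = "RX",
                   year = 2009L, title = "r", journal = NA))
  merged <- rm5_review(merged$review_id, merged$title, merged$studies,
                       merged$references, merged$characteristics)
  ds2 <- build_central(merged, created = "x")
  sp2 <- sum_participants(ds2)
  expect_equal(sp2$total_participants, 220L)
  expect_equal(sp2$n_missing, 1L)
  # all absent
  blank <- rm5_review(
    review_id = "PT2", title = "t",
    studies = tibble::tibble(study_id = "Solo 2001"),
    references = tibble::tibble(study_id = "Solo 2001", citation_id = "R1",
                                year = 2001L, title = "r", journal = NA))
  sp3 <- sum_participants(build_central(blank, created = "x"))
  expect_equal(sp3$total_participants, 0L)
  expect_equal(sp3$n_missing, 1L)
})

test_that("tidy, glance and autoplot methods work on result objects", {
  tc <- test_corpus(42, 10)
  ds <- central_from_corpus(tc)
  expect_equal(nrow(tidy(ds)), nrow(ds$studies))
  expect_equal(glance(ds)$n_outcome_rows, nrow(ds$outcome_rows))
  ys <- publication_year_histogram(ds, reference_year = 2019)
  p <- ggplot2::autoplot(ys)
  expect_s3_class(p, "ggplot")
  cl <- cluster_titles(harvest_titles(read_batch(tc$dir)))
  expect_s3_class(plot_title_clusters(cl), "ggplot")
})
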