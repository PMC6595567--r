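# Reading and writing the .rm5 dialect.

test_that("a written review reads back with the expected structure", {
  path <- write_demo_file()
  rev <- read_review(path)
  expect_equal(nrow(rev$studies), 3)
  expect_equal(nrow(rev$comparisons), 2)
  expect_equal(nrow(rev$references), 4)
  expect_equal(nrow(rev$outcomes), 5)
  expect_equal(nrow(rev$outcome_rows), 6)
  expect_true(rm5_identical(rev, make_demo_review()))
})

test_that("generated corpus counts equal the manifest", {
  tc <- test_corpus(42, 10)
  batch <- read_batch(tc$dir, schema_mode = "strict")
  expect_equal(length(batch), 10)
  n_studies <- sum(vapply(batch, function(r) nrow(r$studies), integer(1)))
  n_refs <- sum(vapply(batch, function(r) nrow(r$references), integer(1)))
  n_rows <- sum(vapply(batch, function(r) nrow(r$outcome_rows), integer(1)))
  expect_equal(n_studies, tc$manifest$totals$n_studies)
  expect_equal(n_rows, tc$manifest$totals$n_outcome_rows)
  expect_gte(n_refs, n_studies)  # many-to-one reports: at least one each
})

test_that("a minimal file with zero studies reads cleanly in lenient mode", {
  f <- tempfile(fileext = ".rm5")
  writeLines(paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<COCHRANE_REVIEW REVIEW_ID=\"EMPTY01\" VERSION=\"5.3\">",
    "<COVER_SHEET><TITLE>Empty</TITLE></COVER_SHEET>",
    "<STUDIES_AND_REFERENCES><STUDIES><INCLUDED_STUDIES/></STUDIES></STUDIES_AND_REFERENCES>",
    "<CHARACTERISTICS_OF_STUDIES><CHARACTERISTICS_OF_INCLUDED_STUDIES/></CHARACTERISTICS_OF_STUDIES>",
    "<QUALITY_ITEMS/><ANALYSES_AND_DATA/></COCHRANE_REVIEW>"), f)
  rev <- read_review(f, schema_mode = "lenient")
  expect_equal(nrow(rev$studies), 0)
  expect_equal(rev$review_id, "EMPTY01")
})

test_that("a dichotomous row with events > total is a validation error", {
  f <- write_demo_file(tempdir())
  txt <- readLines(f, warn = FALSE)
  txt <- sub("EVENTS_1=\"5\"", "EVENTS_1=\"35\"", txt)  # total_1 is 30
  f2 <- tempfile(fileext = ".rm5")
  writeLines(txt, f2)
  err <- expect_error(read_review(f2, schema_mode = "strict"),
                      class = "rm5_validation_error")
  expect_match(conditionMessage(err), "events exceed total")
  expect_warning(read_review(f2, schema_mode = "lenient"),
                 class = "rm5_lenient_warning")
})

test_that("malformed XML raises a classed parse error naming the file", {
  f <- write_demo_file(tempdir())
  corrupt_fixture(f, "truncate")
  err <- expect_error(read_review(f), class = "rm5_parse_error")
  expect_match(conditionMessage(err), basename(f), fixed = TRUE)
})

test_that("strict mode requires the studies container; lenient warns", {
  f <- write_demo_file(tempdir())
  corrupt_fixture(f, "missing_block")
  err <- expect_error(read_review(f, schema_mode = "strict"),
                      class = "rm5_schema_error")
  expect_match(conditionMessage(err), "STUDIES")
  expect_warning(rev <- read_review(f, schema_mode = "lenient"),
                 class = "rm5_lenient_warning")
  expect_equal(nrow(rev$studies), 0)
})

test_that("write_review rejects invariant violations before writing bytes", {
  rev <- make_demo_review()
  rev$references <- rev$references[rev$references$study_id != "Smith 1999", ]
  f <- tempfile(fileext = ".rm5")
  expect_error(write_review(rev, f), class = "rm5_validation_error")
  expect_false(file.exists(f))

  rev2 <- make_demo_review()
  rev2$outcome_rows$events_1[1] <- 999L
  expect_error(write_review(rev2, f), class = "rm5_validation_error")
  expect_false(file.exists(f))
})

test_that("randomized reviews round-trip field-for-field", {
  for (seed in 1:25) {
    r <- random_review(seed)
    f <- tempfile(fileext = ".rm5")
    write_review(r, f)
    r2 <- read_review(f, schema_mode = "strict")
    expect_true(rm5_identical(r, r2), label = sprintf("seed %d round trip", seed))
    unlink(f)
  }
})

test_that("an unedited read/write cycle is canonical-XML-equal to the source", {
  tc <- test_corpus(42, 10)
  for (f in Sys.glob(file.path(tc$dir, "*.rm5"))) {
    rev <- read_review(f)
    f2 <- tempfile(fileext = ".rm5")
    write_review(rev, f2)
    expect_true(xml_canonical_equal(f, f2), label = basename(f))
    unlink(f2)
  }
})

test_that("retained opaque subtrees survive round trips in document order", {
  rev <- make_demo_review()
  rev$retained <- tibble::tibble(
    parent = c("", "STUDIES"), position = c(3L, 2L),
    xml = c("<PRISMA_DIAGRAM kind=\"flow\"><NODE N=\"1\"/></PRISMA_DIAGRAM>",
            "<EXCLUDED_STUDIES><STUDY ID=\"Gone 1990\" NAME=\"Gone 1990\"/></EXCLUDED_STUDIES>"))
  f <- tempfile(fileext = ".rm5")
  write_review(rev, f)
  r2 <- read_review(f)
  expect_true(rm5_identical(rev, r2))
  doc <- xml2::read_xml(f)
  kids <- xml2::xml_name(xml2::xml_children(doc))
  expect_equal(which(kids == "PRISMA_DIAGRAM"), 3L)
})

test_that("batch reading is deterministic and reports per-file failures", {
  tc <- test_corpus(42, 10)
  # copy corpus into a fresh dir in shuffled order; result must not depend on it
  d2 <- file.path(tempdir(), "shuffled_corpus")
  unlink(d2, recursive = TRUE); dir.create(d2)
  files <- Sys.glob(file.path(tc$dir, "*.rm5"))
  for (f in sample(files)) file.copy(f, d2)
  b1 <- read_batch(tc$dir)
  b2 <- read_batch(d2)
  ids1 <- vapply(b1, function(r) r$review_id, character(1))
  ids2 <- vapply(b2, function(r) r$review_id, character(1))
  expect_identical(ids1, ids2)
  expect_identical(ids1, sort(ids1, method = "radix"))

  # inject one corrupt file: others still load, failure recorded
  corrupt_fixture(file.path(d2, "SR0003.rm5"), "truncate")
  expect_warning(b3 <- read_batch(d2), class = "rm5_batch_failure_warning")
  expect_equal(length(b3), 9)
  expect_equal(nrow(batch_failures(b3)), 1)
  expect_match(batch_failures(b3)$path, "SR0003")
})

test_that("an empty directory yields an empty batch with a warning", {
  d <- file.path(tempdir(), "empty_corpus_dir")
  unlink(d, recursive = TRUE); dir.create(d)
  expect_warning(b <- read_batch(d), class = "rm5_empty_batch_warning")
  expect_length(b, 0)
})
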