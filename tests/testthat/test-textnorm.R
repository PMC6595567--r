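# Rule-engine normalisation of free text.

test_that("the classic blinding surface forms all normalize to 'double'", {
  rs <- load_ruleset()
  for (phrase in c("double blind", "double-blind", "doubly blinded")) {
    expect_equal(
      apply_rules(sprintf("Allocation: randomised. Blinding: %s.", phrase),
                  rs, "methods", variable = "blinding"),
      "double", label = phrase)
  }
  # field-scoped call without a variable filter: blinding rules outrank
  # allocation rules by priority, so the same text yields the blinding label
  expect_equal(apply_rules("Allocation: randomised. Blinding: double blind.",
                           rs, "methods"), "double")
})

test_that("every phrase-bank entry maps to its labelled canonical form", {
  rs <- load_ruleset()
  bank <- readr::read_csv(default_phrase_bank_path(), col_types = "cc")
  expect_gte(nrow(bank), 10)
  got <- vapply(bank$phrase, function(p) {
    apply_rules(sprintf("<P>Blinding: %s. Duration: 6 weeks.</P>", p),
                rs, "methods", variable = "blinding")
  }, character(1))
  expect_equal(unname(got), bank$label)
})

test_that("no match falls back, and matching is total on arbitrary text", {
  rs <- load_ruleset()
  expect_equal(apply_rules("", rs, "methods"), "unclassified")
  hostile <- c("étude ouverte (
)", "(((", "NA", "12345", strrep("x", 5000))
  for (txt in hostile) {
    expect_true(is.character(apply_rules(txt, rs, "methods", variable = "blinding")))
  }
})

test_that("priority resolution agrees with an all-rules brute-force oracle", {
  set.seed(901)
  for (i in 1:300) {
    case <- random_ruleset_and_text()
    expect_identical(apply_rules(case$text, case$rs, "methods"),
                     oracle_apply_rules(case$text, case$rs, "methods"),
                     label = sprintf("case %d (%s)", i, case$text))
  }
})

test_that("rule files are validated on load with the offending rule named", {
  write_rules <- function(lines) {
    f <- tempfile(fileext = ".yaml")
    writeLines(c("name: t", "fallback: unclassified", "rules:", lines), f)
    f
  }
  # duplicate priority within a field
  f <- write_rules(c(
    "  - {field: methods, pattern: foo, label: a, priority: 5}",
    "  - {field: methods, pattern: bar, label: b, priority: 5}"))
  expect_error(load_ruleset(f), class = "rm5_config_error")
  expect_match(tryCatch(load_ruleset(f), error = conditionMessage), "priority 5")
  # non-compiling pattern
  f <- write_rules("  - {field: methods, pattern: '(', label: a, priority: 1}")
  err <- tryCatch(load_ruleset(f), error = conditionMessage)
  expect_match(err, "(", fixed = TRUE)
  # missing key
  f <- write_rules("  - {field: methods, label: a, priority: 1}")
  expect_error(load_ruleset(f), class = "rm5_config_error")
  # same priority in different fields is fine
  f <- write_rules(c(
    "  - {field: methods, pattern: foo, label: a, priority: 5}",
    "  - {field: notes, pattern: bar, label: b, priority: 5}"))
  expect_s3_class(load_ruleset(f), "rm5_ruleset")
})

test_that("participant totals are cue-anchored, never guessed", {
  expect_equal(extract_participants_total("N=120 inpatients with schizophrenia"), 120L)
  expect_equal(extract_participants_total("12 weeks, N=60"), 60L)
  expect_equal(extract_participants_total("n = 45 randomised"), 45L)
  expect_equal(extract_participants_total("120 participants enrolled"), 120L)
  expect_equal(extract_participants_total("80 patients; 12 week trial"), 80L)
  expect_true(is.na(extract_participants_total("one hundred participants")))
  expect_true(is.na(extract_participants_total("study ran for 12 weeks")))
  expect_true(is.na(extract_participants_total("")))
})

test_that("durations in weeks are extracted; other units left absent", {
  expect_equal(extract_duration_weeks("Duration: 8 weeks."), 8)
  expect_equal(extract_duration_weeks("over 12.5 weeks of treatment"), 12.5)
  expect_true(is.na(extract_duration_weeks("6 months follow-up")))
  expect_true(is.na(extract_duration_weeks("")))
})

test_that("normalize_studies reproduces every manifest label over a corpus", {
  tc <- test_corpus(42, 10)
  batch <- read_batch(tc$dir)
  recs <- normalize_studies(batch)
  joined <- dplyr::inner_join(recs, tc$manifest$studies,
                              by = c("review_id", "study_id"),
                              suffix = c("", ".true"))
  expect_equal(nrow(joined), tc$manifest$totals$n_studies)
  expect_identical(joined$blinding, joined$blinding.true)
  expect_identical(joined$allocation, joined$allocation.true)
  expect_identical(joined$n_participants, joined$n_participants.true)
  expect_identical(joined$duration_weeks, joined$duration_weeks.true)
})

test_that("empty characteristics give fallback labels and absent numerics", {
  rev <- make_demo_review()
  rec <- normalize_study(rev, "Chen 2010a")
  expect_equal(rec$blinding, "unclassified")
  expect_equal(rec$allocation, "unclassified")
  expect_true(is.na(rec$duration_weeks))
  expect_true(is.na(rec$n_participants))
  # identical text -> identical records (determinism)
  r1 <- normalize_study(rev, "Smith 1999")
  r2 <- normalize_study(rev, "Smith 1999")
  expect_identical(r1, r2)
  expect_error(normalize_study(rev, "Nobody 1900"), class = "rm5_lookup_error")
})
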