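# Outcome-title harvesting, clustering and mapping.

# tiny helper: a review with one outcome per title given
review_with_titles <- function(review_id, titles) {
  n <- length(titles)
  rm5_review(
    review_id = review_id, title = "t",
    studies = tibble::tibble(study_id = "Solo 2000"),
    references = tibble::tibble(study_id = "Solo 2000", citation_id = "R1",
                                year = 2000L, title = "r", journal = NA),
    comparisons = tibble::tibble(comparison_id = "C1", name = "cmp"),
    outcomes = tibble::tibble(comparison_id = "C1",
                              outcome_id = sprintf("O%02d", seq_len(n)),
                              title = titles, data_type = "dichotomous"))
}

test_that("case/punctuation variants share one canonical form and cluster", {
  variants <- c("Mental state", "mental state", "Mental State.")
  expect_equal(unique(canonical_title(variants)), "mental state")
  expect_equal(canonical_title("1.1 Mental state"), "mental state")
  rev <- review_with_titles("RV1", variants)
  cl <- cluster_titles(harvest_titles(rev))
  expect_equal(length(unique(cl$cluster_id)), 1)
  expect_equal(nrow(cl), 3)
  expect_equal(unique(cl$cluster_count), 3)
})

test_that("harvest counts each (review, comparison, outcome) occurrence once", {
  r1 <- review_with_titles("RV1", c("Relapse", "Relapse", "Weight gain"))
  r2 <- review_with_titles("RV2", c("Relapse", "Quality of life"))
  h <- harvest_titles(list(r1, r2))
  expect_equal(sum(h$count), 5)
  rel <- h[h$raw_title == "Relapse", ]
  expect_equal(rel$count, 3)
  expect_equal(rel$source_reviews[[1]], c("RV1", "RV2"))
  expect_equal(h$raw_title[1], "Relapse")  # sorted by descending count
  # single review, single outcome
  h1 <- harvest_titles(review_with_titles("RV3", "Insight"))
  expect_equal(nrow(h1), 1)
  expect_equal(h1$count, 1)
})

test_that("harvest and clustering agree with the corpus manifest", {
  tc <- test_corpus(42, 10)
  batch <- read_batch(tc$dir)
  h <- harvest_titles(batch)
  expect_equal(nrow(h), tc$manifest$totals$n_distinct_titles)
  expect_equal(sum(h$count), tc$manifest$totals$n_occurrences)
  cl <- cluster_titles(h)
  expect_equal(length(unique(cl$cluster_id)), tc$manifest$totals$n_clusters)
  # partition: every record in exactly one cluster; counts conserved
  expect_equal(nrow(cl), nrow(h))
  expect_setequal(cl$raw_title, h$raw_title)
  totals <- dplyr::distinct(cl, cluster_id, cluster_count)
  expect_equal(sum(totals$cluster_count), sum(h$count))
  # harvest is idempotent over a rewritten corpus
  d2 <- file.path(tempdir(), "reexport_corpus")
  unlink(d2, recursive = TRUE); dir.create(d2)
  for (r in batch) write_review(r, file.path(d2, paste0(r$review_id, ".rm5")))
  h2 <- harvest_titles(read_batch(d2))
  expect_equal(as.data.frame(h, stringsAsFactors = FALSE),
               as.data.frame(h2, stringsAsFactors = FALSE))
})

test_that("worksheet exports round-trip and untouched sheets give empty mappings", {
  tc <- test_corpus(42, 10)
  cl <- cluster_titles(harvest_titles(read_batch(tc$dir)))
  f <- tempfile(fileext = ".csv")
  export_worksheet(cl, f)
  ws <- readr::read_csv(f, col_types = readr::cols())
  expect_equal(names(ws), c("raw_title", "canonical_form", "count",
                            "category", "subcategory"))
  expect_equal(nrow(ws), nrow(cl))
  # untouched categories -> empty mapping
  m0 <- import_mapping(f)
  expect_equal(nrow(m0), 0)
  # fill five rows -> mapping of size five
  ws$category[1:5] <- "Mental health"
  f2 <- tempfile(fileext = ".csv")
  readr::write_csv(ws, f2, na = "")
  m5 <- import_mapping(f2)
  expect_equal(nrow(m5), 5)
  # unknown category rejected when a category list is declared
  err <- tryCatch(import_mapping(f2, categories = c("Adverse effects")),
                  error = conditionMessage)
  expect_match(err, "Mental health")
  # empty corpus -> header-only worksheet
  f3 <- tempfile(fileext = ".csv")
  export_worksheet(harvest_titles(list()), f3)
  expect_equal(nrow(readr::read_csv(f3, col_types = readr::cols())), 0)
})

test_that("apply_mapping tags occurrences and reports the unmapped fraction", {
  titles <- sprintf("Outcome %02d", 1:10)
  rev <- review_with_titles("RV1", titles)
  mapping <- tibble::tibble(raw_title = titles[1:8], category = "Cat",
                            subcategory = NA_character_)
  class(mapping) <- c("rm5_mapping", class(mapping))
  tagged <- apply_mapping(rev, mapping)
  expect_equal(nrow(tagged), 10)
  expect_equal(sum(tagged$category == "Cat"), 8)
  expect_equal(sum(tagged$category == "UNMAPPED"), 2)
  expect_equal(attr(tagged, "report")$unmapped_fraction, 0.2)
  # empty mapping: everything unmapped
  all_un <- apply_mapping(rev, NULL)
  expect_equal(attr(all_un, "report")$unmapped_fraction, 1)
})
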