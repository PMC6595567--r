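# Seeded generator of synthetic .rm5 corpora with a ground-truth manifest.
#
# No real review corpus is distributable, so every extraction stage is tested
# against generated files whose true content is known exactly. The generator
# emulates the structures the dialect models: many-to-one report references
# per study, the five-field characteristics table with realistically messy
# free text (blinding phrase variants, "N=<n>" totals, durations), a
# risk-of-bias table, and dichotomous/continuous outcome tables whose titles
# are (base title, surface variant) pairs. The manifest it emits is the
# oracle: pipeline output is compared against it exactly, never loosely.

surname_bank <- c(
  "Smith", "Jones", "Chen", "Garcia", "Kumar", "Okafor", "Mueller", "Tanaka",
  "Rossi", "Novak", "Silva", "Dubois", "Larsen", "Kowalski", "Ivanov",
  "Nguyen", "Haddad", "Owusu", "Bergstrom", "Castillo", "Dimitrov", "Eriksen",
  "Fontaine", "Grigore", "Horvat", "Iqbal", "Jansen", "Keita", "Lindgren",
  "Moreau", "Nakamura", "Olsen", "Petrov", "Quinn", "Rahman", "Santos",
  "Takahashi", "Urbina", "Vasquez", "Weber")

rob_item_bank <- c(
  "Random sequence generation", "Allocation concealment",
  "Blinding of participants and personnel", "Blinding of outcome assessment",
  "Incomplete outcome data", "Selective reporting")

drug_bank <- c("chlorpromazine", "haloperidol", "risperidone", "olanzapine",
               "quetiapine", "clozapine", "amisulpride", "aripiprazole")

allocation_phrase_bank <- function() {
  tibble(
    phrase = c("randomised", "randomized", "randomly allocated to groups",
               "random allocation by computer-generated list",
               "quasi-randomised by alternation",
               "allocation by date of birth",
               "Allocation: not stated"),
    label = c("randomised", "randomised", "randomised", "randomised",
              "quasi", "quasi", "unclear"))
}

#' Paths of the shipped phrase and title banks
#' @return File path.
#' @export
default_phrase_bank_path <- function() {
  system.file("extdata", "blinding_phrases.csv", package = "rm5tools")
}

#' @rdname default_phrase_bank_path
#' @export
default_title_bank_path <- function() {
  system.file("extdata", "title_bank.csv", package = "rm5tools")
}

load_phrase_bank <- function(path = default_phrase_bank_path()) {
  pb <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (nrow(pb) == 0) stop_rm5("rm5_config_error", "phrase bank is empty")
  pb
}

load_title_bank <- function(path = default_title_bank_path()) {
  tb <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (nrow(tb) == 0) stop_rm5("rm5_config_error", "title bank is empty")
  tb
}

# deterministic surface variants of a base title; all share one canonical form
title_variant <- function(title, variant_id) {
  switch(variant_id,
         `1` = title,
         `2` = tolower(title),
         `3` = paste0(title, "."),
         `4` = paste0("1.", variant_id, " ", title),
         title)
}

with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sample_int <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)

#' Generate a synthetic review corpus with a ground-truth manifest
#'
#' Writes `n_reviews` valid .rm5 files plus `manifest.json` to `out_dir`.
#' The same seed always yields a byte-identical corpus. Free text is
#' assembled from templated sentences embedding a blinding phrase drawn from
#' the phrase bank, the true participant total as `"N=<n>"`, an allocation
#' phrase and a duration in weeks; outcome titles are (base title, surface
#' variant) pairs from the title bank, so the expected number of title
#' clusters equals the number of distinct base titles used. Dichotomous rows
#' always satisfy `events <= total`. Publication years default to 1960-2015,
#' wide enough to exercise corpus-age queries.
#'
#' @param seed Integer RNG seed (the caller's RNG state is preserved).
#' @param n_reviews Number of reviews to generate (>= 0).
#' @param out_dir Output directory, created if needed.
#' @param studies_per_review Integer range (length 2) of studies per review.
#' @param phrase_bank,title_bank Paths to the CSV banks; package defaults
#'   ship with >= 10 blinding surface forms and 37 base titles.
#' @param year_range Integer range of publication years.
#' @param retained_fraction Fraction of reviews given an extra
#'   awaiting-classification subtree outside the supported subset, to
#'   exercise opaque retention.
#' @return A `rm5_manifest`: list with `seed`, `n_reviews`, `studies` and
#'   `outcomes` tibbles, and a `totals` list (study count, outcome table
#'   occurrences and data-row count, distinct titles, expected cluster
#'   count, year histogram, per-review participant totals).
#' @export
generate_corpus <- function(seed, n_reviews, out_dir,
                            studies_per_review = c(2L, 8L),
                            phrase_bank = default_phrase_bank_path(),
                            title_bank = default_title_bank_path(),
                            year_range = c(1960L, 2015L),
                            retained_fraction = 0.2) {
  stopifnot(n_reviews >= 0, length(studies_per_review) == 2)
  pb <- load_phrase_bank(phrase_bank)
  tb <- load_title_bank(title_bank)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  with_preserved_rng(seed, {
    man_studies <- list()
    man_outcomes <- list()
    for (i in seq_len(n_reviews)) {
      review_id <- sprintf("SR%04d", i)
      g <- generate_review(review_id, pb, tb, studies_per_review,
                           year_range, retained_fraction)
      write_review(g$review, file.path(out_dir, paste0(review_id, ".rm5")))
      man_studies[[i]] <- g$studies
      man_outcomes[[i]] <- g$outcomes
    }
    studies <- if (length(man_studies)) bind_rows(man_studies) else tibble(
      review_id = character(0), study_id = character(0), year = integer(0),
      n_participants = integer(0), blinding = character(0),
      phrase_index = integer(0), allocation = character(0),
      duration_weeks = double(0))
    outcomes <- if (length(man_outcomes)) bind_rows(man_outcomes) else tibble(
      review_id = character(0), comparison_id = character(0),
      outcome_id = character(0), base_id = character(0),
      variant_id = integer(0), title = character(0),
      data_type = character(0), n_rows = integer(0))
    manifest <- build_manifest(seed, n_reviews, studies, outcomes)
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
    manifest
  })
}

generate_review <- function(review_id, pb, tb, studies_per_review,
                            year_range, retained_fraction) {
  n_studies <- sample_int(studies_per_review[1], studies_per_review[2])
  surnames <- sample(surname_bank, n_studies)
  years <- sample(year_range[1]:year_range[2], n_studies, replace = TRUE)
  study_ids <- paste(surnames, years)

  alloc_bank <- allocation_phrase_bank()
  refs <- list(); chars <- list(); rob <- list()
  man_st <- list()
  for (k in seq_len(n_studies)) {
    sid <- study_ids[k]
    n_refs <- sample_int(1, 3)
    refs[[k]] <- tibble(
      study_id = sid,
      citation_id = sprintf("REF-%s-%d", gsub(" ", "-", sid), seq_len(n_refs)),
      year = as.integer(years[k] + c(0L, sort(sample(0:3, n_refs - 1, replace = TRUE)))[seq_len(n_refs)]),
      title = paste0("Report ", seq_len(n_refs), " of trial ", sid),
      journal = sample(c("J Clin Psychiatry", "Br J Psychiatry",
                         "Schizophr Res", NA_character_), n_refs, replace = TRUE))
    phrase_index <- sample_int(1, nrow(pb))
    alloc_index <- sample_int(1, nrow(alloc_bank))
    n_participants <- sample_int(3, 30) * 4L
    duration <- sample(c(4L, 6L, 8L, 12L, 26L, 52L), 1)
    drug <- sample(drug_bank, 1)
    methods <- sprintf(
      "<P>Allocation: %s. Blinding: %s. Duration: %d weeks.</P>",
      alloc_bank$phrase[alloc_index], pb$phrase[phrase_index], duration)
    participants <- sprintf(
      "<P>N=%d %s with schizophrenia. Mean age %d years.</P>",
      n_participants, sample(c("inpatients", "outpatients"), 1),
      sample_int(25, 55))
    interventions <- sprintf(
      "<P>1. %s: dose %d mg/day. 2. Placebo.</P>", drug, sample_int(5, 60) * 10L)
    outcomes_txt <- "<P>Clinical response, adverse effects and service outcomes reported.</P>"
    notes <- if (stats::runif(1) < 0.3) "" else
      sprintf("<P>Funding: %s.</P>", sample(c("industry", "public", "not stated"), 1))
    chars[[k]] <- tibble(study_id = sid, methods = methods,
                         participants = participants,
                         interventions = interventions,
                         outcomes = outcomes_txt, notes = notes)
    items <- sample(rob_item_bank, sample_int(2, 4))
    rob[[k]] <- tibble(
      study_id = sid, item_name = items,
      judgement = sample(rob_judgements, length(items), replace = TRUE),
      support = paste0("Quote: '", tolower(items), " procedure described'."))
    man_st[[k]] <- tibble(
      review_id = review_id, study_id = sid, year = as.integer(years[k]),
      n_participants = as.integer(n_participants),
      blinding = pb$label[phrase_index],
      phrase_index = as.integer(phrase_index),
      allocation = alloc_bank$label[alloc_index],
      duration_weeks = as.numeric(duration))
  }
  rob_tbl <- bind_rows(rob)
  # group item-major, preserving first-appearance order (document layout)
  rob_tbl <- rob_tbl[order(match(rob_tbl$item_name, unique(rob_tbl$item_name))), ]

  n_cmp <- sample_int(1, 3)
  comparisons <- tibble(
    comparison_id = sprintf("%s.CMP%02d", review_id, seq_len(n_cmp)),
    name = paste(sample(drug_bank, n_cmp), "versus placebo"))
  outcomes <- list(); rows <- list(); man_out <- list()
  oi <- 0L
  for (c_i in seq_len(n_cmp)) {
    n_out <- sample_int(1, 4)
    base_rows <- tb[sample(nrow(tb), n_out), , drop = FALSE]
    for (o_i in seq_len(n_out)) {
      oi <- oi + 1L
      variant_id <- sample_int(1, 4)
      title <- title_variant(base_rows$title[o_i], variant_id)
      # first outcome of the review is always dichotomous so every file has
      # one (negative tests corrupt its counts)
      dt <- if (oi == 1L) "dichotomous" else sample(c("dichotomous", "continuous"), 1)
      oid <- sprintf("%s.O%03d", comparisons$comparison_id[c_i], o_i)
      outcomes[[oi]] <- tibble(
        comparison_id = comparisons$comparison_id[c_i], outcome_id = oid,
        title = title, data_type = dt)
      in_outcome <- which(stats::runif(n_studies) < 0.7)
      if (!length(in_outcome)) in_outcome <- sample_int(1, n_studies)
      r <- tibble(comparison_id = comparisons$comparison_id[c_i],
                  outcome_id = oid, study_id = study_ids[in_outcome],
                  events_1 = NA_integer_, total_1 = NA_integer_,
                  events_2 = NA_integer_, total_2 = NA_integer_,
                  mean_1 = NA_real_, sd_1 = NA_real_, n_1 = NA_integer_,
                  mean_2 = NA_real_, sd_2 = NA_real_, n_2 = NA_integer_)
      m <- length(in_outcome)
      if (dt == "dichotomous") {
        r$total_1 <- as.integer(sample(20:60, m, replace = TRUE))
        r$total_2 <- as.integer(sample(20:60, m, replace = TRUE))
        r$events_1 <- as.integer(floor(stats::runif(m) * (r$total_1 + 1)))
        r$events_2 <- as.integer(floor(stats::runif(m) * (r$total_2 + 1)))
      } else {
        r$n_1 <- as.integer(sample(20:60, m, replace = TRUE))
        r$n_2 <- as.integer(sample(20:60, m, replace = TRUE))
        r$mean_1 <- round(stats::rnorm(m, 50, 10), 2)
        r$mean_2 <- round(stats::rnorm(m, 50, 10), 2)
        r$sd_1 <- round(stats::runif(m, 1, 15), 2)
        r$sd_2 <- round(stats::runif(m, 1, 15), 2)
      }
      rows[[oi]] <- r
      man_out[[oi]] <- tibble(
        review_id = review_id,
        comparison_id = comparisons$comparison_id[c_i], outcome_id = oid,
        base_id = base_rows$base_id[o_i], variant_id = as.integer(variant_id),
        title = title, data_type = dt, n_rows = m)
    }
  }

  retained <- if (stats::runif(1) < retained_fraction) {
    tibble(parent = "STUDIES", position = 2L,
           xml = paste0("<AWAITING_STUDIES><STUDY ID=\"Pending ",
                        sample(1990:2015, 1),
                        "\" NAME=\"awaiting classification\"/></AWAITING_STUDIES>"))
  } else NULL

  review <- rm5_review(
    review_id = review_id,
    title = paste(sample(drug_bank, 1), "versus placebo for schizophrenia"),
    studies = tibble(study_id = study_ids),
    references = bind_rows(refs),
    characteristics = bind_rows(chars),
    risk_of_bias = rob_tbl,
    comparisons = comparisons,
    outcomes = bind_rows(outcomes),
    outcome_rows = bind_rows(rows),
    retained = retained)
  list(review = review, studies = bind_rows(man_st), outcomes = bind_rows(man_out))
}

build_manifest <- function(seed, n_reviews, studies, outcomes) {
  year_hist <- if (nrow(studies)) {
    studies %>% count(.data$year, name = "n") %>% arrange(.data$year)
  } else tibble(year = integer(0), n = integer(0))
  participants <- if (nrow(studies)) {
    studies %>% group_by(.data$review_id) %>%
      summarise(total_participants = sum(.data$n_participants),
                n_studies = dplyr::n(), .groups = "drop") %>%
      arrange(.data$review_id)
  } else tibble(review_id = character(0), total_participants = integer(0),
                n_studies = integer(0))
  totals <- list(
    n_studies = nrow(studies),
    n_occurrences = nrow(outcomes),
    n_outcome_rows = sum(outcomes$n_rows),
    n_distinct_titles = length(unique(outcomes$title)),
    n_clusters = length(unique(outcomes$base_id)),
    year_histogram = year_hist,
    participants = participants)
  structure(list(seed = seed, n_reviews = n_reviews, studies = studies,
                 outcomes = outcomes, totals = totals),
            class = "rm5_manifest")
}

#' @export
print.rm5_manifest <- function(x, ...) {
  cat(sprintf("<rm5_manifest> seed %d: %d review(s), %d studies, %d outcome tables, %d data rows\n",
              x$seed, x$n_reviews, x$totals$n_studies, x$totals$n_occurrences,
              x$totals$n_outcome_rows))
  invisible(x)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a corpus manifest back from JSON
#' @param path Path to a `manifest.json` written by [generate_corpus()].
#' @return An `rm5_manifest`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$studies <- as_tibble(m$studies)
  m$outcomes <- as_tibble(m$outcomes)
  m$totals$year_histogram <- as_tibble(m$totals$year_histogram)
  m$totals$participants <- as_tibble(m$totals$participants)
  structure(m, class = "rm5_manifest")
}

#' Check a manifest's internal consistency
#'
#' Recomputes every aggregate in `totals` from the manifest's own per-review
#' entries and errors on disagreement.
#'
#' @param manifest An `rm5_manifest`.
#' @return Invisibly `TRUE`.
#' @export
validate_manifest <- function(manifest) {
  recomputed <- build_manifest(manifest$seed, manifest$n_reviews,
                               manifest$studies, manifest$outcomes)
  if (!isTRUE(all.equal(as.data.frame(recomputed$totals$year_histogram),
                        as.data.frame(manifest$totals$year_histogram))) ||
      !isTRUE(all.equal(as.data.frame(recomputed$totals$participants),
                        as.data.frame(manifest$totals$participants))) ||
      !identical(recomputed$totals[c("n_studies", "n_occurrences", "n_outcome_rows",
                                     "n_distinct_titles", "n_clusters")],
                 manifest$totals[c("n_studies", "n_occurrences", "n_outcome_rows",
                                   "n_distinct_titles", "n_clusters")])) {
    stop_rm5("rm5_validation_error", "manifest totals disagree with per-review entries")
  }
  invisible(TRUE)
}

#' Generate one randomized in-memory review
#'
#' Used for round-trip property testing: produces a structurally valid
#' review with adversarial content (XML-special characters, unicode,
#' absent optional values) without touching disk.
#'
#' @param seed Integer seed.
#' @return An `rm5_review`.
#' @export
random_review <- function(seed) {
  with_preserved_rng(seed, {
    pb <- load_phrase_bank()
    tb <- load_title_bank()
    g <- generate_review(sprintf("RND%06d", seed), pb, tb, c(1L, 6L),
                         c(1950L, 2020L), retained_fraction = 0.5)
    rev <- g$review
    # sprinkle XML-hostile content through text fields
    if (nrow(rev$references)) {
      rev$references$title[1] <- "Efficacy & safety of <novel> drug \"X\" vs placebo — süperiorité?"
    }
    if (nrow(rev$outcomes)) {
      rev$outcomes$title[1] <- "Mental state: BPRS <50% reduction & relapse"
    }
    i <- nrow(rev$characteristics)
    rev$characteristics$notes[i] <- "<P>Comparison arms: A &amp; B; dose &lt;300 mg.</P>"
    rev$title <- paste0(rev$title, " — révision")
    rev
  })
}

#' Deterministically corrupt a fixture file for negative tests
#'
#' @param path A valid .rm5 file (modified in place).
#' @param mode `"truncate"` (malformed XML), `"bad_numbers"` (a dichotomous
#'   row with events > total), or `"missing_block"` (drops the studies
#'   container).
#' @return Invisibly, `path`.
#' @export
corrupt_fixture <- function(path, mode = c("truncate", "bad_numbers", "missing_block")) {
  mode <- match.arg(mode)
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  txt <- switch(mode,
    truncate = substr(txt, 1, floor(nchar(txt) * 0.6)),
    bad_numbers = sub("EVENTS_1=\"[0-9]+\"", "EVENTS_1=\"999\"", txt),
    missing_block = gsub("(?s)<STUDIES_AND_REFERENCES>.*?</STUDIES_AND_REFERENCES>",
                         "", txt, perl = TRUE))
  con <- file(path, open = "wb")
  writeBin(charToRaw(txt), con)
  close(con)
  invisible(path)
}
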