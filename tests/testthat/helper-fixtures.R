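# Shared fixtures: all generated in code at test time, nothing stored.

# one generated corpus per (seed, n), cached for the session
.corpus_cache <- new.env(parent = emptyenv())

test_corpus <- function(seed = 42, n = 10) {
  key <- sprintf("s%d_n%d", seed, n)
  if (is.null(.corpus_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("rm5_corpus_", key))
    unlink(dir, recursive = TRUE)
    manifest <- generate_corpus(seed = seed, n_reviews = n, out_dir = dir)
    .corpus_cache[[key]] <- list(dir = dir, manifest = manifest)
  }
  .corpus_cache[[key]]
}

# a small hand-built review with fully known structure
make_demo_review <- function(review_id = "DEMO01") {
  studies <- tibble::tibble(study_id = c("Smith 1999", "Jones 2005", "Chen 2010a"))
  references <- tibble::tibble(
    study_id = c("Smith 1999", "Smith 1999", "Jones 2005", "Chen 2010a"),
    citation_id = c("R1", "R2", "R3", "R4"),
    year = c(1999L, 2001L, 2005L, NA_integer_),
    title = paste("Report", 1:4),
    journal = c("J One", NA, "J Two", "J Three"))
  characteristics <- tibble::tibble(
    study_id = studies$study_id,
    methods = c("<P>Allocation: randomised. Blinding: double blind. Duration: 12 weeks.</P>",
                "<P>Quasi-randomised by alternation. Blinding: open label.</P>",
                ""),
    participants = c("<P>N=60 inpatients.</P>", "<P>120 outpatients enrolled.</P>", ""),
    interventions = c("<P>Drug A vs placebo.</P>", "<P>Drug B vs placebo.</P>", ""),
    outcomes = c("<P>Primary: relapse.</P>", "", ""),
    notes = c("", "<P>Industry funded.</P>", ""))
  risk_of_bias <- tibble::tibble(
    study_id = c("Smith 1999", "Jones 2005"),
    item_name = c("Allocation concealment", "Allocation concealment"),
    judgement = c("low", "unclear"),
    support = c("central pharmacy", "not described"))
  comparisons <- tibble::tibble(comparison_id = c("C1", "C2"),
                                name = c("Drug A vs placebo", "Drug B vs placebo"))
  outcomes <- tibble::tibble(
    comparison_id = c("C1", "C1", "C1", "C2", "C2"),
    outcome_id = c("O1", "O2", "O3", "O4", "O5"),
    title = c("Relapse", "Mental state", "Leaving early", "Relapse", "Weight gain"),
    data_type = c("dichotomous", "continuous", "dichotomous", "dichotomous", "continuous"))
  outcome_rows <- tibble::tibble(
    comparison_id = c("C1", "C1", "C1", "C1", "C2", "C2"),
    outcome_id = c("O1", "O1", "O2", "O3", "O4", "O5"),
    study_id = c("Smith 1999", "Jones 2005", "Smith 1999", "Jones 2005",
                 "Smith 1999", "Chen 2010a"),
    events_1 = c(5L, 8L, NA, 3L, 2L, NA),
    total_1 = c(30L, 60L, NA, 60L, 30L, NA),
    events_2 = c(9L, 12L, NA, 4L, 7L, NA),
    total_2 = c(30L, 60L, NA, 58L, 30L, NA),
    mean_1 = c(NA, NA, 45.2, NA, NA, 2.5),
    sd_1 = c(NA, NA, 9.1, NA, NA, 1.1),
    n_1 = c(NA, NA, 30L, NA, NA, 40L),
    mean_2 = c(NA, NA, 48.7, NA, NA, 0.4),
    sd_2 = c(NA, NA, 8.4, NA, NA, 0.9),
    n_2 = c(NA, NA, 30L, NA, NA, 41L))
  rm5_review(review_id = review_id, title = "Demo drugs for schizophrenia",
             studies = studies, references = references,
             characteristics = characteristics, risk_of_bias = risk_of_bias,
             comparisons = comparisons, outcomes = outcomes,
             outcome_rows = outcome_rows)
}

write_demo_file <- function(dir = tempdir(), review = make_demo_review()) {
  path <- file.path(dir, paste0(review$review_id, ".rm5"))
  write_review(review, path)
  path
}

# a review whose studies carry exactly the given publication years
review_with_years <- function(review_id, years) {
  sids <- sprintf("Study%02d %d", seq_along(years), years)
  rm5_review(
    review_id = review_id, title = "t",
    studies = tibble::tibble(study_id = sids),
    references = tibble::tibble(study_id = sids,
                                citation_id = paste0("R", seq_along(years)),
                                year = as.integer(years),
                                title = "r", journal = NA))
}

# brute-force oracle for rule priority: evaluate ALL rules, return the label
# of the minimum-priority match (fallback when none match)
oracle_apply_rules <- function(text, ruleset, field) {
  txt <- plain_text(text)
  sub <- ruleset$rules[ruleset$rules$field == field, , drop = FALSE]
  hits <- vapply(seq_len(nrow(sub)), function(i) {
    grepl(sub$pattern[i], txt, perl = TRUE, ignore.case = TRUE)
  }, logical(1))
  if (!any(hits)) return(ruleset$fallback)
  matched <- sub[hits, , drop = FALSE]
  matched$label[which.min(matched$priority)]
}

random_ruleset_and_text <- function() {
  words <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta", "theta")
  k <- sample(2:6, 1)
  pats <- sample(words, k)
  rules <- tibble::tibble(
    variable = "v", field = "methods",
    pattern = pats,
    label = paste0("L", seq_len(k)),
    priority = sample(1:50, k))
  rs <- rm5_ruleset(rules, fallback = "none")
  text <- paste(sample(words, sample(0:5, 1), replace = TRUE), collapse = " ")
  list(rs = rs, text = text)
}
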