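# Marshalling a parsed batch into one central, queryable dataset.
#
# The central dataset flattens every extracted and normalized variable from a
# batch of reviews into two tables — studies and outcome rows — carrying raw
# free text and canonical labels side by side. It serializes to a documented,
# versioned XML schema plus CSV/JSON exports, and answers the corpus-level
# queries (publication-year histogram, participant totals) that are tedious
# by hand.

central_schema_version <- "1.0"

#' Build the central dataset from a batch
#'
#' Joins parsed reviews with their normalized records and (optionally) the
#' curated outcome ontology into one deterministic dataset, sorted by
#' `review_id`, `study_id`, `comparison_id`, `outcome_id`. A duplicate
#' (review_id, study_id) pair is a hard error naming the collision.
#'
#' @param reviews List of `rm5_review` (e.g. from [read_batch()]).
#' @param records Tibble from [normalize_studies()], or `NULL` to compute it
#'   here with the default rules.
#' @param mapping Optional `rm5_mapping` of outcome titles to categories.
#' @param created Timestamp string recorded in the dataset; inject a fixed
#'   value for reproducible builds. Defaults to the current UTC time.
#' @return An object of class `rm5_central` with elements `created`,
#'   `source_count`, `studies` (one row per study with reference years,
#'   plain-text characteristics, normalized labels and risk-of-bias
#'   judgements) and `outcome_rows` (flattened numeric rows with review,
#'   comparison, outcome and ontology context).
#' @export
build_central <- function(reviews, records = NULL, mapping = NULL,
                          created = NULL) {
  if (inherits(reviews, "rm5_review")) reviews <- list(reviews)
  if (is.null(records)) records <- normalize_studies(reviews)
  created <- created %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

  studies <- purrr::map_dfr(reviews, function(rev) {
    if (nrow(rev$studies) == 0) return(NULL)
    purrr::map_dfr(rev$studies$study_id, function(sid) {
      refs <- rev$references[rev$references$study_id == sid, , drop = FALSE]
      ch <- rev$characteristics[rev$characteristics$study_id == sid, , drop = FALSE]
      rob <- rev$risk_of_bias[rev$risk_of_bias$study_id == sid, , drop = FALSE]
      tibble(
        review_id = rev$review_id, study_id = sid,
        n_references = nrow(refs),
        reference_years = list(sort(refs$year[!is.na(refs$year)])),
        methods = plain_text(ch$methods[1] %||% ""),
        participants = plain_text(ch$participants[1] %||% ""),
        interventions = plain_text(ch$interventions[1] %||% ""),
        outcomes_text = plain_text(ch$outcomes[1] %||% ""),
        notes = plain_text(ch$notes[1] %||% ""),
        rob = list(tibble(item_name = rob$item_name, judgement = rob$judgement)))
    })
  })
  if (is.null(studies) || nrow(studies) == 0) {
    studies <- tibble(review_id = character(0), study_id = character(0),
                      n_references = integer(0), reference_years = list(),
                      methods = character(0), participants = character(0),
                      interventions = character(0), outcomes_text = character(0),
                      notes = character(0), rob = list())
  }
  dup <- studies %>% count(.data$review_id, .data$study_id) %>% filter(.data$n > 1)
  if (nrow(dup)) {
    stop_rm5("rm5_validation_error",
             sprintf("duplicate (review_id, study_id): %s",
                     paste(paste(dup$review_id, dup$study_id), collapse = "; ")))
  }

  rec_cols <- c("blinding", "allocation", "duration_weeks", "n_participants")
  if (nrow(records)) {
    studies <- left_join(studies,
                         records[c("review_id", "study_id", rec_cols)],
                         by = c("review_id", "study_id"))
  } else {
    studies$blinding <- character(nrow(studies))
    studies$allocation <- character(nrow(studies))
    studies$duration_weeks <- numeric(nrow(studies))
    studies$n_participants <- integer(nrow(studies))
  }
  studies <- studies %>%
    mutate(year = resolve_study_year(.data$study_id, .data$reference_years)) %>%
    arrange(.data$review_id, .data$study_id)

  occ <- apply_mapping(reviews, mapping)
  rows <- purrr::map_dfr(reviews, function(rev) {
    if (nrow(rev$outcome_rows) == 0) return(NULL)
    out <- rev$outcomes
    r <- rev$outcome_rows
    key <- paste(r$comparison_id, r$outcome_id)
    okey <- paste(out$comparison_id, out$outcome_id)
    tibble(review_id = rev$review_id,
           comparison_id = r$comparison_id,
           outcome_id = r$outcome_id,
           outcome_title = out$title[match(key, okey)],
           data_type = out$data_type[match(key, okey)],
           study_id = r$study_id,
           events_1 = r$events_1, total_1 = r$total_1,
           events_2 = r$events_2, total_2 = r$total_2,
           mean_1 = r$mean_1, sd_1 = r$sd_1, n_1 = r$n_1,
           mean_2 = r$mean_2, sd_2 = r$sd_2, n_2 = r$n_2)
  })
  if (is.null(rows) || nrow(rows) == 0) {
    rows <- tibble(review_id = character(0), comparison_id = character(0),
                   outcome_id = character(0), outcome_title = character(0),
                   data_type = character(0), study_id = character(0),
                   events_1 = integer(0), total_1 = integer(0),
                   events_2 = integer(0), total_2 = integer(0),
                   mean_1 = double(0), sd_1 = double(0), n_1 = integer(0),
                   mean_2 = double(0), sd_2 = double(0), n_2 = integer(0))
  }
  okey <- paste(occ$review_id, occ$comparison_id, occ$outcome_id)
  rkey <- paste(rows$review_id, rows$comparison_id, rows$outcome_id)
  idx <- match(rkey, okey)
  rows$category <- if (nrow(occ)) occ$category[idx] else character(0)
  rows$subcategory <- if (nrow(occ)) occ$subcategory[idx] else character(0)
  rows <- arrange(rows, .data$review_id, .data$study_id,
                  .data$comparison_id, .data$outcome_id)

  structure(list(created = created,
                 schema_version = central_schema_version,
                 source_count = length(reviews),
                 studies = studies,
                 outcome_rows = rows),
            class = "rm5_central")
}

resolve_study_year <- function(study_id, reference_years) {
  parsed <- parse_study_year(study_id)
  fallback <- vapply(reference_years, function(y) {
    if (length(y)) as.integer(min(y)) else NA_integer_
  }, integer(1))
  ifelse(is.na(parsed), fallback, parsed)
}

#' @export
print.rm5_central <- function(x, ...) {
  cat(sprintf("<rm5_central> v%s, %d review(s), %d studies, %d outcome rows (created %s)\n",
              x$schema_version, x$source_count, nrow(x$studies),
              nrow(x$outcome_rows), x$created))
  invisible(x)
}

#' Serialize the central dataset as XML
#'
#' Writes the versioned central XML schema: a `CENTRAL_DATASET` root with one
#' `STUDY` element per study record and one `OUTCOME_ROW` per flattened data
#' row. Output is byte-deterministic given the same inputs and a pinned
#' `created` timestamp.
#'
#' @param ds An `rm5_central`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_central_xml <- function(ds, path) {
  stopifnot(inherits(ds, "rm5_central"))
  study_els <- vapply(seq_len(nrow(ds$studies)), function(i) {
    s <- ds$studies[i, ]
    rob <- s$rob[[1]]
    rob_els <- if (nrow(rob)) {
      paste0(vapply(seq_len(nrow(rob)), function(j) {
        el("ROB_ITEM", attrs = c(NAME = rob$item_name[j], JUDGEMENT = rob$judgement[j]))
      }, character(1)), collapse = "")
    } else ""
    yrs <- s$reference_years[[1]]
    inner <- paste0(
      el("YEARS", paste0(vapply(yrs, function(y) el("YR", fmt_num(y)), character(1)),
                         collapse = "")),
      el("METHODS", xml_escape_text(s$methods)),
      el("PARTICIPANTS", xml_escape_text(s$participants)),
      el("INTERVENTIONS", xml_escape_text(s$interventions)),
      el("OUTCOMES", xml_escape_text(s$outcomes_text)),
      el("NOTES", xml_escape_text(s$notes)),
      el("RISK_OF_BIAS", rob_els))
    el("STUDY", inner, c(
      REVIEW_ID = s$review_id, STUDY_ID = s$study_id,
      YEAR = fmt_num(s$year), N_REFERENCES = fmt_num(s$n_references),
      BLINDING = s$blinding, ALLOCATION = s$allocation,
      DURATION_WEEKS = fmt_num(s$duration_weeks),
      N_PARTICIPANTS = fmt_num(s$n_participants)))
  }, character(1))
  row_els <- vapply(seq_len(nrow(ds$outcome_rows)), function(i) {
    r <- ds$outcome_rows[i, ]
    el("OUTCOME_ROW", attrs = c(
      REVIEW_ID = r$review_id, COMPARISON_ID = r$comparison_id,
      OUTCOME_ID = r$outcome_id, TITLE = r$outcome_title,
      DATA_TYPE = r$data_type, STUDY_ID = r$study_id,
      CATEGORY = r$category, SUBCATEGORY = r$subcategory,
      EVENTS_1 = fmt_num(r$events_1), TOTAL_1 = fmt_num(r$total_1),
      EVENTS_2 = fmt_num(r$events_2), TOTAL_2 = fmt_num(r$total_2),
      MEAN_1 = fmt_num(r$mean_1), SD_1 = fmt_num(r$sd_1), N_1 = fmt_num(r$n_1),
      MEAN_2 = fmt_num(r$mean_2), SD_2 = fmt_num(r$sd_2), N_2 = fmt_num(r$n_2)))
  }, character(1))
  doc <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    el("CENTRAL_DATASET",
       paste0(el("STUDIES", paste0(study_els, collapse = "")),
              el("OUTCOME_ROWS", paste0(row_els, collapse = ""))),
       c(VERSION = ds$schema_version, CREATED = ds$created,
         SOURCE_COUNT = fmt_num(ds$source_count))),
    "\n")
  con <- file(path, open = "wb")
  writeBin(charToRaw(enc2utf8(doc)), con)
  close(con)
  invisible(path)
}

#' Export the central dataset as flat tables
#'
#' Writes a studies table and an outcome-rows table in CSV (RFC 4180, UTF-8,
#' documented stable column order) or JSON (mirroring the XML structure).
#'
#' @param ds An `rm5_central`.
#' @param dir Output directory (created if needed).
#' @param fmt `"csv"` or `"json"`.
#' @return Invisibly, character vector of the files written.
#' @export
export_tables <- function(ds, dir, fmt = c("csv", "json")) {
  stopifnot(inherits(ds, "rm5_central"))
  fmt <- match.arg(fmt)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  studies_flat <- ds$studies %>%
    mutate(reference_years = vapply(.data$reference_years,
                                    function(y) paste(y, collapse = ";"), character(1)),
           rob = vapply(.data$rob, function(r) {
             paste(paste0(r$item_name, "=", r$judgement), collapse = ";")
           }, character(1)))
  if (fmt == "csv") {
    f1 <- file.path(dir, "studies.csv")
    f2 <- file.path(dir, "outcome_rows.csv")
    readr::write_csv(studies_flat, f1, na = "")
    readr::write_csv(ds$outcome_rows, f2, na = "")
    invisible(c(f1, f2))
  } else {
    f <- file.path(dir, "central.json")
    jsonlite::write_json(
      list(version = ds$schema_version, created = ds$created,
           source_count = ds$source_count,
           studies = studies_flat, outcome_rows = ds$outcome_rows),
      f, auto_unbox = TRUE, digits = NA, na = "null", pretty = FALSE)
    invisible(f)
  }
}

#' Publication-year summary of a central dataset
#'
#' Each study contributes one year: the year parsed from its study identifier
#' when present, else its earliest reference year; studies with neither are
#' excluded and counted. Returns the histogram together with the median year
#' and, given a reference year, the fraction of dated studies more than
#' `age_years` old — the corpus-age query that is the headline use of the
#' central dataset.
#'
#' @param ds An `rm5_central`.
#' @param age_years Age threshold in years (default 20).
#' @param reference_year Year the age is measured from; defaults to the
#'   current year. Pin it for reproducible reports.
#' @return Object of class `rm5_year_summary`: list with `histogram`
#'   (tibble `year`, `n`), `median_year`, `fraction_older`, `age_years`,
#'   `reference_year`, `n_dated`, `n_excluded`.
#' @export
publication_year_histogram <- function(ds, age_years = 20,
                                       reference_year = as.integer(format(Sys.Date(), "%Y"))) {
  stopifnot(inherits(ds, "rm5_central"))
  yrs <- ds$studies$year
  dated <- yrs[!is.na(yrs)]
  hist <- if (length(dated)) {
    tibble(year = as.integer(sort(unique(dated)))) %>%
      mutate(n = vapply(.data$year, function(y) sum(dated == y), integer(1)))
  } else {
    tibble(year = integer(0), n = integer(0))
  }
  structure(list(
    histogram = hist,
    median_year = if (length(dated)) stats::median(dated) else NA_real_,
    fraction_older = if (length(dated)) {
      mean(dated < (reference_year - age_years))
    } else NA_real_,
    age_years = age_years,
    reference_year = as.integer(reference_year),
    n_dated = length(dated),
    n_excluded = sum(is.na(yrs))
  ), class = "rm5_year_summary")
}

#' @export
print.rm5_year_summary <- function(x, ...) {
  cat(sprintf("<rm5_year_summary> %d dated studies (%d undated), median year %s\n",
              x$n_dated, x$n_excluded, format(x$median_year)))
  cat(sprintf("  fraction more than %d years before %d: %s\n",
              x$age_years, x$reference_year, format(x$fraction_older)))
  invisible(x)
}

#' Per-review participant totals
#'
#' Sums the participant counts parsed by the normalizer over each review's
#' studies. Studies without a parsed count are tallied as missing, never
#' imputed.
#'
#' @param ds An `rm5_central`.
#' @return Tibble: `review_id`, `total_participants`, `n_studies`,
#'   `n_missing`.
#' @export
sum_participants <- function(ds) {
  stopifnot(inherits(ds, "rm5_central"))
  if (nrow(ds$studies) == 0) {
    return(tibble(review_id = character(0), total_participants = integer(0),
                  n_studies = integer(0), n_missing = integer(0)))
  }
  ds$studies %>%
    group_by(.data$review_id) %>%
    summarise(total_participants = sum(.data$n_participants, na.rm = TRUE),
              n_studies = dplyr::n(),
              n_missing = sum(is.na(.data$n_participants)),
              .groups = "drop") %>%
    arrange(.data$review_id)
}
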