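# In-memory data model for the supported .rm5 dialect.
#
# A review is a list of tidy tables rather than a nested object tree: every
# downstream stage (normalisation, title harvest, central dataset) consumes
# and returns tibbles, so the model keeps the data in that shape from the
# start. Raw inline markup in free-text fields is preserved verbatim;
# plain_text() provides the projection used for matching.

#' Element paths of the supported .rm5 dialect
#'
#' The reader and writer never hard-code element names; they go through this
#' single mapping table, so the dialect can be re-pointed at another RevMan
#' flavour without code changes. The shipped dialect is modelled on the public
#' RevMan 5.3 schema: a review root holding a cover sheet, a
#' studies-and-references block, a characteristics block with five fixed
#' sub-fields per included study, risk-of-bias (quality) items, and an
#' analyses block of comparisons with dichotomous/continuous outcome tables.
#'
#' @return Named list of element/attribute names.
#' @export
rm5_dialect <- function() {
  list(
    root            = "COCHRANE_REVIEW",
    root_id         = "REVIEW_ID",
    root_version    = "VERSION",
    version         = "5.3",
    cover           = "COVER_SHEET",
    title           = "TITLE",
    studies_refs    = "STUDIES_AND_REFERENCES",
    studies         = "STUDIES",
    included        = "INCLUDED_STUDIES",
    study           = "STUDY",
    study_id        = "ID",
    study_name      = "NAME",
    reference       = "REFERENCE",
    ref_id          = "ID",
    ref_title       = "TI",
    ref_journal     = "SO",
    ref_year        = "YR",
    characteristics = "CHARACTERISTICS_OF_STUDIES",
    char_included   = "CHARACTERISTICS_OF_INCLUDED_STUDIES",
    char_study      = "INCLUDED_CHAR",
    char_study_id   = "STUDY_ID",
    char_fields     = c(
      methods       = "CHAR_METHODS",
      participants  = "CHAR_PARTICIPANTS",
      interventions = "CHAR_INTERVENTIONS",
      outcomes      = "CHAR_OUTCOMES",
      notes         = "CHAR_NOTES"
    ),
    quality         = "QUALITY_ITEMS",
    quality_item    = "QUALITY_ITEM",
    quality_name    = "NAME",
    quality_entry   = "QUALITY_ITEM_DATA_ENTRY",
    quality_study   = "STUDY_ID",
    quality_result  = "RESULT",
    quality_desc    = "DESCRIPTION",
    analyses        = "ANALYSES_AND_DATA",
    comparison      = "COMPARISON",
    cmp_id          = "ID",
    cmp_name        = "NAME",
    dich_outcome    = "DICH_OUTCOME",
    cont_outcome    = "CONT_OUTCOME",
    out_id          = "ID",
    out_name        = "NAME",
    dich_data       = "DICH_DATA",
    cont_data       = "CONT_DATA",
    row_study       = "STUDY_ID",
    dich_attrs      = c(events_1 = "EVENTS_1", total_1 = "TOTAL_1",
                        events_2 = "EVENTS_2", total_2 = "TOTAL_2"),
    cont_attrs      = c(mean_1 = "MEAN_1", sd_1 = "SD_1", n_1 = "TOTAL_1",
                        mean_2 = "MEAN_2", sd_2 = "SD_2", n_2 = "TOTAL_2")
  )
}

rob_judgements <- c("low", "high", "unclear")

empty_studies_tbl <- function() tibble(study_id = character(0))

empty_references_tbl <- function() {
  tibble(study_id = character(0), citation_id = character(0),
         year = integer(0), title = character(0), journal = character(0))
}

empty_characteristics_tbl <- function() {
  tibble(study_id = character(0), methods = character(0),
         participants = character(0), interventions = character(0),
         outcomes = character(0), notes = character(0))
}

empty_rob_tbl <- function() {
  tibble(study_id = character(0), item_name = character(0),
         judgement = character(0), support = character(0))
}

empty_comparisons_tbl <- function() {
  tibble(comparison_id = character(0), name = character(0))
}

empty_outcomes_tbl <- function() {
  tibble(comparison_id = character(0), outcome_id = character(0),
         title = character(0), data_type = character(0))
}

empty_rows_tbl <- function() {
  tibble(comparison_id = character(0), outcome_id = character(0),
         study_id = character(0),
         events_1 = integer(0), total_1 = integer(0),
         events_2 = integer(0), total_2 = integer(0),
         mean_1 = double(0), sd_1 = double(0), n_1 = integer(0),
         mean_2 = double(0), sd_2 = double(0), n_2 = integer(0))
}

empty_retained_tbl <- function() {
  tibble(parent = character(0), position = integer(0), xml = character(0))
}

# retained subtrees are stored in canonical serialization so that the model
# is serializer-independent and round trips compare by simple equality
canonicalize_retained <- function(retained) {
  if (nrow(retained)) {
    retained$xml <- vapply(retained$xml, function(s) {
      canonicalize_node(xml2::xml_root(xml2::read_xml(s)))
    }, character(1), USE.NAMES = FALSE)
  }
  retained
}

coerce_tbl <- function(x, template) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(template)
  x <- as_tibble(x)
  for (nm in setdiff(names(template), names(x))) {
    x[[nm]] <- template[[nm]][NA_integer_][rep(1L, nrow(x))]
  }
  x <- x[names(template)]
  for (nm in names(template)) {
    mode_fn <- if (is.integer(template[[nm]])) as.integer
    else if (is.double(template[[nm]])) as.double
    else as.character
    x[[nm]] <- mode_fn(x[[nm]])
  }
  x
}

#' Construct a review object
#'
#' Assembles the tidy tables describing one systematic review into an
#' `rm5_review`. All tables are optional; missing ones default to empty.
#' Free-text characteristics fields hold raw markup; see [plain_text()].
#'
#' @param review_id Stable, non-empty review identifier.
#' @param title Review title.
#' @param studies Tibble with column `study_id`.
#' @param references Tibble: `study_id`, `citation_id`, `year` (integer or
#'   `NA`), `title`, `journal` (`NA` allowed).
#' @param characteristics Tibble: `study_id` plus the five fixed free-text
#'   fields `methods`, `participants`, `interventions`, `outcomes`, `notes`.
#' @param risk_of_bias Tibble: `study_id`, `item_name`, `judgement`
#'   (`"low"`, `"high"` or `"unclear"`), `support`.
#' @param comparisons Tibble: `comparison_id`, `name`.
#' @param outcomes Tibble: `comparison_id`, `outcome_id`, `title`,
#'   `data_type` (`"dichotomous"` or `"continuous"`).
#' @param outcome_rows Tibble of per-study numeric rows; dichotomous rows
#'   carry `events_*`/`total_*`, continuous rows `mean_*`/`sd_*`/`n_*`.
#' @param retained Tibble of opaque XML subtrees kept for lossless round
#'   trips (`parent`, `position`, `xml`).
#' @param source_path Path the review was read from, or `NA`.
#' @return An object of class `rm5_review`.
#' @export
rm5_review <- function(review_id, title = "",
                       studies = NULL, references = NULL,
                       characteristics = NULL, risk_of_bias = NULL,
                       comparisons = NULL, outcomes = NULL,
                       outcome_rows = NULL, retained = NULL,
                       source_path = NA_character_) {
  rev <- structure(list(
    review_id       = as.character(review_id),
    title           = as.character(title),
    studies         = coerce_tbl(studies, empty_studies_tbl()),
    references      = coerce_tbl(references, empty_references_tbl()),
    characteristics = coerce_tbl(characteristics, empty_characteristics_tbl()),
    risk_of_bias    = coerce_tbl(risk_of_bias, empty_rob_tbl()),
    comparisons     = coerce_tbl(comparisons, empty_comparisons_tbl()),
    outcomes        = coerce_tbl(outcomes, empty_outcomes_tbl()),
    outcome_rows    = coerce_tbl(outcome_rows, empty_rows_tbl()),
    retained        = canonicalize_retained(coerce_tbl(retained, empty_retained_tbl())),
    source_path     = as.character(source_path)
  ), class = "rm5_review")
  # every study must have a characteristics row (five fields always present)
  missing_chars <- setdiff(rev$studies$study_id, rev$characteristics$study_id)
  if (length(missing_chars)) {
    fill <- tibble(study_id = missing_chars, methods = "", participants = "",
                   interventions = "", outcomes = "", notes = "")
    rev$characteristics <- bind_rows(rev$characteristics, fill)
  }
  rev$characteristics <- rev$characteristics[
    match(rev$studies$study_id, rev$characteristics$study_id), , drop = FALSE]
  rev$characteristics[is.na(rev$characteristics)] <- ""
  rev
}

#' @export
print.rm5_review <- function(x, ...) {
  cat(sprintf("<rm5_review> %s: \"%s\"\n", x$review_id, x$title))
  cat(sprintf("  studies: %d  references: %d  comparisons: %d  outcomes: %d  rows: %d\n",
              nrow(x$studies), nrow(x$references), nrow(x$comparisons),
              nrow(x$outcomes), nrow(x$outcome_rows)))
  if (nrow(x$retained)) cat(sprintf("  retained opaque subtrees: %d\n", nrow(x$retained)))
  invisible(x)
}

#' Validate a review against the dialect invariants
#'
#' Checks every structural invariant of the model: non-empty unique
#' identifiers, at least one reference per study, plausible years, the
#' three-valued risk-of-bias judgement vocabulary, dichotomous rows with
#' `events <= total`, continuous rows with `sd >= 0` and `n >= 0`, non-empty
#' outcome titles, and referential integrity from outcome rows to studies.
#'
#' @param review An `rm5_review`.
#' @return Invisibly `TRUE`; signals a classed `rm5_validation_error`
#'   describing every violation otherwise.
#' @export
validate_review <- function(review) {
  stopifnot(inherits(review, "rm5_review"))
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)

  if (!nzchar(review$review_id) || is.na(review$review_id)) {
    add("review_id must be non-empty")
  }
  sid <- review$studies$study_id
  if (any(!nzchar(sid) | is.na(sid))) add("study_id must be non-empty")
  if (anyDuplicated(sid)) {
    add(sprintf("duplicate study_id within review: %s",
                paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  no_ref <- setdiff(sid, review$references$study_id)
  if (length(no_ref)) {
    add(sprintf("study without references: %s", paste(no_ref, collapse = ", ")))
  }
  orphan_ref <- setdiff(review$references$study_id, sid)
  if (length(orphan_ref)) {
    add(sprintf("reference for unknown study: %s", paste(orphan_ref, collapse = ", ")))
  }
  yr <- review$references$year
  bad_yr <- !is.na(yr) & (yr < 1800 | yr > 2100)
  if (any(bad_yr)) {
    add(sprintf("reference year out of range 1800-2100: %s",
                paste(yr[bad_yr], collapse = ", ")))
  }
  bad_j <- !review$risk_of_bias$judgement %in% rob_judgements
  if (any(bad_j)) {
    add(sprintf("risk-of-bias judgement must be one of %s; got: %s",
                paste(rob_judgements, collapse = "/"),
                paste(unique(review$risk_of_bias$judgement[bad_j]), collapse = ", ")))
  }
  cid <- review$comparisons$comparison_id
  if (anyDuplicated(cid)) {
    add(sprintf("duplicate comparison_id: %s",
                paste(unique(cid[duplicated(cid)]), collapse = ", ")))
  }
  out <- review$outcomes
  if (nrow(out)) {
    if (any(!nzchar(out$title) | is.na(out$title))) add("outcome title must be non-empty")
    bad_dt <- !out$data_type %in% c("dichotomous", "continuous")
    if (any(bad_dt)) {
      add(sprintf("unknown outcome data_type: %s",
                  paste(unique(out$data_type[bad_dt]), collapse = ", ")))
    }
    dup_out <- duplicated(out[c("comparison_id", "outcome_id")])
    if (any(dup_out)) add("duplicate outcome_id within comparison")
  }
  rows <- review$outcome_rows
  if (nrow(rows)) {
    orphan <- setdiff(rows$study_id, sid)
    if (length(orphan)) {
      add(sprintf("outcome row for unknown study: %s", paste(orphan, collapse = ", ")))
    }
    key <- paste(rows$comparison_id, rows$outcome_id)
    okey <- paste(out$comparison_id, out$outcome_id)
    dt <- out$data_type[match(key, okey)]
    if (anyNA(dt)) add("outcome row for unknown outcome table")
    dich <- which(!is.na(dt) & dt == "dichotomous")
    for (arm in 1:2) {
      ev <- rows[[paste0("events_", arm)]][dich]
      tot <- rows[[paste0("total_", arm)]][dich]
      if (any(!is.na(ev) & !is.na(tot) & ev > tot)) {
        add(sprintf("events exceed total in arm %d of a dichotomous row", arm))
      }
      if (any(!is.na(ev) & ev < 0) || any(!is.na(tot) & tot < 0)) {
        add("negative count in a dichotomous row")
      }
    }
    cont <- which(!is.na(dt) & dt == "continuous")
    for (arm in 1:2) {
      sdv <- rows[[paste0("sd_", arm)]][cont]
      nv <- rows[[paste0("n_", arm)]][cont]
      if (any(!is.na(sdv) & sdv < 0)) add("negative sd in a continuous row")
      if (any(!is.na(nv) & nv < 0)) add("negative n in a continuous row")
    }
  }

  if (length(errs)) {
    stop_rm5("rm5_validation_error",
             paste0("invalid review '", review$review_id, "':\n",
                    paste0("- ", errs, collapse = "\n")))
  }
  invisible(TRUE)
}

#' Field-for-field equality of two reviews
#'
#' Compares every modelled field (identifier, title, all tables including
#' retained opaque subtrees); `source_path` is ignored, as two copies of the
#' same review read from different locations are the same review.
#'
#' @param a,b `rm5_review` objects.
#' @return `TRUE` or `FALSE`.
#' @export
rm5_identical <- function(a, b) {
  strip <- function(r) {
    r$source_path <- NULL
    r[] <- lapply(r, function(el) {
      if (is.data.frame(el)) as.data.frame(el) else el
    })
    unclass(r)
  }
  isTRUE(all.equal(strip(a), strip(b), check.attributes = TRUE, tolerance = 0))
}
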