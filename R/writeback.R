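# Feeding curated content back into source .rm5 files.
#
# The one write-back implemented is the contributed-outcomes list: for each
# included study, the titles of every outcome table it contributed data to
# are appended to that study's characteristics — a list normally maintained
# by hand and notoriously inconsistent. The generated block is delimited by
# sentinel XML comments carrying a tool tag and version, so re-running the
# injection replaces the block instead of appending again: the edit is
# idempotent, and stripping the sentinels recovers the original file.

sentinel_open <- "<!--rm5tools:outcome-list v1-->"
sentinel_close <- "<!--/rm5tools:outcome-list-->"
sentinel_re <- "(?s)<!--rm5tools:outcome-list v1-->.*?<!--/rm5tools:outcome-list-->"

#' Outcomes a study contributed data to
#'
#' Scans a review's analyses for every outcome table containing a data row
#' for `study_id` and returns the outcome titles, deduplicated, in
#' comparison-then-outcome document order.
#'
#' @param review An `rm5_review`.
#' @param study_id A study present in the review.
#' @return Character vector of outcome titles (possibly empty).
#' @export
contributed_outcomes <- function(review, study_id) {
  stopifnot(inherits(review, "rm5_review"))
  if (!study_id %in% review$studies$study_id) {
    stop_rm5("rm5_lookup_error",
             sprintf("no study '%s' in review '%s'", study_id, review$review_id))
  }
  rows <- review$outcome_rows[review$outcome_rows$study_id == study_id, , drop = FALSE]
  if (nrow(rows) == 0) return(character(0))
  # outcomes table is in document order (comparison, then outcome within it)
  out <- review$outcomes
  hit <- paste(out$comparison_id, out$outcome_id) %in%
    paste(rows$comparison_id, rows$outcome_id)
  unique(out$title[hit])
}

outcome_list_block <- function(titles) {
  body <- if (length(titles)) {
    paste0("<P>Contributing to outcomes: ",
           xml_escape_text(paste(titles, collapse = "; ")), ".</P>")
  } else {
    "<P>Contributing to outcomes: none.</P>"
  }
  paste0(sentinel_open, body, sentinel_close)
}

strip_sentinel_blocks <- function(text) {
  gsub(sentinel_re, "", text, perl = TRUE)
}

#' Inject contributed-outcome lists into an .rm5 file
#'
#' Reads the file, appends (or replaces) a sentinel-delimited
#' "Contributing to outcomes" block in each included study's characteristics
#' field, and writes the result. All other content round-trips untouched
#' (canonical-XML-equal); studies with no outcome rows are skipped. The
#' output is written atomically — on failure no partial file is left behind.
#'
#' @param path_in Source .rm5 file.
#' @param path_out Destination path; defaults to `path_in` (in-place, in
#'   which case a `.bak` copy of the source is written first).
#' @param field Characteristics field to carry the block: `"outcomes"`
#'   (default) or `"notes"`.
#' @return Edit report tibble: `study_id`, `edited` (logical), `n_outcomes`.
#' @export
inject_outcome_lists <- function(path_in, path_out = path_in,
                                 field = c("outcomes", "notes")) {
  field <- match.arg(field)
  rev <- read_review(path_in, schema_mode = "lenient")
  in_place <- normalizePath(path_out, mustWork = FALSE) ==
    normalizePath(path_in, mustWork = FALSE)
  if (in_place) {
    file.copy(path_in, paste0(path_in, ".bak"), overwrite = TRUE)
  }

  report <- purrr::map_dfr(rev$studies$study_id, function(sid) {
    titles <- contributed_outcomes(rev, sid)
    i <- which(rev$characteristics$study_id == sid)
    if (length(titles)) {
      cur <- strip_sentinel_blocks(rev$characteristics[[field]][i])
      rev$characteristics[[field]][i] <<- paste0(cur, outcome_list_block(titles))
    } else {
      # no contribution: leave the field untouched (but drop a stale block)
      rev$characteristics[[field]][i] <<- strip_sentinel_blocks(
        rev$characteristics[[field]][i])
    }
    tibble(study_id = sid, edited = length(titles) > 0,
           n_outcomes = length(titles))
  })
  if (is.null(report) || nrow(report) == 0) {
    report <- tibble(study_id = character(0), edited = logical(0),
                     n_outcomes = integer(0))
  }
  write_review(rev, path_out)
  report
}

#' Remove injected outcome lists from an .rm5 file
#'
#' Deletes every sentinel-delimited block written by
#' [inject_outcome_lists()], recovering the pre-injection content.
#'
#' @param path_in Source file.
#' @param path_out Destination path (default in-place).
#' @return Invisibly, `path_out`.
#' @export
strip_outcome_lists <- function(path_in, path_out = path_in) {
  rev <- read_review(path_in, schema_mode = "lenient")
  for (fld in char_field_names) {
    rev$characteristics[[fld]] <- strip_sentinel_blocks(rev$characteristics[[fld]])
  }
  write_review(rev, path_out)
  invisible(path_out)
}
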