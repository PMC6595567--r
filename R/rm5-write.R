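# Serializing reviews back to .rm5 XML.
#
# The writer emits the dialect in a fixed canonical order and re-inserts
# retained opaque subtrees at their recorded positions, so an unedited
# read/write cycle is canonical-XML-equal to the source file. Output is
# assembled as text (raw markup fragments must pass through verbatim) and
# re-parsed once before any bytes hit disk, so a malformed fragment can
# never produce a corrupt file.

el <- function(name, inner = "", attrs = NULL) {
  a <- if (length(attrs)) {
    attrs <- attrs[!is.na(attrs)]
    if (length(attrs)) {
      paste0(" ", paste0(names(attrs), "=\"", xml_escape_attr(unname(attrs)), "\"",
                         collapse = " "))
    } else ""
  } else ""
  if (nzchar(inner)) {
    paste0("<", name, a, ">", inner, "</", name, ">")
  } else {
    paste0("<", name, a, "/>")
  }
}

insert_retained <- function(children, retained_rows) {
  if (nrow(retained_rows) == 0) return(children)
  retained_rows <- arrange(retained_rows, .data$position)
  for (i in seq_len(nrow(retained_rows))) {
    pos <- min(retained_rows$position[i], length(children) + 1L)
    children <- append(children, retained_rows$xml[i], after = pos - 1L)
  }
  children
}

#' Write a review to an .rm5 file
#'
#' Serializes an [rm5_review()] as UTF-8 XML over the supported dialect.
#' The review is validated first and nothing is written on failure; the file
#' is written to a temporary sibling and atomically moved into place.
#' `read_review(write_review(r))` reproduces `r` field for field, and
#' retained opaque subtrees are re-emitted in original document order.
#'
#' Missing optional values (absent years, empty free-text fields) are
#' omitted from the output rather than emitted as empty elements.
#'
#' @param review A valid `rm5_review`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_review <- function(review, path) {
  stopifnot(inherits(review, "rm5_review"))
  validate_review(review)
  d <- rm5_dialect()

  # studies + references
  study_els <- vapply(seq_len(nrow(review$studies)), function(i) {
    sid <- review$studies$study_id[i]
    refs <- review$references[review$references$study_id == sid, , drop = FALSE]
    ref_els <- vapply(seq_len(nrow(refs)), function(j) {
      inner <- character(0)
      if (nzchar(refs$title[j])) {
        inner <- c(inner, el(d$ref_title, xml_escape_text(refs$title[j])))
      }
      if (!is.na(refs$journal[j]) && nzchar(refs$journal[j])) {
        inner <- c(inner, el(d$ref_journal, xml_escape_text(refs$journal[j])))
      }
      if (!is.na(refs$year[j])) {
        inner <- c(inner, el(d$ref_year, fmt_num(refs$year[j])))
      }
      el(d$reference, paste0(inner, collapse = ""), c(ID = refs$citation_id[j]))
    }, character(1))
    el(d$study, paste0(ref_els, collapse = ""),
       stats::setNames(c(sid, sid), c(d$study_id, d$study_name)))
  }, character(1))
  studies_children <- if (length(study_els)) {
    el(d$included, paste0(study_els, collapse = ""))
  } else {
    el(d$included)
  }
  studies_children <- insert_retained(
    studies_children, review$retained[review$retained$parent == d$studies, , drop = FALSE])
  sr_el <- el(d$studies_refs, el(d$studies, paste0(studies_children, collapse = "")))

  # characteristics
  char_els <- vapply(seq_len(nrow(review$characteristics)), function(i) {
    row <- review$characteristics[i, ]
    inner <- character(0)
    for (fld in names(d$char_fields)) {
      v <- row[[fld]]
      if (!is.na(v) && nzchar(v)) inner <- c(inner, el(d$char_fields[[fld]], v))
    }
    if (!length(inner)) return(NA_character_)
    el(d$char_study, paste0(inner, collapse = ""),
       stats::setNames(row$study_id, d$char_study_id))
  }, character(1))
  char_els <- char_els[!is.na(char_els)]
  char_el <- el(d$characteristics,
                el(d$char_included, paste0(char_els, collapse = "")))

  # risk of bias, grouped by item in first-appearance order
  rob <- review$risk_of_bias
  item_order <- unique(rob$item_name)
  item_els <- vapply(item_order, function(item) {
    entries <- rob[rob$item_name == item, , drop = FALSE]
    entry_els <- vapply(seq_len(nrow(entries)), function(j) {
      inner <- if (nzchar(entries$support[j])) {
        el(d$quality_desc, xml_escape_text(entries$support[j]))
      } else ""
      el(d$quality_entry, inner,
         stats::setNames(c(entries$study_id[j], toupper(entries$judgement[j])),
                         c(d$quality_study, d$quality_result)))
    }, character(1))
    el(d$quality_item, paste0(entry_els, collapse = ""),
       stats::setNames(item, d$quality_name))
  }, character(1))
  quality_el <- el(d$quality, paste0(item_els, collapse = ""))

  # analyses
  cmp_els <- vapply(seq_len(nrow(review$comparisons)), function(i) {
    cmp <- review$comparisons[i, ]
    outs <- review$outcomes[review$outcomes$comparison_id == cmp$comparison_id, , drop = FALSE]
    out_els <- vapply(seq_len(nrow(outs)), function(j) {
      o <- outs[j, ]
      rows <- review$outcome_rows[
        review$outcome_rows$comparison_id == o$comparison_id &
        review$outcome_rows$outcome_id == o$outcome_id, , drop = FALSE]
      if (o$data_type == "dichotomous") {
        row_els <- vapply(seq_len(nrow(rows)), function(k) {
          r <- rows[k, ]
          at <- c(stats::setNames(r$study_id, d$row_study),
                  stats::setNames(fmt_num(c(r$events_1, r$total_1, r$events_2, r$total_2)),
                                  unname(d$dich_attrs)))
          el(d$dich_data, attrs = at)
        }, character(1))
        el(d$dich_outcome, paste0(row_els, collapse = ""),
           stats::setNames(c(o$outcome_id, o$title), c(d$out_id, d$out_name)))
      } else {
        row_els <- vapply(seq_len(nrow(rows)), function(k) {
          r <- rows[k, ]
          at <- c(stats::setNames(r$study_id, d$row_study),
                  stats::setNames(fmt_num(c(r$mean_1, r$sd_1, r$n_1, r$mean_2, r$sd_2, r$n_2)),
                                  unname(d$cont_attrs)))
          el(d$cont_data, attrs = at)
        }, character(1))
        el(d$cont_outcome, paste0(row_els, collapse = ""),
           stats::setNames(c(o$outcome_id, o$title), c(d$out_id, d$out_name)))
      }
    }, character(1))
    el(d$comparison, paste0(out_els, collapse = ""),
       stats::setNames(c(cmp$comparison_id, cmp$name), c(d$cmp_id, d$cmp_name)))
  }, character(1))
  analyses_el <- el(d$analyses, paste0(cmp_els, collapse = ""))

  cover_el <- el(d$cover, el(d$title, xml_escape_text(review$title)))

  root_children <- c(cover_el, sr_el, char_el, quality_el, analyses_el)
  root_children <- insert_retained(
    root_children, review$retained[review$retained$parent == "", , drop = FALSE])

  doc <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    el(d$root, paste0(root_children, collapse = ""),
       stats::setNames(c(review$review_id, d$version),
                       c(d$root_id, d$root_version))),
    "\n")

  tryCatch(xml2::read_xml(doc),
           error = function(e) {
             stop_rm5("rm5_validation_error",
                      sprintf("review '%s' serializes to malformed XML (bad embedded markup?): %s",
                              review$review_id, conditionMessage(e)))
           })

  tmp <- tempfile(tmpdir = dirname(path), fileext = ".rm5.tmp")
  con <- file(tmp, open = "wb")
  writeBin(charToRaw(enc2utf8(doc)), con)
  close(con)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
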