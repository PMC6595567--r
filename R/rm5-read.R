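# Reading .rm5 files over the supported dialect subset.

xml_children_elems <- function(node) {
  kids <- xml2::xml_contents(node)
  kids[xml2::xml_type(kids) == "element"]
}

inner_xml <- function(node) {
  kids <- xml2::xml_contents(node)
  if (length(kids) == 0) return("")
  paste0(vapply(kids, as.character, character(1)), collapse = "")
}

attr_or_na <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NA_character_ else v
}

attr_int <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NA_integer_ else suppressWarnings(as.integer(v))
}

attr_dbl <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NA_real_ else suppressWarnings(as.numeric(v))
}

#' Read one .rm5 review file
#'
#' Parses a RevMan 5 dialect file into an [rm5_review()]. Element subtrees
#' outside the supported subset are retained opaquely and re-emitted by
#' [write_review()] in their original document order, so a read-then-write
#' cycle with no edits is canonically equal to the input.
#'
#' In `lenient` mode (the default) missing optional blocks yield empty tables
#' with one warning per file, and invariant violations in the data warn
#' rather than fail. In `strict` mode a missing required block raises a
#' classed `rm5_schema_error` naming the missing element path and any
#' invariant violation raises an `rm5_validation_error`; strict mode is what
#' the synthetic-corpus generator is held to.
#'
#' @param path Path to an .rm5 XML file.
#' @param schema_mode `"lenient"` or `"strict"`.
#' @return An `rm5_review`.
#' @export
read_review <- function(path, schema_mode = c("lenient", "strict")) {
  schema_mode <- match.arg(schema_mode)
  d <- rm5_dialect()
  if (!file.exists(path)) {
    stop_rm5("rm5_io_error", sprintf("file does not exist: %s", path))
  }
  doc <- tryCatch(
    xml2::read_xml(path, encoding = "UTF-8"),
    error = function(e) {
      stop_rm5("rm5_parse_error",
               sprintf("malformed XML in '%s' (location from parser): %s",
                       path, conditionMessage(e)))
    }
  )
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != d$root) {
    stop_rm5("rm5_schema_error",
             sprintf("root element is <%s>, expected <%s>: %s",
                     xml2::xml_name(root), d$root, path))
  }

  warn_once <- local({
    warned <- FALSE
    function(msg) {
      if (!warned) {
        warned <<- TRUE
        rlang::warn(sprintf("%s: %s", basename(path), msg),
                    class = "rm5_lenient_warning")
      }
    }
  })
  missing_blocks <- character(0)

  review_id <- attr_or_na(root, d$root_id)
  if (is.na(review_id)) review_id <- ""
  kids <- xml_children_elems(root)
  kid_names <- vapply(kids, xml2::xml_name, character(1))
  known_root <- c(d$cover, d$studies_refs, d$characteristics, d$quality, d$analyses)

  find_block <- function(name) {
    i <- which(kid_names == name)
    if (length(i)) kids[[i[1]]] else NULL
  }

  retained <- empty_retained_tbl()
  keep <- function(parent, position, node) {
    retained <<- bind_rows(retained, tibble(
      parent = parent, position = as.integer(position),
      xml = canonicalize_node(node)))
  }
  for (i in seq_along(kids)) {
    if (!kid_names[i] %in% known_root) keep("", i, kids[[i]])
  }

  # title ------------------------------------------------------------------
  title <- ""
  cover <- find_block(d$cover)
  if (!is.null(cover)) {
    tnode <- xml2::xml_find_first(cover, d$title)
    if (!inherits(tnode, "xml_missing")) title <- xml2::xml_text(tnode)
  }

  # studies and references --------------------------------------------------
  studies <- empty_studies_tbl()
  references <- empty_references_tbl()
  sr <- find_block(d$studies_refs)
  studies_node <- NULL
  if (!is.null(sr)) {
    studies_node <- xml2::xml_find_first(sr, d$studies)
    if (inherits(studies_node, "xml_missing")) studies_node <- NULL
  }
  if (is.null(studies_node)) {
    p <- paste(d$root, d$studies_refs, d$studies, sep = "/")
    if (schema_mode == "strict") {
      stop_rm5("rm5_schema_error",
               sprintf("missing required block %s in %s", p, path))
    }
    missing_blocks <- c(missing_blocks, p)
  } else {
    skids <- xml_children_elems(studies_node)
    sknames <- vapply(skids, xml2::xml_name, character(1))
    for (i in seq_along(skids)) {
      if (sknames[i] != d$included) keep(d$studies, i, skids[[i]])
    }
    inc <- which(sknames == d$included)
    if (length(inc)) {
      for (st in xml2::xml_find_all(skids[[inc[1]]], d$study)) {
        sid <- attr_or_na(st, d$study_id)
        studies <- bind_rows(studies, tibble(study_id = sid))
        for (ref in xml2::xml_find_all(st, d$reference)) {
          ti <- xml2::xml_find_first(ref, d$ref_title)
          so <- xml2::xml_find_first(ref, d$ref_journal)
          yr <- xml2::xml_find_first(ref, d$ref_year)
          references <- bind_rows(references, tibble(
            study_id = sid,
            citation_id = attr_or_na(ref, d$ref_id),
            year = if (inherits(yr, "xml_missing")) NA_integer_
                   else suppressWarnings(as.integer(xml2::xml_text(yr))),
            title = if (inherits(ti, "xml_missing")) "" else xml2::xml_text(ti),
            journal = if (inherits(so, "xml_missing")) NA_character_
                      else xml2::xml_text(so)))
        }
      }
    }
  }

  # characteristics ---------------------------------------------------------
  characteristics <- empty_characteristics_tbl()
  cb <- find_block(d$characteristics)
  if (is.null(cb)) {
    p <- paste(d$root, d$characteristics, sep = "/")
    if (schema_mode == "strict") {
      stop_rm5("rm5_schema_error",
               sprintf("missing required block %s in %s", p, path))
    }
    missing_blocks <- c(missing_blocks, p)
  } else {
    ci <- xml2::xml_find_first(cb, d$char_included)
    if (!inherits(ci, "xml_missing")) {
      for (ch in xml2::xml_find_all(ci, d$char_study)) {
        sid <- attr_or_na(ch, d$char_study_id)
        row <- tibble(study_id = sid)
        for (fld in names(d$char_fields)) {
          node <- xml2::xml_find_first(ch, d$char_fields[[fld]])
          row[[fld]] <- if (inherits(node, "xml_missing")) "" else inner_xml(node)
        }
        characteristics <- bind_rows(characteristics, row)
      }
    }
  }
  unknown_chars <- setdiff(characteristics$study_id, studies$study_id)
  if (length(unknown_chars)) {
    warn_once(sprintf("characteristics for unknown studies ignored: %s",
                      paste(unknown_chars, collapse = ", ")))
    characteristics <- filter(characteristics, .data$study_id %in% studies$study_id)
  }

  # risk of bias ------------------------------------------------------------
  risk_of_bias <- empty_rob_tbl()
  qb <- find_block(d$quality)
  if (!is.null(qb)) {
    for (item in xml2::xml_find_all(qb, d$quality_item)) {
      item_name <- attr_or_na(item, d$quality_name)
      for (entry in xml2::xml_find_all(item, d$quality_entry)) {
        desc <- xml2::xml_find_first(entry, d$quality_desc)
        risk_of_bias <- bind_rows(risk_of_bias, tibble(
          study_id = attr_or_na(entry, d$quality_study),
          item_name = item_name,
          judgement = tolower(attr_or_na(entry, d$quality_result)),
          support = if (inherits(desc, "xml_missing")) "" else xml2::xml_text(desc)))
      }
    }
  }

  # analyses ----------------------------------------------------------------
  comparisons <- empty_comparisons_tbl()
  outcomes <- empty_outcomes_tbl()
  outcome_rows <- empty_rows_tbl()
  ab <- find_block(d$analyses)
  if (!is.null(ab)) {
    for (cmp in xml2::xml_find_all(ab, d$comparison)) {
      cmp_id <- attr_or_na(cmp, d$cmp_id)
      comparisons <- bind_rows(comparisons, tibble(
        comparison_id = cmp_id, name = attr_or_na(cmp, d$cmp_name) %||% ""))
      for (out in xml_children_elems(cmp)) {
        onm <- xml2::xml_name(out)
        if (!onm %in% c(d$dich_outcome, d$cont_outcome)) next
        dt <- if (onm == d$dich_outcome) "dichotomous" else "continuous"
        oid <- attr_or_na(out, d$out_id)
        outcomes <- bind_rows(outcomes, tibble(
          comparison_id = cmp_id, outcome_id = oid,
          title = attr_or_na(out, d$out_name) %||% "", data_type = dt))
        data_el <- if (dt == "dichotomous") d$dich_data else d$cont_data
        for (dr in xml2::xml_find_all(out, data_el)) {
          row <- tibble(comparison_id = cmp_id, outcome_id = oid,
                        study_id = attr_or_na(dr, d$row_study),
                        events_1 = NA_integer_, total_1 = NA_integer_,
                        events_2 = NA_integer_, total_2 = NA_integer_,
                        mean_1 = NA_real_, sd_1 = NA_real_, n_1 = NA_integer_,
                        mean_2 = NA_real_, sd_2 = NA_real_, n_2 = NA_integer_)
          if (dt == "dichotomous") {
            for (f in names(d$dich_attrs)) row[[f]] <- attr_int(dr, d$dich_attrs[[f]])
          } else {
            for (f in names(d$cont_attrs)) {
              row[[f]] <- if (grepl("^n_", f)) attr_int(dr, d$cont_attrs[[f]])
                          else attr_dbl(dr, d$cont_attrs[[f]])
            }
          }
          outcome_rows <- bind_rows(outcome_rows, row)
        }
      }
    }
  }

  rev <- rm5_review(
    review_id = review_id, title = title,
    studies = studies, references = references,
    characteristics = characteristics, risk_of_bias = risk_of_bias,
    comparisons = comparisons, outcomes = outcomes,
    outcome_rows = outcome_rows, retained = retained,
    source_path = normalizePath(path))

  if (length(missing_blocks)) {
    warn_once(sprintf("missing optional block(s), empty collections used: %s",
                      paste(missing_blocks, collapse = ", ")))
  }
  val <- tryCatch({ validate_review(rev); NULL }, rm5_validation_error = function(e) e)
  if (!is.null(val)) {
    if (schema_mode == "strict") stop(val)
    warn_once(conditionMessage(val))
  }
  rev
}

#' Read a directory of .rm5 files as a batch
#'
#' Reads every file matching `glob`, skipping (and recording) per-file
#' failures rather than aborting the batch. The result is sorted by
#' `review_id`, so batch output is deterministic regardless of filesystem
#' listing order.
#'
#' @param dir Directory containing .rm5 files.
#' @param glob Filename glob, default `"*.rm5"`.
#' @param schema_mode Passed to [read_review()].
#' @return List of `rm5_review` objects sorted by `review_id`, with a tibble
#'   of failures (`path`, `error`) in attribute `"failures"`; see
#'   [batch_failures()].
#' @export
read_batch <- function(dir, glob = "*.rm5", schema_mode = c("lenient", "strict")) {
  schema_mode <- match.arg(schema_mode)
  if (!dir.exists(dir)) {
    stop_rm5("rm5_io_error", sprintf("directory does not exist: %s", dir))
  }
  paths <- Sys.glob(file.path(dir, glob))
  if (length(paths) == 0) {
    rlang::warn(sprintf("no files matching '%s' in %s", glob, dir),
                class = "rm5_empty_batch_warning")
  }
  failures <- tibble(path = character(0), error = character(0))
  reviews <- list()
  for (p in paths) {
    r <- tryCatch(
      suppressWarnings(read_review(p, schema_mode = schema_mode)),
      error = function(e) e)
    if (inherits(r, "error")) {
      failures <- bind_rows(failures, tibble(path = p, error = conditionMessage(r)))
    } else {
      reviews[[length(reviews) + 1L]] <- r
    }
  }
  ids <- vapply(reviews, function(r) r$review_id, character(1))
  reviews <- reviews[order(ids, method = "radix")]
  if (nrow(failures)) {
    rlang::warn(sprintf("%d file(s) failed to parse; see batch_failures()",
                        nrow(failures)), class = "rm5_batch_failure_warning")
  }
  attr(reviews, "failures") <- failures
  reviews
}

#' Per-file failures recorded by [read_batch()]
#'
#' @param batch The list returned by [read_batch()].
#' @return Tibble with columns `path` and `error`.
#' @export
batch_failures <- function(batch) {
  attr(batch, "failures") %||% tibble(path = character(0), error = character(0))
}
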