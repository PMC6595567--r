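# Rule-engine normalisation of semi-structured free text.
#
# Cochrane characteristics tables express the same design feature in many
# surface forms ("double blind", "double-blind", "doubly blinded", ...).
# An ordered set of case-insensitive regular expressions maps each field's
# free text onto canonical labels; first match by ascending priority wins.
# The rules are data (a YAML file), not code, so review groups with other
# conventions can swap them without touching the package.

char_field_names <- c("methods", "participants", "interventions", "outcomes", "notes")

#' Construct and validate a normalization rule set
#'
#' @param rules Tibble with columns `variable` (the output label slot, e.g.
#'   `"blinding"`), `field` (one of the five characteristics fields the rule
#'   scans), `pattern` (case-insensitive Perl regex), `label` (canonical
#'   label, non-empty), `priority` (integer; unique within `field`).
#' @param name Rule-set name.
#' @param fallback Label returned when no rule matches; default
#'   `"unclassified"`.
#' @param codes Optional named character vector mapping canonical labels to
#'   numeric/short codes (kept as data; unused by matching).
#' @return An object of class `rm5_ruleset`.
#' @export
rm5_ruleset <- function(rules, name = "ruleset", fallback = "unclassified",
                        codes = NULL) {
  rules <- as_tibble(rules)
  if (!"variable" %in% names(rules)) rules$variable <- rules$field
  required <- c("variable", "field", "pattern", "label", "priority")
  missing_cols <- setdiff(required, names(rules))
  if (length(missing_cols)) {
    stop_rm5("rm5_config_error",
             sprintf("rule set missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  rules <- rules[required]
  rules$priority <- as.integer(rules$priority)

  errs <- character(0)
  bad_field <- !rules$field %in% char_field_names
  if (any(bad_field)) {
    errs <- c(errs, sprintf("rule %d: unknown field '%s'",
                            which(bad_field), rules$field[bad_field]))
  }
  for (i in seq_len(nrow(rules))) {
    ok <- tryCatch({ grepl(rules$pattern[i], "", perl = TRUE, ignore.case = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) errs <- c(errs, sprintf("rule %d: pattern does not compile: %s",
                                     i, rules$pattern[i]))
    if (is.na(rules$label[i]) || !nzchar(rules$label[i])) {
      errs <- c(errs, sprintf("rule %d: empty canonical label", i))
    }
  }
  dup <- rules %>% count(.data$field, .data$priority) %>% filter(.data$n > 1)
  if (nrow(dup)) {
    errs <- c(errs, sprintf("duplicate priority %d within field '%s'",
                            dup$priority, dup$field))
  }
  if (length(errs)) {
    stop_rm5("rm5_config_error",
             paste0("invalid rule set '", name, "':\n", paste0("- ", errs, collapse = "\n")))
  }
  rules <- arrange(rules, .data$field, .data$priority)
  structure(list(name = name, fallback = fallback, rules = rules, codes = codes),
            class = "rm5_ruleset")
}

#' @export
print.rm5_ruleset <- function(x, ...) {
  cat(sprintf("<rm5_ruleset> %s: %d rule(s), fallback \"%s\"\n",
              x$name, nrow(x$rules), x$fallback))
  invisible(x)
}

#' Load a rule set from a YAML file
#'
#' The file layout is: top-level `name`, `fallback`, optional `codes`
#' (label: code), and `rules:` — a list of `{field, pattern, label,
#' priority}` entries, each optionally carrying `variable` to direct the
#' label into a named slot of the normalized record (defaults to the field
#' name). Non-compiling patterns and duplicate priorities are rejected with
#' the offending rule identified.
#'
#' @param path Path to the YAML rule file. The package default (covering
#'   blinding, allocation and duration) ships at
#'   `system.file("extdata", "default_rules.yaml", package = "rm5tools")`.
#' @return An [rm5_ruleset()].
#' @export
load_ruleset <- function(path = default_ruleset_path()) {
  if (!file.exists(path)) {
    stop_rm5("rm5_config_error", sprintf("rule file does not exist: %s", path))
  }
  y <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_rm5("rm5_config_error", sprintf("rule file is not valid YAML: %s",
                                         conditionMessage(e)))
  })
  if (is.null(y$rules) || !length(y$rules)) {
    stop_rm5("rm5_config_error", sprintf("rule file has no rules: %s", path))
  }
  rules <- purrr::map_dfr(seq_along(y$rules), function(i) {
    r <- y$rules[[i]]
    for (k in c("field", "pattern", "label", "priority")) {
      if (is.null(r[[k]])) {
        stop_rm5("rm5_config_error",
                 sprintf("rule %d in %s: missing key '%s'", i, basename(path), k))
      }
    }
    tibble(variable = r$variable %||% r$field, field = r$field,
           pattern = r$pattern, label = r$label, priority = as.integer(r$priority))
  })
  codes <- if (!is.null(y$codes)) unlist(y$codes) else NULL
  rm5_ruleset(rules, name = y$name %||% basename(path),
              fallback = y$fallback %||% "unclassified", codes = codes)
}

#' Path of the shipped default rule file
#' @return File path.
#' @export
default_ruleset_path <- function() {
  system.file("extdata", "default_rules.yaml", package = "rm5tools")
}

#' Apply a rule set to one text field
#'
#' Returns the canonical label of the highest-priority (lowest priority
#' number) rule for `field` whose pattern matches `text`, or the rule set's
#' fallback label when none match. Matching is case-insensitive against the
#' plain-text projection; the function is total and deterministic and never
#' errors on content.
#'
#' @param text A character scalar (raw markup allowed; it is stripped).
#' @param rules An [rm5_ruleset()].
#' @param field One of `"methods"`, `"participants"`, `"interventions"`,
#'   `"outcomes"`, `"notes"`.
#' @param variable Optionally restrict to rules for one output variable.
#' @return A single canonical label.
#' @export
#' @examples
#' rs <- load_ruleset()
#' apply_rules("Allocation: randomised. Blinding: double blind.", rs, "methods",
#'             variable = "blinding")
apply_rules <- function(text, rules, field, variable = NULL) {
  stopifnot(inherits(rules, "rm5_ruleset"))
  field <- match.arg(field, char_field_names)
  txt <- plain_text(if (is.null(text) || length(text) == 0) "" else text[1])
  sub <- rules$rules[rules$rules$field == field, , drop = FALSE]
  if (!is.null(variable)) sub <- sub[sub$variable == variable, , drop = FALSE]
  # rules are stored pre-sorted by priority within field
  for (i in seq_len(nrow(sub))) {
    if (grepl(sub$pattern[i], txt, perl = TRUE, ignore.case = TRUE)) {
      return(sub$label[i])
    }
  }
  rules$fallback
}

#' Extract a participant count from free text
#'
#' Parses totals like `"N=120"` or `"120 participants"`. Only cue-anchored
#' numerals are accepted (an `N =` prefix, or a number immediately followed
#' by a participant word); bare numbers are never guessed, and written-out
#' numbers ("one hundred") are out of scope. When several cue-anchored
#' numbers occur, an explicit `N=` match wins over a "<n> participants"
#' match; ties go to the first occurrence.
#'
#' @param text Character scalar (raw markup allowed).
#' @return Integer count, or `NA_integer_` when no confident match.
#' @export
#' @examples
#' extract_participants_total("N=120 inpatients with schizophrenia")
#' extract_participants_total("12 weeks, N=60")
#' extract_participants_total("one hundred participants")
extract_participants_total <- function(text) {
  txt <- plain_text(if (is.null(text) || length(text) == 0) "" else text[1])
  m <- stringr::str_match(txt, stringr::regex("\\bN\\s*=\\s*(\\d+)", ignore_case = TRUE))
  if (!is.na(m[1, 2])) return(as.integer(m[1, 2]))
  cue <- "participants?|patients?|inpatients?|outpatients?|people|persons|subjects?|adults|individuals"
  m2 <- stringr::str_match(txt, stringr::regex(
    paste0("\\b(\\d+)\\s+(?:", cue, ")\\b"), ignore_case = TRUE))
  if (!is.na(m2[1, 2])) return(as.integer(m2[1, 2]))
  NA_integer_
}

#' Extract a trial duration in weeks from free text
#'
#' Recognises numeric durations expressed in weeks (`"Duration: 8 weeks"`,
#' `"over 12 weeks"`). Other units are not converted; absence returns `NA`.
#'
#' @param text Character scalar.
#' @return Non-negative double, or `NA_real_`.
#' @export
extract_duration_weeks <- function(text) {
  txt <- plain_text(if (is.null(text) || length(text) == 0) "" else text[1])
  m <- stringr::str_match(txt, stringr::regex(
    "\\b(\\d+(?:\\.\\d+)?)\\s*(?:-|\\s)?\\s*weeks?\\b", ignore_case = TRUE))
  if (!is.na(m[1, 2])) return(as.numeric(m[1, 2]))
  NA_real_
}

#' Normalize the characteristics of every study in one or more reviews
#'
#' Applies the rule set per configured field and the numeric extractors to
#' each study's characteristics, producing one tidy record per study. The
#' free text itself is untouched — raw and normalized forms travel side by
#' side through the pipeline.
#'
#' Labels for the standard variables `blinding` and `allocation` are taken
#' from rules with those `variable` names; labels for any other variable
#' names appearing in the rule set are gathered into list-column `extras`.
#'
#' @param reviews An `rm5_review` or list of them.
#' @param rules An [rm5_ruleset()]; defaults to the shipped rules.
#' @return Tibble with columns `review_id`, `study_id`, `blinding`,
#'   `allocation`, `duration_weeks`, `n_participants`, `extras`.
#' @export
normalize_studies <- function(reviews, rules = load_ruleset()) {
  if (inherits(reviews, "rm5_review")) reviews <- list(reviews)
  purrr::map_dfr(reviews, function(rev) {
    purrr::map_dfr(seq_len(nrow(rev$studies)), function(i) {
      sid <- rev$studies$study_id[i]
      ch <- rev$characteristics[rev$characteristics$study_id == sid, , drop = FALSE]
      normalize_study_chars(rev$review_id, sid, ch, rules)
    })
  })
}

#' @rdname normalize_studies
#' @param study_id Identifier of one study present in `review`.
#' @param review A single `rm5_review`.
#' @export
normalize_study <- function(review, study_id, rules = load_ruleset()) {
  stopifnot(inherits(review, "rm5_review"))
  if (!study_id %in% review$studies$study_id) {
    stop_rm5("rm5_lookup_error", sprintf("no study '%s' in review '%s'",
                                         study_id, review$review_id))
  }
  ch <- review$characteristics[review$characteristics$study_id == study_id, , drop = FALSE]
  normalize_study_chars(review$review_id, study_id, ch, rules)
}

normalize_study_chars <- function(review_id, study_id, ch, rules) {
  get_field <- function(f) if (nrow(ch)) ch[[f]][1] else ""
  vars <- unique(rules$rules$variable)
  labels <- stats::setNames(lapply(vars, function(v) {
    fld <- rules$rules$field[rules$rules$variable == v][1]
    apply_rules(get_field(fld), rules, fld, variable = v)
  }), vars)
  std <- c("blinding", "allocation")
  extras <- labels[setdiff(names(labels), c(std, "duration"))]
  tibble(
    review_id = review_id,
    study_id = study_id,
    blinding = labels[["blinding"]] %||% rules$fallback,
    allocation = labels[["allocation"]] %||% rules$fallback,
    duration_weeks = extract_duration_weeks(get_field("methods")),
    n_participants = extract_participants_total(get_field("participants")),
    extras = list(extras)
  )
}
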