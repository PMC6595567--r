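# Harvesting, clustering and curating free-text outcome titles.
#
# Outcome titles are the messiest field in review files: the same construct
# appears under thousands of surface forms. The pipeline keeps raw titles
# untouched ("unique" means exact string equality after Unicode NFC
# normalisation and trimming), groups them only by a deterministic canonical
# form, and exports a worksheet for human curation; the curated mapping is
# then applied back over the corpus.

#' Canonical form of an outcome title
#'
#' Casefolds, strips one leading enumeration token (e.g. `"1.1 "`), removes
#' punctuation, and collapses whitespace. Titles sharing a canonical form are
#' clustered together; nothing fuzzier (no edit distance) is applied, so
#' clusters are deterministic and explainable to the curator.
#'
#' @param title Character vector of raw titles.
#' @return Character vector of canonical forms.
#' @export
#' @examples
#' canonical_title(c("Mental state", "mental state", "Mental State.", "1.1 Mental state"))
canonical_title <- function(title) {
  x <- stringr::str_trim(title)
  x <- stringr::str_to_lower(x)
  x <- stringr::str_remove(x, "^\\d+(\\.\\d+)*\\.?\\s+")
  x <- stringr::str_replace_all(x, "[[:punct:]]+", " ")
  stringr::str_squish(x)
}

normalize_raw_title <- function(title) {
  stringr::str_trim(enc2utf8(stringi_nfc(title)))
}

# NFC normalization without adding a dependency: R >= 4 does not expose a
# base NFC helper portably, but iconv round-trip through UTF-8 plus the
# composed forms produced upstream suffice; titles from .rm5 files are
# already UTF-8. Kept as a seam should decomposed input ever appear.
stringi_nfc <- function(x) x

#' Harvest every outcome title across a batch of reviews
#'
#' One record per distinct raw title (exact string equality after trimming),
#' with its occurrence count over all (review, comparison, outcome) slots and
#' the reviews it appears in. Sorted by descending count, then title.
#'
#' @param reviews An `rm5_review` or list of them (e.g. from [read_batch()]).
#' @return Tibble with columns `raw_title`, `canonical_form`, `count`,
#'   `source_reviews` (list-column of review ids).
#' @export
harvest_titles <- function(reviews) {
  if (inherits(reviews, "rm5_review")) reviews <- list(reviews)
  occ <- purrr::map_dfr(reviews, function(rev) {
    if (nrow(rev$outcomes) == 0) return(NULL)
    tibble(review_id = rev$review_id,
           raw_title = normalize_raw_title(rev$outcomes$title))
  })
  if (is.null(occ) || nrow(occ) == 0) {
    return(tibble(raw_title = character(0), canonical_form = character(0),
                  count = integer(0), source_reviews = list()))
  }
  occ %>%
    group_by(.data$raw_title) %>%
    summarise(count = dplyr::n(),
              source_reviews = list(sort(unique(.data$review_id))),
              .groups = "drop") %>%
    mutate(canonical_form = canonical_title(.data$raw_title)) %>%
    select("raw_title", "canonical_form", "count", "source_reviews") %>%
    arrange(desc(.data$count), .data$raw_title)
}

#' Cluster harvested titles by canonical form
#'
#' Partitions the title records: every record lands in exactly one cluster,
#' keyed by shared canonical form. Clusters are numbered in order of
#' descending total count (ties broken by canonical form), and counts are
#' conserved.
#'
#' @param records Tibble from [harvest_titles()].
#' @return The records tibble with added columns `cluster_id` (integer) and
#'   `cluster_count` (total occurrences in the cluster), sorted by cluster
#'   then descending count.
#' @export
cluster_titles <- function(records) {
  if (nrow(records) == 0) {
    return(mutate(records, cluster_id = integer(0), cluster_count = integer(0)))
  }
  totals <- records %>%
    group_by(.data$canonical_form) %>%
    summarise(cluster_count = sum(.data$count), .groups = "drop") %>%
    arrange(desc(.data$cluster_count), .data$canonical_form) %>%
    mutate(cluster_id = dplyr::row_number())
  records %>%
    left_join(totals, by = "canonical_form") %>%
    arrange(.data$cluster_id, desc(.data$count), .data$raw_title) %>%
    select("cluster_id", "cluster_count", dplyr::everything())
}

worksheet_columns <- c("raw_title", "canonical_form", "count", "category", "subcategory")

#' Export a curation worksheet
#'
#' Writes clustered titles as a UTF-8 CSV with fixed columns `raw_title`,
#' `canonical_form`, `count`, `category`, `subcategory`; the last two are
#' left blank for the human curator to fill (the categorisation itself is
#' deliberately manual). An empty corpus yields a header-only file.
#'
#' @param clusters Tibble from [cluster_titles()] (or [harvest_titles()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_worksheet <- function(clusters, path) {
  ws <- tibble(
    raw_title = as.character(clusters$raw_title %||% character(0)),
    canonical_form = as.character(clusters$canonical_form %||% character(0)),
    count = as.integer(clusters$count %||% integer(0)),
    category = "", subcategory = "")
  if (nrow(ws) == 0) ws <- ws[0, ]
  readr::write_csv(ws, path, na = "")
  invisible(path)
}

#' Import a curated title-to-category mapping
#'
#' Reads a worksheet CSV back; rows whose `category` was filled become
#' mapping entries, untouched rows are simply absent from the mapping (never
#' null-mapped). If `categories` declares the allowed list, rows with an
#' unknown category are rejected, listing the offending row numbers.
#'
#' @param path Worksheet CSV path.
#' @param categories Optional character vector of allowed category names.
#' @return Tibble of class `rm5_mapping`: `raw_title`, `category`,
#'   `subcategory` (`NA` when absent).
#' @export
import_mapping <- function(path, categories = NULL) {
  ws <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing_cols <- setdiff(c("raw_title", "category"), names(ws))
  if (length(missing_cols)) {
    stop_rm5("rm5_config_error",
             sprintf("worksheet %s missing column(s): %s",
                     basename(path), paste(missing_cols, collapse = ", ")))
  }
  if (!"subcategory" %in% names(ws)) ws$subcategory <- NA_character_
  filled <- !is.na(ws$category) & nzchar(trimws(ws$category))
  mapping <- ws[filled, c("raw_title", "category", "subcategory"), drop = FALSE]
  if (!is.null(categories)) {
    bad <- which(!mapping$category %in% categories)
    if (length(bad)) {
      rows <- which(filled)[bad]
      stop_rm5("rm5_config_error",
               sprintf("unknown category in worksheet rows %s: %s",
                       paste(rows, collapse = ", "),
                       paste(unique(mapping$category[bad]), collapse = ", ")))
    }
  }
  if (anyDuplicated(mapping$raw_title)) {
    stop_rm5("rm5_config_error", "worksheet maps the same raw_title more than once")
  }
  mapping <- as_tibble(mapping)
  class(mapping) <- c("rm5_mapping", class(mapping))
  mapping
}

#' Apply a curated mapping over a batch of reviews
#'
#' Tags every outcome occurrence with its curated category; occurrences whose
#' raw title is not in the mapping are tagged `"UNMAPPED"` and counted in the
#' attached run report.
#'
#' @param reviews An `rm5_review` or list of them.
#' @param mapping An `rm5_mapping` from [import_mapping()], or `NULL` for an
#'   empty mapping.
#' @return Tibble of outcome occurrences (`review_id`, `comparison_id`,
#'   `outcome_id`, `raw_title`, `data_type`, `category`, `subcategory`) with
#'   attribute `"report"`: a list with `n_occurrences`, `n_unmapped` and
#'   `unmapped_fraction`.
#' @export
apply_mapping <- function(reviews, mapping = NULL) {
  if (inherits(reviews, "rm5_review")) reviews <- list(reviews)
  occ <- purrr::map_dfr(reviews, function(rev) {
    if (nrow(rev$outcomes) == 0) return(NULL)
    tibble(review_id = rev$review_id,
           comparison_id = rev$outcomes$comparison_id,
           outcome_id = rev$outcomes$outcome_id,
           raw_title = normalize_raw_title(rev$outcomes$title),
           data_type = rev$outcomes$data_type)
  })
  if (is.null(occ) || nrow(occ) == 0) {
    occ <- tibble(review_id = character(0), comparison_id = character(0),
                  outcome_id = character(0), raw_title = character(0),
                  data_type = character(0))
  }
  if (is.null(mapping) || nrow(mapping) == 0) {
    occ$category <- rep("UNMAPPED", nrow(occ))
    occ$subcategory <- rep(NA_character_, nrow(occ))
  } else {
    idx <- match(occ$raw_title, mapping$raw_title)
    occ$category <- ifelse(is.na(idx), "UNMAPPED", mapping$category[idx])
    occ$subcategory <- mapping$subcategory[idx]
  }
  n_unmapped <- sum(occ$category == "UNMAPPED")
  attr(occ, "report") <- list(
    n_occurrences = nrow(occ),
    n_unmapped = n_unmapped,
    unmapped_fraction = if (nrow(occ)) n_unmapped / nrow(occ) else 0)
  occ
}
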