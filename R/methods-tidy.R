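# tidy()/glance()/autoplot() methods for the package's result objects.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy the study table of a central dataset
#'
#' @param x An `rm5_central`.
#' @param ... Unused.
#' @return Tibble of flattened study records.
#' @method tidy rm5_central
#' @export
tidy.rm5_central <- function(x, ...) {
  x$studies %>%
    mutate(reference_years = vapply(.data$reference_years,
                                    function(y) paste(y, collapse = ";"), character(1))) %>%
    select(-"rob")
}

#' One-row summary of a central dataset
#'
#' @param x An `rm5_central`.
#' @param ... Unused.
#' @return One-row tibble: source, study and outcome-row counts.
#' @method glance rm5_central
#' @export
glance.rm5_central <- function(x, ...) {
  tibble(source_count = x$source_count,
         n_studies = nrow(x$studies),
         n_outcome_rows = nrow(x$outcome_rows),
         schema_version = x$schema_version,
         created = x$created)
}

#' Tidy a publication-year summary into its histogram
#'
#' @param x An `rm5_year_summary`.
#' @param ... Unused.
#' @return Tibble with columns `year`, `n`.
#' @method tidy rm5_year_summary
#' @export
tidy.rm5_year_summary <- function(x, ...) x$histogram

#' One-row summary of a publication-year analysis
#'
#' @param x An `rm5_year_summary`.
#' @param ... Unused.
#' @return One-row tibble: median year, fraction older than the threshold,
#'   dated and undated study counts.
#' @method glance rm5_year_summary
#' @export
glance.rm5_year_summary <- function(x, ...) {
  tibble(median_year = x$median_year,
         fraction_older = x$fraction_older,
         age_years = x$age_years,
         reference_year = x$reference_year,
         n_dated = x$n_dated,
         n_excluded = x$n_excluded)
}

#' Plot a publication-year histogram
#'
#' Bar chart of study counts per publication year, with the median year
#' marked — the corpus-age picture behind "how old is the evidence?".
#'
#' @param object An `rm5_year_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rm5_year_summary
#' @export
autoplot.rm5_year_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$year, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$median_year, linetype = "dashed") +
    ggplot2::labs(x = "Publication year", y = "Included studies",
                  title = "Publication years of included studies",
                  subtitle = sprintf("median %s; %.0f%% more than %d years before %d",
                                     format(object$median_year),
                                     100 * object$fraction_older,
                                     object$age_years, object$reference_year)) +
    ggplot2::theme_minimal()
}

#' Plot the largest outcome-title clusters
#'
#' Horizontal bars of total occurrence counts for the top clusters, labelled
#' by the most frequent raw title in each.
#'
#' @param clusters Tibble from [cluster_titles()].
#' @param top_n Number of clusters to show.
#' @return A ggplot object.
#' @export
plot_title_clusters <- function(clusters, top_n = 20) {
  top <- clusters %>%
    group_by(.data$cluster_id) %>%
    summarise(label = dplyr::first(.data$raw_title),
              total = dplyr::first(.data$cluster_count), .groups = "drop") %>%
    arrange(.data$cluster_id) %>%
    utils::head(top_n)
  ggplot2::ggplot(top, ggplot2::aes(x = .data$total,
                                    y = stats::reorder(.data$label, .data$total))) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Occurrences", y = NULL,
                  title = "Most frequent outcome-title clusters") +
    ggplot2::theme_minimal()
}
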