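# ggplot2 views of the main result types.

#' Bar chart of U/T beta-diversity ratios
#'
#' @param ut Output of [ut_ratio()], optionally row-bound over several
#'   scopes/modalities (needs a `group` column; `scope` and `modality`
#'   columns, if present, become facets).
#' @return A ggplot object.
#' @export
plot_ut <- function(ut) {
  p <- ggplot2::ggplot(ut, ggplot2::aes(x = .data$group, y = .data$ratio,
                                        fill = .data$group)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4,
                       size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "unique/total species ratio") +
    ggplot2::theme_minimal()
  facets <- intersect(c("modality", "scope"), names(ut))
  if (length(facets)) {
    p <- p + ggplot2::facet_grid(
      rows = if ("modality" %in% facets) ggplot2::vars(.data$modality),
      cols = if ("scope" %in% facets) ggplot2::vars(.data$scope)
    )
  }
  p
}

#' Boxplot of per-sample Shannon indices by group and scope
#'
#' @param shannon Output of [shannon_by_sample()] joined with a `group`
#'   column (as produced by [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_shannon <- function(shannon) {
  ggplot2::ggplot(
    filter(shannon, !is.na(.data$shannon_bits)),
    ggplot2::aes(x = .data$group, y = .data$shannon_bits, fill = .data$group)
  ) +
    ggplot2::geom_boxplot(show.legend = FALSE, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6,
                         show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scope)) +
    ggplot2::labs(x = NULL, y = "Shannon index (bits)") +
    ggplot2::theme_minimal()
}

#' Phylum breakdown of the missing repertoire
#'
#' @param object A `repertoire_report` from [annotate_candidates()].
#' @param ... Unused.
#' @return A ggplot object: species counts per phylum, split by candidacy
#'   and oxygen tolerance.
#' @method autoplot repertoire_report
#' @export
autoplot.repertoire_report <- function(object, ...) {
  df <- object$species |>
    mutate(
      status = case_when(
        .data$candidate %+na% FALSE ~ "probiotic candidate",
        .data$obligate_anaerobe %+na% FALSE ~ "obligate anaerobe",
        TRUE ~ "other missing species"
      )
    ) |>
    count(.data$phylum, .data$status)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$phylum, .data$n),
                                   y = .data$n, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "missing species", fill = NULL) +
    ggplot2::theme_minimal()
}
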