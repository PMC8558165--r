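#' Plot a phase-stratified frequency table
#'
#' Bar chart of the within-phase percent distribution by category, one facet
#' per phase of care.
#'
#' @param object a `care_freqtab` from [tabulate_patterns()] or
#'   [frequency_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.care_freqtab <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    dplyr::filter(is.na(.data$subcategory)) %>%
    tidyr::pivot_longer(
      dplyr::starts_with("pct_"),
      names_to = "phase", names_prefix = "pct_", values_to = "pct"
    ) %>%
    dplyr::mutate(phase = factor(.data$phase, levels = cp_phases))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$category, .data$pct),
                                   y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = NULL, y = "% of events within phase") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the phase-weighted distribution of categories
#'
#' Stacked horizontal bars of each category's per-patient-rate share across
#' the three phases of care (the figure-style view of where each kind of
#' care concentrates along the disease course).
#'
#' @param shares output of [phase_weighted_distribution()].
#' @return a ggplot object.
#' @export
plot_phase_weighted <- function(shares) {
  df <- shares %>%
    tidyr::pivot_longer(
      dplyr::starts_with("share_"),
      names_to = "phase", names_prefix = "share_", values_to = "share"
    ) %>%
    dplyr::mutate(phase = factor(.data$phase, levels = rev(cp_phases)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$share,
                                   fill = .data$phase)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_brewer(palette = "Set2", direction = -1,
                               breaks = cp_phases) +
    ggplot2::labs(x = NULL, y = "% of per-patient rate", fill = "Phase of care") +
    ggplot2::theme_minimal()
}
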