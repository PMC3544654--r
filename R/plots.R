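#' Plots for age-group summaries
#'
#' ggplot2 views of the main result types: the age distribution of families,
#' per-group expression specificity/abundance, and variant densities.
#'
#' @name plots
NULL

#' Age distribution of families
#'
#' @param ages tibble from [assign_ages()].
#' @return a ggplot bar chart of family counts per age group.
#' @export
plot_age_distribution <- function(ages) {
  ggplot2::ggplot(ages, ggplot2::aes(x = .data$age_label)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::labs(x = "age group (young to old)", y = "families") +
    ggplot2::theme_minimal()
}

#' Boxplots of a per-miRNA statistic by group
#'
#' @param df data frame with the value and group columns.
#' @param value,group column names (strings).
#' @param log_y log10 the y axis (useful for abundance).
#' @return a ggplot.
#' @export
plot_group_boxes <- function(df, value, group, log_y = FALSE) {
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[group]], y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Variant density by region class
#'
#' @param density tibble from [variant_density()].
#' @return a ggplot bar chart.
#' @export
plot_variant_density <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(x = .data$class, y = .data$density)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "region class", y = "variants per bp") +
    ggplot2::theme_minimal()
}
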