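# ggplot2 views of the main result objects.

#' Bar chart of percent contributions
#'
#' @param model A fitted `maxent_model` or a [percent_contribution()] tibble.
#' @return A ggplot object.
#' @export
plot_contributions <- function(model) {
  pc <- if (inherits(model, "maxent_model")) percent_contribution(model) else model
  ggplot2::ggplot(pc, ggplot2::aes(
    x = stats::reorder(.data$variable, .data$contribution_pct),
    y = .data$contribution_pct, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "contribution to regularized gain (%)",
                  fill = "category")
}

#' Net range change by projection configuration
#'
#' Bar height is the mean net change across scenarios; whiskers span the
#' scenario minimum and maximum.
#'
#' @param results Run-result tibble containing future runs (optionally with a
#'   `species` column).
#' @return A ggplot object.
#' @export
plot_net_change <- function(results) {
  sv <- scenario_variability(results)
  has_sp <- "species" %in% names(sv)
  p <- ggplot2::ggplot(sv, ggplot2::aes(x = .data$config, y = .data$mean_change)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min_change,
                                        ymax = .data$max_change), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "net range change vs contemporary (%)")
  if (has_sp) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$species))
  p
}

#' AUC by run configuration
#'
#' @param results Run-result tibble with contemporary runs.
#' @return A ggplot object.
#' @export
plot_auc <- function(results) {
  df <- dplyr::filter(results, .data$epoch == "contemporary")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$config, y = .data$auc_test)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = NULL, y = "test AUC") +
    (if ("species" %in% names(df)) {
      ggplot2::facet_wrap(ggplot2::vars(.data$species))
    } else NULL)
}
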