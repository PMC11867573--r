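#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of per-patient agreement metrics
#'
#' The standard summary figure of a contouring variability study: one box
#' per structure and comparison, per metric (DSC on its unit scale, 95% HD
#' in mm), over the per-patient values. Not-available records are dropped.
#'
#' @param object A `variability_result`.
#' @param metrics Which metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variability_result <- function(object, metrics = c("dsc", "hd95"),
                                        ...) {
  df <- object$records |>
    dplyr::filter(.data$metric %in% metrics, !is.na(.data$value)) |>
    dplyr::mutate(metric = factor(.data$metric, levels = metrics))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$structure, y = .data$value,
                                   fill = .data$comparison)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(dsc = "DSC", hd95 = "95% HD (mm)", hd = "HD (mm)")
                        )) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = paste0("Contour agreement: ", object$design)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Boxplots of structure volumes per arm
#'
#' Shows the distribution of physical volumes (cm^3) entering the ICC and
#' Wilcoxon volume comparisons, per structure and comparison arm.
#'
#' @param result A `variability_result`.
#' @return A ggplot object.
#' @export
plot_volumes <- function(result) {
  df <- result$records |>
    dplyr::filter(.data$metric %in% c("volume_a", "volume_b"),
                  !is.na(.data$value)) |>
    dplyr::mutate(arm = ifelse(.data$metric == "volume_a", "A", "B"),
                  volume_cm3 = .data$value / 1000)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$structure,
                                   y = .data$volume_cm3,
                                   fill = .data$arm)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::labs(x = NULL, y = "volume (cm³)", fill = "arm",
                  title = paste0("Structure volumes: ", result$design)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
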