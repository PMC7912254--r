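#' Plot the loading profile of a dietary pattern
#'
#' @param object An [fit_rrr()] result.
#' @param threshold Reference lines at +/- threshold (default 0.3).
#' @param ... Unused.
#' @return A ggplot: horizontal bars of food-group loadings.
#' @export
autoplot.rrr_fit <- function(object, threshold = 0.3, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loading,
                                   y = stats::reorder(.data$food_group, .data$loading),
                                   fill = .data$loading > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold), linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "factor loading (food-score correlation)", y = NULL,
                  title = sprintf("Dietary pattern (%s, R² = %.2f)",
                                  object$response_name, object$response_r2)) +
    ggplot2::theme_minimal()
}

#' Plot an enterotype solution in principal-coordinate space
#'
#' @param object An [find_enterotypes()] result.
#' @param ... Unused.
#' @return A ggplot: samples on PCo1/PCo2 coloured by enterotype.
#' @export
autoplot.enterotype_fit <- function(object, ...) {
  df <- tidy(object)
  colour_var <- if ("enterotype" %in% names(df)) "enterotype" else "cluster"
  df[[colour_var]] <- factor(df[[colour_var]])
  ve <- object$pcoa$variance_explained
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2,
                                   colour = .data[[colour_var]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::stat_ellipse(level = 0.9, linewidth = 0.3) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PCo2 (%.1f%%)", 100 * ve[2]),
                  colour = "enterotype") +
    ggplot2::theme_minimal()
}

#' Plot cluster-number diagnostics
#'
#' @param object A [choose_k()] result.
#' @param ... Unused.
#' @return A ggplot with the elbow, silhouette and gap curves side by side.
#' @export
autoplot.k_diagnostics <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("wss", "silhouette", "gap"),
                            names_to = "criterion", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$criterion, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Heatmap of a correlation screen
#'
#' @param screen A [correlation_screen()] tibble.
#' @param q_cutoff Cells with `q_value` below this are marked (default 0.05).
#' @return A ggplot tile heatmap of partial correlations.
#' @export
plot_correlation_heatmap <- function(screen, q_cutoff = 0.05) {
  stopifnot(all(c("left", "right", "coefficient") %in% names(screen)))
  screen$flag <- if ("q_value" %in% names(screen)) screen$q_value < q_cutoff else FALSE
  ggplot2::ggplot(screen, ggplot2::aes(x = .data$right, y = .data$left,
                                       fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$flag, "*", "")), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
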