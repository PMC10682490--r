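#' Gradient trajectory plot of group-mean network metrics
#'
#' Line chart of group-mean within-network (or one-versus-others)
#' connectivity across the ordered groups, one line per network -- the
#' display used to read off inverted-U / U-shaped gradient patterns.
#'
#' @param group_summary Tibble from [summarize_groups()].
#' @param metric_type `"wnc"` or `"ovo"`.
#' @param networks Optional subset of networks to show.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(group_summary, metric_type = c("wnc", "ovo"),
                            networks = NULL) {
  metric_type <- match.arg(metric_type)
  df <- dplyr::filter(group_summary, .data$metric_type == !!metric_type)
  if (!is.null(networks)) df <- dplyr::filter(df, .data$net_a %in% networks)
  df$group <- factor(as.character(df$group),
                     levels = intersect(suicidality_groups(), unique(as.character(df$group))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   colour = .data$net_a, group = .data$net_a)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = paste("group-mean", toupper(metric_type)),
                  colour = "network") +
    ggplot2::theme_minimal()
}

#' Heterogeneity screen plot
#'
#' log10 p-values of the rank-sum screen per variable, with the dashed
#' significance line at log10(0.05) (about -1.301); points below the line
#' indicate a significant sex or age effect.
#'
#' @param screen Tibble from [heterogeneity_screen()] (possibly several
#'   splits row-bound together).
#' @param alpha Significance level for the reference line.
#' @return A ggplot object.
#' @export
plot_heterogeneity <- function(screen, alpha = 0.05) {
  ggplot2::ggplot(screen, ggplot2::aes(x = .data$variable, y = .data$log10_p,
                                       colour = .data$split)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = log10(alpha), linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = NULL, y = "log10 p (rank-sum)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname tidy.sg_nbs
#' @param object An `sg_nbs` object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sg_nbs <- function(object, ...) {
  nm <- tidyr::pivot_longer(object$null_max, -"perm",
                            names_to = "direction", values_to = "max_size")
  p <- ggplot2::ggplot(nm, ggplot2::aes(x = .data$max_size)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "null max component size (edges)", y = "permutations") +
    ggplot2::theme_minimal()
  if (nrow(object$components)) {
    obs <- dplyr::select(object$components, "direction", "n_edges")
    p <- p + ggplot2::geom_vline(data = obs,
                                 ggplot2::aes(xintercept = .data$n_edges),
                                 colour = "red", linetype = "dashed")
  }
  p
}

#' @rdname tidy.sg_classification
#' @param object An `sg_classification` object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sg_classification <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = object$contrast, x = NULL, y = "test-set value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
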