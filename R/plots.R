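#' Plot module eigengene trajectories by genotype
#'
#' Per-module mean eigengene value for each genotype over time, the standard
#' view of module dynamics across the factorial design.
#'
#' @param eigengenes Eigengene matrix (modules x samples) or
#'   [compute_eigengenes()] result.
#' @param design Sample design matching the eigengene columns.
#' @param modules Optional subset of module names to show.
#' @return A ggplot object (facets per module, lines per genotype).
#' @export
plot_eigengenes <- function(eigengenes, design, modules = NULL) {
  me <- if (is.list(eigengenes)) eigengenes$eigengenes else eigengenes
  df <- matrix_to_tibble(me, id_col = "module")
  df <- pivot_longer(df, -"module", names_to = "sample_id",
                     values_to = "value")
  df <- inner_join(df, design, by = "sample_id")
  if (!is.null(modules)) df <- filter(df, .data$module %in% modules)
  df <- summarise(group_by(df, .data$module, .data$genotype,
                           .data$timepoint),
                  value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$value,
                                   colour = .data$genotype)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~module, scales = "free_y") +
    ggplot2::labs(x = "timepoint (DAP)", y = "module eigengene") +
    ggplot2::theme_minimal()
}

#' Plot module flows between two timepoints
#'
#' Tile view of [trace_module_flow()] fractions (share of the later module's
#' genes contributed by each earlier module).
#'
#' @param flows Flow tibble from [trace_module_flow()].
#' @return A ggplot object.
#' @export
plot_module_flow <- function(flows) {
  ggplot2::ggplot(flows, ggplot2::aes(x = .data$to, y = .data$from,
                                      fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$shared), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "later module", y = "earlier module",
                  fill = "fraction of\nlater module") +
    ggplot2::theme_minimal()
}

#' @describeIn coexpression_network Heatmap of module-TF correlations from a
#'   fitted coexpression network.
#' @param object A `coexpression_fit`.
#' @param ... Unused.
#' @export
autoplot.coexpression_fit <- function(object, ...) {
  if (is.null(object$tf_correlation)) {
    abort("fit has no tf_correlation; pass tf_expr to coexpression_network()")
  }
  df <- object$tf_correlation
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tf, y = .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(sprintf("%.2f", .data$r), .data$stars)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::labs(x = "regulator", y = "module", fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
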