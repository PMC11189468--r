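#' Plot the step-up panel-size curve
#'
#' Mean cross-validated AUROC against panel size with a +/- 1 sd ribbon;
#' the selected size is marked.
#'
#' @param object a `stepup_curve` from [stepup_select()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot stepup_curve
autoplot.stepup_curve <- function(object, ...) {
  d <- object$curve
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$auroc_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$auroc_mean - .data$auroc_sd,
                                      ymax = .data$auroc_mean + .data$auroc_sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$n_star, linetype = 2) +
    ggplot2::labs(x = "panel size (transcripts)", y = "cross-validated AUROC",
                  title = sprintf("Step-up selection: %d transcripts", object$n_star)) +
    ggplot2::theme_minimal()
}

#' Plot fold-level AUROC of a model report
#'
#' Boxplots of the per-fold AUROC for the gene panel and, when present, the
#' clinical-score comparator.
#'
#' @param object a `model_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot model_report
autoplot.model_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$auroc)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = NULL, y = "held-out AUROC", title = object$group) +
    ggplot2::theme_minimal()
}

#' Plot a mapper graph
#'
#' Force-directed layout of the node graph; node size scales with the
#' number of member patients, colour with a per-node summary of `color_by`
#' (e.g. mortality).
#'
#' @param object a `mapper_graph`.
#' @param color_by optional named per-patient numeric vector, averaged per
#'   node.
#' @param seed layout seed.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot mapper_graph
autoplot.mapper_graph <- function(object, color_by = NULL, seed = 1L, ...) {
  g <- mapper_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nd <- tibble::tibble(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                       size = igraph::V(g)$size)
  if (!is.null(color_by)) {
    nd$value <- vapply(nd$node, function(n) {
      p <- object$nodes$patients[[match(n, object$nodes$node)]]
      mean(color_by[p], na.rm = TRUE)
    }, numeric(1))
  }
  ed <- dplyr::left_join(object$edges, nd, by = c(from = "node"))
  ed <- dplyr::left_join(ed, nd, by = c(to = "node"), suffix = c("", "_to"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_to, yend = .data$y_to),
                          color = "grey70", linewidth = 0.3)
  p <- if (is.null(color_by)) {
    p + ggplot2::geom_point(data = nd, ggplot2::aes(.data$x, .data$y, size = .data$size))
  } else {
    p + ggplot2::geom_point(data = nd, ggplot2::aes(.data$x, .data$y, size = .data$size,
                                                    color = .data$value)) +
      ggplot2::scale_color_gradient(low = "forestgreen", high = "red")
  }
  p + ggplot2::theme_void() + ggplot2::labs(size = "patients", color = "mean value")
}

#' Mean-sd plot of an expression matrix
#'
#' Per-gene standard deviation against the rank of the per-gene mean — the
#' standard visual check that the VST flattened the variance-mean trend.
#'
#' @param expr genes-by-patients matrix.
#' @return A ggplot object.
#' @export
plot_mean_sd <- function(expr) {
  d <- tibble::tibble(rank_mean = rank(rowMeans(expr)),
                      sd = apply(expr, 1, stats::sd))
  ggplot2::ggplot(d, ggplot2::aes(.data$rank_mean, .data$sd)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_smooth(formula = y ~ x, method = "loess", se = FALSE,
                         color = "red", linewidth = 0.6) +
    ggplot2::labs(x = "rank of per-gene mean", y = "per-gene sd") +
    ggplot2::theme_minimal()
}

#' Plot normalized enrichment scores
#'
#' Horizontal bar chart of NES for the top sets of an enrichment table,
#' shaded by adjusted significance.
#'
#' @param enrich tibble from [gsea_preranked()].
#' @param top number of sets to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrich, top = 20) {
  d <- utils::head(dplyr::arrange(enrich, .data$p_value), top)
  d$set <- factor(d$set, levels = rev(d$set))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nes, y = .data$set,
                                  fill = .data$p_adjusted <= 0.05)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                               name = "p_adjusted <= 0.05") +
    ggplot2::labs(x = "normalized enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}
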