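# ggplot2 displays for the result types.

#' Plot an association scan
#'
#' One panel per (selected) trait with -log10 P against variant index, the
#' usual per-trait association profile.
#'
#' @param object A `poem_scan`.
#' @param traits Optional character vector of trait ids to show (defaults to
#'   the first 6).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot poem_scan
#' @export
autoplot.poem_scan <- function(object, traits = NULL, ...) {
  tb <- tidy(object)
  if (is.null(traits)) traits <- utils::head(rownames(object$scores), 6)
  tb <- tb[tb$trait_id %in% traits, , drop = FALSE]
  tb$index <- match(tb$variant_id, colnames(object$scores))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$index, y = .data$score)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait_id)) +
    ggplot2::labs(x = "variant index", y = expression(-log[10] ~ P),
                  title = paste0(object$provenance, " one-locus scan")) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' Achieved points with the step extension used by the accuracy score.
#'
#' @param object A `poem_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot poem_roc
#' @export
autoplot.poem_roc <- function(object, ...) {
  p <- object$points
  path <- rbind(tibble::tibble(fpr = 0, tpr = 0),
                p[order(p$fpr, p$tpr), c("fpr", "tpr")],
                tibble::tibble(fpr = 1, tpr = max(p$tpr)))
  ggplot2::ggplot(path, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = p, size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("accuracy score = %.3f", object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot the module-eQTL graph of a POEM fit
#'
#' Bipartite layout: poeModules (squares) between their primary and
#' secondary eQTLs (points), coloured by component structure.
#'
#' @param fit A `poem_fit` or module tibble.
#' @return A ggplot.
#' @export
plot_module_graph <- function(fit) {
  modules <- if (inherits(fit, "poem_fit")) fit$modules else fit
  mg <- module_graph(modules)
  if (nrow(modules) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no poeModules"))
  }
  lay <- igraph::layout_with_fr(mg$graph)
  nodes <- tibble::tibble(
    name = igraph::V(mg$graph)$name,
    is_eqtl = igraph::V(mg$graph)$type,
    x = lay[, 1], y = lay[, 2],
    component = igraph::components(mg$graph)$membership)
  nodes$structure <- mg$components$structure[nodes$component]
  el <- igraph::as_edgelist(mg$graph)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1], nodes$name)],
    y = nodes$y[match(el[, 1], nodes$name)],
    xend = nodes$x[match(el[, 2], nodes$name)],
    yend = nodes$y[match(el[, 2], nodes$name)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$is_eqtl,
                                     colour = .data$structure), size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 16),
                                labels = c("poeModule", "eQTL"),
                                name = NULL) +
    ggplot2::theme_void()
}

#' Accuracy-by-method bar chart for a comparison
#'
#' @param comparison Result of [compare_methods()].
#' @return A ggplot.
#' @export
plot_method_comparison <- function(comparison) {
  ggplot2::ggplot(comparison$accuracy,
                  ggplot2::aes(x = .data$method, y = .data$accuracy)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "accuracy score") +
    ggplot2::theme_minimal()
}
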