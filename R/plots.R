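# ggplot2 views of the result objects, plus a base-graphics tree plot.

#' @method autoplot taxon_support
#' @export
autoplot.taxon_support <- function(object, ...) {
  df <- object$report |>
    filter(.data$status != "trivial") |>
    mutate(taxon = stats::reorder(.data$taxon, .data$signed_support))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon, y = .data$signed_support,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "signed branch support (%)",
                  title = paste0("Taxon support at rank '", object$rank,
                                 "' (overall ", round(object$overall, 3), ")")) +
    ggplot2::theme_minimal()
}

#' @method autoplot threshold_fit
#' @export
autoplot.threshold_fit <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$threshold, y = .data$mri)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = tibble(threshold = object$threshold,
                                      mri = object$mri),
                        colour = "red", size = 2) +
    ggplot2::labs(x = "distance threshold T", y = "agreement index (MRI)",
                  title = if (!is.na(object$rank))
                    paste0("Threshold scan, rank '", object$rank, "'")
                  else "Threshold scan") +
    ggplot2::theme_minimal()
}

#' Plot a support-annotated tree
#'
#' Base-graphics wrapper drawing the midpoint-rooted tree with internal
#' branch support percentages.
#'
#' @param tree A rooted [ape::phylo] with support node labels.
#' @param support_min Only show supports at or above this value.
#' @param ... Passed to [ape::plot.phylo()].
#' @return The tree, invisibly.
#' @export
plot_support_tree <- function(tree, support_min = 60, ...) {
  ape::plot.phylo(tree, ...)
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    show <- !is.na(sup) & sup >= support_min
    if (any(show))
      ape::nodelabels(text = tree$node.label[show],
                      node = (ape::Ntip(tree) + 1L:tree$Nnode)[show],
                      frame = "none", adj = c(1.2, -0.3), cex = 0.8)
  }
  invisible(tree)
}
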