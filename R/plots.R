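# Publication-style figures for the pipeline stages (ggplot2).

#' Ordination scatter plot coloured by group
#'
#' @param ord a \code{"chipbiome_ordination"} from [pcoaOrdination()] or
#'   [nmdsOrdination()].
#' @param groups factor of group labels, parallel to the samples.
#' @return a ggplot object.
#' @export
plotOrdination <- function(ord, groups) {
  df <- data.frame(x = ord$coordinates[, 1], y = ord$coordinates[, 2],
                   group = factor(groups))
  labs <- colnames(ord$coordinates)[1:2]
  if (ord$method == "PCoA" && !is.null(ord$explained))
    labs <- sprintf("%s (%.1f%%)", labs, 100 * ord$explained[1:2])
  sub <- if (ord$method == "NMDS") sprintf("stress = %.3f", ord$stress) else NULL
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.9, linetype = 2, na.rm = TRUE) +
    ggplot2::labs(x = labs[1], y = labs[2], title = ord$method,
                  subtitle = sub, colour = "group") +
    ggplot2::theme_classic()
}

#' Horizontal LEfSe effect-size bar plot
#'
#' @param results output of [lefse()] (or one rank of
#'   [buildCladogramTable()]).
#' @return a ggplot object.
#' @export
plotLefse <- function(results) {
  if (!nrow(results)) stop("no differential taxa to plot")
  df <- results[order(results$lda_score), ]
  df$taxon <- factor(df$taxon, levels = df$taxon)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lda_score, y = .data$taxon,
                                   fill = .data$enriched_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "LDA score (log10)", y = NULL, fill = "enriched in") +
    ggplot2::theme_classic()
}

#' ROC curve plot
#'
#' @param report a \code{"chipbiome_roc"} from [rocAuc()].
#' @return a ggplot object.
#' @export
plotRoc <- function(report) {
  ggplot2::ggplot(report$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                                  report$auc, report$auc_ci_low,
                                  report$auc_ci_high)) +
    ggplot2::theme_classic()
}

#' Species-cytokine correlation heatmap
#'
#' Tiles coloured by Spearman rho with significance stars, restricted to
#' species with at least one significant correlation.
#'
#' @param corr output of [spearmanMatrix()].
#' @return a ggplot object.
#' @export
plotCorrelationHeatmap <- function(corr) {
  keep <- unique(corr$species[!is.na(corr$p_value) & corr$p_value < 0.05])
  if (!length(keep)) stop("no significant correlations to plot")
  df <- corr[corr$species %in% keep, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cytokine, y = .data$species,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$tier), size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 .data
NULL
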