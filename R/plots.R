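# ggplot2 displays for curves, score tracks and cross-validation results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PR or ROC curve
#'
#' @param object An `na_curve` from [pr_curve()] or [roc_curve()].
#' @param baseline Optional horizontal (PRC) baseline, e.g.
#'   [random_baseline()]; the ROC diagonal is always drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot na_curve
#' @export
autoplot.na_curve <- function(object, baseline = NULL, ...) {
  kind <- attr(object, "kind")
  labs <- if (identical(kind, "ROC")) {
    c("False positive rate", "True positive rate")
  } else {
    c("Recall", "Precision")
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = labs[1], y = labs[2],
                  title = sprintf("%s (AUC %.3f)", kind, auc(object))) +
    ggplot2::theme_minimal()
  if (identical(kind, "ROC")) {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0,
                                  linetype = "dashed", colour = "grey60")
  } else if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline, linetype = "dashed",
                                 colour = "grey60")
  }
  p
}

#' Plot a per-residue score track
#'
#' @param scores Numeric per-residue scores.
#' @param labels Optional 0/1 ground-truth labels shown as points.
#' @param cutoff Optional horizontal cutoff line.
#' @return A ggplot.
#' @export
plot_score_track <- function(scores, labels = NULL, cutoff = NULL) {
  df <- tibble::tibble(residue_index = seq_along(scores) - 1L, score = scores)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_index,
                                        y = .data$score)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Residue index", y = "Binding score") +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    df$label <- factor(labels, levels = c(0, 1),
                       labels = c("non-binding", "binding"))
    p <- p + ggplot2::geom_point(data = df[df$label == "binding", ],
                                 colour = "#b2182b", size = 1.4)
  }
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' Plot out-of-fold ROC curves of a cross-validated run
#'
#' @param object An `na_two_stage_cv`.
#' @param ... Unused.
#' @return A ggplot with the residue-level and protein-level ROC curves.
#' @method autoplot na_two_stage_cv
#' @export
autoplot.na_two_stage_cv <- function(object, ...) {
  s1 <- stage1_pooled(object)
  r1 <- roc_curve(s1$scores, s1$labels)
  r2 <- roc_curve(object$proteins$oof_score, object$proteins$label)
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(r1),
                  stage = sprintf("residues (AUC %.2f)", auc(r1))),
    dplyr::mutate(tibble::as_tibble(r2),
                  stage = sprintf("proteins (AUC %.2f)", auc(r2)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$stage)) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
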