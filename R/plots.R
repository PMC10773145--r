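#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_errorbarh geom_boxplot geom_jitter geom_abline geom_line labs
#'   scale_color_manual theme_minimal position_jitter
NULL

#' @export
ggplot2::autoplot

#' Volcano plot of differential proteins
#'
#' @param object A `dep_results` tibble from [differential_proteins()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dep_results <- function(object, ...) {
  params <- attr(object, "params")
  df <- as_tibble(object)
  df$status <- ifelse(df$significant, df$direction, "ns")
  ggplot(df, aes(x = .data$log2fc, y = -log10(.data$p), color = .data$status)) +
    geom_point(alpha = 0.6, size = 1.2) +
    geom_vline(xintercept = c(-1, 1) * params$lfc_threshold, linetype = "dashed") +
    geom_hline(yintercept = -log10(params$alpha), linetype = "dashed") +
    scale_color_manual(values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")) +
    labs(x = "log2 fold change (cancer / non-cancer)", y = "-log10 p",
         color = NULL) +
    theme_minimal()
}

#' Forest plot of per-species risk odds ratios
#'
#' @param object A `risk_results` tibble from [species_risk()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.risk_results <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$converged, ]
  df$taxon_id <- stats::reorder(df$taxon_id, df$odds_ratio)
  ggplot(df, aes(x = .data$odds_ratio, y = .data$taxon_id)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    labs(x = "odds ratio (95% CI)", y = NULL) +
    theme_minimal()
}

#' Box plot of intra- vs inter-individual stability correlations
#'
#' @param object A `stability_summary` from [stability_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_summary <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot(pairs, aes(x = .data$stratum, y = .data$r)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.3, size = 0.8) +
    labs(x = NULL, y = "Spearman correlation") +
    theme_minimal()
}

#' ROC curve of a screening model evaluation
#'
#' @param object A `screening_eval` from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screening_eval <- function(object, ...) {
  sc <- object$scores
  roc <- pROC::roc(response = sc$truth, predictor = sc$probability,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  df <- tibble(fpr = rev(1 - roc$specificities), tpr = rev(roc$sensitivities))
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("AUC = %.3f", object$metrics$auc)) +
    theme_minimal()
}

#' Scatter plot of the 2-D sample embedding
#'
#' @param object An `embedding_diagnostics` from [embedding_diagnostics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.embedding_diagnostics <- function(object, ...) {
  ggplot(object$embedding,
         aes(x = .data$tsne1, y = .data$tsne2, color = .data$group)) +
    geom_point(alpha = 0.8) +
    labs(x = "t-SNE 1", y = "t-SNE 2", color = NULL) +
    theme_minimal()
}
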