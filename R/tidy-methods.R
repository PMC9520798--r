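# broom-style tidiers and ggplot2 autoplot methods for the fitted-object
# classes.

#' Tidy a fitted model bundle
#'
#' @param x A `phis_model`.
#' @param ... Unused.
#' @return Tibble of the selected features with their F-scores and ranks
#'   (or just the feature names when the bundle was trained on a bare
#'   matrix without pipeline selection).
#' @method tidy phis_model
#' @export
tidy.phis_model <- function(x, ...) {
  if (!is.null(x$scores)) {
    out <- as_tibble(x$scores)
    out[out$selected, c("feature", "f", "rank")]
  } else {
    tibble(feature = x$selected_features,
           rank = seq_along(x$selected_features))
  }
}

#' One-row summary of a fitted model bundle
#'
#' @param x A `phis_model`.
#' @param ... Unused.
#' @return One-row tibble: algorithm, window, number of selected features,
#'   class weights, threshold, seed.
#' @method glance phis_model
#' @export
glance.phis_model <- function(x, ...) {
  tibble(
    algorithm = x$algorithm,
    window = x$window %||% NA_integer_,
    n_features = length(x$selected_features),
    weight_nonphis = unname(x$class_weights["nonpHis"]),
    weight_phis = unname(x$class_weights["pHis"]),
    threshold = x$threshold,
    seed = x$seed
  )
}

#' Tidy a cross-validation report
#'
#' @param x A `phis_eval`.
#' @param ... Unused.
#' @return The per-fold metric tibble.
#' @method tidy phis_eval
#' @export
tidy.phis_eval <- function(x, ...) x$per_fold

#' One-row summary of a cross-validation report
#'
#' @param x A `phis_eval`.
#' @param ... Unused.
#' @return One-row tibble with mean/sd AUC and F1 and the pooled AUC.
#' @method glance phis_eval
#' @export
glance.phis_eval <- function(x, ...) {
  tibble(
    algorithm = x$config$algorithm, k = x$config$k, folds = x$config$folds,
    mean_auc = x$mean_auc, sd_auc = x$sd_auc,
    mean_f1 = x$mean_f1, sd_f1 = x$sd_f1,
    pooled_auc = x$pooled_auc
  )
}

#' Plot the pooled ROC curve of a cross-validation report
#'
#' @param object A `phis_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phis_eval
#' @export
autoplot.phis_eval <- function(object, ...) {
  ggplot2::ggplot(object$curves$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Pooled out-of-fold ROC (AUC = %.3f)", object$pooled_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot ROC and precision-recall curves
#'
#' @param object A `phis_curves` object from [roc_pr()].
#' @param which `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phis_curves
#' @export
autoplot.phis_curves <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           color = "grey60") +
      ggplot2::geom_path() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC (AUC = %.3f)", object$auc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_path() +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("Precision-recall (AUC = %.3f)", object$auc_pr)) +
      ggplot2::theme_minimal()
  }
}

#' Plot a positional enrichment table as a signed significance map
#'
#' Tiles mark (offset, residue) cells called enriched (positive) or
#' depleted (negative), shaded by the frequency difference.
#'
#' @param object A `phis_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phis_enrichment
#' @export
autoplot.phis_enrichment <- function(object, ...) {
  df <- as_tibble(object)
  df$delta <- ifelse(df$direction == "ns", NA_real_,
                     df$freq_pos - df$freq_neg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$residue,
                                   fill = .data$delta)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", na.value = "white",
                                  name = "freq(pHis) - freq(non)") +
    ggplot2::labs(x = "Offset from central His", y = "Residue",
                  title = "Positional enrichment (significant cells shaded)") +
    ggplot2::theme_minimal()
}

#' Plot the pHis-to-nearest-non-pHis distance distribution
#'
#' @param object A `phis_distances` object.
#' @param binwidth Histogram bin width (default 5 residues).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phis_distances
#' @export
autoplot.phis_distances <- function(object, binwidth = 5, ...) {
  ggplot2::ggplot(object$distances, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(
      x = "Distance to nearest non-pHis His (residues)", y = "pHis sites",
      title = sprintf("%.0f%% of distances < %d residues",
                      100 * object$fraction_below, object$cutoff)
    ) +
    ggplot2::theme_minimal()
}
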