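# Imbalance-aware evaluation: confusion-matrix metrics, ROC/PR curves with
# trapezoid AUC, threshold sweeps, and leak-free stratified k-fold
# cross-validation in which the variance filter, normalization bounds and
# F-score selection are refit inside every training fold.

#' Confusion counts from truth and calls
#'
#' @param truth Binary ground-truth labels.
#' @param call Binary predicted labels.
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, call) {
  yt <- as_binary_labels(truth)
  yc <- as_binary_labels(call)
  tibble(
    tp = sum(yt == 1 & yc == 1), tn = sum(yt == 0 & yc == 0),
    fp = sum(yt == 0 & yc == 1), fn = sum(yt == 1 & yc == 0)
  )
}

#' Scalar metrics from confusion counts
#'
#' Specificity TN/(TN+FP), recall TP/(TP+FN), precision TP/(TP+FP),
#' F1 = 2*recall*precision/(recall+precision), accuracy, and Matthews
#' correlation coefficient. Any metric whose denominator vanishes is
#' reported as 0 and the `degenerate` flag is set, so extreme thresholds
#' still produce finite reports.
#'
#' @param counts One-row tibble/list with `tp`, `tn`, `fp`, `fn` (or the
#'   four counts given separately via `tp`, `tn`, `fp`, `fn` arguments).
#' @param tp,tn,fp,fn Optional scalar counts, used when `counts` is missing.
#' @return One-row tibble: `specificity`, `recall`, `precision`, `f1`,
#'   `accuracy`, `mcc`, `degenerate`.
#' @export
metrics_from_confusion <- function(counts = NULL, tp = NULL, tn = NULL,
                                   fp = NULL, fn = NULL) {
  if (!is.null(counts)) {
    tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  }
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  degenerate <- (tn + fp) == 0 || (tp + fn) == 0 || (tp + fp) == 0
  specificity <- safe_div(tn, tn + fp)
  recall <- safe_div(tp, tp + fn)
  precision <- safe_div(tp, tp + fp)
  f1 <- if (recall + precision == 0) {
    degenerate <- TRUE
    0
  } else 2 * recall * precision / (recall + precision)
  accuracy <- safe_div(tp + tn, tp + tn + fp + fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tp + fn) * sqrt(tn + fp)
  mcc <- if (mcc_den == 0) {
    degenerate <- TRUE
    0
  } else (tp * tn - fp * fn) / mcc_den
  tibble(specificity = specificity, recall = recall, precision = precision,
         f1 = f1, accuracy = accuracy, mcc = mcc, degenerate = degenerate)
}

#' ROC and precision-recall curves with trapezoid AUC
#'
#' The ROC curve is built by sweeping the decision threshold over the
#' distinct scores; the returned AUC is the trapezoid-rule area, which
#' equals the Mann-Whitney concordance probability (ties counted half).
#'
#' @param scores Per-sample scores (higher = more likely pHis).
#' @param labels Binary labels.
#' @return A `phis_curves` list: `roc` tibble (`threshold`, `fpr`, `tpr`),
#'   `pr` tibble (`threshold`, `recall`, `precision`), `auc`, `auc_pr`.
#' @export
roc_pr <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) abort("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  # cumulative counts at each distinct-score cut (call positive if score >= s)
  cut_idx <- which(!duplicated(s, fromLast = TRUE) |
                     seq_along(s) == length(s))
  cum_tp <- cumsum(yy)[cut_idx]
  cum_fp <- cumsum(1 - yy)[cut_idx]
  roc <- tibble(
    threshold = c(Inf, s[cut_idx]),
    fpr = c(0, cum_fp / n_neg),
    tpr = c(0, cum_tp / n_pos)
  )
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  precision <- ifelse(cum_tp + cum_fp == 0, 1, cum_tp / (cum_tp + cum_fp))
  pr <- tibble(
    threshold = s[cut_idx],
    recall = cum_tp / n_pos,
    precision = precision
  )
  rec <- c(0, pr$recall)
  prec <- c(if (nrow(pr) > 0) pr$precision[1] else 1, pr$precision)
  auc_pr <- sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
  structure(list(roc = roc, pr = pr, auc = auc, auc_pr = auc_pr),
            class = "phis_curves")
}

#' Area under the ROC curve
#'
#' @inheritParams roc_pr
#' @return AUC as a single number.
#' @export
auc_score <- function(scores, labels) roc_pr(scores, labels)$auc

#' Metrics across a grid of classification thresholds
#'
#' A sample is called positive when its score is `>= threshold`; at
#' threshold 1 the call is strictly `> 1` (the "1 + epsilon" convention),
#' so threshold 0 yields recall 1 / specificity 0 and threshold 1 yields
#' recall 0 / specificity 1.
#'
#' @param scores Per-sample scores in \[0,1\].
#' @param labels Binary labels.
#' @param grid Thresholds in \[0,1\] (default `seq(0, 1, by = 0.05)`).
#' @return A tibble with one row per threshold: the four confusion counts
#'   and the six metrics.
#' @export
threshold_sweep <- function(scores, labels, grid = seq(0, 1, by = 0.05)) {
  if (length(grid) == 0) abort("threshold grid is empty")
  if (any(grid < 0 | grid > 1)) abort("thresholds must lie in [0, 1]")
  y <- as_binary_labels(labels)
  rows <- lapply(sort(grid), function(t) {
    call <- if (t >= 1) scores > 1 else scores >= t
    cc <- confusion_counts(y, as.integer(call))
    bind_cols(tibble(threshold = t), cc, metrics_from_confusion(cc))
  })
  bind_rows(rows)
}

# ---- cross-validation -------------------------------------------------------

#' Leak-free stratified k-fold cross-validation on a feature table
#'
#' Inside every training fold — and only there — constant features are
#' dropped, normalization bounds are fitted, features are ranked by ANOVA
#' F-score and the top `k` are selected; the held-out fold is then
#' transformed with those frozen choices and scored. Setting
#' `leaky = TRUE` deliberately fits the variance filter, normalizer and
#' selection on all samples before folding (the optimistically biased
#' protocol this package exists to avoid); it is provided only so the bias
#' can be demonstrated and regression-tested.
#'
#' @param features Feature tibble (with `label`) or numeric matrix.
#' @param labels Binary labels; from `features$label` when omitted.
#' @param k Number of features to select inside each fold.
#' @param algorithm One of [algorithms()].
#' @param folds Number of stratified folds (default 10).
#' @param seed Integer seed (fold assignment and every stochastic learner).
#' @param hyperparams Named list of classifier hyperparameter overrides.
#' @param threshold Probability threshold for the per-fold binary metrics.
#' @param leaky Fit selection/normalization on all data first (default
#'   FALSE; see above).
#' @return A `phis_eval` object: per-fold metric tibble, pooled
#'   out-of-fold scores, pooled ROC/PR curves, and summary statistics.
#' @export
cv_evaluate <- function(features, labels = NULL, k = 140L,
                        algorithm = "svm_rbf", folds = 10L, seed = 1L,
                        hyperparams = list(), threshold = 0.5,
                        leaky = FALSE) {
  m <- if (is.matrix(features)) features else feature_matrix(features)
  if (is.null(labels)) {
    if (is.data.frame(features) && "label" %in% names(features)) {
      labels <- features$label
    } else abort("labels must be supplied")
  }
  y <- as_binary_labels(labels)
  fold_id <- stratified_folds(y, folds, seed)
  if (leaky) {
    m_all <- drop_zero_variance(m)
    b_all <- fit_normalizer(m_all)
    m_all <- scale_min_max(m_all, b_all$min, b_all$max)
    sel_all <- head(score_features(m_all, y)$feature, min(k, ncol(m_all)))
  }
  oof <- tibble(row = seq_along(y), fold = fold_id, label = y,
                probability = NA_real_)
  fold_rows <- vector("list", folds)
  for (fo in seq_len(folds)) {
    tr <- fold_id != fo
    if (leaky) {
      xtr <- m_all[tr, sel_all, drop = FALSE]
      xte <- m_all[!tr, sel_all, drop = FALSE]
    } else {
      # variance filter, F-ranking and normalization bounds from one chunked
      # pass over the training rows; only the selected columns are ever
      # materialized (F ranks are invariant to the per-feature [0,1] map,
      # so ranking on the raw scale is equivalent to ranking after
      # normalization)
      st <- fold_stats(m, y, rows = which(tr))
      varying <- which(st$max > st$min)
      f <- f_from_sums(st)[varying]
      nm <- colnames(m)[varying]
      ord <- order(-f, nm, method = "radix")
      sel <- nm[ord[seq_len(min(k, length(varying)))]]
      si <- match(sel, colnames(m))
      lo <- st$min[si]
      hi <- st$max[si]
      xtr <- scale_min_max(m[tr, si, drop = FALSE], lo, hi)
      xte <- scale_min_max(m[!tr, si, drop = FALSE], lo, hi)
      colnames(xtr) <- colnames(xte) <- sel
    }
    clf <- fit_classifier(xtr, y[tr], algorithm, hyperparams,
                          seed = seed + fo)
    prob <- predict_classifier(clf, xte)
    oof$probability[!tr] <- prob
    cc <- confusion_counts(y[!tr], as.integer(prob >= threshold))
    fold_rows[[fo]] <- bind_cols(
      tibble(fold = fo, n_test = sum(!tr), n_pos_test = sum(y[!tr] == 1),
             auc = auc_score(prob, y[!tr])),
      metrics_from_confusion(cc)
    )
  }
  per_fold <- bind_rows(fold_rows)
  curves <- roc_pr(oof$probability, oof$label)
  structure(
    list(
      per_fold = per_fold,
      scores = oof,
      curves = curves,
      mean_auc = mean(per_fold$auc), sd_auc = sd(per_fold$auc),
      mean_f1 = mean(per_fold$f1), sd_f1 = sd(per_fold$f1),
      pooled_auc = curves$auc,
      config = list(k = k, algorithm = algorithm, folds = folds,
                    seed = seed, threshold = threshold, leaky = leaky)
    ),
    class = "phis_eval"
  )
}

#' @export
print.phis_eval <- function(x, ...) {
  cfg <- x$config
  cat("phis_eval:", cfg$algorithm, "| k =", cfg$k, "|", cfg$folds,
      "stratified folds", if (isTRUE(cfg$leaky)) "(LEAKY protocol)" else "",
      "\n")
  cat(sprintf("  mean AUC %.3f (sd %.3f), mean F1 %.3f (sd %.3f), pooled AUC %.3f\n",
              x$mean_auc, x$sd_auc, x$mean_f1, x$sd_f1, x$pooled_auc))
  invisible(x)
}
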