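# Feature normalization to [0,1], zero-variance filtering, ANOVA F-score
# ranking and top-k selection. Normalization bounds are frozen on the
# training data and reused verbatim (with clipping) at prediction time.

# matrix helpers used both here and inside cross-validation. They avoid
# materializing row-subset copies of wide matrices (30k+ columns), so
# cross-validation never duplicates the full feature matrix.

col_min_max <- function(m, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(m))
  lo <- m[rows[1], ]
  hi <- lo
  for (i in rows[-1]) {
    v <- m[i, ]
    lo <- pmin(lo, v)
    hi <- pmax(hi, v)
  }
  list(min = lo, max = hi)
}

# per-class column sums, sums of squares, and column min/max of m[rows, ],
# computed in row chunks to bound transient memory
fold_stats <- function(m, y, rows = NULL, chunk = 256L) {
  if (is.null(rows)) rows <- seq_len(nrow(m))
  d <- ncol(m)
  s1 <- s0 <- q1 <- q0 <- numeric(d)
  lo <- hi <- NULL
  n1 <- 0L
  for (start in seq(1L, length(rows), by = chunk)) {
    idx <- rows[start:min(start + chunk - 1L, length(rows))]
    sub <- m[idx, , drop = FALSE]
    cls1 <- y[idx] == 1
    n1 <- n1 + sum(cls1)
    if (any(cls1)) {
      b <- sub[cls1, , drop = FALSE]
      s1 <- s1 + colSums(b)
      q1 <- q1 + colSums(b^2)
    }
    if (any(!cls1)) {
      b <- sub[!cls1, , drop = FALSE]
      s0 <- s0 + colSums(b)
      q0 <- q0 + colSums(b^2)
    }
    for (j in seq_len(nrow(sub))) {
      v <- sub[j, ]
      if (is.null(lo)) {
        lo <- v
        hi <- v
      } else {
        lo <- pmin(lo, v)
        hi <- pmax(hi, v)
      }
    }
  }
  list(s1 = s1, s0 = s0, q1 = q1, q0 = q0, n1 = n1, n0 = length(rows) - n1,
       min = lo, max = hi)
}

# F statistics from class-wise sums (same conventions as col_f_scores)
f_from_sums <- function(cs) {
  n <- cs$n1 + cs$n0
  m1 <- cs$s1 / cs$n1
  m0 <- cs$s0 / cs$n0
  gm <- (cs$s1 + cs$s0) / n
  ssa <- cs$n1 * (m1 - gm)^2 + cs$n0 * (m0 - gm)^2
  sse <- pmax((cs$q1 - cs$n1 * m1^2) + (cs$q0 - cs$n0 * m0^2), 0)
  ifelse(sse > 0, ssa / (sse / (n - 2)), ifelse(ssa > 0, Inf, 0))
}

scale_min_max <- function(m, lo, hi, clip = TRUE) {
  rng <- hi - lo
  rng[rng == 0] <- 1 # constant features map to 0
  out <- sweep(sweep(m, 2, lo, "-"), 2, rng, "/")
  out[, hi == lo] <- 0
  if (clip) {
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  out
}

# column-wise two-group ANOVA F statistics; +Inf where the classes separate
# perfectly (SSA > 0, SSE = 0), 0 where both SSA and SSE vanish
col_f_scores <- function(m, y) {
  n <- nrow(m)
  if (n < 3) abort("F-score needs at least 3 samples")
  idx1 <- y == 1
  n1 <- sum(idx1)
  n0 <- n - n1
  if (n1 == 0 || n0 == 0) abort("F-score needs both classes present")
  s1 <- colSums(m[idx1, , drop = FALSE])
  s0 <- colSums(m[!idx1, , drop = FALSE])
  q1 <- colSums(m[idx1, , drop = FALSE]^2)
  q0 <- colSums(m[!idx1, , drop = FALSE]^2)
  m1 <- s1 / n1
  m0 <- s0 / n0
  gm <- (s1 + s0) / n
  ssa <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  sse <- (q1 - n1 * m1^2) + (q0 - n0 * m0^2)
  sse <- pmax(sse, 0) # guard tiny negative rounding
  f <- ifelse(sse > 0, ssa / (sse / (n - 2)),
              ifelse(ssa > 0, Inf, 0))
  f
}

#' Fit per-feature [0,1] normalization bounds
#'
#' Records the minimum and maximum of each feature on the training data.
#' Applying the bounds maps every training value into \[0,1\]; constant
#' features map to 0.
#'
#' @param features Encoded feature tibble (see [encode_segments()]) or
#'   numeric matrix.
#' @return A tibble (class `phis_normalizer`) with columns `feature`, `min`,
#'   `max`.
#' @export
fit_normalizer <- function(features) {
  m <- if (is.matrix(features)) features else feature_matrix(features)
  if (!all(is.finite(m))) {
    bad <- colnames(m)[apply(m, 2, function(x) any(!is.finite(x)))]
    abort(paste0("non-finite values in feature(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  b <- col_min_max(m)
  out <- tibble(feature = colnames(m), min = unname(b$min), max = unname(b$max))
  class(out) <- c("phis_normalizer", class(out))
  out
}

#' Apply fitted normalization bounds
#'
#' Values outside the training bounds (possible at prediction time) are
#' clipped into \[0,1\] by default, keeping the classifier input domain
#' bounded.
#'
#' @param features Feature tibble or matrix; must contain every feature the
#'   bounds know.
#' @param bounds A `phis_normalizer` from [fit_normalizer()].
#' @param clip Clip transformed values into \[0,1\] (default TRUE).
#' @return Object of the same shape as `features` with normalized values.
#' @export
apply_normalizer <- function(features, bounds, clip = TRUE) {
  is_mat <- is.matrix(features)
  m <- if (is_mat) features else feature_matrix(features)
  missing <- setdiff(bounds$feature, colnames(m))
  if (length(missing) > 0) {
    abort(paste0("features missing from input: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  m <- m[, bounds$feature, drop = FALSE]
  out <- scale_min_max(m, bounds$min, bounds$max, clip = clip)
  if (is_mat) return(out)
  meta_cols <- intersect(c("protein_id", "position", "label", "segment"),
                         names(features))
  res <- bind_cols(as_tibble(features[, meta_cols, drop = FALSE]),
                   as_tibble(out, .name_repair = "minimal"))
  attr(res, "window") <- attr(features, "window")
  res
}

#' Drop features with zero training variance
#'
#' @param features Feature tibble or matrix.
#' @return The input without its constant features; the names of the removed
#'   features are in the `dropped` attribute.
#' @export
drop_zero_variance <- function(features) {
  is_mat <- is.matrix(features)
  m <- if (is_mat) features else feature_matrix(features)
  b <- col_min_max(m)
  keep <- b$max > b$min
  if (!any(keep)) abort("all features are constant")
  dropped <- colnames(m)[!keep]
  if (is_mat) {
    out <- m[, keep, drop = FALSE]
  } else {
    out <- features[, !(names(features) %in% dropped), drop = FALSE]
    attr(out, "window") <- attr(features, "window")
  }
  attr(out, "dropped") <- dropped
  out
}

#' ANOVA F-score of one feature
#'
#' The classical one-way two-group ANOVA F statistic
#' \eqn{F = SSA / (SSE / (n - 2))} with
#' \eqn{SSA = \sum_i n_i(\bar X_i - \bar X)^2} (between-class sum of squares)
#' and \eqn{SSE = \sum_i \sum_j (X_{ij} - \bar X_i)^2} (within-class sum of
#' squared deviations from the class mean). Degenerate conventions: a
#' feature with zero within-class spread but separated class means scores
#' `+Inf` (total separation must win); a constant feature scores 0.
#'
#' @param values Numeric vector of per-sample feature values.
#' @param labels Binary labels (0/1, logical, or `pHis`/`nonpHis` factor).
#' @return A single non-negative number (possibly `Inf`).
#' @export
f_score <- function(values, labels) {
  y <- as_binary_labels(labels)
  col_f_scores(matrix(values, ncol = 1), y)[1]
}

#' Score every feature by ANOVA F-score
#'
#' @param features Feature tibble (with a `label` column) or numeric matrix.
#' @param labels Binary labels; taken from `features$label` when omitted.
#' @return A tibble with columns `feature`, `f`, `rank` (1 = best). Ties are
#'   broken by lexicographic feature name, so ranking does not depend on
#'   column order.
#' @export
score_features <- function(features, labels = NULL) {
  m <- if (is.matrix(features)) features else feature_matrix(features)
  if (is.null(labels)) {
    if (is.data.frame(features) && "label" %in% names(features)) {
      labels <- features$label
    } else {
      abort("labels must be supplied (no `label` column found)")
    }
  }
  y <- as_binary_labels(labels)
  f <- col_f_scores(m, y)
  ord <- order(-f, colnames(m), method = "radix")
  rank <- integer(length(f))
  rank[ord] <- seq_along(f)
  tibble(feature = colnames(m), f = unname(f), rank = rank) |>
    arrange(.data$rank)
}

#' Select the top-k features by F-score
#'
#' @inheritParams score_features
#' @param k Number of features to keep (1 <= k <= feature count).
#' @return The score table of [score_features()] with an added logical
#'   `selected` column; the selected feature names, in rank order, are in
#'   the `selected_features` attribute.
#' @export
select_top_k <- function(features, k, labels = NULL) {
  scores <- score_features(features, labels)
  if (k < 1 || k > nrow(scores)) {
    abort(paste0("k must be between 1 and ", nrow(scores)))
  }
  scores$selected <- scores$rank <= k
  attr(scores, "selected_features") <- scores$feature[scores$selected]
  scores
}
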