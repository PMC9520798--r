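# Sequence-analysis procedures: per-position residue enrichment/depletion
# between pHis and non-pHis windows (two-sample-logo style, Welch t-test on
# presence/absence indicators) and pHis <-> nearest non-pHis His distance
# distributions.

#' Positional residue enrichment between pHis and non-pHis windows
#'
#' For every (position offset, residue) cell, the per-sample presence
#' indicator (1 if the window carries that residue at that offset, 0
#' otherwise; windows padded with 'X' at that offset are ignored) is
#' compared between the positive and negative window sets with a Welch
#' two-sample t-test. Cells with `p < alpha` are labeled `enriched`
#' (positive frequency higher) or `depleted`; the center position (always
#' His in both sets, hence a zero-variance indicator) is excluded. No
#' multiple-testing correction is applied by default, matching the
#' two-sample-logo convention of flagging cells at a fixed per-cell alpha;
#' set `bonferroni = TRUE` to divide alpha by the number of tested cells.
#'
#' @param segments Segment tibble with `segment` and `label` columns
#'   ([extract_segments()]), or a character vector of positive windows when
#'   `negative` is given.
#' @param negative Optional character vector of negative windows (used with
#'   a character-vector `segments`).
#' @param alpha Per-cell significance level (default 0.05).
#' @param bonferroni Divide alpha by the number of tested cells
#'   (default FALSE).
#' @return A tibble with one row per tested cell: `offset`, `residue`,
#'   `freq_pos`, `freq_neg`, `n_pos`, `n_neg`, `p_value`, `direction`
#'   (`enriched` / `depleted` / `ns`).
#' @export
positional_enrichment <- function(segments, negative = NULL, alpha = 0.05,
                                  bonferroni = FALSE) {
  if (is.data.frame(segments)) {
    y <- as_binary_labels(segments$label)
    pos <- segments$segment[y == 1]
    neg <- segments$segment[y == 0]
  } else {
    pos <- segments
    neg <- negative
  }
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both window sets must be non-empty")
  }
  wp <- unique(nchar(pos)); wn <- unique(nchar(neg))
  if (length(wp) != 1 || length(wn) != 1 || wp != wn) {
    abort("mismatched window sizes between the two sets")
  }
  W <- wp
  center <- (W + 1L) %/% 2L
  Cp <- seg_codes(pos)
  Cn <- seg_codes(neg)
  offsets <- setdiff(seq_len(W), center)
  aa <- amino_acids()
  rows <- vector("list", length(offsets) * 20L)
  ri <- 0L
  for (j in offsets) {
    vp <- Cp[, j]; vn <- Cn[, j]
    vp <- vp[!is.na(vp)]; vn <- vn[!is.na(vn)]
    n1 <- length(vp); n2 <- length(vn)
    for (a in seq_len(20L)) {
      x1 <- as.numeric(vp == a)
      x2 <- as.numeric(vn == a)
      p1 <- mean(x1); p2 <- mean(x2)
      pv <- welch_p(x1, x2)
      ri <- ri + 1L
      rows[[ri]] <- tibble(
        offset = j - center, residue = aa[a],
        freq_pos = p1, freq_neg = p2, n_pos = n1, n_neg = n2, p_value = pv
      )
    }
  }
  out <- bind_rows(rows)
  cut <- if (bonferroni) alpha / nrow(out) else alpha
  out$direction <- ifelse(
    out$p_value < cut,
    ifelse(out$freq_pos > out$freq_neg, "enriched", "depleted"),
    "ns"
  )
  attr(out, "alpha") <- alpha
  attr(out, "bonferroni") <- bonferroni
  class(out) <- c("phis_enrichment", class(out))
  out
}

# Welch two-sample t-test p-value; degenerate (zero pooled spread or
# too-small groups) -> 1
welch_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) return(1)
  v1 <- var(x1); v2 <- var(x2)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(1)
  tval <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs(tval), df)
}

#' Distance from each pHis site to its nearest non-pHis His
#'
#' For every positive site, the minimum absolute residue-index distance to
#' a histidine of the same protein that is not itself a positive site.
#' Positive sites in proteins containing no other His are skipped and
#' counted.
#'
#' @param sites Site tibble with labels.
#' @param proteins Protein tibble.
#' @param cutoff Distance cutoff for the reported fraction (default 15).
#' @return A `phis_distances` list: `distances` tibble (`protein_id`,
#'   `position`, `distance`), `n_skipped`, `fraction_below`, `cutoff`.
#' @export
nearest_nonphis_distances <- function(sites, proteins, cutoff = 15L) {
  y <- as_binary_labels(sites$label)
  pos_sites <- sites[y == 1, ]
  his <- enumerate_his_sites(proteins)
  pos_key <- paste(pos_sites$protein_id, pos_sites$position)
  his$is_pos <- paste(his$protein_id, his$position) %in% pos_key
  rows <- vector("list", nrow(pos_sites))
  n_skipped <- 0L
  for (i in seq_len(nrow(pos_sites))) {
    pid <- pos_sites$protein_id[i]
    p <- pos_sites$position[i]
    others <- his$position[his$protein_id == pid & !his$is_pos]
    if (length(others) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[i]] <- tibble(protein_id = pid, position = p,
                        distance = min(abs(others - p)))
  }
  distances <- bind_rows(rows)
  fraction_below <- if (nrow(distances) > 0) {
    mean(distances$distance < cutoff)
  } else NA_real_
  structure(
    list(distances = distances, n_skipped = n_skipped,
         fraction_below = fraction_below, cutoff = cutoff),
    class = "phis_distances"
  )
}

#' @export
print.phis_distances <- function(x, ...) {
  cat("phis_distances:", nrow(x$distances), "pHis sites with a non-pHis His",
      paste0("(", x$n_skipped, " skipped)"), "\n")
  cat(sprintf("  fraction of distances < %d: %.3f\n", x$cutoff,
              x$fraction_below))
  invisible(x)
}
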