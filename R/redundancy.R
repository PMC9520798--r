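# Greedy identity-based clustering of equal-length windows, the
# fixed-window analogue of CD-HIT-style redundancy reduction: windows are
# processed most-informative-first (descending non-'X' count, ties broken
# lexicographically) and each joins the first cluster whose representative
# it matches at >= ceiling(threshold * W_valid) aligned positions, where
# W_valid counts positions at which neither window carries 'X'.

#' Reduce near-duplicate windows by greedy identity clustering
#'
#' @param segments Segment tibble ([extract_segments()]) or character
#'   vector of equal-length windows.
#' @param threshold Identity threshold in (0, 1\] (default 0.9).
#' @param keep Which member represents a cluster: `"first"` (the founding
#'   member in canonical processing order).
#' @return The input rows with added `cluster` (integer id) and
#'   `is_representative` columns, in the original input order; the
#'   threshold is stored in the `identity_threshold` attribute.
#' @export
reduce_redundancy <- function(segments, threshold = 0.9, keep = "first") {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  keep <- match.arg(keep, "first")
  if (is.data.frame(segments)) {
    tbl <- as_tibble(segments)
    segs <- tbl$segment
  } else {
    tbl <- tibble(segment = segments)
    segs <- segments
  }
  C <- seg_codes(segs)
  n <- nrow(C)
  valid_count <- rowSums(!is.na(C))
  # canonical processing order: most valid residues first, ties lexicographic
  ord <- order(-valid_count, segs, method = "radix")
  cluster <- integer(n)
  rep_rows <- integer(0) # row indices (in C) of representatives
  for (i in ord) {
    assigned <- FALSE
    if (length(rep_rows) > 0) {
      v <- C[i, ]
      reps <- C[rep_rows, , drop = FALSE]
      eq <- sweep(reps, 2, v, "==")
      both_valid <- !is.na(eq)
      matches <- rowSums(eq & both_valid, na.rm = TRUE)
      w_valid <- rowSums(both_valid)
      need <- ceiling(threshold * w_valid)
      hit <- which(w_valid > 0 & matches >= need)
      if (length(hit) > 0) {
        cluster[i] <- hit[1]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      rep_rows <- c(rep_rows, i)
      cluster[i] <- length(rep_rows)
    }
  }
  tbl$cluster <- cluster
  tbl$is_representative <- seq_len(n) %in% rep_rows
  attr(tbl, "identity_threshold") <- threshold
  tbl
}

#' Pairwise identity of two equal-length windows
#'
#' Fraction of aligned positions with identical residues, counting only
#' positions where neither window carries 'X'; `NA` when no such position
#' exists.
#'
#' @param a,b Window strings of equal length.
#' @return Identity in \[0,1\], or `NA`.
#' @export
segment_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) abort("windows differ in length")
  ok <- ca != "X" & cb != "X"
  if (!any(ok)) return(NA_real_)
  mean(ca[ok] == cb[ok])
}
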