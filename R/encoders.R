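# Feature encoders: 26 families transforming His-centered windows into named
# numeric descriptors. Every encoder is a pure function of the segment string
# and its parameters. The dummy residue 'X' never contributes to a count or a
# sum: n-grams/pairs/triads containing 'X' are excluded from numerators and
# denominators, and order/autocorrelation statistics run over the compacted
# valid-residue subsequence.

#' The 26 encoder families, in canonical order
#'
#' Canonical order follows the standard descriptor-suite grouping
#' (composition, grouped composition, C/T/D, conjoint triads,
#' quasi-sequence-order, pseudo amino acid composition, autocorrelation,
#' then the positional expansions); feature columns of
#' [encode_segments()] always appear in this family order.
#'
#' @return Character vector of 26 family names.
#' @export
encoder_families <- function() {
  c("AAC", "EAAC", "CKSAAP", "DPC", "TPC",
    "GAAC", "EGAAC", "CKSAAGP", "GDPC", "GTPC",
    "CTDC", "CTDD", "CTDT",
    "CTriad", "KSCTriad",
    "SOCNumber", "QSOrder",
    "PAAC", "APAAC",
    "NMBroto", "Moran", "Geary",
    "Binary", "AAIndex", "BLOSUM62", "ZScale")
}

#' Default encoder parameters
#'
#' Sub-window size 5 for EAAC/EGAAC, maximum gap 5 for CKSAAP/CKSAAGP, 1 for
#' the k-spaced conjoint triads, lag 5 for the sequence-order and
#' autocorrelation families, lambda 5 and weight 0.05 for PAAC/APAAC, weight
#' 0.1 for the quasi-sequence-order descriptors. All overridable via the
#' `params` argument of the encoding functions.
#'
#' @param family Encoder family name.
#' @return Named list of the family's parameters (possibly empty).
#' @export
default_encoder_params <- function(family) {
  switch(family,
    EAAC = , EGAAC = list(sub_window = 5L),
    CKSAAP = , CKSAAGP = list(k_max = 5L),
    KSCTriad = list(k_max = 1L),
    SOCNumber = , NMBroto = , Moran = , Geary = list(n_lag = 5L),
    QSOrder = list(n_lag = 5L, weight = 0.1),
    PAAC = , APAAC = list(lambda = 5L, weight = 0.05),
    list()
  )
}

merge_params <- function(family, params = list()) {
  out <- default_encoder_params(family)
  for (nm in names(params)) out[[nm]] <- params[[nm]]
  out
}

#' Declared dimensionality of an encoder family
#'
#' @param family Family name.
#' @param window Window size.
#' @param params Optional parameter overrides.
#' @return Integer feature count.
#' @export
encoder_dim <- function(family, window, params = list()) {
  p <- merge_params(family, params)
  W <- as.integer(window)
  switch(family,
    AAC = 20L,
    EAAC = (W - p$sub_window + 1L) * 20L,
    CKSAAP = 400L * (p$k_max + 1L),
    DPC = 400L,
    TPC = 8000L,
    GAAC = 5L,
    EGAAC = (W - p$sub_window + 1L) * 5L,
    CKSAAGP = 25L * (p$k_max + 1L),
    GDPC = 25L,
    GTPC = 125L,
    CTDC = 21L,
    CTDD = 105L,
    CTDT = 21L,
    CTriad = 343L,
    KSCTriad = 343L * (p$k_max + 1L),
    SOCNumber = 2L * p$n_lag,
    QSOrder = 2L * (20L + p$n_lag),
    PAAC = 20L + p$lambda,
    APAAC = 20L + 2L * p$lambda,
    NMBroto = , Moran = , Geary = 8L * p$n_lag,
    Binary = 20L * W,
    AAIndex = nrow(aaindex_table()) * W,
    BLOSUM62 = 20L * W,
    ZScale = 5L * W,
    abort(paste0("unknown encoder family: ", family))
  )
}

# ---- internal representation ------------------------------------------------

# segments -> integer code matrix (n x W), codes 1..20 in amino_acids() order,
# NA for the dummy residue 'X'
seg_codes <- function(segments) {
  w <- unique(nchar(segments))
  if (length(w) != 1) abort("segments have mixed window sizes")
  chars <- matrix(unlist(strsplit(segments, ""), use.names = FALSE),
                  nrow = length(segments), ncol = w, byrow = TRUE)
  codes <- match(chars, amino_acids())
  bad <- is.na(codes) & chars != "X"
  if (any(bad)) abort(paste0("invalid residue character(s): ",
                             paste(unique(chars[bad]), collapse = ", ")))
  matrix(codes, nrow = length(segments), ncol = w)
}

group_code_map <- function() {
  grp <- integer(20)
  groups <- residue_groups()
  for (i in seq_along(groups)) grp[match(groups[[i]], amino_acids())] <- i
  grp
}

conjoint_code_map <- function() {
  cl <- integer(20)
  classes <- conjoint_classes()
  for (i in seq_along(classes)) cl[match(classes[[i]], amino_acids())] <- i
  cl
}

signed_pos <- function(W) sprintf("pos%+d", seq_len(W) - (W + 1L) %/% 2L)

# count fixed-span n-grams per row. `offsets` are 0-based column offsets of
# the n-gram members (e.g. c(0, 2) = pair with one gap); `base` is the
# alphabet size of `C`'s codes. Returns relative frequencies over the valid
# (NA-free) n-grams of each row; rows with no valid n-gram are all zero.
ngram_freq <- function(C, offsets, base) {
  W <- ncol(C); n <- nrow(C)
  span <- max(offsets)
  nbins <- base^length(offsets)
  if (W <= span) {
    warn(paste0("segment shorter than required n-gram span (", span + 1,
                "); zero block emitted"))
    return(matrix(0, n, nbins))
  }
  starts <- seq_len(W - span)
  idx <- matrix(0L, n, length(starts))
  for (t in seq_along(offsets)) {
    idx <- idx * base + (C[, starts + offsets[t], drop = FALSE] - 1L)
  }
  idx <- idx + 1L
  out <- matrix(0, n, nbins)
  for (i in seq_len(n)) {
    v <- idx[i, ]
    v <- v[!is.na(v)]
    if (length(v) > 0) out[i, ] <- tabulate(v, nbins) / length(v)
  }
  out
}

ngram_names <- function(letters_vec, k) {
  grids <- rev(rep(list(letters_vec), k))
  g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste0, collapse = "")
}

# ---- family implementations (codes matrix -> named feature matrix) ---------

.enc_AAC <- function(C, p) {
  out <- ngram_freq(C, 0L, 20L)
  colnames(out) <- paste0("AAC:", amino_acids())
  out
}

.enc_DPC <- function(C, p) {
  out <- ngram_freq(C, c(0L, 1L), 20L)
  colnames(out) <- paste0("DPC:", ngram_names(amino_acids(), 2))
  out
}

.enc_TPC <- function(C, p) {
  out <- ngram_freq(C, c(0L, 1L, 2L), 20L)
  colnames(out) <- paste0("TPC:", ngram_names(amino_acids(), 3))
  out
}

.enc_CKSAAP <- function(C, p, prefix = "CKSAAP", base = 20L,
                        letters_vec = amino_acids()) {
  blocks <- lapply(0:p$k_max, function(k) {
    b <- ngram_freq(C, c(0L, k + 1L), base)
    colnames(b) <- paste0(prefix, ":", ngram_names(letters_vec, 2), ":gap", k)
    b
  })
  do.call(cbind, blocks)
}

.enc_EAAC <- function(C, p, prefix = "EAAC", base = 20L,
                      letters_vec = amino_acids()) {
  W <- ncol(C); n <- nrow(C); s <- p$sub_window
  if (s > W) abort("sub_window larger than the segment window")
  blocks <- lapply(seq_len(W - s + 1L), function(j) {
    sub <- C[, j:(j + s - 1L), drop = FALSE]
    cnt <- matrix(0, n, base)
    for (a in seq_len(base)) cnt[, a] <- rowSums(sub == a, na.rm = TRUE)
    valid <- rowSums(!is.na(sub))
    freq <- cnt / ifelse(valid == 0, 1, valid)
    colnames(freq) <- paste0(prefix, ":win", j, ":", letters_vec)
    freq
  })
  do.call(cbind, blocks)
}

.enc_GAAC <- function(C, p) {
  G <- group_recode(C)
  out <- ngram_freq(G, 0L, 5L)
  colnames(out) <- paste0("GAAC:", names(residue_groups()))
  out
}

.enc_GDPC <- function(C, p) {
  G <- group_recode(C)
  out <- ngram_freq(G, c(0L, 1L), 5L)
  colnames(out) <- paste0("GDPC:", ngram_names2(names(residue_groups()), 2))
  out
}

.enc_GTPC <- function(C, p) {
  G <- group_recode(C)
  out <- ngram_freq(G, c(0L, 1L, 2L), 5L)
  colnames(out) <- paste0("GTPC:", ngram_names2(names(residue_groups()), 3))
  out
}

.enc_EGAAC <- function(C, p) {
  .enc_EAAC(group_recode(C), p, prefix = "EGAAC", base = 5L,
            letters_vec = names(residue_groups()))
}

.enc_CKSAAGP <- function(C, p) {
  G <- group_recode(C)
  blocks <- lapply(0:p$k_max, function(k) {
    b <- ngram_freq(G, c(0L, k + 1L), 5L)
    colnames(b) <- paste0("CKSAAGP:", ngram_names2(names(residue_groups()), 2),
                          ":gap", k)
    b
  })
  do.call(cbind, blocks)
}

group_recode <- function(C) {
  grp <- group_code_map()
  G <- C
  ok <- !is.na(C)
  G[ok] <- grp[C[ok]]
  G
}

# dotted multi-letter n-gram names, e.g. "aliphatic.aromatic"
ngram_names2 <- function(letters_vec, k) {
  grids <- rev(rep(list(letters_vec), k))
  g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = ".")
}

.enc_CTriad <- function(C, p) {
  cl <- conjoint_recode(C)
  out <- ngram_freq(cl, c(0L, 1L, 2L), 7L)
  colnames(out) <- paste0("CTriad:", ngram_names(as.character(1:7), 3))
  out
}

.enc_KSCTriad <- function(C, p) {
  cl <- conjoint_recode(C)
  blocks <- lapply(0:p$k_max, function(k) {
    b <- ngram_freq(cl, c(0L, k + 1L, 2L * (k + 1L)), 7L)
    colnames(b) <- paste0("KSCTriad:", ngram_names(as.character(1:7), 3),
                          ":gap", k)
    b
  })
  do.call(cbind, blocks)
}

conjoint_recode <- function(C) {
  cl <- conjoint_code_map()
  G <- C
  ok <- !is.na(C)
  G[ok] <- cl[C[ok]]
  G
}

.enc_CTD <- function(C, which = c("C", "T", "D")) {
  which <- match.arg(which)
  attrs <- ctd_attributes()
  n <- nrow(C)
  blocks <- vector("list", length(attrs))
  for (ai in seq_along(attrs)) {
    cls_map <- integer(20)
    for (g in 1:3) cls_map[match(attrs[[ai]][[g]], amino_acids())] <- g
    M <- C
    ok <- !is.na(C)
    M[ok] <- cls_map[C[ok]]
    if (which == "C") {
      b <- matrix(0, n, 3)
      valid <- rowSums(ok)
      for (g in 1:3) b[, g] <- rowSums(M == g, na.rm = TRUE)
      b <- b / ifelse(valid == 0, 1, valid)
      colnames(b) <- paste0("CTDC:", names(attrs)[ai], ":g", 1:3)
    } else if (which == "T") {
      b <- matrix(0, n, 3)
      for (i in seq_len(n)) {
        v <- M[i, ]; v <- v[!is.na(v)]
        if (length(v) < 2) next
        a <- v[-length(v)]; bb <- v[-1]
        pair <- pmin(a, bb) * 10 + pmax(a, bb)
        b[i, ] <- c(sum(pair == 12), sum(pair == 13), sum(pair == 23)) /
          (length(v) - 1)
      }
      colnames(b) <- paste0("CTDT:", names(attrs)[ai],
                            ":", c("g1g2", "g1g3", "g2g3"))
    } else {
      b <- matrix(0, n, 15)
      qs <- c(0, 0.25, 0.5, 0.75, 1)
      for (i in seq_len(n)) {
        v <- M[i, ]; v <- v[!is.na(v)]
        N <- length(v)
        if (N == 0) next
        for (g in 1:3) {
          idx <- which(v == g)
          m <- length(idx)
          if (m == 0) next
          ranks <- pmax(1L, ceiling(qs * m))
          ranks[1] <- 1L
          b[i, (g - 1) * 5 + (1:5)] <- idx[ranks] / N * 100
        }
      }
      colnames(b) <- paste0("CTDD:", names(attrs)[ai], ":",
                            rep(paste0("g", 1:3), each = 5), ":p",
                            rep(c(0, 25, 50, 75, 100), 3))
    }
    blocks[[ai]] <- b
  }
  do.call(cbind, blocks)
}

.enc_CTDC <- function(C, p) .enc_CTD(C, "C")
.enc_CTDT <- function(C, p) .enc_CTD(C, "T")
.enc_CTDD <- function(C, p) .enc_CTD(C, "D")

# compacted valid-residue code sequences, one per segment
compact_rows <- function(C) {
  lapply(seq_len(nrow(C)), function(i) {
    v <- C[i, ]
    v[!is.na(v)]
  })
}

check_lag <- function(rows, lag, what) {
  min_len <- min(lengths(rows))
  if (lag >= min_len) {
    abort(paste0(what, " (", lag, ") must be smaller than the shortest ",
                 "valid-residue count (", min_len, "); lower the parameter"))
  }
}

.enc_SOCNumber <- function(C, p) {
  rows <- compact_rows(C)
  check_lag(rows, p$n_lag, "n_lag")
  mats <- list(physchem = physchem_distance(), grantham = grantham_distance())
  out <- matrix(0, nrow(C), 2L * p$n_lag)
  cn <- character(0)
  col <- 0L
  for (mn in names(mats)) {
    D2 <- mats[[mn]]^2
    for (d in seq_len(p$n_lag)) {
      col <- col + 1L
      cn <- c(cn, paste0("SOCNumber:", mn, ":lag", d))
      out[, col] <- vapply(rows, function(v) {
        N <- length(v)
        sum(D2[cbind(v[1:(N - d)], v[(1 + d):N])])
      }, numeric(1))
    }
  }
  colnames(out) <- cn
  out
}

.enc_QSOrder <- function(C, p) {
  rows <- compact_rows(C)
  check_lag(rows, p$n_lag, "n_lag")
  mats <- list(physchem = physchem_distance(), grantham = grantham_distance())
  n <- nrow(C)
  blocks <- lapply(names(mats), function(mn) {
    D2 <- mats[[mn]]^2
    b <- matrix(0, n, 20L + p$n_lag)
    for (i in seq_len(n)) {
      v <- rows[[i]]
      N <- length(v)
      f <- tabulate(v, 20L) / N
      tau <- vapply(seq_len(p$n_lag), function(d) {
        sum(D2[cbind(v[1:(N - d)], v[(1 + d):N])])
      }, numeric(1))
      denom <- 1 + p$weight * sum(tau)
      b[i, ] <- c(f / denom, p$weight * tau / denom)
    }
    colnames(b) <- paste0("QSOrder:", mn, ":",
                          c(amino_acids(), paste0("lag", seq_len(p$n_lag))))
    b
  })
  do.call(cbind, blocks)
}

.enc_PAAC <- function(C, p) {
  rows <- compact_rows(C)
  if (p$lambda > 0) check_lag(rows, p$lambda, "lambda")
  sc <- paac_scales()
  n <- nrow(C)
  out <- matrix(0, n, 20L + p$lambda)
  for (i in seq_len(n)) {
    v <- rows[[i]]
    N <- length(v)
    f <- tabulate(v, 20L) / N
    theta <- numeric(p$lambda)
    if (p$lambda > 0) {
      for (d in seq_len(p$lambda)) {
        a <- v[1:(N - d)]; b <- v[(1 + d):N]
        # Theta = mean over the three scales of squared property differences
        theta[d] <- mean((sc[, a] - sc[, b])^2)
      }
    }
    denom <- 1 + p$weight * sum(theta)
    out[i, ] <- c(f / denom, p$weight * theta / denom)
  }
  colnames(out) <- paste0("PAAC:", c(amino_acids(),
                                     if (p$lambda > 0) paste0("lambda", seq_len(p$lambda))))
  out
}

.enc_APAAC <- function(C, p) {
  rows <- compact_rows(C)
  if (p$lambda > 0) check_lag(rows, p$lambda, "lambda")
  sc <- paac_scales()[c("hydrophobicity", "hydrophilicity"), , drop = FALSE]
  n <- nrow(C)
  out <- matrix(0, n, 20L + 2L * p$lambda)
  for (i in seq_len(n)) {
    v <- rows[[i]]
    N <- length(v)
    f <- tabulate(v, 20L) / N
    tau <- numeric(2L * p$lambda)
    for (d in seq_len(p$lambda)) {
      a <- v[1:(N - d)]; b <- v[(1 + d):N]
      tau[2 * d - 1] <- mean(sc[1, a] * sc[1, b])
      tau[2 * d] <- mean(sc[2, a] * sc[2, b])
    }
    denom <- 1 + p$weight * sum(tau)
    out[i, ] <- c(f / denom, p$weight * tau / denom)
  }
  lam_names <- as.vector(t(outer(seq_len(p$lambda), c("hb", "hl"),
                                 function(d, s) paste0("lam", d, ".", s))))
  colnames(out) <- paste0("APAAC:", c(amino_acids(), lam_names))
  out
}

.enc_autocorr <- function(C, p, family) {
  rows <- compact_rows(C)
  check_lag(rows, p$n_lag, "n_lag")
  sc <- autocorrelation_scales()
  n <- nrow(C)
  out <- matrix(0, n, nrow(sc) * p$n_lag)
  cn <- character(ncol(out))
  col <- 0L
  for (pi in seq_len(nrow(sc))) {
    P <- sc[pi, ]
    for (d in seq_len(p$n_lag)) {
      col <- col + 1L
      cn[col] <- paste0(family, ":", rownames(sc)[pi], ":lag", d)
      out[, col] <- vapply(rows, function(v) {
        N <- length(v)
        x <- P[v]
        xb <- mean(x)
        if (family == "NMBroto") {
          sum(x[1:(N - d)] * x[(1 + d):N]) / (N - d)
        } else if (family == "Moran") {
          v2 <- mean((x - xb)^2)
          if (v2 == 0) 0 else
            (sum((x[1:(N - d)] - xb) * (x[(1 + d):N] - xb)) / (N - d)) / v2
        } else { # Geary
          v2 <- sum((x - xb)^2) / (N - 1)
          if (v2 == 0) 0 else
            (sum((x[1:(N - d)] - x[(1 + d):N])^2) / (2 * (N - d))) / v2
        }
      }, numeric(1))
    }
  }
  colnames(out) <- cn
  out
}

.enc_NMBroto <- function(C, p) .enc_autocorr(C, p, "NMBroto")
.enc_Moran <- function(C, p) .enc_autocorr(C, p, "Moran")
.enc_Geary <- function(C, p) .enc_autocorr(C, p, "Geary")

# positional expansion of a residues x properties value matrix; 'X' -> 0
positional_expand <- function(C, vals, prefix, prop_names) {
  n <- nrow(C); W <- ncol(C); np <- ncol(vals)
  out <- matrix(0, n, W * np)
  pos_names <- signed_pos(W)
  cn <- character(W * np)
  for (j in seq_len(W)) {
    idx <- C[, j]
    ok <- !is.na(idx)
    cols <- (j - 1L) * np + seq_len(np)
    if (any(ok)) out[ok, cols] <- vals[idx[ok], , drop = FALSE]
    cn[cols] <- paste0(prefix, ":", pos_names[j], ":", prop_names)
  }
  colnames(out) <- cn
  out
}

.enc_Binary <- function(C, p) {
  positional_expand(C, diag(20L), "Binary", amino_acids())
}

.enc_AAIndex <- function(C, p) {
  tab <- t(aaindex_table()) # residues x properties
  positional_expand(C, tab, "AAIndex", colnames(tab))
}

.enc_BLOSUM62 <- function(C, p) {
  positional_expand(C, blosum62_matrix(), "BLOSUM62", amino_acids())
}

.enc_ZScale <- function(C, p) {
  positional_expand(C, zscales(), "ZScale", paste0("z", 1:5))
}

# ---- public surface ---------------------------------------------------------

#' Encode segments with one encoder family
#'
#' @param segments Character vector of equal-length segments, or a segment
#'   tibble from [extract_segments()].
#' @param family One of [encoder_families()].
#' @param params Named list of parameter overrides
#'   (see [default_encoder_params()]).
#' @return Numeric matrix, one row per segment, with stable
#'   `family:descriptor` column names.
#' @export
encode_family <- function(segments, family, params = list()) {
  if (is.data.frame(segments)) segments <- segments$segment
  if (!family %in% encoder_families()) {
    abort(paste0("unknown encoder family: ", family))
  }
  C <- seg_codes(segments)
  p <- merge_params(family, params)
  fn <- get(paste0(".enc_", family), mode = "function")
  out <- fn(C, p)
  stopifnot(ncol(out) == encoder_dim(family, ncol(C), params))
  out
}

#' Encode segments with a set of encoder families
#'
#' Columns are the concatenation of the family blocks in canonical
#' [encoder_families()] order; feature names are stable
#' `family:descriptor[:position|:gap]` identifiers, so a feature keeps its
#' identity across runs, selections and model bundles.
#'
#' @param segments Segment tibble from [extract_segments()] (columns
#'   `protein_id`, `position`, optionally `label`, and `segment`), or a bare
#'   character vector of equal-length segments.
#' @param families Character vector of families to apply (default: all 26).
#' @param params Named list of per-family parameter overrides, e.g.
#'   `list(CKSAAP = list(k_max = 3))`.
#' @param feature_subset Optional character vector of feature names: only the
#'   families contributing at least one of these features are computed and
#'   only those columns (in `feature_subset` order) are returned. Used to
#'   make prediction with a fitted bundle cheap.
#' @return A tibble: metadata columns (`protein_id`, `position`, `label`,
#'   when present in the input) followed by one numeric column per feature.
#'   The window size is recorded in the `window` attribute.
#' @export
encode_segments <- function(segments, families = encoder_families(),
                            params = list(), feature_subset = NULL) {
  meta <- NULL
  if (is.data.frame(segments)) {
    keep <- intersect(c("protein_id", "position", "label"), names(segments))
    meta <- as_tibble(segments[, keep, drop = FALSE])
    segments <- segments$segment
  }
  mat <- encode_matrix(segments, families, params, feature_subset)
  out <- bind_cols(
    if (!is.null(meta)) meta else tibble(.rows = nrow(mat)),
    as_tibble(mat, .name_repair = "minimal")
  )
  attr(out, "window") <- unique(nchar(segments))
  attr(out, "feature_names") <- colnames(mat)
  out
}

# matrix-only encoding backend (used internally where the metadata tibble
# would just duplicate a wide matrix in memory)
encode_matrix <- function(segments, families = encoder_families(),
                          params = list(), feature_subset = NULL) {
  bad <- setdiff(families, encoder_families())
  if (length(bad) > 0) abort(paste0("unknown encoder families: ",
                                    paste(bad, collapse = ", ")))
  families <- intersect(encoder_families(), families) # canonical order
  if (!is.null(feature_subset)) {
    fam_of <- sub(":.*$", "", feature_subset)
    families <- intersect(families, unique(fam_of))
  }
  C <- seg_codes(segments)
  blocks <- lapply(families, function(fam) {
    p <- merge_params(fam, params[[fam]] %||% list())
    fn <- get(paste0(".enc_", fam), mode = "function")
    fn(C, p)
  })
  mat <- do.call(cbind, blocks)
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, colnames(mat))
    if (length(missing) > 0) {
      abort(paste0("unknown feature name(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    mat <- mat[, feature_subset, drop = FALSE]
  }
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature columns of an encoded tibble
#'
#' @param features Tibble from [encode_segments()] (or any tibble whose
#'   non-metadata columns are features).
#' @return Character vector of feature column names.
#' @export
feature_names <- function(features) {
  setdiff(names(features), c("protein_id", "position", "label", "segment"))
}

#' Extract the numeric feature matrix from an encoded tibble
#'
#' @param features Tibble from [encode_segments()].
#' @return Numeric matrix (samples x features) with feature column names.
#' @export
feature_matrix <- function(features) {
  fn <- feature_names(features)
  m <- as.matrix(features[, fn, drop = FALSE])
  storage.mode(m) <- "double"
  m
}
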