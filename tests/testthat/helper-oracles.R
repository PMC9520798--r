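# Shared fixtures and independent brute-force oracles. The oracles work on
# the raw segment strings (substring / paste / table), a deliberately
# different route from the integer-code matrices the encoders use.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

# random His-centered segments, optionally with terminal 'X' padding as
# produced by window extraction near protein ends
random_segments <- function(n, window, seed, pad_prob = 0.3) {
  flank <- (window - 1) %/% 2
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      ch <- sample(aa20, window, replace = TRUE)
      ch[flank + 1] <- "H"
      if (runif(1) < pad_prob) {
        npad <- sample.int(flank, 1)
        side <- sample(c("l", "r"), 1)
        if (side == "l") ch[seq_len(npad)] <- "X"
        else ch[window - seq_len(npad) + 1] <- "X"
      }
      paste(ch, collapse = "")
    }, character(1))
  })
}

# list of valid (X-free) spaced grams of a segment; offsets are 0-based
oracle_grams <- function(seg, offsets, map = identity, sep = "") {
  ch <- strsplit(seg, "")[[1]]
  span <- max(offsets)
  out <- character(0)
  for (i in seq_len(max(0, length(ch) - span))) {
    g <- ch[i + offsets]
    if (any(g == "X")) next
    out <- c(out, paste(map(g), collapse = sep))
  }
  out
}

# named relative frequencies over a closed descriptor universe
oracle_freq <- function(grams, universe) {
  v <- setNames(numeric(length(universe)), universe)
  if (length(grams) > 0) {
    tb <- table(grams) / length(grams)
    v[names(tb)] <- as.numeric(tb)
  }
  v
}

group_of <- function(ch) {
  gs <- residue_groups()
  vapply(ch, function(a) names(gs)[vapply(gs, function(g) a %in% g, logical(1))],
         character(1), USE.NAMES = FALSE)
}

conjoint_of <- function(ch) {
  cc <- conjoint_classes()
  vapply(ch, function(a) as.character(which(vapply(cc, function(g) a %in% g,
                                                   logical(1)))),
         character(1), USE.NAMES = FALSE)
}

# two-class Gaussian toy data with specified standardized mean shift
separable_data <- function(n, d, dprime, seed) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * d), n, d)
    x[y == 1, 1] <- x[y == 1, 1] + dprime
    colnames(x) <- sprintf("f%03d", seq_len(d))
    list(x = x, y = y)
  })
}

expect_all_equal <- function(actual, expected, tol = 1e-9) {
  expect_true(max(abs(actual - expected)) < tol)
}
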