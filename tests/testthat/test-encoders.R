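# Counting encoders are checked against string-level brute-force oracles;
# order/autocorrelation encoders against direct implementations of their
# published formulas; positional encoders against the bundled tables.

test_that("simple composition examples are exact", {
  expect_equal(unname(encode_family("HHHHH", "AAC")[1, "AAC:H"]), 1.0)
  expect_equal(sum(encode_family("HHHHH", "AAC")), 1.0)
  v <- encode_family("AHA", "CKSAAP", params = list(k_max = 1))
  expect_equal(unname(v[1, "CKSAAP:AA:gap1"]), 1.0)
  expect_equal(sum(v[1, grepl(":gap1$", colnames(v))]), 1.0)
  g <- encode_family("KRHKRH", "GAAC")
  expect_equal(unname(g[1, "GAAC:positive"]), 1.0)
  tri <- encode_family("CCC", "CTriad")
  expect_equal(unname(tri[1, "CTriad:777"]), 1.0)
  expect_equal(sum(tri), 1.0)
})

test_that("counting encoders match brute-force n-gram/pair/triad oracles", {
  segs <- unlist(lapply(c(21L, 31L), function(w)
    random_segments(15, w, seed = 100 + w)))
  for (seg in segs) {
    aac <- encode_family(seg, "AAC")[1, ]
    expect_all_equal(
      unname(aac),
      unname(oracle_freq(oracle_grams(seg, 0), aa20)[sub("^AAC:", "", names(aac))])
    )
    dpc <- encode_family(seg, "DPC")[1, ]
    exp_dpc <- oracle_freq(oracle_grams(seg, 0:1),
                           sub("^DPC:", "", names(dpc)))
    expect_all_equal(unname(dpc), unname(exp_dpc))
    ck <- encode_family(seg, "CKSAAP", params = list(k_max = 3))[1, ]
    for (k in 0:3) {
      blk <- ck[grepl(paste0(":gap", k, "$"), names(ck))]
      uni <- sub(paste0(":gap", k, "$"), "", sub("^CKSAAP:", "", names(blk)))
      exp_blk <- oracle_freq(oracle_grams(seg, c(0, k + 1)), uni)
      expect_all_equal(unname(blk), unname(exp_blk))
    }
    gd <- encode_family(seg, "GDPC")[1, ]
    exp_gd <- oracle_freq(oracle_grams(seg, 0:1, map = group_of, sep = "."),
                          sub("^GDPC:", "", names(gd)))
    expect_all_equal(unname(gd), unname(exp_gd))
    kst <- encode_family(seg, "KSCTriad")[1, ]
    for (k in 0:1) {
      blk <- kst[grepl(paste0(":gap", k, "$"), names(kst))]
      uni <- sub(paste0(":gap", k, "$"), "", sub("^KSCTriad:", "", names(blk)))
      exp_blk <- oracle_freq(
        oracle_grams(seg, c(0, k + 1, 2 * (k + 1)), map = conjoint_of), uni
      )
      expect_all_equal(unname(blk), unname(exp_blk))
    }
  }
})

test_that("sliding-window composition (EAAC) matches a windowed oracle", {
  segs <- random_segments(10, 21, seed = 7)
  enc <- encode_family(segs, "EAAC")
  for (i in seq_along(segs)) {
    ch <- strsplit(segs[i], "")[[1]]
    for (j in 1:17) {
      win <- ch[j:(j + 4)]
      valid <- sum(win != "X")
      for (a in c("A", "H", "G")) {
        expected <- if (valid == 0) 0 else sum(win == a) / valid
        expect_equal(unname(enc[i, paste0("EAAC:win", j, ":", a)]), expected)
      }
    }
  }
})

test_that("composition blocks sum to one on X-free segments", {
  segs <- random_segments(30, 31, seed = 3, pad_prob = 0)
  sum_blocks <- list(
    AAC = "^AAC:", DPC = "^DPC:", TPC = "^TPC:", GAAC = "^GAAC:",
    GDPC = "^GDPC:", GTPC = "^GTPC:", CTriad = "^CTriad:"
  )
  for (fam in names(sum_blocks)) {
    m <- encode_family(segs, fam)
    expect_all_equal(rowSums(m), rep(1, nrow(m)))
  }
  ck <- encode_family(segs, "CKSAAP")
  for (k in 0:5) {
    expect_all_equal(rowSums(ck[, grepl(paste0(":gap", k, "$"), colnames(ck))]),
                     rep(1, nrow(ck)))
  }
  ctdc <- encode_family(segs, "CTDC")
  for (at in names(ctd_attributes())) {
    expect_all_equal(rowSums(ctdc[, grepl(paste0("^CTDC:", at, ":"), colnames(ctdc))]),
                     rep(1, nrow(ctdc)))
  }
})

test_that("C/T/D descriptors match direct index-scan oracles", {
  # all residues in one class -> zero transitions for that attribute
  m <- encode_family("KKKKK", "CTDT")
  expect_all_equal(m[1, grepl("^CTDT:charge:", colnames(m))], c(0, 0, 0))
  segs <- random_segments(12, 21, seed = 9)
  ctdd <- encode_family(segs, "CTDD")
  ctdt <- encode_family(segs, "CTDT")
  attrs <- ctd_attributes()
  for (i in seq_along(segs)) {
    ch <- strsplit(segs[i], "")[[1]]
    ch <- ch[ch != "X"]
    N <- length(ch)
    for (at in names(attrs)) {
      cls <- vapply(ch, function(a)
        which(vapply(attrs[[at]], function(g) a %in% g, logical(1))),
        integer(1), USE.NAMES = FALSE)
      # transitions (unordered distinct-class adjacent pairs) / (N - 1)
      pr <- cbind(cls[-N], cls[-1])
      expected_t <- c(
        sum((pr[, 1] == 1 & pr[, 2] == 2) | (pr[, 1] == 2 & pr[, 2] == 1)),
        sum((pr[, 1] == 1 & pr[, 2] == 3) | (pr[, 1] == 3 & pr[, 2] == 1)),
        sum((pr[, 1] == 2 & pr[, 2] == 3) | (pr[, 1] == 3 & pr[, 2] == 2))
      ) / (N - 1)
      expect_all_equal(ctdt[i, paste0("CTDT:", at, ":", c("g1g2", "g1g3", "g2g3"))],
                       expected_t)
      for (g in 1:3) {
        idx <- which(cls == g)
        expected_d <- if (length(idx) == 0) rep(0, 5) else {
          ranks <- pmax(1, ceiling(c(0, 0.25, 0.5, 0.75, 1) * length(idx)))
          idx[ranks] / N * 100
        }
        expect_all_equal(
          ctdd[i, paste0("CTDD:", at, ":g", g, ":p", c(0, 25, 50, 75, 100))],
          expected_d
        )
      }
    }
  }
})

test_that("sequence-order encoders match direct formula oracles", {
  # homopolymer: zero self-distance -> all coupling numbers zero
  soc <- encode_family("AAAAAAAA", "SOCNumber", params = list(n_lag = 3))
  expect_all_equal(soc[1, ], rep(0, 6))
  # PAAC with lambda = 0 reduces to plain AAC
  segs <- random_segments(8, 21, seed = 13)
  paac0 <- encode_family(segs, "PAAC", params = list(lambda = 0))
  aac <- encode_family(segs, "AAC")
  expect_all_equal(as.numeric(paac0), as.numeric(aac))
  # QSOrder against an independent implementation of the quasi-sequence-order
  # formulas (relative frequencies, tau from squared distance-matrix entries)
  qso <- encode_family(segs, "QSOrder", params = list(n_lag = 4))
  mats <- list(physchem = physchem_distance(), grantham = grantham_distance())
  w <- 0.1
  for (i in seq_along(segs)) {
    ch <- strsplit(segs[i], "")[[1]]
    ch <- ch[ch != "X"]
    N <- length(ch)
    for (mn in names(mats)) {
      D <- mats[[mn]]
      tau <- vapply(1:4, function(d)
        sum(vapply(1:(N - d), function(j) D[ch[j], ch[j + d]]^2, numeric(1))),
        numeric(1))
      f <- vapply(aa20, function(a) mean(ch == a), numeric(1))
      denom <- 1 + w * sum(tau)
      expect_all_equal(qso[i, paste0("QSOrder:", mn, ":", aa20)], f / denom)
      expect_all_equal(qso[i, paste0("QSOrder:", mn, ":lag", 1:4)],
                       w * tau / denom)
    }
  }
})

test_that("autocorrelation encoders match loop oracles; homopolymers give 0", {
  mg <- encode_family("LLLLLLLL", "Moran", params = list(n_lag = 2))
  expect_all_equal(mg[1, ], rep(0, 16))
  gg <- encode_family("LLLLLLLL", "Geary", params = list(n_lag = 2))
  expect_all_equal(gg[1, ], rep(0, 16))
  nb <- encode_family("AC", "NMBroto", params = list(n_lag = 1))
  sc <- autocorrelation_scales()
  expect_all_equal(nb[1, ], sc[, "A"] * sc[, "C"])
  segs <- random_segments(8, 21, seed = 17)
  for (fam in c("NMBroto", "Moran", "Geary")) {
    enc <- encode_family(segs, fam, params = list(n_lag = 3))
    for (i in seq_along(segs)) {
      ch <- strsplit(segs[i], "")[[1]]
      ch <- ch[ch != "X"]
      N <- length(ch)
      for (pi in rownames(sc)) {
        x <- sc[pi, ch]
        for (d in 1:3) {
          expected <- if (fam == "NMBroto") {
            sum(x[1:(N - d)] * x[(1 + d):N]) / (N - d)
          } else if (fam == "Moran") {
            num <- sum((x[1:(N - d)] - mean(x)) * (x[(1 + d):N] - mean(x))) / (N - d)
            den <- mean((x - mean(x))^2)
            if (den == 0) 0 else num / den
          } else {
            num <- sum((x[1:(N - d)] - x[(1 + d):N])^2) / (2 * (N - d))
            den <- sum((x - mean(x))^2) / (N - 1)
            if (den == 0) 0 else num / den
          }
          expect_equal(unname(enc[i, paste0(fam, ":", pi, ":lag", d)]),
                       expected, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("positional encoders expand bundled tables position by position", {
  seg <- "XWHAG"
  b <- encode_family(seg, "Binary")
  expect_equal(sum(b[1, grepl("^Binary:pos-2:", colnames(b))]), 0) # X row
  expect_equal(sum(b[1, grepl("^Binary:pos-1:", colnames(b))]), 1)
  expect_equal(unname(b[1, "Binary:pos-1:W"]), 1)
  bl <- encode_family(seg, "BLOSUM62")
  expect_equal(unname(bl[1, "BLOSUM62:pos-1:W"]), 11) # W-row diagonal
  expect_equal(unname(bl[1, "BLOSUM62:pos+0:H"]), blosum62_matrix()["H", "H"])
  expect_all_equal(bl[1, grepl("^BLOSUM62:pos-2:", colnames(bl))], rep(0, 20))
  z <- encode_family(seg, "ZScale")
  expect_all_equal(z[1, paste0("ZScale:pos+1:z", 1:5)], zscales()["A", ])
  ai <- encode_family(seg, "AAIndex")
  expect_equal(unname(ai[1, "AAIndex:pos+0:CIDH920105"]),
               unname(aaindex_table()["CIDH920105", "H"]))
  # dimensional bookkeeping: positional families together give (20+531+20+5)*W
  for (w in c(5L, 21L)) {
    dims <- vapply(c("Binary", "AAIndex", "BLOSUM62", "ZScale"),
                   function(f) encoder_dim(f, w), integer(1))
    expect_equal(sum(dims), (20 + 531 + 20 + 5) * w)
  }
})

test_that("every family's output width equals its declared dimensionality", {
  for (w in c(21L, 31L)) {
    segs <- random_segments(3, w, seed = w)
    for (fam in encoder_families()) {
      expect_equal(ncol(encode_family(segs, fam)), encoder_dim(fam, w),
                   info = paste(fam, w))
    }
  }
})

test_that("encoders are pure functions and full encoding is well-behaved", {
  segs <- random_segments(4, 21, seed = 23)
  tbl <- tibble::tibble(protein_id = "p", position = 1:4, segment = segs,
                        label = c("pHis", "nonpHis", "pHis", "nonpHis"))
  e1 <- encode_segments(tbl)
  e2 <- encode_segments(tbl)
  expect_identical(e1, e2)
  # two identical segments -> identical rows
  tbl2 <- tbl
  tbl2$segment <- rep(segs[1], 4)
  e3 <- encode_segments(tbl2)
  m3 <- feature_matrix(e3)
  expect_identical(m3[1, ], m3[3, ])
  # removing one family removes exactly that family's named block
  e4 <- encode_segments(tbl, families = setdiff(encoder_families(), "TPC"))
  expect_setequal(
    setdiff(feature_names(e1), feature_names(e4)),
    grep("^TPC:", feature_names(e1), value = TRUE)
  )
  # mixed window sizes error
  expect_error(encode_segments(c("AHAHA", "AHA")), "mixed window")
  # total dimensionality strictly increases with window size
  dims <- vapply(c(21L, 25L, 31L, 35L, 41L), function(w)
    sum(vapply(encoder_families(), function(f) encoder_dim(f, w), integer(1))),
    integer(1))
  expect_true(all(diff(dims) > 0))
})
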