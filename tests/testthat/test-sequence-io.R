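test_that("FASTA parsing concatenates lines, takes first header token, upper-cases", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKh", "AG", ">sp|Q1|NAME some description", "MH"), f)
  p <- read_fasta(f)
  expect_equal(p$id, c("p1", "sp|Q1|NAME"))
  expect_equal(p$sequence, c("MKHAG", "MH"))
})

test_that("FASTA ingest maps non-standard residues to X with a warning", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MBHZU"), f)
  expect_warning(p <- read_fasta(f), "mapped to 'X'")
  expect_equal(p$sequence, "MXHXX")
})

test_that("malformed FASTA and duplicate IDs raise informative errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKHAG", ">p1", "MH"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c(">p1", "MH", ">p1 other", "AHA"), f)
  expect_error(read_fasta(f), "duplicate.*p1")
})

test_that("write/read FASTA round trip is the identity on random records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  recs <- withr::with_seed(11, tibble::tibble(
    id = sprintf("prot%02d", 1:25),
    sequence = vapply(1:25, function(i) {
      paste(sample(aa20, sample(5:200, 1), replace = TRUE), collapse = "")
    }, character(1))
  ))
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("site tables are validated against their proteins", {
  prot <- tibble::tibble(id = "p1", sequence = "MKHAG")
  ok <- validate_sites(
    tibble::tibble(protein_id = "p1", position = 3L, label = "pHis"), prot
  )
  expect_equal(as.character(ok$label), "pHis")
  expect_error(validate_sites(
    tibble::tibble(protein_id = "p1", position = 2L, label = "pHis"), prot
  ), "not H.*residue K")
  expect_error(validate_sites(
    tibble::tibble(protein_id = "p9", position = 3L, label = "pHis"), prot
  ), "unknown protein")
  expect_error(validate_sites(
    tibble::tibble(protein_id = "p1", position = 9L, label = "pHis"), prot
  ), "out of range")
})

test_that("site table TSV round trip preserves records and label tokens", {
  prot <- tibble::tibble(id = "p1", sequence = "MKHAGH")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tlabel", "p1\t3\t1", "p1\t6\t0"), f)
  s <- read_sites(f, prot)
  expect_equal(as.character(s$label), c("pHis", "nonpHis"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_sites(s, f2)
  s2 <- read_sites(f2, prot)
  expect_equal(s2, s)
})

test_that("His enumeration agrees with a character-by-character scan", {
  p <- tibble::tibble(id = c("a", "b"), sequence = c("MKHAGH", "MKAG"))
  h <- enumerate_his_sites(p)
  expect_equal(h$position[h$protein_id == "a"], c(3L, 6L))
  expect_false("b" %in% h$protein_id)
  rand <- withr::with_seed(5, tibble::tibble(
    id = sprintf("r%d", 1:20),
    sequence = vapply(1:20, function(i)
      paste(sample(aa20, 80, replace = TRUE), collapse = ""), character(1))
  ))
  got <- enumerate_his_sites(rand)
  for (i in seq_len(nrow(rand))) {
    expect_equal(got$position[got$protein_id == rand$id[i]],
                 which(strsplit(rand$sequence[i], "")[[1]] == "H"))
  }
})

test_that("segment extraction pads termini with X and keeps His centered", {
  expect_equal(extract_segment("MHA", 2, 5), "XMHAX")
  expect_equal(extract_segment("H", 1, 7), "XXXHXXX")
  expect_error(extract_segment("MHA", 1, 5), "not H")
  expect_error(extract_segment("MHA", 2, 6), "odd")
  # property: length, centered His, pad-count formula, interior faithfulness
  rand <- withr::with_seed(21, tibble::tibble(
    id = sprintf("r%d", 1:30),
    sequence = vapply(1:30, function(i)
      paste(c(sample(aa20, sample(10:60, 1), replace = TRUE), "H"),
            collapse = ""), character(1))
  ))
  sites <- enumerate_his_sites(rand)
  for (w in c(5L, 21L, 31L)) {
    flank <- (w - 1L) %/% 2L
    segs <- extract_segments(sites, rand, w)
    expect_true(all(nchar(segs$segment) == w))
    expect_true(all(substr(segs$segment, flank + 1, flank + 1) == "H"))
    L <- nchar(setNames(rand$sequence, rand$id)[segs$protein_id])
    left_pad <- pmax(0L, flank - (segs$position - 1L))
    right_pad <- pmax(0L, flank - (L - segs$position))
    got_left <- nchar(sub("[^X].*$", "", segs$segment))
    got_right <- nchar(sub("^.*[^X]", "", segs$segment))
    expect_equal(got_left, unname(left_pad))
    expect_equal(got_right, unname(right_pad))
    interior <- left_pad == 0 & right_pad == 0
    expect_equal(
      segs$segment[interior],
      substr(setNames(rand$sequence, rand$id)[segs$protein_id[interior]],
             segs$position[interior] - flank, segs$position[interior] + flank),
      ignore_attr = TRUE
    )
  }
})

test_that("train/test split is stratified, exhaustive, disjoint, seeded", {
  sites <- tibble::tibble(
    protein_id = "p", position = 1:100,
    label = rep(c("pHis", "nonpHis"), times = c(20, 80))
  )
  sp <- split_train_test(sites, 0.8, seed = 4)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(sum(sp$train$label == "pHis"), 16)
  sp2 <- split_train_test(sites, 0.8, seed = 4)
  expect_identical(sp, sp2)
  key <- function(x) paste(x$protein_id, x$position)
  expect_setequal(c(key(sp$train), key(sp$test)), key(sites))
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  tiny <- tibble::tibble(protein_id = "p", position = 1:3,
                         label = c("pHis", "nonpHis", "nonpHis"))
  expect_error(split_train_test(tiny, 0.8, 1), "at least 2")
})
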