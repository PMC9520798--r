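# Sequence and site-table I/O, His-centered window extraction, train/test
# splitting. Coordinates are 1-based in every user-facing table (the
# convention phospho-site resources use); any 0-based arithmetic is internal.

# run expr with a temporary RNG state seeded from `seed`; global RNG restored
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# normalize a label vector (factor / character / logical / 0-1 numeric) to
# integer 0 = non-pHis, 1 = pHis
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  x <- tolower(as.character(labels))
  pos <- x %in% c("1", "phis", "positive", "pos", "true")
  neg <- x %in% c("0", "nonphis", "non-phis", "negative", "neg", "false")
  if (!all(pos | neg)) {
    abort(paste0("unrecognized label token(s): ",
                 paste(unique(x[!(pos | neg)]), collapse = ", ")))
  }
  as.integer(pos)
}

label_factor <- function(labels) {
  factor(ifelse(as_binary_labels(labels) == 1, "pHis", "nonpHis"),
         levels = c("nonpHis", "pHis"))
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased; the record ID is the first whitespace-delimited
#' token of the header. Non-standard residue codes (B, Z, U, O, J) are mapped
#' to the dummy residue 'X' with a warning reporting how many residues were
#' affected, so downstream encoders work over a closed 21-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) abort(paste0("empty FASTA file: ", path))
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(paste0("malformed FASTA: sequence before header at line ", first))
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA IDs: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  sq <- toupper(as.character(seqs))
  names(sq) <- NULL
  n_mapped <- sum(vapply(
    sq, function(s) sum(strsplit(s, "")[[1]] %in% .nonstandard_codes), integer(1)
  ))
  if (n_mapped > 0) {
    for (code in .nonstandard_codes) sq <- gsub(code, "X", sq, fixed = TRUE)
    warn(paste0(n_mapped, " non-standard residue(s) (B/Z/U/O/J) mapped to 'X'"))
  }
  bad <- !grepl(paste0("^[", paste(c(amino_acids(), "X"), collapse = ""), "]+$"), sq)
  if (any(bad)) {
    abort(paste0("invalid residue characters in record(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  if (any(!nzchar(sq))) abort("empty sequence(s) in FASTA")
  tibble(id = ids, sequence = sq)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return The input `proteins`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  x <- Biostrings::AAStringSet(proteins$sequence)
  names(x) <- proteins$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(proteins)
}

#' Read a His-site annotation table
#'
#' The table is tab-separated with a header and columns `protein_id`,
#' `position` (1-based) and `label` (tokens `1`/`0` or `pHis`/`nonpHis`).
#' Every record is validated against its protein: the position must be in
#' range and the residue at that position must be histidine.
#'
#' @param path Path to the TSV site table.
#' @param proteins Tibble of proteins as returned by [read_fasta()].
#' @return A tibble with columns `protein_id`, `position`, `label`
#'   (factor `nonpHis`/`pHis`).
#' @export
read_sites <- function(path, proteins) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    label = readr::col_character()
  ), progress = FALSE)
  sites <- tibble(
    protein_id = raw$protein_id,
    position = raw$position,
    label = label_factor(raw$label)
  )
  validate_sites(sites, proteins)
}

#' Validate a site table against its proteins
#'
#' @param sites Tibble with `protein_id`, `position`, `label`.
#' @param proteins Tibble with `id`, `sequence`.
#' @return `sites`, invisibly usable, with label normalized to a factor.
#' @export
validate_sites <- function(sites, proteins) {
  sites <- as_tibble(sites)
  sites$label <- label_factor(sites$label)
  unknown <- setdiff(sites$protein_id, proteins$id)
  if (length(unknown) > 0) {
    abort(paste0("unknown protein_id(s) in site table: ",
                 paste(unique(unknown), collapse = ", ")))
  }
  seqs <- setNames(proteins$sequence, proteins$id)
  len <- nchar(seqs)[sites$protein_id]
  out_of_range <- sites$position < 1L | sites$position > len
  if (any(out_of_range)) {
    bad <- sites[out_of_range, ]
    abort(paste0("site position out of range: ",
                 paste(paste0(bad$protein_id, ":", bad$position), collapse = ", ")))
  }
  res <- substr(seqs[sites$protein_id], sites$position, sites$position)
  not_h <- res != "H"
  if (any(not_h)) {
    bad <- sites[not_h, ]
    abort(paste0("residue at annotated site is not H: ",
                 paste(paste0(bad$protein_id, ":", bad$position,
                              " (residue ", res[not_h], ")"), collapse = ", ")))
  }
  if (anyDuplicated(sites[, c("protein_id", "position")])) {
    abort("duplicate (protein_id, position) pairs in site table")
  }
  sites
}

#' Write a site table as TSV
#'
#' @param sites Site tibble.
#' @param path Output path.
#' @return `sites`, invisibly.
#' @export
write_sites <- function(sites, path) {
  out <- sites
  out$label <- as.character(out$label)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(sites)
}

#' Enumerate histidine positions
#'
#' Lists every His residue of every protein — the candidate site universe;
#' in the benchmark-construction convention, His sites of phosphorylated
#' proteins that are not annotated pHis become negative samples.
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @return Tibble with columns `protein_id`, `position` (ascending within
#'   protein).
#' @export
enumerate_his_sites <- function(proteins) {
  res <- purrr::map2(proteins$id, proteins$sequence, function(id, sq) {
    pos <- which(strsplit(sq, "")[[1]] == "H")
    if (length(pos) == 0) return(NULL)
    tibble(protein_id = id, position = as.integer(pos))
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) tibble(protein_id = character(), position = integer()) else out
}

#' Extract one His-centered window from a sequence
#'
#' Positions falling outside the protein are filled with the dummy residue
#' 'X', so the returned segment always has exactly `window` characters with
#' the His at the center.
#'
#' @param sequence Protein sequence string.
#' @param position 1-based position of the central His.
#' @param window Odd window size >= 5.
#' @return A character scalar of length `window`.
#' @export
extract_segment <- function(sequence, position, window = 31L) {
  check_window(window)
  L <- nchar(sequence)
  if (position < 1 || position > L) abort("position out of range")
  if (substr(sequence, position, position) != "H") {
    abort(paste0("residue at position ", position, " is ",
                 substr(sequence, position, position), ", not H"))
  }
  flank <- (window - 1L) %/% 2L
  lo <- position - flank
  hi <- position + flank
  left_pad <- max(0L, 1L - lo)
  right_pad <- max(0L, hi - L)
  core <- substr(sequence, max(1L, lo), min(L, hi))
  paste0(strrep("X", left_pad), core, strrep("X", right_pad))
}

check_window <- function(window) {
  if (length(window) != 1 || window < 5 || window %% 2 == 0) {
    abort("window must be a single odd integer >= 5")
  }
  invisible(window)
}

#' Extract His-centered windows for a site table
#'
#' @param sites Site tibble (`protein_id`, `position`, optionally `label`).
#' @param proteins Protein tibble (`id`, `sequence`).
#' @param window Odd window size (default 31).
#' @return `sites` with an added `segment` column and a `window` attribute.
#' @export
extract_segments <- function(sites, proteins, window = 31L) {
  check_window(window)
  seqs <- setNames(proteins$sequence, proteins$id)
  unknown <- setdiff(sites$protein_id, proteins$id)
  if (length(unknown) > 0) {
    abort(paste0("unknown protein_id(s): ", paste(unique(unknown), collapse = ", ")))
  }
  out <- as_tibble(sites)
  out$segment <- vapply(
    seq_len(nrow(out)),
    function(i) extract_segment(seqs[[out$protein_id[i]]], out$position[i], window),
    character(1)
  )
  attr(out, "window") <- as.integer(window)
  out
}

#' Stratified train/test split of a site table
#'
#' The split is stratified by label (with heavy class imbalance an
#' unstratified split can produce degenerate partitions) and is
#' deterministic given `seed`.
#'
#' @param sites Site tibble with a `label` column.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.8).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(sites, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  y <- as_binary_labels(sites$label)
  counts <- table(y)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("each class needs at least 2 members to stratify the split")
  }
  train_idx <- local_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      n_train <- round(train_fraction * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      sample(idx, n_train)
    }))
  })
  train_idx <- sort(train_idx)
  list(
    train = as_tibble(sites[train_idx, ]),
    test = as_tibble(sites[setdiff(seq_len(nrow(sites)), train_idx), ])
  )
}
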