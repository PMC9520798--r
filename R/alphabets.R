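# Residue alphabets, physicochemical groupings and property scales used by the
# feature encoders. Everything here is a fixed lookup: no function depends on
# the data being encoded.

#' The 20 standard amino acid one-letter codes
#'
#' Canonical residue order used for every composition-style feature block.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")
}

# Ambiguity / non-standard codes collapsed to 'X' on ingest so that every
# encoder works over a closed 21-letter alphabet (20 standard + 'X').
.nonstandard_codes <- c("B", "Z", "U", "O", "J")

#' Five-group physicochemical amino acid alphabet
#'
#' Grouping used by the grouped-composition encoders (GAAC, EGAAC, GDPC,
#' GTPC, CKSAAGP): aliphatic, aromatic, positively charged, negatively
#' charged, and uncharged polar residues.
#'
#' @return Named list of five character vectors covering all 20 residues.
#' @export
residue_groups <- function() {
  list(
    aliphatic = c("G", "A", "V", "L", "M", "I"),
    aromatic  = c("F", "Y", "W"),
    positive  = c("K", "R", "H"),
    negative  = c("D", "E"),
    uncharged = c("S", "T", "C", "P", "N", "Q")
  )
}

#' Seven-class conjoint-triad alphabet
#'
#' Residue classes of the conjoint-triad descriptors, grouped by dipole and
#' side-chain volume.
#'
#' @return Named list of seven character vectors.
#' @export
conjoint_classes <- function() {
  list(
    g1 = c("A", "G", "V"),
    g2 = c("I", "L", "F", "P"),
    g3 = c("Y", "M", "T", "S"),
    g4 = c("H", "N", "Q", "W"),
    g5 = c("R", "K"),
    g6 = c("D", "E"),
    g7 = c("C")
  )
}

#' Three-class partitions for the C/T/D descriptors
#'
#' Seven physicochemical attributes, each partitioning the 20 residues into
#' three classes (the standard partitions used by C/T/D descriptor suites).
#'
#' @return Named list; each element is a list of three character vectors.
#' @export
ctd_attributes <- function() {
  list(
    hydrophobicity = list(
      c("R", "K", "E", "D", "Q", "N"),
      c("G", "A", "S", "T", "P", "H", "Y"),
      c("C", "L", "V", "I", "M", "F", "W")
    ),
    vdw_volume = list(
      c("G", "A", "S", "T", "P", "D", "C"),
      c("N", "V", "E", "Q", "I", "L"),
      c("M", "H", "K", "F", "R", "Y", "W")
    ),
    polarity = list(
      c("L", "I", "F", "W", "C", "M", "V", "Y"),
      c("P", "A", "T", "G", "S"),
      c("H", "Q", "R", "K", "N", "E", "D")
    ),
    polarizability = list(
      c("G", "A", "S", "D", "T"),
      c("C", "P", "N", "V", "E", "Q", "I", "L"),
      c("K", "M", "H", "F", "R", "Y", "W")
    ),
    charge = list(
      c("K", "R"),
      c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F", "P", "S", "T", "W", "Y", "V"),
      c("D", "E")
    ),
    secondary_structure = list(
      c("E", "A", "L", "M", "Q", "K", "R", "H"),
      c("V", "I", "Y", "C", "W", "F", "T"),
      c("G", "N", "P", "S", "D")
    ),
    solvent_access = list(
      c("A", "L", "F", "C", "G", "I", "V", "W"),
      c("R", "K", "Q", "E", "N", "D"),
      c("M", "S", "P", "T", "H", "Y")
    )
  )
}

# --- property scales ---------------------------------------------------------

# Hydrophobicity scale of the pseudo amino acid composition descriptor set.
.paac_hydrophobicity <- c(
  A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48, H = -0.40,
  I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78, P = 0.12, Q = -0.85,
  R = -2.53, S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08
)

# Hopp-Woods hydrophilicity.
.paac_hydrophilicity <- c(
  A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
  I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
  R = 3.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5
)

# Side-chain mass.
.paac_mass <- c(
  A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82,
  I = 57, K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72,
  R = 101, S = 31, T = 45, W = 130, Y = 107, V = 43
)

#' Property scales of the pseudo amino acid composition encoders
#'
#' Hydrophobicity, hydrophilicity and side-chain mass, each standardized to
#' zero mean and unit (population) standard deviation over the 20 residues,
#' the normalization conventionally applied before computing sequence-order
#' correlation factors.
#'
#' @return A 3 x 20 numeric matrix (rows: hydrophobicity, hydrophilicity,
#'   mass; columns in [amino_acids()] order).
#' @export
paac_scales <- function() {
  std <- function(x) {
    x <- x[amino_acids()]
    (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  }
  rbind(
    hydrophobicity = std(.paac_hydrophobicity),
    hydrophilicity = std(.paac_hydrophilicity),
    mass           = std(.paac_mass)
  )
}

# Sandberg z-scales (5 principal property scores per residue).
.zscale_table <- matrix(c(
  # z1, z2, z3, z4, z5
   0.24, -2.32,  0.60, -0.14,  1.30, # A
   0.84, -1.67,  3.71,  0.18, -2.65, # C
   3.98,  0.93,  1.93, -2.46,  0.75, # D
   3.11,  0.26, -0.11, -3.04, -0.25, # E
  -4.22,  1.94,  1.06,  0.54, -0.62, # F
   2.05, -4.06,  0.36, -0.82, -0.38, # G
   2.47,  1.95,  0.26,  3.90,  0.09, # H
  -3.89, -1.73, -1.71, -0.84,  0.26, # I
   2.29,  0.89, -2.49,  1.49,  0.31, # K
  -4.28, -1.30, -1.49, -0.72,  0.84, # L
  -2.85, -0.22,  0.47,  1.94, -0.98, # M
   3.05,  1.62,  1.04, -1.15,  1.61, # N
  -1.66,  0.27,  1.84,  0.70,  2.00, # P
   1.75,  0.50, -1.44, -1.34,  0.66, # Q
   3.52,  2.50, -3.50,  1.99, -0.17, # R
   2.39, -1.07,  1.15, -1.39,  0.67, # S
   0.75, -2.18, -1.12, -1.46, -0.40, # T
  -4.36,  3.94,  0.59,  3.44, -1.59, # W
  -2.54,  2.44,  0.43,  0.04, -1.47, # Y
  -2.59, -2.64, -1.54, -0.85, -0.02  # V
), nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V"),
                  paste0("z", 1:5)))

#' Sandberg z-scales
#'
#' @return A 20 x 5 numeric matrix of the five z-scale property scores,
#'   rows in [amino_acids()] order.
#' @export
zscales <- function() .zscale_table[amino_acids(), ]

# Grantham (1974) residue properties: composition (c), polarity (p),
# side-chain volume (v).
.grantham_properties <- matrix(c(
  # c,     p,    v
  0.00,  8.1,  31.0, # A
  2.75,  5.5,  55.0, # C
  1.38, 13.0,  54.0, # D
  0.92, 12.3,  83.0, # E
  0.00,  5.2, 132.0, # F
  0.74,  9.0,   3.0, # G
  0.58, 10.4,  96.0, # H
  0.00,  5.2, 111.0, # I
  0.33, 11.3, 119.0, # K
  0.00,  4.9, 111.0, # L
  0.00,  5.7, 105.0, # M
  1.33, 11.6,  56.0, # N
  0.39,  8.0,  32.5, # P
  0.89, 10.5,  85.0, # Q
  0.65, 10.5, 124.0, # R
  1.42,  9.2,  32.0, # S
  0.71,  8.6,  61.0, # T
  0.13,  5.4, 170.0, # W
  0.20,  6.2, 136.0, # Y
  0.00,  5.9,  84.0  # V
), nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V"),
                  c("composition", "polarity", "volume")))

#' Grantham chemical distance matrix
#'
#' Computed from Grantham's formula
#' \eqn{D_{ij} = \rho\sqrt{\alpha(c_i-c_j)^2 + \beta(p_i-p_j)^2 +
#' \gamma(v_i-v_j)^2}} with \eqn{\alpha = 1.833}, \eqn{\beta = 0.1018},
#' \eqn{\gamma = 0.000399} over his composition/polarity/volume property
#' table, scaled so the mean inter-residue distance is 100 (which recovers
#' the published values, e.g. Leu-Ile 5, Ser-Arg 110, Cys-Trp 215).
#'
#' @return Symmetric 20 x 20 numeric matrix with zero diagonal.
#' @export
grantham_distance <- function() {
  if (!is.null(.phisite_cache$grantham)) return(.phisite_cache$grantham)
  pr <- .grantham_properties[amino_acids(), ]
  alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399
  d2 <- alpha * outer(pr[, 1], pr[, 1], "-")^2 +
    beta  * outer(pr[, 2], pr[, 2], "-")^2 +
    gamma * outer(pr[, 3], pr[, 3], "-")^2
  d <- sqrt(d2)
  off <- d[upper.tri(d)]
  d <- d * (100 / mean(off))
  .phisite_cache$grantham <- d
  d
}

#' Synthetic physicochemical distance matrix
#'
#' A residue-pair distance matrix built as the Euclidean distance between
#' residues in the standardized three-dimensional property space of
#' [paac_scales()] (hydrophobicity, hydrophilicity, side-chain mass). It is a
#' synthetic, clearly self-derived stand-in for a Schneider-Wrede-style
#' physicochemical distance matrix (whose published values are not bundled
#' here), and is used alongside [grantham_distance()] by the
#' sequence-order-coupling encoders.
#'
#' @return Symmetric 20 x 20 numeric matrix with zero diagonal.
#' @export
physchem_distance <- function() {
  if (!is.null(.phisite_cache$physchem)) return(.phisite_cache$physchem)
  sc <- paac_scales()
  d <- sqrt(outer(sc[1, ], sc[1, ], "-")^2 +
            outer(sc[2, ], sc[2, ], "-")^2 +
            outer(sc[3, ], sc[3, ], "-")^2)
  .phisite_cache$physchem <- d
  d
}

#' BLOSUM62 substitution scores for the 20 standard residues
#'
#' @return 20 x 20 integer matrix (subset of the Biostrings BLOSUM62 data).
#' @export
blosum62_matrix <- function() {
  if (!is.null(.phisite_cache$blosum62)) return(.phisite_cache$blosum62)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[amino_acids(), amino_acids()]
  .phisite_cache$blosum62 <- m
  m
}

# three-letter -> one-letter mapping for the seqinr AAindex tables
.aa3to1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

#' AAindex1 property table
#'
#' All AAindex1 entries bundled with seqinr that have no missing value
#' (531 properties), as a properties x residues matrix. Used by the
#' positional AAindex encoder.
#'
#' @return Numeric matrix, 531 rows (AAindex accessions, sorted) x 20
#'   residue columns in [amino_acids()] order.
#' @export
aaindex_table <- function() {
  if (!is.null(.phisite_cache$aaindex)) return(.phisite_cache$aaindex)
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  entries <- env$aaindex
  rows <- lapply(entries, function(e) {
    v <- e$I
    names(v) <- .aa3to1[names(v)]
    v[amino_acids()]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(entries)
  m <- m[!apply(m, 1, anyNA), , drop = FALSE]
  m <- m[order(rownames(m)), , drop = FALSE]
  .phisite_cache$aaindex <- m
  m
}

#' Default autocorrelation property scales
#'
#' Eight AAindex1 properties (hydrophobicity, flexibility, polarizability,
#' free energy of solution, accessible surface area, residue volume, steric
#' hindrance, relative mutability) standardized to zero mean / unit variance
#' over the 20 residues; the default property set of the autocorrelation
#' encoders (normalized Moreau-Broto, Moran, Geary).
#'
#' @return 8 x 20 numeric matrix, rows named by AAindex accession.
#' @export
autocorrelation_scales <- function() {
  if (!is.null(.phisite_cache$autocorr)) return(.phisite_cache$autocorr)
  acc <- c("CIDH920105", "BHAR880101", "CHAM820101", "CHAM820102",
           "CHOC760101", "BIGC670101", "CHAM810101", "DAYM780201")
  m <- aaindex_table()[acc, , drop = FALSE]
  m <- t(apply(m, 1, function(x) (x - mean(x)) / sd(x)))
  colnames(m) <- amino_acids()
  .phisite_cache$autocorr <- m
  m
}
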