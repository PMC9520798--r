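---
title: "Predicting phosphohistidine sites from sequence windows: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phosphohistidine sites from sequence windows: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Histidine phosphorylation (pHis) is an acid-labile post-translational
modification, chronically under-detected by standard phosphoproteomics and
central to bacterial two-component signalling and a growing set of
eukaryotic processes. Given a protein sequence, only a small minority of
its histidines are phosphorylated, so the computational task is a heavily
imbalanced binary classification: for each His residue, decide from its
local sequence context whether it is a pHis site.

phisite implements the full sequence-based pipeline for this task:
His-centered window extraction, massive descriptor-based feature encoding,
ANOVA F-score filter selection, class-weighted classification (weighted
RBF-kernel SVM by default), imbalance-aware evaluation, and the two
sequence-analysis procedures that motivate the feature design (positional
residue enrichment and pHis-to-non-pHis distance distributions).

## Windows

Each annotated site is represented by the window of `W` residues centered
on the His (`W` odd; supported sizes 21, 25, 31, 35, 41; default 31, i.e.
15 residues of flank on each side). Window positions falling outside the
protein are filled with the dummy residue `X`. Coordinates are 1-based in
every user-facing table, the convention used by phospho-site resources.
Non-standard residue codes (B, Z, U, O, J) are mapped to `X` at FASTA
ingest, with a warning count, so every encoder operates over a closed
21-letter alphabet.

A design rule applied uniformly across the package: **padding must never
masquerade as signal**. `X` positions contribute to no count, sum, or
correlation — n-grams, pairs and triads containing `X` are excluded from
numerators *and* denominators, order/autocorrelation statistics run over
the compacted valid-residue subsequence, positional encoders emit zero
vectors at `X` positions, and identity clustering scores only mutually
valid positions.

## Feature encoders

Twenty-six encoder families grouped into eleven groups transform a window
into named numeric descriptors (`family:descriptor[:position|:gap]`), in a
fixed canonical family order so a feature keeps its identity across runs
and model bundles:

| Group | Families (dimensionality at window `W`) |
|---|---|
| Amino acid composition | AAC (20), EAAC ((W−s+1)·20), CKSAAP (400·(k+1)), DPC (400), TPC (8000) |
| Grouped composition | GAAC (5), EGAAC ((W−s+1)·5), CKSAAGP (25·(k+1)), GDPC (25), GTPC (125) |
| C/T/D | CTD-C (21), CTD-D (105), CTD-T (21) |
| Conjoint triad | C-Triad (343), k-spaced Triad (343·(k+1)) |
| Quasi-sequence-order | SOC-Number (2·nlag), QS-Order (2·(20+nlag)) |
| Pseudo amino acid composition | PAAC (20+λ), APAAC (20+2λ) |
| Autocorrelation | NM-Broto, Moran, Geary (8·nlag each) |
| Positional | Binary (20W), AA-index (531W), BLOSUM62 (20W), Z-scale (5W) |

Parameter defaults — sub-window 5 (EAAC/EGAAC), maximum gap 5
(CKSAAP/CKSAAGP) and 1 (k-spaced triads), lag 5 (sequence-order and
autocorrelation), λ = 5 and weight 0.05 (PAAC/APAAC), weight 0.1
(QS-Order) — are the common descriptor-suite defaults that remain valid at
the smallest supported window, and every one is overridable per family.
At window 31 the default suite yields 31,067 features, within the
26,000–38,000 range such suites typically produce across windows 21–41;
the exact total depends on these parameter choices, so it is treated as a
property of the configuration, not a contract.

Descriptor conventions worth stating precisely:

* **CKSAAP**: ordered residue pairs at distance `k+1`, each gap block
  normalized by its own valid-pair count, so each block sums to 1 on
  X-free windows.
* **CTD**: seven physicochemical attributes each partition the 20 residues
  into three classes. C = class frequencies; T = adjacent distinct-class
  transitions over `N−1` consecutive valid pairs; D = the relative
  positions (% of valid length) of the 1st, 25%, 50%, 75% and 100%
  occurrence of each class, using the `ceiling(q·m)`-th occurrence.
* **Conjoint triads** are normalized by the valid-triad count (blocks sum
  to 1), rather than min–max within block; the conservation property is
  directly testable and the choice is documented here because both
  conventions exist in the wild.
* **Quasi-sequence-order / SOC-Number** use two residue-distance matrices:
  the Grantham chemical distance, computed from Grantham's published
  formula and composition/polarity/volume table (the computation
  reproduces the canonical values, e.g. Leu–Ile 5, Ser–Arg 110, Cys–Trp
  215), and a **synthetic physicochemical distance** built as the
  Euclidean distance in the standardized hydrophobicity / hydrophilicity /
  side-chain-mass space of the PAAC scales. The latter stands in for a
  Schneider–Wrede-style matrix whose published values are not bundled; it
  is clearly labelled synthetic (`physchem_distance()`) and any fixed
  symmetric zero-diagonal distance matrix serves the same structural role
  in these descriptors.
* **PAAC/APAAC** standardize their three property scales to zero mean and
  unit population variance over the 20 residues before computing
  sequence-order correlation factors; with λ = 0, PAAC reduces exactly to
  AAC.
* **Autocorrelation** families use eight NA-free AAindex1 properties
  (taken from the seqinr AAindex distribution, standardized per property).
  Zero within-window property variance (homopolymeric windows) defines
  Moran and Geary as 0 rather than undefined, keeping vectors finite.
* **AA-index positional encoding** uses all 531 AAindex1 entries without
  missing values, in sorted accession order.

## Normalization and selection

Each feature is min–max normalized to [0, 1] with bounds frozen on the
training data; constant features map to 0, and prediction-time values
outside the training range are clipped into [0, 1], keeping the SVM input
domain bounded. Features with zero training variance are removed first.

Features are ranked by the classical two-group one-way ANOVA F statistic

$$F = \frac{SSA}{SSE/(n-2)}, \qquad
SSA = \sum_{i=1}^{2} n_i(\bar X_i - \bar X)^2, \qquad
SSE = \sum_{i=1}^{2}\sum_{j=1}^{n_i} (X_{ij} - \bar X_i)^2,$$

where SSE is the within-class sum of squared deviations from the class
mean (the only reading under which SSE is a sum of squared errors).
Degenerate conventions: SSA = 0 with SSE = 0 gives F = 0 (constant
features must lose); SSA > 0 with SSE = 0 gives F = +Inf (totally
separating features must win). Ties are broken by lexicographic feature
name so ranking is independent of column order. Because F is invariant to
per-feature affine maps with positive scale, ranking before or after the
[0, 1] rescaling is equivalent; the implementation exploits this to rank
on the raw scale inside cross-validation folds, where it also computes the
variance filter, the F statistics and the normalization bounds from a
single chunked pass over the training rows so that the ~31,000-column
matrix is never duplicated.

The selection size `k` follows the published production profiles: 140
(eukaryotic) and 150 (prokaryotic) at window 31, with the exploratory grid
`k ∈ {5, 10, …, 150}` × windows {21, 25, 31, 35, 41} available through
`grid_evaluate()`.

## Classifiers and class weighting

Class imbalance is handled by inverse-frequency ("balanced") weights
$w_c = n/(2n_c)$, which equalize the weighted sample mass of the two
classes. The five algorithms and their fixed hyperparameters:

* **LR** — L2-penalized logistic regression with the penalty strength
  chosen by internal 5-fold cross-validation (glmnet `cv.glmnet`,
  `lambda.min`), maximum 5000 iterations, class-weighted.
* **KNN** — k = 20 neighbours (matched to the scale of the minority
  class rather than √n, which would drown positives in negatives),
  inverse-distance vote weighting. KNN has no class-weight mechanism;
  imbalance is addressed only through k and distance weighting. The
  distance-weighted vote is implemented directly in the package (no
  installed R implementation offers distance weighting).
* **SVM-RBF** (production default) — e1071/libsvm with C = 1 and
  γ = 1/(d·Var(X)) by default (both exposed; no grid search is performed
  because none is prescribed), class-weighted. Probability estimates come
  from a seeded, stratified 5-fold cross-validated sigmoid (Platt)
  calibration of the decision values implemented in the package: libsvm's
  built-in calibration draws on C-library RNG state that cannot be seeded
  from R, which would break the package's determinism contract.
* **RF** — 100 trees, class weights passed to the forest, out-of-bag
  error recorded in the bundle notes as the generalization estimate.
* **MLP** — two hidden layers of 100 and 50 ReLU units, logistic output,
  L2 penalty 1e-4, L-BFGS optimization up to 1000 iterations, weight
  initialization seeded (default seed 1, overridable). Implemented in the
  package because no installed R package provides a two-hidden-layer
  perceptron; it is unweighted, as multi-layer perceptron
  implementations conventionally lack per-class weights.

All stochastic components flow from a single seed; training twice with
the same seed reproduces predictions bit-for-bit, and a serialized bundle
(`write_model()`/`read_model()`) round-trips exactly.

## Evaluation

Six confusion-based metrics (specificity, recall, precision, F1,
accuracy, MCC) with the convention that any metric whose denominator
vanishes is reported as 0 with a `degenerate` flag, so threshold sweeps
remain finite at the extremes. ROC curves sweep the distinct scores; AUC
is the trapezoid area, identical to the Mann–Whitney concordance
probability with ties counted half. Binary calls use `score ≥ t`, with
strict `> 1` at t = 1 (the "1 + ε" convention), so t = 0 gives recall 1 /
specificity 0 and t = 1 gives recall 0 / specificity 1.

Cross-validation is stratified (with ~7% positives, unstratified folds
can lose the minority class entirely) and **leak-free**: the variance
filter, normalization bounds and F-score selection are refit inside every
training fold. The deliberately leaky protocol (selection fit on all data
before folding) is retained behind `leaky = TRUE` solely so the optimism
it produces can be demonstrated and regression-tested; on pure-noise
features (n = 1000, d = 5000, k = 140) the leak-free path stays at chance
while the leaky path is visibly biased upward.

## Sequence analysis

`positional_enrichment()` compares, for every (offset, residue) cell, the
per-window presence indicator between positive and negative sets with a
Welch two-sample t-test on the 0/1 indicators — the testing scheme of
two-sample sequence logos. The center position (His in both sets, a
zero-variance indicator) is excluded, `X` positions are ignored, and no
multiple-testing correction is applied by default (cells are flagged at a
fixed per-cell α = 0.05, the convention of that analysis style; a
Bonferroni toggle exists and the inflation risk of the uncorrected
default is the user's to weigh). `nearest_nonphis_distances()` reports,
for each positive site, the minimum residue distance to a His of the same
protein that is not itself positive, plus the fraction below a cutoff
(default 15) — the structure that makes within-protein negatives both
realistic and partially overlapping with positive windows.

## Redundancy reduction

Near-duplicate windows are removed by greedy identity clustering, the
fixed-length analogue of CD-HIT at 0.9 identity: windows are processed in
canonical order (descending valid-residue count, ties lexicographic — the
fixed-window analogue of longest-first) and each joins the first cluster
whose representative matches it at ≥ ⌈threshold·W_valid⌉ mutually valid
positions, else founds a new cluster. Ungapped aligned-position identity
is exact here because windows are equal-length and center-anchored; no
alignment heuristic is involved. Random windows essentially never reach
0.9 identity, so on synthetic data this step is nearly a no-op, which is
the correct behaviour — it exists to collapse genuine homologous
repetition in real data.

## The synthetic generator

`generate_dataset()` emulates the data regime the pipeline targets:
proteins (default 300, uniform length 60–200) drawn from a uniform
residue background, ~20% of His sites labelled positive, and a planted
positive-site motif — G at offsets −1 and +1 with probability 0.5 each, H
at −3 with probability 0.3 — mirroring the glycine flanking enrichment
and the His clustering that real pHis neighbourhoods show. Negatives are
the remaining His sites of the same proteins, reproducing the
within-protein negative-sampling convention and its overlap caveat. The
uniform background makes the planted biases the only signal, so a
chance-level result under label permutation is a meaningful no-leakage
control; a natural-abundance background preset exists for more realistic
composition. The generator is deterministic given its seed, emits its
ground truth for recovery tests, re-draws positives whose motif offsets
would leave the protein (counted), and never lets planting overwrite
another positive site's central His (collisions counted).

What passing on this generator does *not* show: real pHis specificity is
not a three-cell positional motif; there is no kinase-family structure,
no homology between proteins (so redundancy reduction is barely
exercised), and no species-level composition bias. Results on synthetic
data validate the machinery — encoding correctness, leak-freedom,
calibration, determinism — not biological performance. Published
benchmark-scale performance (tenfold-CV AUC ≈ 0.8 on curated eukaryotic
and prokaryotic datasets of a few hundred positives) requires the curated
sites, which this package deliberately does not bundle or fetch.

## Validation scale

The shipped validation suite runs the full pipeline at the generator's
default scale (~2,000 windows × ~31,000 features, 10-fold CV of the
weighted SVM, plus a permuted-label control and a 1,000 × 5,000
pure-noise leak check), sizes chosen so the whole suite completes on a
single CPU in well under half an hour while keeping the statistical bands
(AUC ≥ 0.85 for signal recovery; [0.45, 0.55] for the chance controls)
several standard errors wide.

## Known limitations

* No evolutionary-profile (PSSM) or structure-derived features; the
  descriptor suite is sequence-only, as in the original design.
* The exploratory k × window grid refits the full CV per cell and is
  CPU-hungry at full feature dimensionality.
* The synthetic physicochemical distance matrix is a stand-in (see
  above); users wanting the published Schneider–Wrede values can pass
  their own matrix-backed descriptors once such a table is available to
  them.
* With the uncorrected per-cell α, the enrichment table's expected false
  positive count is α × 800 cells at window 21; use the Bonferroni toggle
  when cell-level error control matters.
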