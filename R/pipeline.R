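# The end-to-end workflow: segment extraction, optional redundancy
# reduction, encoding, per-training-set variance filtering / normalization /
# F-score selection, classifier training, and prediction on new sequences.

#' Shipped configuration profiles
#'
#' Two profiles mirror the published production configurations: the
#' eukaryotic profile keeps 140 features at window 31, the prokaryotic one
#' 150 features at window 31; both use the class-weighted RBF-kernel SVM
#' and 10-fold evaluation. Profiles are plain JSON files under
#' `inst/extdata/profiles/`, not constants baked into code.
#'
#' @param name `"eukaryotic"` or `"prokaryotic"`.
#' @return Named list: `window`, `k`, `algorithm`, `folds`,
#'   `identity_threshold`.
#' @export
profile_config <- function(name = c("eukaryotic", "prokaryotic")) {
  name <- match.arg(name)
  path <- system.file("extdata", "profiles", paste0(name, ".json"),
                      package = "phisite", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$window <- as.integer(cfg$window)
  cfg$k <- as.integer(cfg$k)
  cfg$folds <- as.integer(cfg$folds)
  cfg
}

#' Fit the full prediction pipeline
#'
#' Extracts His-centered windows for the annotated sites, optionally
#' reduces near-duplicate windows by greedy identity clustering, encodes
#' the retained windows with all requested encoder families, drops
#' constant features, freezes \[0,1\] normalization bounds, ranks features
#' by ANOVA F-score, keeps the top `k`, and trains the classifier on them.
#' Everything needed to score new sequences (window size, encoder
#' parameters, bounds, selected feature names, fitted state) is stored in
#' the returned bundle.
#'
#' @param proteins Protein tibble ([read_fasta()]).
#' @param sites Site tibble with labels ([read_sites()]).
#' @param window Odd window size (default 31).
#' @param k Number of features to select (default 140, the eukaryotic
#'   profile; use 150 for the prokaryotic profile).
#' @param algorithm One of [algorithms()] (default `svm_rbf`).
#' @param families Encoder families to use (default: all 26).
#' @param encoder_params Per-family parameter overrides.
#' @param identity_threshold Identity threshold for redundancy reduction of
#'   the training windows, or `NULL` to skip (default 0.9).
#' @param hyperparams Classifier hyperparameter overrides.
#' @param seed Integer seed.
#' @param threshold Probability threshold for binary calls (default 0.5).
#' @return A `phis_model` bundle.
#' @export
fit_pipeline <- function(proteins, sites, window = 31L, k = 140L,
                         algorithm = "svm_rbf",
                         families = encoder_families(),
                         encoder_params = list(),
                         identity_threshold = 0.9,
                         hyperparams = list(), seed = 1L, threshold = 0.5) {
  segs <- extract_segments(sites, proteins, window)
  if (!is.null(identity_threshold)) {
    cl <- reduce_redundancy(segs, threshold = identity_threshold)
    segs <- cl[cl$is_representative,
               setdiff(names(cl), c("cluster", "is_representative"))]
  }
  m <- encode_matrix(segs$segment, families = families,
                     params = encoder_params)
  y <- as_binary_labels(segs$label)
  # variance filter, normalization bounds and F-ranking from one chunked
  # pass (F ranks are invariant to the per-feature [0,1] rescaling)
  st <- fold_stats(m, y)
  varying <- which(st$max > st$min)
  f <- f_from_sums(st)[varying]
  nm <- colnames(m)[varying]
  ord <- order(-f, nm, method = "radix")
  k_eff <- min(k, length(varying))
  rank <- integer(length(f))
  rank[ord] <- seq_along(f)
  scores <- tibble(feature = nm, f = unname(f), rank = rank) |>
    arrange(.data$rank)
  scores$selected <- scores$rank <= k_eff
  sel <- scores$feature[scores$selected]
  si <- match(sel, colnames(m))
  bounds <- tibble(feature = sel, min = st$min[si], max = st$max[si])
  class(bounds) <- c("phis_normalizer", class(bounds))
  xtr <- scale_min_max(m[, si, drop = FALSE], bounds$min, bounds$max)
  colnames(xtr) <- sel
  clf <- fit_classifier(xtr, y, algorithm, hyperparams, seed)
  structure(
    list(algorithm = clf$algorithm, hyperparams = clf$hyperparams,
         window = as.integer(window), selected_features = sel,
         normalization = bounds[match(sel, bounds$feature), ],
         encoder_params = encoder_params, families = families,
         classifier = clf, class_weights = clf$class_weights,
         threshold = threshold, seed = seed, notes = clf$notes,
         scores = scores),
    class = "phis_model"
  )
}

#' Cross-validate the pipeline on annotated proteins
#'
#' Windows are extracted and encoded once (encoding is label-free), then
#' evaluated with [cv_evaluate()], whose variance filter, normalization and
#' F-score selection are refit inside each training fold.
#'
#' @inheritParams fit_pipeline
#' @param folds Number of stratified folds (default 10).
#' @return A `phis_eval` object.
#' @export
cv_pipeline <- function(proteins, sites, window = 31L, k = 140L,
                        algorithm = "svm_rbf",
                        families = encoder_families(),
                        encoder_params = list(),
                        identity_threshold = 0.9,
                        folds = 10L, hyperparams = list(), seed = 1L,
                        threshold = 0.5) {
  segs <- extract_segments(sites, proteins, window)
  if (!is.null(identity_threshold)) {
    cl <- reduce_redundancy(segs, threshold = identity_threshold)
    segs <- cl[cl$is_representative,
               setdiff(names(cl), c("cluster", "is_representative"))]
  }
  m <- encode_matrix(segs$segment, families = families,
                     params = encoder_params)
  cv_evaluate(m, labels = segs$label, k = k,
              algorithm = algorithm, folds = folds, seed = seed,
              hyperparams = hyperparams, threshold = threshold)
}

#' Predict pHis probabilities for every His site of new proteins
#'
#' @param object A `phis_model` bundle from [fit_pipeline()].
#' @param proteins Protein tibble.
#' @param sites Optional site tibble (`protein_id`, `position`); defaults
#'   to every His position of `proteins`.
#' @return Site tibble with `probability` and `call` columns.
#' @export
predict_sites <- function(object, proteins, sites = NULL) {
  if (is.null(sites)) sites <- enumerate_his_sites(proteins)
  segs <- extract_segments(sites, proteins, object$window)
  bind_cols(as_tibble(sites), predict(object, segs))
}

# ---- bundle serialization ---------------------------------------------------

#' Save a model bundle to a directory
#'
#' Writes `model.json` (algorithm, hyperparameters, window, selected
#' features, normalization bounds, class weights, threshold, seed, package
#' version) plus `state.rds` holding the opaque fitted classifier state.
#'
#' @param object A `phis_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    version = as.character(utils::packageVersion("phisite")),
    algorithm = object$algorithm,
    hyperparams = object$hyperparams,
    window = object$window,
    selected_features = object$selected_features,
    normalization = if (!is.null(object$normalization))
      as.list(object$normalization),
    encoder_params = object$encoder_params,
    families = object$families,
    class_weights = as.list(object$class_weights),
    threshold = object$threshold,
    seed = object$seed,
    notes = object$notes
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(object, file.path(dir, "state.rds"))
  invisible(dir)
}

#' Load a model bundle saved by [write_model()]
#'
#' @param dir Bundle directory.
#' @return A `phis_model`.
#' @export
read_model <- function(dir) {
  path <- file.path(dir, "state.rds")
  if (!file.exists(path)) abort(paste0("no model bundle in ", dir))
  obj <- readRDS(path)
  if (!inherits(obj, "phis_model")) abort("state.rds is not a phis_model")
  obj
}

#' Evaluate selection sizes and window sizes on a grid
#'
#' The grid protocol of the published workflow: every combination of
#' `k in {5, 10, ..., 150}` and window size in `{21, 25, 31, 35, 41}`,
#' scored by stratified cross-validation.
#'
#' @inheritParams cv_pipeline
#' @param k_grid Selection sizes (default `seq(5, 150, by = 5)`).
#' @param windows Window sizes (default `c(21, 25, 31, 35, 41)`).
#' @return Tibble with one row per (window, k): mean/sd AUC and F1.
#' @export
grid_evaluate <- function(proteins, sites, k_grid = seq(5L, 150L, by = 5L),
                          windows = c(21L, 25L, 31L, 35L, 41L),
                          algorithm = "svm_rbf",
                          families = encoder_families(),
                          encoder_params = list(), folds = 10L,
                          hyperparams = list(), seed = 1L) {
  rows <- list()
  for (w in windows) {
    segs <- extract_segments(sites, proteins, w)
    m <- encode_matrix(segs$segment, families = families,
                       params = encoder_params)
    for (k in k_grid) {
      ev <- cv_evaluate(m, labels = segs$label, k = k,
                        algorithm = algorithm, folds = folds, seed = seed,
                        hyperparams = hyperparams)
      rows[[length(rows) + 1]] <- tibble(
        window = w, k = k, mean_auc = ev$mean_auc, sd_auc = ev$sd_auc,
        mean_f1 = ev$mean_f1, sd_f1 = ev$sd_f1
      )
    }
  }
  bind_rows(rows)
}
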