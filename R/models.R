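# Classifier training and prediction: the five supported algorithms with
# inverse-frequency class weighting where the underlying learner supports it
# (LR, SVM, RF), distance weighting for KNN, and an unweighted two-hidden-
# layer MLP. The production default is the class-weighted RBF-kernel SVM.

#' Supported classification algorithms
#'
#' @return Character vector: `lr`, `knn`, `svm_rbf`, `rf`, `mlp`.
#' @export
algorithms <- function() c("lr", "knn", "svm_rbf", "rf", "mlp")

#' Inverse-frequency ("balanced") class weights
#'
#' \eqn{w_c = n / (2 n_c)} for each class, so the weighted sample mass is
#' equal across classes.
#'
#' @param labels Binary label vector.
#' @return Named numeric vector `c(nonpHis = ..., pHis = ...)`.
#' @export
class_weights <- function(labels) {
  y <- as_binary_labels(labels)
  n <- length(y)
  n1 <- sum(y == 1)
  n0 <- n - n1
  if (n1 == 0 || n0 == 0) abort("class weights need both classes present")
  c(nonpHis = n / (2 * n0), pHis = n / (2 * n1))
}

default_hyperparams <- function(algorithm) {
  switch(algorithm,
    lr = list(nfolds = 5L, maxit = 5000L),
    knn = list(k = 20L, weights = "distance"),
    svm_rbf = list(cost = 1, gamma = NULL, calibration_folds = 5L),
    rf = list(ntree = 100L),
    mlp = list(hidden = c(100L, 50L), alpha = 1e-4, maxit = 1000L,
               init_seed = 1L),
    abort(paste0("unknown algorithm: ", algorithm))
  )
}

# ---- internal fitting --------------------------------------------------------

stratified_folds <- function(y, folds, seed) {
  counts <- table(y)
  if (min(counts) < folds) {
    abort(paste0("minority class has ", min(counts), " samples; use <= ",
                 min(counts), " folds"))
  }
  fold_id <- integer(length(y))
  local_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

fit_classifier <- function(x, y, algorithm, hyperparams = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, algorithms())
  hp <- default_hyperparams(algorithm)
  for (nm in names(hyperparams)) hp[[nm]] <- hyperparams[[nm]]
  if (!all(is.finite(x))) abort("non-finite values in training features")
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) abort("training labels contain a single class")
  notes <- character(0)
  w <- class_weights(y)
  state <- switch(algorithm,
    lr = {
      foldid <- stratified_folds(y, hp$nfolds, seed)
      fit <- withCallingHandlers(
        glmnet::cv.glmnet(
          x, y, family = "binomial", foldid = foldid,
          weights = unname(w[y + 1]), maxit = hp$maxit,
          standardize = FALSE
        ),
        warning = function(wrn) {
          notes <<- c(notes, conditionMessage(wrn))
          invokeRestart("muffleWarning")
        }
      )
      list(fit = fit)
    },
    knn = list(x = x, y = y, k = min(hp$k, nrow(x))),
    svm_rbf = {
      gamma <- hp$gamma
      if (is.null(gamma)) {
        vx <- var(as.vector(x))
        gamma <- if (vx > 0) 1 / (ncol(x) * vx) else 1 / ncol(x)
      }
      yf <- factor(ifelse(y == 1, "pos", "neg"), levels = c("neg", "pos"))
      cw <- c(neg = unname(w["nonpHis"]), pos = unname(w["pHis"]))
      fit <- e1071::svm(x, yf, kernel = "radial", cost = hp$cost,
                        gamma = gamma, class.weights = cw, scale = FALSE)
      # seeded cross-validated sigmoid (Platt) calibration of decision values
      fold_id <- stratified_folds(y, hp$calibration_folds, seed)
      dv_cv <- rep(NA_real_, length(y))
      for (fo in seq_len(hp$calibration_folds)) {
        tr <- fold_id != fo
        sub <- e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = "radial",
                          cost = hp$cost, gamma = gamma, class.weights = cw,
                          scale = FALSE)
        dv_cv[!tr] <- svm_decision(sub, x[!tr, , drop = FALSE])
      }
      sig <- suppressWarnings(
        glm(y ~ dv, data = data.frame(y = y, dv = dv_cv), family = binomial())
      )
      if (!sig$converged) notes <- c(notes, "sigmoid calibration did not converge")
      list(fit = fit, gamma = gamma, sigmoid = unname(coef(sig)))
    },
    rf = {
      yf <- factor(ifelse(y == 1, "pos", "neg"), levels = c("neg", "pos"))
      fit <- local_seed(seed, {
        randomForest::randomForest(
          x, yf, ntree = hp$ntree,
          classwt = c(neg = unname(w["nonpHis"]), pos = unname(w["pHis"]))
        )
      })
      notes <- c(notes, paste0("oob_error=", signif(fit$err.rate[hp$ntree, "OOB"], 4)))
      list(fit = fit)
    },
    mlp = {
      fit <- fit_mlp(x, y, hidden = hp$hidden, alpha = hp$alpha,
                     maxit = hp$maxit, init_seed = hp$init_seed)
      if (!fit$converged) notes <- c(notes, "L-BFGS did not converge within maxit")
      list(fit = fit)
    }
  )
  structure(
    list(algorithm = algorithm, hyperparams = hp, class_weights = w,
         seed = seed, state = state, notes = notes,
         feature_names = colnames(x)),
    class = "phis_classifier"
  )
}

# decision values of an e1071 SVM, oriented so larger = "pos"
svm_decision <- function(fit, x) {
  pr <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  orient <- if (startsWith(colnames(dv)[1], "pos")) 1 else -1
  as.numeric(dv[, 1]) * orient
}

predict_classifier <- function(clf, x) {
  if (!all(clf$feature_names == colnames(x))) {
    x <- x[, clf$feature_names, drop = FALSE]
  }
  switch(clf$algorithm,
    lr = as.numeric(predict(clf$state$fit, x, s = "lambda.min",
                            type = "response")),
    knn = knn_prob(clf$state, x),
    svm_rbf = {
      dv <- svm_decision(clf$state$fit, x)
      ab <- clf$state$sigmoid
      as.numeric(stats::plogis(ab[1] + ab[2] * dv))
    },
    rf = as.numeric(predict(clf$state$fit, x, type = "prob")[, "pos"]),
    mlp = as.numeric(mlp_forward(clf$state$fit$par, x,
                                 clf$state$fit$hidden)$p)
  )
}

# distance-weighted k-nearest-neighbour probability of the positive class
knn_prob <- function(state, xnew) {
  tr <- state$x
  trn2 <- rowSums(tr^2)
  vapply(seq_len(nrow(xnew)), function(i) {
    d2 <- trn2 - 2 * as.numeric(tr %*% xnew[i, ]) + sum(xnew[i, ]^2)
    d2 <- pmax(d2, 0)
    ord <- order(d2)[seq_len(state$k)]
    d <- sqrt(d2[ord])
    if (any(d == 0)) return(mean(state$y[ord[d == 0]]))
    wts <- 1 / d
    sum(wts * state$y[ord]) / sum(wts)
  }, numeric(1))
}

# ---- two-hidden-layer MLP (ReLU, logistic output, L-BFGS) -------------------

mlp_unpack <- function(par, d, hidden) {
  h1 <- hidden[1]; h2 <- hidden[2]
  i <- 0
  W1 <- matrix(par[i + seq_len(d * h1)], d, h1); i <- i + d * h1
  b1 <- par[i + seq_len(h1)]; i <- i + h1
  W2 <- matrix(par[i + seq_len(h1 * h2)], h1, h2); i <- i + h1 * h2
  b2 <- par[i + seq_len(h2)]; i <- i + h2
  W3 <- par[i + seq_len(h2)]; i <- i + h2
  b3 <- par[i + 1]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
}

mlp_forward <- function(par, x, hidden) {
  p <- mlp_unpack(par, ncol(x), hidden)
  z1 <- sweep(x %*% p$W1, 2, p$b1, "+")
  a1 <- pmax(z1, 0)
  z2 <- sweep(a1 %*% p$W2, 2, p$b2, "+")
  a2 <- pmax(z2, 0)
  z3 <- as.numeric(a2 %*% p$W3 + p$b3)
  list(p = stats::plogis(z3), a1 = a1, a2 = a2, z1 = z1, z2 = z2, w = p)
}

mlp_loss_grad <- function(par, x, y, hidden, alpha) {
  n <- nrow(x)
  fw <- mlp_forward(par, x, hidden)
  eps <- 1e-12
  loss <- -mean(y * log(fw$p + eps) + (1 - y) * log(1 - fw$p + eps)) +
    alpha / (2 * n) * (sum(fw$w$W1^2) + sum(fw$w$W2^2) + sum(fw$w$W3^2))
  dz3 <- (fw$p - y) / n
  gW3 <- as.numeric(t(fw$a2) %*% dz3) + alpha / n * fw$w$W3
  gb3 <- sum(dz3)
  da2 <- outer(dz3, fw$w$W3)
  dz2 <- da2 * (fw$z2 > 0)
  gW2 <- t(fw$a1) %*% dz2 + alpha / n * fw$w$W2
  gb2 <- colSums(dz2)
  da1 <- dz2 %*% t(fw$w$W2)
  dz1 <- da1 * (fw$z1 > 0)
  gW1 <- t(x) %*% dz1 + alpha / n * fw$w$W1
  gb1 <- colSums(dz1)
  list(loss = loss,
       grad = c(as.numeric(gW1), gb1, as.numeric(gW2), gb2, gW3, gb3))
}

# multi-layer perceptron with hidden layers (100, 50), ReLU activations,
# logistic output, L2 penalty, fit with L-BFGS from a seeded Glorot init
fit_mlp <- function(x, y, hidden = c(100L, 50L), alpha = 1e-4,
                    maxit = 1000L, init_seed = 1L) {
  d <- ncol(x)
  glorot <- function(fan_in, fan_out, n) {
    b <- sqrt(6 / (fan_in + fan_out))
    runif(n, -b, b)
  }
  par0 <- local_seed(init_seed, c(
    glorot(d, hidden[1], d * hidden[1]), rep(0, hidden[1]),
    glorot(hidden[1], hidden[2], hidden[1] * hidden[2]), rep(0, hidden[2]),
    glorot(hidden[2], 1, hidden[2]), 0
  ))
  opt <- optim(
    par0,
    fn = function(p) mlp_loss_grad(p, x, y, hidden, alpha)$loss,
    gr = function(p) mlp_loss_grad(p, x, y, hidden, alpha)$grad,
    method = "L-BFGS-B",
    control = list(maxit = maxit)
  )
  list(par = opt$par, hidden = hidden, alpha = alpha,
       converged = opt$convergence == 0, value = opt$value)
}

# ---- user-facing model bundle ----------------------------------------------

#' Train a classifier on selected, normalized features
#'
#' Expects features already normalized to \[0,1\] and reduced to the
#' selected subset (the full pipeline in [fit_pipeline()] does this
#' internally). Class weighting is inverse-frequency for LR, SVM and RF;
#' KNN relies on `k = 20` and distance weighting; the MLP is unweighted.
#'
#' @param features Feature tibble (with `label` column) or numeric matrix.
#' @param labels Binary labels; taken from `features$label` when omitted.
#' @param algorithm One of [algorithms()] (default `svm_rbf`).
#' @param hyperparams Named list of overrides (see
#'   `phisite:::default_hyperparams`).
#' @param seed Integer seed controlling every stochastic component.
#' @param threshold Probability threshold for the binary call (default 0.5).
#' @return A `phis_model` object.
#' @export
train_model <- function(features, labels = NULL, algorithm = "svm_rbf",
                        hyperparams = list(), seed = 1L, threshold = 0.5) {
  m <- if (is.matrix(features)) features else feature_matrix(features)
  if (is.null(labels)) {
    if (is.data.frame(features) && "label" %in% names(features)) {
      labels <- features$label
    } else abort("labels must be supplied")
  }
  clf <- fit_classifier(m, labels, algorithm, hyperparams, seed)
  structure(
    list(algorithm = clf$algorithm, hyperparams = clf$hyperparams,
         window = NULL, selected_features = colnames(m),
         normalization = NULL, encoder_params = NULL,
         classifier = clf, class_weights = clf$class_weights,
         threshold = threshold, seed = seed, notes = clf$notes,
         scores = NULL),
    class = "phis_model"
  )
}

#' Predict pHis probabilities with a fitted model
#'
#' Accepts a feature tibble/matrix matching the model's selected features
#' (raw-scale features are normalized with the bundle's frozen bounds when
#' the bundle carries them), or — for a full pipeline bundle — a segment
#' tibble from [extract_segments()], in which case encoding, normalization
#' and feature subsetting are applied internally.
#'
#' @param object A `phis_model`.
#' @param newdata Feature tibble/matrix or segment tibble.
#' @param ... Unused.
#' @return A tibble with `probability` and `call` (factor `nonpHis`/`pHis`),
#'   rows in input order.
#' @export
predict.phis_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata) && "segment" %in% names(newdata)) {
    if (is.null(object$window)) {
      abort("model was trained on a bare feature matrix; supply features")
    }
    w <- unique(nchar(newdata$segment))
    if (length(w) != 1 || w != object$window) {
      abort(paste0("window mismatch: model expects ", object$window,
                   ", got ", paste(w, collapse = "/")))
    }
    enc <- encode_segments(newdata, params = object$encoder_params %||% list(),
                           feature_subset = object$normalization$feature)
    m <- apply_normalizer(feature_matrix(enc), object$normalization)
    m <- m[, object$selected_features, drop = FALSE]
  } else {
    m <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
    missing <- setdiff(object$selected_features, colnames(m))
    if (length(missing) > 0) {
      abort(paste0("unknown/missing feature name(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[, object$selected_features, drop = FALSE]
    if (!is.null(object$normalization)) {
      b <- object$normalization
      b <- b[match(object$selected_features, b$feature), ]
      m <- scale_min_max(m, b$min, b$max)
    }
  }
  prob <- predict_classifier(object$classifier, m)
  # threshold semantics match threshold_sweep(): >= t, strict > at t = 1
  pos <- if (object$threshold >= 1) prob > 1 else prob >= object$threshold
  tibble(
    probability = prob,
    call = factor(ifelse(pos, "pHis", "nonpHis"),
                  levels = c("nonpHis", "pHis"))
  )
}

#' @export
print.phis_model <- function(x, ...) {
  cat("phis_model:", x$algorithm, "\n")
  if (!is.null(x$window)) cat("  window:", x$window, "\n")
  cat("  selected features:", length(x$selected_features), "\n")
  cat("  class weights:", paste(sprintf("%s=%.3f", names(x$class_weights),
                                        x$class_weights), collapse = ", "), "\n")
  cat("  threshold:", x$threshold, " seed:", x$seed, "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
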