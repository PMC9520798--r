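test_that("confusion metrics reproduce hand-derived values", {
  perfect <- metrics_from_confusion(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(unlist(perfect[1, c("recall", "precision", "f1", "accuracy",
                                   "mcc", "specificity")]),
               c(recall = 1, precision = 1, f1 = 1, accuracy = 1, mcc = 1,
                 specificity = 1))
  m <- metrics_from_confusion(tp = 30, fn = 20, tn = 40, fp = 10)
  expect_equal(m$recall, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$f1, 2 * 0.6 * 0.75 / 1.35, tolerance = 1e-12)
  expect_equal(m$mcc, (30 * 40 - 10 * 20) / sqrt(40 * 60 * 50 * 50),
               tolerance = 1e-12)
  degen <- metrics_from_confusion(tp = 0, fp = 0, tn = 10, fn = 5)
  expect_equal(degen$precision, 0)
  expect_true(degen$degenerate)
})

test_that("confusion metrics agree with direct-formula recomputation on random tables", {
  withr::with_seed(77, {
    for (i in 1:1000) {
      cc <- as.list(sample(0:30, 4, replace = TRUE))
      names(cc) <- c("tp", "tn", "fp", "fn")
      m <- metrics_from_confusion(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn)
      sdiv <- function(a, b) if (b == 0) 0 else a / b
      expect_equal(m$specificity, sdiv(cc$tn, cc$tn + cc$fp))
      expect_equal(m$recall, sdiv(cc$tp, cc$tp + cc$fn))
      expect_equal(m$precision, sdiv(cc$tp, cc$tp + cc$fp))
      expect_equal(m$accuracy, sdiv(cc$tp + cc$tn, Reduce(`+`, cc)))
      den <- sqrt(cc$tp + cc$fp) * sqrt(cc$tn + cc$fn) *
        sqrt(cc$tp + cc$fn) * sqrt(cc$tn + cc$fp)
      expect_equal(m$mcc, if (den == 0) 0 else
        (cc$tp * cc$tn - cc$fp * cc$fn) / den, tolerance = 1e-12)
    }
  })
})

test_that("trapezoid AUC equals pairwise concordance and matches pROC", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  withr::with_seed(19, {
    for (i in 1:20) {
      n <- 150
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      s <- round(runif(n), 2) # coarse scores force ties
      a <- auc_score(s, y)
      pos <- s[y == 1]; neg <- s[y == 0]
      conc <- 0
      for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
      expect_equal(a, conc / (length(pos) * length(neg)), tolerance = 1e-9)
      expect_equal(a, as.numeric(pROC::auc(pROC::roc(
        y, s, quiet = TRUE, direction = "<", levels = c(0, 1)
      ))), tolerance = 1e-9)
    }
  })
})

test_that("AUC of label-independent scores is near one half", {
  withr::with_seed(23, {
    y <- rep(c(0, 1), each = 1000)
    s <- runif(2000)
    expect_gt(auc_score(s, y), 0.47)
    expect_lt(auc_score(s, y), 0.53)
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(29, {
    y <- rbinom(100, 1, 0.3)
    s <- rnorm(100)
    a <- auc_score(s, y)
    expect_equal(auc_score(plogis(s), y), a, tolerance = 1e-12)
    expect_equal(auc_score(exp(2 * s) + 1, y), a, tolerance = 1e-12)
  })
})

test_that("ROC curves span (0,0) to (1,1)", {
  withr::with_seed(31, {
    cur <- roc_pr(runif(50), rbinom(50, 1, 0.5))
    expect_equal(cur$roc$fpr[1], 0)
    expect_equal(cur$roc$tpr[1], 0)
    expect_equal(cur$roc$fpr[nrow(cur$roc)], 1)
    expect_equal(cur$roc$tpr[nrow(cur$roc)], 1)
  })
  expect_error(roc_pr(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("threshold sweep honors the >= convention with monotone recall/specificity", {
  withr::with_seed(37, {
    s <- runif(200)
    y <- rbinom(200, 1, 0.3)
    tab <- threshold_sweep(s, y, grid = seq(0, 1, by = 0.1))
    expect_equal(tab$recall[tab$threshold == 0], 1)
    expect_equal(tab$specificity[tab$threshold == 0], 0)
    expect_equal(tab$recall[tab$threshold == 1], 0)
    expect_equal(tab$specificity[tab$threshold == 1], 1)
    expect_true(all(diff(tab$recall) <= 0))
    expect_true(all(diff(tab$specificity) >= 0))
  })
  expect_error(threshold_sweep(runif(5), rbinom(5, 1, 0.5), grid = numeric(0)),
               "empty")
})

test_that("cross-validation folds are balanced and stratified", {
  d <- withr::with_seed(41, {
    y <- rep(c(0, 1), times = c(160, 40))
    x <- matrix(rnorm(200 * 20), 200, 20)
    colnames(x) <- paste0("f", 1:20)
    list(x = x, y = y)
  })
  ev <- cv_evaluate(d$x, d$y, k = 10, algorithm = "lr", folds = 10, seed = 2)
  expect_equal(nrow(ev$per_fold), 10)
  expect_lte(diff(range(ev$per_fold$n_test)), 1)
  expect_lte(diff(range(ev$per_fold$n_pos_test)), 1)
  expect_true(all(!is.na(ev$scores$probability)))
  expect_error(cv_evaluate(d$x, rep(c(0, 1), times = c(195, 5)), k = 5,
                           folds = 10, seed = 1), "folds")
})

test_that("per-fold refitting avoids the selection-leak optimism of the leaky path", {
  d <- withr::with_seed(43, {
    y <- rep(c(0, 1), each = 60)
    x <- matrix(rnorm(120 * 800), 120, 800)
    colnames(x) <- sprintf("n%03d", 1:800)
    list(x = x, y = y)
  })
  clean <- cv_evaluate(d$x, d$y, k = 40, algorithm = "lr", folds = 10, seed = 3)
  leaky <- cv_evaluate(d$x, d$y, k = 40, algorithm = "lr", folds = 10, seed = 3,
                       leaky = TRUE)
  expect_lt(clean$mean_auc, 0.62)
  expect_gt(leaky$mean_auc, clean$mean_auc + 0.05)
})
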