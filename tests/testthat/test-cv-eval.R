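test_that("fold sizes and stratification match the design", {
  y <- c(rep(1L, 99), rep(0L, 24))
  f <- make_folds(y, k = 5, seed = 3)
  expect_equal(sort(as.vector(table(f)), decreasing = TRUE), c(25, 25, 25, 24, 24))
  # minority spread: 24 negatives over 5 folds -> 4 or 5 per fold
  expect_true(all(table(f[y == 0]) %in% 4:5))
  # every sample in exactly one fold
  expect_length(f, 123)
  expect_setequal(unique(f), 1:5)
  # balanced toy case: one of each class per fold
  yb <- rep(0:1, 5)
  fb <- make_folds(yb, k = 5, seed = 1)
  expect_true(all(table(fb, yb) == 1))
  # determinism
  expect_identical(make_folds(y, 5, seed = 9), make_folds(y, 5, seed = 9))
  expect_warning(make_folds(c(1, rep(0, 9)), k = 5, seed = 1), "fewer")
})

test_that("confusion-derived metrics match hand calculations", {
  m <- classification_metrics(list(TP = 9, FN = 1, TN = 4, FP = 1))
  expect_equal(unname(m["TER"]), 2 / 15)
  expect_equal(unname(m["FNR"]), 0.1)
  expect_equal(unname(m["FPR"]), 0.2)
  expect_equal(unname(m["TPR"]), 0.9)
  expect_equal(unname(m["TNR"]), 0.8)
  perfect <- classification_metrics(list(TP = 9, FN = 0, TN = 4, FP = 0))
  expect_equal(unname(perfect[c("TER", "FPR", "FNR")]), c(0, 0, 0))
  inverted <- classification_metrics(confusion_counts(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(unname(inverted[c("TPR", "TNR")]), c(0, 0))
  expect_error(classification_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "empty")
})

test_that("metric identities TPR = 1 - FNR and TNR = 1 - FPR always hold", {
  set.seed(77)
  for (i in 1:50) {
    truth <- sample(0:1, 30, replace = TRUE, prob = c(0.3, 0.7))
    pred <- sample(0:1, 30, replace = TRUE)
    if (length(unique(truth)) < 2) next
    m <- classification_metrics(confusion_counts(truth, pred))
    expect_equal(unname(m["TPR"]), unname(1 - m["FNR"]))
    expect_equal(unname(m["TNR"]), unname(1 - m["FPR"]))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("AUC equals the trapezoidal ROC oracle on random instances with ties", {
  expect_equal(auc_mann_whitney(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc_mann_whitney(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  # enumerated pair example: 5 of 6 positive-negative pairs concordant
  expect_equal(auc_mann_whitney(c(1, 1, 0, 0, 0), c(0.9, 0.4, 0.6, 0.3, 0.2)),
               5 / 6)
  set.seed(123)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    # coarse scores guarantee plenty of ties
    s <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    expect_equal(auc_mann_whitney(y, s), roc_trapezoid_auc(y, s),
                 tolerance = 1e-12)
  }
  expect_true(is.na(auc_mann_whitney(rep(1, 4), runif(4))))
})

test_that("AUC agrees with pROC and is invariant to monotone rescaling", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- sample(0:1, 40, replace = TRUE)
  y[1:2] <- 0:1
  s <- rnorm(40)
  ours <- auc_mann_whitney(y, s)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(auc_mann_whitney(y, exp(3 * s)), ours, tolerance = 1e-12)
})

test_that("tuning returns the dominant grid point and honours tie preference", {
  qc <- default_qc()
  X <- qc$genotypes$dosage
  y <- true_labels()
  # single-point grid short-circuits
  one <- tune_hyperparameters(X, y, "knn", data.frame(K = 3, weighting = "uniform"),
                              seed = 1)
  expect_equal(one$hyper$K, 3)
  # on the clean separable fixture KNN picks a K from the study grid
  tuned <- tune_hyperparameters(X, y, "knn", default_grid("knn"), seed = 2)
  expect_true(tuned$hyper$K %in% c(1, 3, 5, 7))
  # argmax of the inner AUC is what gets returned
  grid2 <- data.frame(K = c(1L, 7L), weighting = "uniform")
  idx <- c(1:20, 104:123)
  t2 <- tune_hyperparameters(X[idx, ], y[idx], "knn", grid2, seed = 3)
  expect_true(t2$hyper$K %in% grid2$K)
  expect_equal(which.max(t2$inner_auc), match(t2$hyper$K, grid2$K))
})

test_that("SVM warm-started grid evaluation equals cold-start evaluation", {
  idx <- c(1:46, 100:123)
  X <- qc_dosage()[idx, ]
  y <- flip_labels(true_labels()[idx], 0.3, seed = 4)$labels
  grid <- expand.grid(C = c(4, 64, 512), gamma = c(0.001, 0.1))[, c("C", "gamma")]
  folds <- make_folds(y, 5, seed = 6)
  warm <- snpnoise:::svm_grid_auc(X, y, "svm_rbf", grid, folds, 5)
  cold <- matrix(NA_real_, nrow(grid), 5)
  for (g in seq_len(nrow(grid))) for (f in 1:5) {
    tr <- folds != f
    m <- fit_model("svm_rbf", X[tr, ], y[tr], grid[g, , drop = FALSE])
    cold[g, f] <- auc_mann_whitney(y[!tr], score_model(m, X[!tr, ]))
  }
  expect_equal(warm, cold, tolerance = 1e-6)
})

test_that("a replicate validates every sample once and is seed-deterministic", {
  X <- qc_dosage()
  y <- true_labels()
  r1 <- run_replicate(X, y, "knn", p = 0.1, seed = 31)
  r2 <- run_replicate(X, y, "knn", p = 0.1, seed = 31)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 5)
  # the union of validation folds is the full sample set
  folds <- make_folds(flip_labels(y, 0.1, seed = child_seed(31, 1))$labels,
                      5, seed = child_seed(31, 2))
  expect_setequal(unlist(lapply(1:5, function(f) which(folds == f))), 1:123)
  # clean separable fixture: KNN perfect in every fold
  r0 <- run_replicate(X, y, "knn", p = 0, seed = 8)
  expect_equal(r0$TER, rep(0, 5))
  expect_equal(r0$AUC, rep(1, 5))
})

test_that("TER from metrics equals direct recount of errors", {
  X <- qc_dosage()
  y <- true_labels()
  set.seed(9)
  tr <- sample(123, 90)
  m <- fit_model("knn", X[tr, ], y[tr], list(K = 5, weighting = "inverse"))
  pred <- predict_label(m, X[-tr, ])
  met <- classification_metrics(confusion_counts(y[-tr], pred))
  expect_equal(unname(met["TER"]), mean(pred != y[-tr]))
})

test_that("aggregation reduces records to per-cell means and SDs", {
  rec <- data.frame(replicate = rep(1:100, each = 5), fold = rep(1:5, 100),
                    p = 0.1, family = "knn", hyper = "K=3",
                    TER = 0.2, FPR = 0.1, FNR = 0.3, TPR = 0.7, TNR = 0.9,
                    AUC = 0.8, min_freq = 0.25)
  agg <- aggregate_records(rec)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$n_records, 500)
  expect_equal(agg$TER, 0.2)
  expect_equal(agg$TER_sd, 0)
  expect_equal(agg$AUC, 0.8)
  # mean bounded by min/max of the records
  rec2 <- rec
  rec2$AUC <- runif(500)
  agg2 <- aggregate_records(rec2)
  expect_gte(agg2$AUC, min(rec2$AUC))
  expect_lte(agg2$AUC, max(rec2$AUC))
})
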