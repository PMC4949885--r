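test_that("euclidean distance matches hand values and the scaled identity", {
  expect_equal(euclidean_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(2, 1)), sqrt(5))
  expect_error(euclidean_distance(c(0, 0), c(1, 1, 1)), "length")
  # scaled = unscaled / (2 sqrt(m)), always in [0, 1] for dosage vectors
  for (s in 1:20) {
    m <- with_seed(s, sample(3:30, 1))
    a <- rand_dosage(1, m, seed = s)[1, ]
    b <- rand_dosage(1, m, seed = s + 100)[1, ]
    ds <- euclidean_distance(a, b, scaled = TRUE)
    expect_equal(ds, euclidean_distance(a, b) / (2 * sqrt(m)))
    expect_gte(ds, 0)
    expect_lte(ds, 1)
  }
})

test_that("KNN scores agree with the brute-force oracle on random instances", {
  set.seed(404)
  for (case in 1:100) {
    n <- sample(5:20, 1)
    m <- sample(2:12, 1)
    Xtr <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    ytr <- sample(0:1, n, replace = TRUE)
    x0 <- sample(0:2, m, replace = TRUE)
    K <- sample(seq_len(min(n, 7)), 1)
    wgt <- sample(c("uniform", "inverse", "reciprocal"), 1)
    model <- fit_model("knn", Xtr, ytr, list(K = K, weighting = wgt))
    expect_equal(score_model(model, matrix(x0, 1)),
                 knn_oracle(Xtr, ytr, x0, K, wgt),
                 tolerance = 1e-12,
                 label = sprintf("case %d (K=%d, %s)", case, K, wgt))
  }
})

test_that("KNN exact matches dominate reciprocal weighting and ties go positive", {
  Xtr <- rbind(c(0, 0), c(0, 0), c(2, 2))
  m <- fit_model("knn", Xtr, c(1, 0, 1), list(K = 3, weighting = "reciprocal"))
  # query equal to two training points with labels {1, 0}: vote 0.5 -> label 1
  expect_equal(score_model(m, matrix(c(0, 0), 1)), 0.5)
  expect_equal(predict_label(m, matrix(c(0, 0), 1)), 1L)
  # plain 1-NN
  m1 <- fit_model("knn", rbind(c(0, 0), c(2, 2)), c(0, 1),
                  list(K = 1, weighting = "uniform"))
  expect_equal(score_model(m1, rbind(c(0, 0))), 0)
  expect_equal(predict_label(m1, rbind(c(0, 0))), 0L)
})

test_that("ridge logistic regression maximises the penalised likelihood", {
  # optimum not beaten on a surrounding finite-difference grid
  set.seed(11)
  X <- matrix(sample(0:2, 6 * 2, replace = TRUE), 6, 2)
  y <- c(0, 1, 0, 1, 1, 0)
  lam <- 0.5
  fit <- ridge_logistic_fit(X, y, lam)
  expect_true(fit$converged)
  ll_opt <- snpnoise:::ridge_logistic_loglik(X, y, fit$mu, fit$beta, lam)
  for (dmu in c(-0.05, 0, 0.05)) for (d1 in c(-0.05, 0, 0.05))
    for (d2 in c(-0.05, 0, 0.05)) {
      ll <- snpnoise:::ridge_logistic_loglik(X, y, fit$mu + dmu,
                                             fit$beta + c(d1, d2), lam)
      expect_lte(ll, ll_opt + 1e-10)
    }
})

test_that("ridge LR coefficients shrink with lambda and limit to the base rate", {
  idx <- c(1:40, 104:123) # both vigor classes represented
  X <- qc_dosage()[idx, ]
  y <- true_labels()[idx]
  norms <- sapply(c(0.1, 1, 10, 100), function(l)
    sqrt(sum(ridge_logistic_fit(X, y, l)$beta^2)))
  expect_true(all(diff(norms) < 0))
  big <- fit_model("lr", X, y, list(lambda = 1e8))
  expect_equal(unname(score_model(big, X[1:5, ])), rep(mean(y), 5),
               tolerance = 1e-3)
})

test_that("dual and primal ridge LR Newton routes coincide", {
  # p > n triggers the row-space solver; compare with the primal route on
  # the transposable case p < n by padding
  idx <- c(1:20, 104:123)
  X <- qc_dosage()[idx, 1:60]   # p 60 > n 40 -> dual route
  y <- true_labels()[idx]
  f_dual <- ridge_logistic_fit(X, y, 3)
  # primal reference: direct Newton in (mu, beta) using the generic branch
  Xa <- cbind(1, X)
  beta <- numeric(61)
  for (i in 1:100) {
    pr <- stats::plogis(as.vector(Xa %*% beta))
    g <- as.vector(crossprod(Xa, y - pr)) - c(0, rep(3, 60)) * beta
    if (max(abs(g)) <= 1e-8) break
    w <- pmax(pr * (1 - pr), 1e-10)
    H <- crossprod(Xa * w, Xa)
    diag(H) <- diag(H) + c(0, rep(3, 60))
    beta <- beta + solve(H, g)
  }
  expect_equal(f_dual$mu, unname(beta[1]), tolerance = 1e-6)
  expect_equal(f_dual$beta, unname(beta[-1]), tolerance = 1e-6)
})

test_that("separable data is fit perfectly by LR and linear SVM", {
  qc <- default_qc()
  X <- qc$genotypes$dosage
  y <- true_labels()
  m <- fit_model("lr", X, y, list(lambda = 0.01))
  expect_equal(predict_label(m, X), y)
  s <- fit_model("svm_lin", X, y, list(C = 256))
  expect_equal(predict_label(s, X), y)
})

test_that("lambda = 0 is rejected in the high-dimensional regime", {
  X <- qc_dosage()[c(1:15, 109:123), ]
  expect_error(ridge_logistic_fit(X, true_labels()[c(1:15, 109:123)], 0), "lambda")
})

test_that("random forest votes are vote fractions and reproducible", {
  idx <- c(1:40, 104:123)
  X <- qc_dosage()[idx, ]
  y <- true_labels()[idx]
  m <- fit_model("rf", X, y, list(B = 25, m = 8), seed = 9)
  s <- score_model(m, X[1:20, ])
  expect_true(all(s %in% ((0:25) / 25)))
  m2 <- fit_model("rf", X, y, list(B = 25, m = 8), seed = 9)
  expect_equal(score_model(m2, X[1:20, ]), s)
  expect_error(fit_model("rf", X, y, list(B = 5, m = 999)), "m exceeds")
  # RF grid: j = int(log2(175) + 1) = 8
  g <- default_grid("rf", n_markers = 175)
  expect_setequal(unique(g$B), c(1, 5, 10, 50, 100))
  expect_setequal(unique(g$m), c(2, 4, 8))
})

test_that("SVM decision values match the reference libsvm implementation", {
  skip_if_not_installed("e1071")
  idx <- c(1:60, 104:123)
  X <- qc_dosage()[idx, ]
  y <- flip_labels(true_labels()[idx], 0.2, seed = 3)$labels
  Xte <- qc_dosage()[61:103, ]
  for (case in list(list("svm_lin", "linear", 4, 1),
                    list("svm_lin", "linear", 256, 1),
                    list("svm_rbf", "radial", 16, 0.01),
                    list("svm_rbf", "radial", 512, 1))) {
    m1 <- fit_model(case[[1]], X, y, list(C = case[[3]], gamma = case[[4]]))
    s1 <- score_model(m1, Xte)
    ref <- e1071::svm(x = X, y = factor(y, levels = 0:1),
                      type = "C-classification", kernel = case[[2]],
                      cost = case[[3]], gamma = case[[4]], scale = FALSE)
    pr <- predict(ref, Xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    s2 <- if (strsplit(colnames(dv), "/")[[1]][1] == "1") as.vector(dv)
          else -as.vector(dv)
    expect_equal(s1, s2, tolerance = 0.01)
    expect_equal(as.integer(s1 >= 0), as.integer(s2 >= 0))
  }
})

test_that("SVM toy geometry: separation, kernel limits, XOR", {
  # two well-separated points, linear kernel
  m <- fit_model("svm_lin", rbind(c(0, 0), c(2, 2)), c(0, 1), list(C = 512))
  s <- score_model(m, rbind(c(0, 0), c(2, 2)))
  expect_lt(s[1], 0)
  expect_gt(s[2], 0)
  # gamma -> 0: constant kernel, decision driven by class balance
  Xb <- rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2), c(1, 1), c(1, 0))
  yb <- c(1, 1, 1, 1, 0, 0)
  m0 <- fit_model("svm_rbf", Xb, yb, list(C = 4, gamma = 1e-8))
  expect_true(all(predict_label(m0, rbind(c(9, 9), c(0, 1))) == 1))
  # XOR: linear fails, rbf succeeds
  Xx <- rbind(c(0, 0), c(2, 2), c(0, 2), c(2, 0))
  yx <- c(1, 1, 0, 0)
  lin <- fit_model("svm_lin", Xx, yx, list(C = 512))
  expect_gt(sum(predict_label(lin, Xx) != yx), 0)
  rbf <- fit_model("svm_rbf", Xx, yx, list(C = 512, gamma = 1))
  expect_equal(predict_label(rbf, Xx), yx)
})

test_that("single-class training folds produce a constant scorer", {
  X <- rand_dosage(8, 4, seed = 5)
  for (fam in model_families()) {
    m <- fit_model(fam, X, rep(1L, 8), list(K = 1, weighting = "uniform",
                                            B = 3, m = 2, lambda = 1, C = 4,
                                            gamma = 0.1), seed = 1)
    expect_equal(predict_label(m, X[1:3, ]), rep(1L, 3))
  }
})

test_that("hyperparameter grids match the study design", {
  g <- default_grid("knn")
  expect_equal(sort(unique(g$K)), c(1, 3, 5, 7))
  expect_setequal(unique(g$weighting), c("uniform", "inverse", "reciprocal"))
  expect_equal(nrow(g), 12)
  expect_equal(default_grid("svm_lin")$C, 2^(2:9))
  gr <- default_grid("svm_rbf")
  expect_equal(sort(unique(gr$gamma)), 10^(-3:1))
  expect_equal(nrow(gr), 40)
  expect_equal(default_grid("lr")$lambda, 10^(3:-3))
})
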