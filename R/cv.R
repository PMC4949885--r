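#' Stratified k-fold assignment
#'
#' Assigns each sample to exactly one validation fold. Under stratification
#' (the default) samples are shuffled within class and dealt to the
#' currently smallest fold, so fold sizes differ by at most one and each
#' fold's class proportions differ from the global ones by at most one
#' sample; 123 samples in 5 folds gives sizes \{25, 25, 25, 24, 24\}.
#'
#' @param labels 0/1 labels (used only when \code{stratified}).
#' @param k Number of folds, 2 <= k <= n.
#' @param seed Integer seed.
#' @param stratified Keep class proportions balanced across folds (default).
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
make_folds <- function(labels, k = 5L, seed = NULL, stratified = TRUE) {
  n <- length(labels)
  stopifnot(k >= 2, k <= n)
  if (stratified && min(table(labels)) < k)
    warning("a class has fewer members than folds; best-effort stratification")
  with_seed(seed, {
    fold <- integer(n)
    sizes <- integer(k)
    groups <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
    # deal larger classes first so small classes land on the lighter folds
    groups <- groups[order(-lengths(groups))]
    for (idx in groups) {
      for (i in sample(idx, length(idx))) {
        f <- which.min(sizes) # ties -> lowest fold index
        fold[i] <- f
        sizes[f] <- sizes[f] + 1L
      }
    }
    fold
  })
}

#' Confusion counts and the derived error rates
#'
#' The positive class is high vigor (label 1, the majority class). TER is
#' the total error rate (FP + FN) / n; FNR = FN / (TP + FN) and
#' FPR = FP / (FP + TN), with TPR = 1 - FNR and TNR = 1 - FPR.
#'
#' @param truth 0/1 true labels.
#' @param predicted 0/1 predicted labels.
#' @return \code{confusion_counts}: list(TP, FP, TN, FN).
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  list(TP = sum(truth == 1 & predicted == 1),
       FP = sum(truth == 0 & predicted == 1),
       TN = sum(truth == 0 & predicted == 0),
       FN = sum(truth == 1 & predicted == 0))
}

#' @rdname confusion_counts
#' @param counts A list with TP, FP, TN, FN.
#' @return \code{classification_metrics}: named vector TER, FPR, FNR, TPR,
#'   TNR (\code{NaN} where a class is absent from the validated samples).
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    n <- TP + FP + TN + FN
    if (n == 0) stop("empty confusion counts")
    fnr <- FN / (TP + FN)
    fpr <- FP / (FP + TN)
    c(TER = (FP + FN) / n, FPR = fpr, FNR = fnr, TPR = 1 - fnr, TNR = 1 - fpr)
  })
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC = (concordant pairs + tied pairs / 2) / (n_pos * n_neg), computed via
#' midranks; identical to the trapezoidal area under the ROC curve,
#' including under tied scores.
#'
#' @param y_true 0/1 labels with both classes present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in [0, 1], or \code{NA} (with a message attribute) when only
#'   one class is present.
#' @export
auc_mann_whitney <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0)
    return(structure(NA_real_, reason = "single-class validation set"))
  r <- rank(scores) # midranks handle ties as half-concordant
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Select hyperparameters by nested cross-validation
#'
#' For every grid point, runs an inner stratified k-fold CV on the (noisy)
#' training labels — the truth is unavailable at tuning time — and scores
#' mean validation AUC; the grid point with the highest mean inner AUC wins,
#' ties going to the earlier (simpler) grid row. Inner folds are fixed
#' across grid points. Degenerate inner folds (single-class validation) are
#' skipped; if every fold is degenerate for all grid points the grid
#' midpoint is returned with a warning.
#'
#' @param X Training feature matrix.
#' @param y Training (noisy) 0/1 labels.
#' @param family Classifier family.
#' @param grid Data frame of candidate hyperparameters (one row each).
#' @param seed Integer seed (inner fold assignment and stochastic fits).
#' @param inner_k Inner fold count (default 5).
#' @return List: \code{hyper} (chosen row as a list), \code{inner_auc}
#'   (mean inner AUC per grid row).
#' @export
tune_hyperparameters <- function(X, y, family, grid, seed = NULL,
                                 inner_k = 5L) {
  stopifnot(nrow(grid) >= 1)
  if (nrow(grid) == 1)
    return(list(hyper = as.list(grid[1, , drop = FALSE]), inner_auc = NA_real_))
  folds <- suppressWarnings(
    make_folds(y, k = inner_k, seed = child_seed(seed, 11L), stratified = TRUE))
  aucs <- if (family %in% c("svm_lin", "svm_rbf"))
    svm_grid_auc(X, y, family, grid, folds, inner_k)
  else if (family == "knn")
    knn_grid_auc(X, y, grid, folds, inner_k)
  else {
    out <- matrix(NA_real_, nrow(grid), inner_k)
    for (g in seq_len(nrow(grid))) {
      for (f in seq_len(inner_k)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
        model <- fit_model(family, X[tr, , drop = FALSE], y[tr],
                           grid[g, , drop = FALSE],
                           seed = child_seed(seed, 13L, g, f))
        out[g, f] <- auc_mann_whitney(y[!tr],
                                      score_model(model, X[!tr, , drop = FALSE]))
      }
    }
    out
  }
  mean_auc <- apply(aucs, 1, function(a)
    if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE))
  if (all(is.na(mean_auc))) {
    warning("all inner folds degenerate; falling back to the grid midpoint")
    best <- ceiling(nrow(grid) / 2)
  } else {
    best <- which.max(mean_auc) # first max = simplest on ties
  }
  list(hyper = as.list(grid[best, , drop = FALSE]), inner_auc = mean_auc)
}

# Inner-CV AUC for the KNN grid, sharing the validation-to-training distance
# matrix across all (K, weighting) combinations within a fold.
knn_grid_auc <- function(X, y, grid, folds, inner_k) {
  aucs <- matrix(NA_real_, nrow(grid), inner_k)
  for (f in seq_len(inner_k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
    D <- scaled_dist_matrix(X[!tr, , drop = FALSE], X[tr, , drop = FALSE])
    for (g in seq_len(nrow(grid)))
      aucs[g, f] <- auc_mann_whitney(
        y[!tr], apply_knn_votes(D, y[tr], grid$K[g], grid$weighting[g]))
  }
  aucs
}

# Inner-CV AUC for the SVM grids, sharing the kernel matrix per (fold, gamma)
# and warm-starting the dual solver along the ascending C path. The solutions
# match cold starts to the solver's KKT tolerance; this only removes
# redundant work.
svm_grid_auc <- function(X, y, family, grid, folds, inner_k) {
  kernel <- if (family == "svm_lin") "linear" else "rbf"
  aucs <- matrix(NA_real_, nrow(grid), inner_k)
  gammas <- if (kernel == "rbf") unique(grid$gamma) else NA_real_
  for (f in seq_len(inner_k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
    Xtr <- X[tr, , drop = FALSE]
    Xva <- X[!tr, , drop = FALSE]
    ypm <- as.integer(2L * y[tr] - 1L)
    yva <- y[!tr]
    for (g in gammas) {
      rows <- if (kernel == "rbf") which(grid$gamma == g) else seq_len(nrow(grid))
      rows <- rows[order(grid$C[rows])]
      Ktr <- kernel_matrix(Xtr, Xtr, kernel, g)
      Kva <- kernel_matrix(Xva, Xtr, kernel, g)
      alpha <- numeric(0)
      for (r in rows) {
        sol <- .smo_csvc(Ktr, ypm, grid$C[r], tol = 1e-3, alpha0 = alpha)
        alpha <- sol$alpha
        scores <- as.vector(Kva %*% (alpha * ypm)) - sol$rho
        aucs[r, f] <- auc_mann_whitney(yva, scores)
      }
    }
  }
  aucs
}

#' Run one noise replicate of nested cross-validation
#'
#' One replicate = flip a fraction \code{p} of the true labels once, split
#' the samples into \code{k} stratified outer folds, and for each fold:
#' tune hyperparameters by inner CV on the noisy training labels, refit on
#' the full outer-training partition, score the held-out samples, and
#' evaluate TER/FPR/FNR/TPR/TNR/AUC against the \emph{original} (true)
#' labels.
#'
#' @param X QC'd feature matrix (samples x markers).
#' @param y_true Original 0/1 labels.
#' @param family Classifier family.
#' @param p Mislabel proportion in [0, 0.5].
#' @param seed Integer seed for this replicate (flips, folds, fits).
#' @param grid Hyperparameter grid (default \code{\link{default_grid}}).
#' @param k Outer fold count (default 5).
#' @param inner_k Inner fold count (default 5).
#' @param replicate Replicate id recorded in the output.
#' @param stratified Stratify the outer folds (default) on the noisy labels.
#' @param flip_scope \code{"replicate"} (default): labels are flipped once
#'   over the full sample before fold splitting; \code{"training"}: flipped
#'   independently within each outer-training partition.
#' @return Data frame with one row per outer fold: fold, chosen
#'   hyperparameters, the derived metrics and AUC, and the realized
#'   frequency of the original minority class among the noisy labels
#'   (which drifts toward 0.5 as p grows and can exceed it in a single
#'   realization).
#' @export
run_replicate <- function(X, y_true, family, p, seed, grid = NULL,
                          k = 5L, inner_k = 5L, replicate = 1L,
                          stratified = TRUE, flip_scope = c("replicate", "training")) {
  family <- match.arg(family, model_families())
  flip_scope <- match.arg(flip_scope)
  X <- as.matrix(X)
  if (is.null(grid)) grid <- default_grid(family, n_markers = ncol(X))
  flip <- flip_labels(y_true, p, seed = child_seed(seed, 1L))
  y_noisy <- flip$labels
  # realized frequency of the original minority class after flipping
  # (may exceed 0.5 in a single realization at high noise)
  minority <- if (mean(y_true) >= 0.5) 0 else 1
  min_freq <- mean(y_noisy == minority)
  folds <- suppressWarnings(
    make_folds(y_noisy, k = k, seed = child_seed(seed, 2L),
               stratified = stratified))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    ytr <- if (flip_scope == "replicate") y_noisy[tr] else
      flip_labels(y_true[tr], p, seed = child_seed(seed, 3L, f))$labels
    tuned <- tune_hyperparameters(X[tr, , drop = FALSE], ytr, family, grid,
                                  seed = child_seed(seed, 4L, f),
                                  inner_k = inner_k)
    model <- fit_model(family, X[tr, , drop = FALSE], ytr, tuned$hyper,
                       seed = child_seed(seed, 5L, f))
    scores <- score_model(model, X[!tr, , drop = FALSE])
    pred <- predict_label(model, X[!tr, , drop = FALSE])
    met <- classification_metrics(confusion_counts(y_true[!tr], pred))
    auc <- auc_mann_whitney(y_true[!tr], scores)
    rows[[f]] <- data.frame(
      replicate = replicate, fold = f, p = p, family = family,
      hyper = paste(names(tuned$hyper), unlist(tuned$hyper),
                    sep = "=", collapse = ";"),
      TER = met[["TER"]], FPR = met[["FPR"]], FNR = met[["FNR"]],
      TPR = met[["TPR"]], TNR = met[["TNR"]], AUC = as.numeric(auc),
      min_freq = min_freq,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Aggregate per-fold metric records into a summary table
#'
#' Groups the per-fold records by model family and mislabel proportion and
#' reports the mean and SD of each metric over all fold-level replicates
#' (100 repeats x 5 folds = 500 records per cell in the full design),
#' together with the realized minority frequency.
#'
#' @param records Data frame of rows produced by \code{\link{run_replicate}}.
#' @return Data frame with one row per (family, p) cell.
#' @export
aggregate_records <- function(records) {
  stopifnot(nrow(records) > 0)
  cells <- split(records, list(records$family, records$p), drop = TRUE)
  out <- lapply(cells, function(d) {
    data.frame(
      family = d$family[1], p = d$p[1], n_records = nrow(d),
      min_freq = mean(d$min_freq),
      TER = mean(d$TER), TER_sd = stats::sd(d$TER),
      FPR = mean(d$FPR, na.rm = TRUE), FPR_sd = stats::sd(d$FPR, na.rm = TRUE),
      FNR = mean(d$FNR, na.rm = TRUE), FNR_sd = stats::sd(d$FNR, na.rm = TRUE),
      AUC = mean(d$AUC, na.rm = TRUE), AUC_sd = stats::sd(d$AUC, na.rm = TRUE),
      AUC_defined = sum(!is.na(d$AUC)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$family, out$p), ]
  rownames(out) <- NULL
  out
}
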