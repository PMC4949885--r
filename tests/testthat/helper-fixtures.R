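# Shared fixtures, built once per test run. The default synthetic population
# uses master seed 7 throughout the suite; heavier cross-validation results
# are cached lazily so several test files can share them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

default_pop <- function() cached("pop", syn_beet_population(seed = 7))

default_qc <- function() cached("qc", run_qc(default_pop()$genotypes))

qc_dosage <- function() default_qc()$genotypes$dosage

true_labels <- function() default_pop()$phenotypes$label

# small random genotype-like matrix for property tests
rand_dosage <- function(n, m, seed) {
  with_seed(seed, matrix(sample(0:2, n * m, replace = TRUE), n, m))
}

with_seed <- snpnoise:::with_seed

# independent AUC oracle: explicit trapezoidal integration of the ROC curve
roc_trapezoid_auc <- function(y, s) {
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(s[y == 1] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(s[y == 0] >= t), 0), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# brute-force KNN oracle: explicit distances, explicit sort, explicit weights
knn_oracle <- function(Xtr, ytr, x0, K, weighting) {
  d <- apply(Xtr, 1, function(r) sqrt(sum((x0 / 2 - r / 2)^2)) / sqrt(ncol(Xtr)))
  ord <- order(d, seq_along(d))[1:K]
  if (weighting == "reciprocal" && any(d[ord] == 0))
    return(mean(ytr[d == 0]))
  w <- switch(weighting, uniform = rep(1, K),
              inverse = pmax(1 - d[ord], 0), reciprocal = 1 / d[ord])
  if (sum(w) == 0) w <- rep(1, K)
  sum(w * ytr[ord]) / sum(w)
}

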