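#' Model specifications and tuning grids for the five classifier families
#'
#' The study compares five families under a uniform fit/score contract:
#' \itemize{
#'   \item \code{"knn"}: K-nearest neighbours with K in \{1, 3, 5, 7\} and
#'     neighbour weights uniform, \code{1 - D} or \code{1 / D} (D the
#'     normalised Euclidean genotype distance);
#'   \item \code{"rf"}: random forest with B trees in \{1, 5, 10, 50, 100\}
#'     and m candidate markers per node in \{j, 2, 4\},
#'     j = int(log2(#markers) + 1);
#'   \item \code{"lr"}: ridge-penalised logistic regression, penalty lambda
#'     in \{1e-3, ..., 1e3\} (powers of ten);
#'   \item \code{"svm_lin"}: soft-margin SVM, linear kernel, cost C in
#'     \{2^2, ..., 2^9\};
#'   \item \code{"svm_rbf"}: SVM with radial basis kernel, the same C grid
#'     crossed with gamma in \{1e-3, ..., 10\} (powers of ten).
#' }
#' Grids are enumerated in preference order: when inner-CV AUC ties, the
#' earlier (simpler) grid point wins — smaller K/B/C/gamma, larger lambda,
#' unweighted before distance-weighted votes.
#'
#' @param family One of \code{"knn"}, \code{"rf"}, \code{"lr"},
#'   \code{"svm_lin"}, \code{"svm_rbf"}.
#' @param n_markers Marker count, used for the RF per-node subset j.
#' @return For \code{default_grid}, a data frame with one row per grid point.
#' @export
default_grid <- function(family, n_markers = 175L) {
  switch(match.arg(family, model_families()),
    knn = expand.grid(K = c(1L, 3L, 5L, 7L),
                      weighting = c("uniform", "inverse", "reciprocal"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    rf = {
      j <- as.integer(log2(n_markers) + 1)
      expand.grid(B = c(1L, 5L, 10L, 50L, 100L),
                  m = sort(unique(c(2L, 4L, j))), KEEP.OUT.ATTRS = FALSE)
    },
    lr = data.frame(lambda = 10^(3:-3)),           # larger lambda = simpler
    svm_lin = data.frame(C = 2^(2:9)),
    svm_rbf = expand.grid(C = 2^(2:9), gamma = 10^(-3:1),
                          KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")])
}

#' @rdname default_grid
#' @export
model_families <- function() c("knn", "rf", "lr", "svm_lin", "svm_rbf")

#' Fit one classifier
#'
#' Uniform contract over the five families: given a feature matrix (allele
#' dosages), 0/1 labels and one grid point of hyperparameters, return a
#' fitted model that \code{\link{score_model}} can evaluate on new samples.
#' Higher scores always mean "more positive" (label 1, high vigor). KNN
#' (distance-weighted voting) and ridge logistic regression
#' (unpenalised-intercept ridge likelihood) are implemented natively, as is
#' the SVM dual solver (sequential minimal optimization over a precomputed
#' kernel matrix, KKT tolerance 1e-3); random forests are grown by
#' \pkg{ranger} (bootstrap resamples, Gini splits on m random markers per
#' node, trees grown to purity), the score being the fraction of trees
#' voting positive.
#'
#' Degenerate single-class training sets yield a constant scorer rather
#' than an error, so cross-validation loops never die on an unlucky fold.
#'
#' @param family Classifier family, see \code{\link{model_families}}.
#' @param X Numeric matrix, samples in rows, markers in columns.
#' @param y 0/1 labels, length \code{nrow(X)}.
#' @param hyper Named list or one-row data frame of hyperparameters.
#' @param seed Integer seed (consumed by the random forest; ignored by the
#'   deterministic fits).
#' @return An object of class \code{snpnoise_model}.
#' @useDynLib snpnoise, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @export
fit_model <- function(family, X, y, hyper, seed = NULL) {
  family <- match.arg(family, model_families())
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% 0:1))
  hyper <- as.list(hyper)
  if (length(unique(y)) < 2) {
    fit <- list(constant = mean(y)) # single-class training fold
  } else {
    fit <- switch(family,
      knn = knn_fit(X, y, K = hyper$K, weighting = hyper$weighting),
      lr = ridge_logistic_fit(X, y, lambda = hyper$lambda),
      rf = rf_fit(X, y, B = hyper$B, m = hyper$m, seed = seed),
      svm_lin = svm_fit(X, y, kernel = "linear", C = hyper$C),
      svm_rbf = svm_fit(X, y, kernel = "rbf", C = hyper$C,
                        gamma = hyper$gamma))
  }
  structure(list(family = family, hyper = hyper, fit = fit),
            class = "snpnoise_model")
}

#' Score samples with a fitted classifier
#'
#' @param model A fitted \code{snpnoise_model}.
#' @param X Feature matrix of samples to score.
#' @return Numeric score per row: a positive-class vote fraction or
#'   probability in [0, 1] for KNN/RF/LR, a signed decision value for the
#'   SVMs. \code{predict_label} thresholds the scores (at 0.5, or 0 for
#'   decision values), ties resolved toward the positive class.
#' @export
score_model <- function(model, X) {
  X <- as.matrix(X)
  fit <- model$fit
  if (!is.null(fit$constant)) {
    base <- if (model$family %in% c("svm_lin", "svm_rbf"))
      ifelse(fit$constant >= 0.5, 1, -1) else fit$constant
    return(rep(base, nrow(X)))
  }
  switch(model$family,
    knn = knn_score(fit, X),
    lr = as.vector(stats::plogis(fit$mu + X %*% fit$beta)),
    rf = rf_score(fit, X),
    svm_lin = ,
    svm_rbf = svm_decision_values(fit, X))
}

#' @rdname score_model
#' @export
predict_label <- function(model, X) {
  s <- score_model(model, X)
  thr <- if (model$family %in% c("svm_lin", "svm_rbf")) 0 else 0.5
  as.integer(s >= thr)
}

## ---- KNN (native) ----------------------------------------------------------

#' Euclidean genotype distance
#'
#' Plain Euclidean distance between two dosage vectors; in scaled mode the
#' dosages are divided by 2 and the distance by sqrt(m), mapping it into
#' [0, 1] so that the \code{1 - D} neighbour weight is a proper weight.
#'
#' @param x0,xi Equal-length numeric dosage vectors without missing values.
#' @param scaled Use the normalised [0, 1] form (default \code{FALSE}).
#' @return A nonnegative scalar.
#' @export
euclidean_distance <- function(x0, xi, scaled = FALSE) {
  if (length(x0) != length(xi)) stop("vectors differ in length")
  d <- sqrt(sum((x0 - xi)^2))
  if (scaled) d / (2 * sqrt(length(x0))) else d
}

# All pairwise scaled distances between rows of A (queries) and B (training).
scaled_dist_matrix <- function(A, B) {
  A <- A / 2
  B <- B / 2
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0) / ncol(B))
}

knn_fit <- function(X, y, K, weighting) {
  weighting <- match.arg(weighting, c("uniform", "inverse", "reciprocal"))
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(X)) stop("K exceeds the number of training samples")
  list(X = X, y = y, K = as.integer(K), weighting = weighting)
}

# Weighted positive-vote fraction among the K nearest training samples.
# Zero-distance neighbours dominate under reciprocal weighting: the score is
# then the plain vote among exact genotype matches.
knn_score <- function(fit, X) {
  D <- scaled_dist_matrix(X, fit$X)
  apply_knn_votes(D, fit$y, fit$K, fit$weighting)
}

apply_knn_votes <- function(D, y_train, K, weighting) {
  vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, ]
    nn <- order(d, seq_along(d))[seq_len(K)] # stable tie-break by index
    dn <- d[nn]
    yn <- y_train[nn]
    w <- switch(weighting,
      uniform = rep(1, K),
      inverse = pmax(1 - dn, 0),
      reciprocal = {
        if (any(dn == 0)) return(mean(y_train[d == 0])) # exact matches rule
        1 / dn
      })
    if (sum(w) == 0) w <- rep(1, K)
    sum(w * yn) / sum(w)
  }, numeric(1))
}

## ---- Ridge logistic regression (native IRLS) -------------------------------

#' Ridge-penalised logistic regression
#'
#' Models logit P(y = 1 | x) = mu + sum_j z_j beta_j over allele dosages
#' z_j and maximises the log-likelihood minus the ridge penalty
#' (lambda / 2) * sum_j beta_j^2 (the intercept mu is not penalised) by
#' Newton iteratively-reweighted least squares, to gradient max-norm 1e-6
#' or 100 iterations. A positive lambda is required when markers outnumber
#' samples, as the unpenalised likelihood is then unbounded.
#'
#' When markers outnumber samples the Newton step is solved in the
#' n-dimensional row space of the dosage matrix (the optimum's effect
#' vector always lies in it), which keeps the per-iteration cost at
#' O(n^3) instead of O(p^3); the two routes produce the same model.
#'
#' @param X Dosage matrix (samples x markers).
#' @param y 0/1 labels.
#' @param lambda Ridge penalty, >= 0.
#' @return List with intercept \code{mu}, marker effects \code{beta},
#'   \code{converged} flag and iteration count.
#' @export
ridge_logistic_fit <- function(X, y, lambda) {
  stopifnot(lambda >= 0)
  if (lambda == 0 && ncol(X) >= nrow(X))
    stop("lambda > 0 is required when markers outnumber samples")
  n <- nrow(X); p <- ncol(X)
  dual <- lambda > 0 && p > n
  if (dual) Kg <- tcrossprod(X) # beta = X'a, penalty (lambda/2) a'Kg a
  mu <- 0
  beta <- numeric(p)
  a <- numeric(n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    eta <- as.vector(mu + X %*% beta)
    mu_i <- stats::plogis(eta)
    resid <- y - mu_i
    grad <- c(sum(resid), as.vector(crossprod(X, resid)) - lambda * beta)
    if (max(abs(grad)) <= 1e-6) { converged <- TRUE; break }
    w <- pmax(mu_i * (1 - mu_i), 1e-10)
    if (dual) {
      # reduced (n+1)-dim Newton system; multiplying the a-block by Kg
      # recovers the full Newton equations
      WK <- w * Kg
      M <- rbind(c(sum(w), colSums(WK)),
                 cbind(w, WK + diag(lambda, n)))
      rhs <- c(sum(resid), resid - lambda * a)
      step <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(step)) break
      mu <- mu + step[1]
      a <- a + step[-1]
      beta <- as.vector(crossprod(X, a))
    } else {
      Xa <- cbind(1, X)
      H <- crossprod(Xa * w, Xa)
      diag(H) <- diag(H) + c(0, rep(lambda, p))
      step <- tryCatch(solve(H, grad), error = function(e) NULL)
      if (is.null(step)) {
        diag(H) <- diag(H) + 1e-8
        step <- solve(H, grad)
      }
      mu <- mu + step[1]
      beta <- beta + step[-1]
    }
  }
  if (!converged)
    warning("ridge logistic regression did not converge; best iterate returned")
  list(mu = unname(mu), beta = unname(as.vector(beta)), lambda = lambda,
       converged = converged, iterations = iter)
}

# Penalised log-likelihood, used by tests to verify optimality.
ridge_logistic_loglik <- function(X, y, mu, beta, lambda) {
  eta <- as.vector(mu + X %*% beta)
  sum(y * eta - log1p(exp(eta))) - lambda / 2 * sum(beta^2)
}

## ---- Random forest (ranger backend) ----------------------------------------

rf_fit <- function(X, y, B, m, seed = NULL) {
  stopifnot(B >= 1)
  if (m > ncol(X)) stop("m exceeds the number of markers")
  forest <- ranger::ranger(
    x = X, y = factor(y, levels = c(0, 1)),
    num.trees = B, mtry = m, replace = TRUE, min.node.size = 1L,
    splitrule = "gini", num.threads = 1L,
    seed = if (is.null(seed)) 1L else seed)
  list(forest = forest, B = B, m = m)
}

# Fraction of trees voting for the positive class.
rf_score <- function(fit, X) {
  pred <- predict(fit$forest, data = X, predict.all = TRUE,
                  num.threads = 1L)$predictions
  pred <- matrix(pred, nrow = nrow(X))
  pos <- match("1", fit$forest$forest$levels)
  rowMeans(pred == pos)
}

## ---- SVM (native SMO over precomputed kernels) -----------------------------

kernel_matrix <- function(A, B, kernel, gamma = NULL) {
  if (kernel == "linear") return(tcrossprod(A, B))
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

svm_fit <- function(X, y, kernel, C, gamma = NULL) {
  stopifnot(C > 0)
  if (kernel == "rbf" && (is.null(gamma) || gamma <= 0))
    stop("rbf kernel requires gamma > 0")
  ypm <- as.integer(2L * y - 1L) # {-1, +1}
  K <- kernel_matrix(X, X, kernel, gamma)
  sol <- .smo_csvc(K, ypm, C, tol = 1e-3)
  if (!sol$converged)
    stop(sprintf("SVM solver failed to converge (kernel=%s, C=%g%s)",
                 kernel, C,
                 if (kernel == "rbf") sprintf(", gamma=%g", gamma) else ""))
  sv <- which(sol$alpha > 1e-12)
  list(X_sv = X[sv, , drop = FALSE], coef = sol$alpha[sv] * ypm[sv],
       rho = sol$rho, kernel = kernel, gamma = gamma, C = C,
       iterations = sol$iterations)
}

# Signed decision value f(x) = sum_i alpha_i y_i K(x, x_i) - rho;
# positive = class 1.
svm_decision_values <- function(fit, X) {
  K <- kernel_matrix(X, fit$X_sv, fit$kernel, fit$gamma)
  as.vector(K %*% fit$coef - fit$rho)
}
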