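#' Per-marker and per-sample call-rate
#'
#' Call-rate is the fraction of non-missing genotype calls per marker
#' (or per sample).
#'
#' @param G A \code{\link{geno_matrix}}.
#' @return Named numeric vector of fractions in [0, 1].
#' @export
marker_call_rate <- function(G) {
  if (n_markers(G) == 0) stop("empty genotype matrix")
  colMeans(!is.na(G$dosage))
}

#' @rdname marker_call_rate
#' @export
sample_call_rate <- function(G) {
  if (n_samples(G) == 0) stop("empty genotype matrix")
  rowMeans(!is.na(G$dosage))
}

#' Remove markers with low call-rate
#'
#' @param G A \code{\link{geno_matrix}}.
#' @param threshold Call-rate threshold in [0, 1].
#' @param inclusive When \code{TRUE} (default) markers with call-rate
#'   \emph{equal} to the threshold are also removed (the "<= 85 %"
#'   convention).
#' @return List with \code{genotypes} (filtered matrix) and \code{removed}
#'   (character vector of dropped marker ids).
#' @export
filter_by_call_rate <- function(G, threshold = 0.85, inclusive = TRUE) {
  stopifnot(threshold >= 0, threshold <= 1)
  cr <- marker_call_rate(G)
  drop <- if (inclusive) cr <= threshold else cr < threshold
  if (all(drop)) stop("call-rate filter would remove every marker")
  list(genotypes = subset_markers(G, which(!drop)),
       removed = G$map$marker_id[drop])
}

#' Impute missing genotypes from the k nearest samples
#'
#' Each missing call is filled with the average dosage of the \code{k}
#' nearest samples (Euclidean distance over mutually observed markers,
#' normalised by the number of shared markers) that have the marker
#' observed, rounded half away from zero to the nearest valid dosage.
#' When no neighbour observes the marker the marker's modal dosage is used;
#' a fully missing marker falls back to dosage 0 with a warning.
#'
#' @param G A \code{\link{geno_matrix}}.
#' @param k Number of neighbours (default 5).
#' @return A \code{geno_matrix} with no missing cells.
#' @export
impute_missing <- function(G, k = 5L) {
  stopifnot(k >= 1)
  X <- G$dosage
  if (!anyNA(X)) return(G)
  n <- nrow(X)
  obs <- !is.na(X)
  X0 <- X
  X0[!obs] <- 0L
  # mean squared difference over mutually observed markers
  cross <- tcrossprod(X0)            # sum x_i x_j over shared (0-filled)
  sq <- X0^2
  s_i <- sq %*% t(obs)               # sum x_i^2 over markers observed in both
  shared <- tcrossprod(obs * 1)
  d2 <- (s_i + t(s_i) - 2 * cross) / pmax(shared, 1)
  d2[shared == 0] <- Inf
  diag(d2) <- Inf

  for (j in which(colSums(!obs) > 0)) {
    donors <- which(obs[, j])
    if (length(donors) == 0) {
      warning(sprintf("marker %s fully missing; imputed as dosage 0",
                      G$map$marker_id[j]))
      X[, j] <- 0L
      next
    }
    mode_j <- as.integer(names(which.max(table(X[donors, j]))))
    for (i in which(!obs[, j])) {
      dv <- d2[i, donors]
      usable <- donors[is.finite(dv)]
      if (length(usable) == 0) {
        X[i, j] <- mode_j
        next
      }
      nn <- usable[order(d2[i, usable], usable)][seq_len(min(k, length(usable)))]
      X[i, j] <- as.integer(min(2, max(0, round_half_away(mean(X[nn, j])))))
    }
  }
  geno_matrix(X, map = G$map[, c("marker_id", "chromosome")], samples = G$samples)
}

#' Minor allele frequency
#'
#' MAF = min(f, 1 - f) with f = (sum of dosages) / (2 n). Requires a fully
#' observed matrix (run after imputation).
#'
#' @param G A \code{\link{geno_matrix}} without missing cells.
#' @return Named numeric vector of fractions in [0, 0.5].
#' @export
minor_allele_frequency <- function(G) {
  if (anyNA(G$dosage)) stop("MAF is computed after imputation; missing cells present")
  f <- colSums(G$dosage) / (2 * n_samples(G))
  pmin(f, 1 - f)
}

#' Remove markers with low minor allele frequency
#'
#' @inheritParams filter_by_call_rate
#' @param threshold MAF threshold (default 0.025).
#' @export
filter_by_maf <- function(G, threshold = 0.025, inclusive = TRUE) {
  maf <- minor_allele_frequency(G)
  drop <- if (inclusive) maf <= threshold else maf < threshold
  if (all(drop)) stop("MAF filter would remove every marker")
  list(genotypes = subset_markers(G, which(!drop)),
       removed = G$map$marker_id[drop])
}

#' Marker quality control pipeline
#'
#' Applies the fixed editing order: call-rate filter, k-nearest-sample
#' imputation, MAF filter. Under the default thresholds (call-rate <= 0.85
#' and MAF <= 0.025 removed, both inclusive) the default synthetic fixture
#' loses 1 + 16 of its 192 markers, leaving 175 fully observed SNPs.
#'
#' @param G A \code{\link{geno_matrix}}.
#' @param callrate_max Markers with call-rate at or below this are removed.
#' @param maf_max Markers with MAF at or below this are removed.
#' @param impute_k Neighbours used by \code{\link{impute_missing}}.
#' @return List of class \code{qc_result}: \code{genotypes} (clean matrix)
#'   and \code{report} (a \code{qc_report} with counts, removed ids, and the
#'   per-marker call-rate and MAF vectors).
#' @export
run_qc <- function(G, callrate_max = 0.85, maf_max = 0.025, impute_k = 5L) {
  cr <- marker_call_rate(G)
  step1 <- filter_by_call_rate(G, callrate_max, inclusive = TRUE)
  n_missing <- sum(is.na(step1$genotypes$dosage))
  imputed <- impute_missing(step1$genotypes, k = impute_k)
  maf <- minor_allele_frequency(imputed)
  step2 <- filter_by_maf(imputed, maf_max, inclusive = TRUE)
  report <- structure(list(
    n_markers_in = n_markers(G),
    n_removed_callrate = length(step1$removed),
    n_imputed_cells = n_missing,
    n_removed_maf = length(step2$removed),
    n_markers_out = n_markers(step2$genotypes),
    removed_callrate = step1$removed,
    removed_maf = step2$removed,
    marker_call_rate = cr,
    sample_call_rate = sample_call_rate(G),
    maf = maf), class = "qc_report")
  stopifnot(report$n_markers_out ==
              report$n_markers_in - report$n_removed_callrate - report$n_removed_maf)
  structure(list(genotypes = step2$genotypes, report = report),
            class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "genotype QC: %d markers in | %d removed (call-rate) | %d cells imputed | ",
    "%d removed (MAF) | %d markers out\n",
    "mean per-marker call-rate %.3f, mean per-sample call-rate %.3f\n"),
    x$n_markers_in, x$n_removed_callrate, x$n_imputed_cells,
    x$n_removed_maf, x$n_markers_out,
    mean(x$marker_call_rate), mean(x$sample_call_rate)))
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report)
  print(x$genotypes)
  invisible(x)
}
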