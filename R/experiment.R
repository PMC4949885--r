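#' Rank markers by the proportion of label variance they explain
#'
#' Scores each marker by the R-squared of the single-marker linear
#' regression of the 0/1 label on allele dosage (the squared point-biserial
#' correlation) and orders markers by decreasing score, ties broken by
#' marker index. Zero-variance markers score 0. Used to extract the
#' "most informative SNP" subsets (e.g. top 50 / top 30).
#'
#' @param G A QC'd \code{\link{geno_matrix}} (no missing cells).
#' @param labels True 0/1 labels.
#' @return Data frame (marker_id, index, r_squared) in rank order.
#' @export
rank_snps_by_variance_explained <- function(G, labels) {
  stopifnot(all(labels %in% 0:1), length(labels) == n_samples(G))
  if (anyNA(G$dosage)) stop("rank markers after QC; missing cells present")
  r2 <- apply(G$dosage, 2, function(x) {
    if (stats::sd(x) == 0) return(0)
    stats::cor(x, labels)^2
  })
  ord <- order(-r2, seq_along(r2))
  data.frame(marker_id = G$map$marker_id[ord], index = ord,
             r_squared = as.numeric(r2[ord]), stringsAsFactors = FALSE)
}

#' Configuration of a noise-ladder experiment
#'
#' @param ladder Mislabel proportions (default the 14-level ladder of
#'   \code{\link{default_noise_ladder}}).
#' @param families Classifier families to run (default all five).
#' @param replicates Repeats of the outer 5-fold CV per (family, p) cell.
#'   100 reproduces the full design; 20 is a practical default for
#'   interactive work.
#' @param k,inner_k Outer and inner fold counts.
#' @param seed Master seed; every stochastic stage derives a child seed
#'   from it, so a rerun reproduces the output exactly.
#' @param grids Optional named list of hyperparameter grids per family
#'   (default \code{\link{default_grid}} for each); thinned grids speed up
#'   smoke runs.
#' @param subset_sizes Marker subset sizes for
#'   \code{\link{run_snp_subset_experiment}} (\code{NA} = full panel).
#' @return List of class \code{experiment_config}.
#' @export
experiment_config <- function(ladder = default_noise_ladder(),
                              families = model_families(),
                              replicates = 20L, k = 5L, inner_k = 5L,
                              seed = 1L, grids = NULL,
                              subset_sizes = c(NA, 50L, 30L)) {
  stopifnot(replicates >= 1, all(ladder >= 0), all(ladder <= 0.5),
            !is.unsorted(ladder, strictly = TRUE))
  structure(list(ladder = ladder, families = families,
                 replicates = replicates, k = k, inner_k = inner_k,
                 seed = seed, grids = grids, subset_sizes = subset_sizes),
            class = "experiment_config")
}

config_grid <- function(config, family, n_markers) {
  if (!is.null(config$grids[[family]])) config$grids[[family]]
  else default_grid(family, n_markers = n_markers)
}

#' Run the full noise-ladder study
#'
#' For every mislabel proportion in the ladder and every classifier family,
#' runs \code{replicates} repeats of nested 5-fold cross-validation
#' (\code{\link{run_replicate}}) and aggregates the per-fold records. The
#' label flips and fold assignments for a given (noise level, replicate)
#' pair are shared across families — a paired design, so family contrasts
#' at a noise level are not confounded by different noise draws.
#'
#' @param X Feature matrix (QC'd dosages) or a \code{\link{geno_matrix}}.
#' @param y_true True 0/1 labels.
#' @param config An \code{\link{experiment_config}}.
#' @return List of class \code{ladder_result}: \code{records} (per-fold
#'   rows) and \code{summary} (\code{\link{aggregate_records}} table).
#' @export
run_noise_ladder <- function(X, y_true, config = experiment_config()) {
  if (inherits(X, "geno_matrix")) X <- X$dosage
  X <- as.matrix(X)
  out <- vector("list", length(config$ladder) * length(config$families) *
                  config$replicates)
  i <- 0L
  for (pi in seq_along(config$ladder)) {
    for (family in config$families) {
      grid <- config_grid(config, family, ncol(X))
      for (r in seq_len(config$replicates)) {
        i <- i + 1L
        # child seed independent of family: shared flips/folds across models
        out[[i]] <- tryCatch(
          run_replicate(
            X, y_true, family, config$ladder[pi],
            seed = child_seed(config$seed, pi, r),
            grid = grid, k = config$k, inner_k = config$inner_k,
            replicate = r),
          error = function(e) {
            data.frame(family = family, p = config$ladder[pi], replicate = r,
                       message = conditionMessage(e),
                       stringsAsFactors = FALSE)
          })
      }
    }
  }
  failed <- vapply(out, function(d) "message" %in% names(d), logical(1))
  failures <- if (any(failed)) do.call(rbind, out[failed]) else NULL
  if (!is.null(failures))
    warning(sprintf("%d replicate(s) failed; see $failures", nrow(failures)))
  records <- do.call(rbind, out[!failed])
  if (is.null(records) || nrow(records) == 0)
    stop("every replicate failed: ", failures$message[1])
  structure(list(records = records, summary = aggregate_records(records),
                 failures = failures, config = config),
            class = "ladder_result")
}

#' @export
print.ladder_result <- function(x, ...) {
  cat(sprintf("noise-ladder result: %d families x %d noise levels, %d replicates\n",
              length(unique(x$records$family)),
              length(unique(x$records$p)),
              max(x$records$replicate)))
  print(x$summary[, c("family", "p", "min_freq", "TER", "AUC", "AUC_sd")],
        digits = 3)
  invisible(x)
}

#' Noise ladder on reduced "most informative SNP" panels
#'
#' Repeats the ladder for the selected families (default the two local
#' methods, KNN and RF) on the full panel and on the top-N marker subsets
#' ranked by \code{\link{rank_snps_by_variance_explained}} on the clean
#' labels, before any noise injection. Child seeds depend only on the
#' (noise level, replicate) pair, so the full-panel runs coincide exactly
#' with \code{\link{run_noise_ladder}} under the same master seed.
#'
#' @param G A QC'd \code{\link{geno_matrix}}.
#' @param y_true True 0/1 labels.
#' @param config An \code{\link{experiment_config}}; its
#'   \code{subset_sizes} (\code{NA} = all markers) and \code{families}
#'   (default here: knn, rf) are used.
#' @return List of class \code{subset_result}: \code{records} and
#'   \code{summary}, each carrying a \code{subset} column, plus the marker
#'   \code{ranking}.
#' @export
run_snp_subset_experiment <- function(G, y_true,
                                      config = experiment_config(families = c("knn", "rf"))) {
  stopifnot(inherits(G, "geno_matrix"))
  ranking <- rank_snps_by_variance_explained(G, y_true)
  records <- NULL
  for (s in config$subset_sizes) {
    if (!is.na(s) && s > n_markers(G))
      stop("subset size exceeds the marker panel")
    Gs <- if (is.na(s)) G else subset_markers(G, ranking$index[seq_len(s)])
    res <- run_noise_ladder(Gs, y_true, config)
    res$records$subset <- if (is.na(s)) n_markers(G) else s
    records <- rbind(records, res$records)
  }
  cells <- split(records, records$subset)
  summary <- do.call(rbind, lapply(cells, function(d) {
    s <- aggregate_records(d)
    s$subset <- d$subset[1]
    s
  }))
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary, ranking = ranking,
                 config = config), class = "subset_result")
}

#' Write figures and a summary table for a ladder run
#'
#' Produces the standard report artefacts in \code{dir}: mean AUC versus
#' noise level per family (line plot), TPR/TNR distributions per family and
#' noise level (boxplots), an optional subset-comparison plot, and a
#' long-format text table (one row per noise level, minority frequency and
#' error type, one column per family).
#'
#' @param result A \code{ladder_result} (and optionally a
#'   \code{subset_result} via \code{subset}).
#' @param dir Output directory (created if absent).
#' @param subset Optional \code{subset_result} for the comparison plot.
#' @param force Overwrite existing files (default \code{FALSE}).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(result, dir, subset = NULL, force = FALSE) {
  if (is.null(result$records) || nrow(result$records) == 0) {
    warning("empty results; nothing to render")
    return(invisible(character(0)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(auc = file.path(dir, "auc_vs_noise.pdf"),
             rates = file.path(dir, "tpr_tnr_distributions.pdf"),
             table = file.path(dir, "summary_table.tsv"),
             records = file.path(dir, "metric_records.tsv"))
  if (!is.null(subset)) paths["subset"] <- file.path(dir, "snp_subsets.pdf")
  exists <- file.exists(paths)
  if (any(exists) && !force)
    stop("report files already exist; use force = TRUE to overwrite: ",
         paste(paths[exists], collapse = ", "))

  smry <- result$summary
  p1 <- ggplot2::ggplot(smry, ggplot2::aes(x = p, y = AUC, colour = family)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "proportion of mislabeled observations",
                  y = "mean validation AUC", colour = "model") +
    ggplot2::theme_bw()
  ggplot2::ggsave(paths[["auc"]], p1, width = 7, height = 5)

  long <- rbind(
    data.frame(result$records[c("family", "p")], rate = "TPR",
               value = result$records$TPR),
    data.frame(result$records[c("family", "p")], rate = "TNR",
               value = result$records$TNR))
  p2 <- ggplot2::ggplot(long, ggplot2::aes(x = factor(p), y = value, fill = rate)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.2) +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "proportion of mislabeled observations", y = "rate") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  ggplot2::ggsave(paths[["rates"]], p2, width = 9, height = 6)

  if (!is.null(subset)) {
    ss <- subset$summary
    ss$subset <- factor(ss$subset, levels = sort(unique(ss$subset), decreasing = TRUE))
    p3 <- ggplot2::ggplot(ss, ggplot2::aes(x = p, y = AUC, colour = family,
                                           linetype = subset)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "proportion of mislabeled observations",
                    y = "mean validation AUC", linetype = "SNPs") +
      ggplot2::theme_bw()
    ggplot2::ggsave(paths[["subset"]], p3, width = 7, height = 5)
  }

  utils::write.table(summary_long_table(smry), paths[["table"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$records, paths[["records"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

# Long-format table: one row per (p, minority frequency, error type),
# one column per family.
summary_long_table <- function(smry) {
  fams <- sort(unique(smry$family))
  rows <- NULL
  for (p in sort(unique(smry$p))) {
    cell <- smry[smry$p == p, ]
    for (err in c("TER", "FNR", "FPR", "AUC")) {
      vals <- vapply(fams, function(f) cell[cell$family == f, err][1],
                     numeric(1))
      rows <- rbind(rows, data.frame(
        misLabels = 100 * p, minFreq = round(mean(cell$min_freq), 4),
        errType = err, t(round(vals, 4)), check.names = FALSE))
    }
  }
  names(rows)[-(1:3)] <- fams
  rows
}
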