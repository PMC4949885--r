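#' Genotype matrix container
#'
#' A light S3 container for a samples-by-markers allele-dosage matrix
#' (0/1/2 copies of one allele for AA/AB/BB; \code{NA} = missing call),
#' together with a marker map (marker id, chromosome).
#'
#' @param dosage Integer matrix, samples in rows, markers in columns; values
#'   in \{0, 1, 2\} or \code{NA}.
#' @param map Data frame with columns \code{marker_id} and \code{chromosome};
#'   defaults to column names of \code{dosage} on a single chromosome.
#' @param samples Character vector of sample ids; defaults to row names.
#' @return An object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(dosage, map = NULL, samples = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(samples)) {
    samples <- rownames(dosage)
    if (is.null(samples)) samples <- sprintf("S%03d", seq_len(nrow(dosage)))
  }
  if (is.null(map)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- sprintf("SNP_%03d", seq_len(ncol(dosage)))
    map <- data.frame(marker_id = ids, chromosome = 1L,
                      stringsAsFactors = FALSE)
  }
  map$index <- seq_len(nrow(map))
  stopifnot(length(samples) == nrow(dosage), nrow(map) == ncol(dosage))
  if (anyDuplicated(map$marker_id)) stop("marker ids must be unique")
  rownames(dosage) <- samples
  colnames(dosage) <- map$marker_id
  structure(list(dosage = dosage, map = map, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d markers (%d chromosome(s)), %d missing cells (%.2f%%)\n",
              n_samples(x), n_markers(x), length(unique(x$map$chromosome)),
              sum(is.na(x$dosage)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @rdname geno_matrix
#' @param G A \code{geno_matrix}.
#' @export
n_samples <- function(G) nrow(G$dosage)

#' @rdname geno_matrix
#' @export
n_markers <- function(G) ncol(G$dosage)

#' @rdname geno_matrix
#' @export
missing_mask <- function(G) is.na(G$dosage)

#' Keep a subset of markers
#'
#' @param G A \code{geno_matrix}.
#' @param idx Integer indices or marker ids to keep, in the given order.
#' @return A \code{geno_matrix} restricted to those markers.
#' @export
subset_markers <- function(G, idx) {
  if (is.character(idx)) idx <- match(idx, G$map$marker_id)
  if (anyNA(idx)) stop("unknown marker id")
  geno_matrix(G$dosage[, idx, drop = FALSE],
              map = G$map[idx, c("marker_id", "chromosome"), drop = FALSE],
              samples = G$samples)
}

#' Read and write the genotype/phenotype CSV dialect
#'
#' Genotype tables are written with samples in rows and markers in columns,
#' cells in \{0,1,2,NA\}; the marker map and phenotype table are plain CSV.
#'
#' @param G A \code{geno_matrix}.
#' @param path Output file path.
#' @export
write_geno_csv <- function(G, path) {
  df <- data.frame(sample = G$samples, G$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  utils::write.csv(G$map, sub("(\\.csv)?$", ".map.csv", path, perl = TRUE),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_geno_csv
#' @param map_path Optional marker-map CSV (columns marker_id, chromosome);
#'   when \code{NULL} the default \code{<path>.map.csv} companion is used if
#'   present.
#' @export
read_geno_csv <- function(path, map_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  dosage <- as.matrix(df[, -1, drop = FALSE])
  rownames(dosage) <- df[[1]]
  if (is.null(map_path)) {
    cand <- sub("(\\.csv)?$", ".map.csv", path, perl = TRUE)
    if (file.exists(cand)) map_path <- cand
  }
  map <- if (!is.null(map_path))
    utils::read.csv(map_path, stringsAsFactors = FALSE)[, c("marker_id", "chromosome")]
  else NULL
  geno_matrix(dosage, map = map, samples = df[[1]])
}

#' @rdname write_geno_csv
#' @param pheno Phenotype data frame (sample, line, elongation, label).
#' @export
write_pheno_csv <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_geno_csv
#' @export
read_pheno_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Minimal VCF export/import (GT field only)
#'
#' Writes an unphased diploid VCF v4.2 with genotypes derived from dosages
#' (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.). Positions are the marker index
#' within the chromosome; REF/ALT are placeholders A/B. Import maps GT back
#' to dosages (count of ALT alleles) and accepts any GT-bearing VCF.
#'
#' @param G A \code{geno_matrix}.
#' @param path File path.
#' @return \code{read_vcf_dosage} returns a \code{geno_matrix}.
#' @export
write_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$samples), collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  pos <- stats::ave(seq_len(n_markers(G)), G$map$chromosome, FUN = seq_along)
  for (j in seq_len(n_markers(G))) {
    d <- G$dosage[, j]
    calls <- ifelse(is.na(d), "./.", gt[d + 1L])
    writeLines(paste(c(G$map$chromosome[j], pos[j], G$map$marker_id[j],
                       "A", "B", ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf_dosage <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:9)]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(body, `[`, "", 3)
  chroms <- suppressWarnings(as.integer(vapply(body, `[`, "", 1)))
  if (anyNA(chroms)) chroms <- as.integer(factor(vapply(body, `[`, "", 1)))
  dos <- vapply(body, function(f) {
    gt_idx <- match("GT", strsplit(f[9], ":", fixed = TRUE)[[1]])
    calls <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gt_idx)
    alleles <- strsplit(calls, "[/|]")
    vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(as.integer(a) > 0L)
    }, integer(1))
  }, integer(length(samples)))
  geno_matrix(matrix(dos, nrow = length(samples),
                     dimnames = list(samples, ids)),
              map = data.frame(marker_id = ids, chromosome = chroms,
                               stringsAsFactors = FALSE),
              samples = samples)
}
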