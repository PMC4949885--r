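#' Configuration for the synthetic sugar-beet population
#'
#' Bundles the parameters of the synthetic population generator. The defaults
#' emulate the structure of a real sugar-beet root-vigor panel: 123 plants
#' from 18 lines (15 high-vigor lines contributing 99 plants, 3 low-vigor
#' lines contributing 24), 192 SNPs spread over 9 chromosomes, a bimodal
#' root-elongation phenotype (class means 12.9 and 2.6 mm/day), 738 missing
#' genotype calls including one marker pushed below 85 % call-rate, and 16
#' markers forced to minor allele frequency below 2.5 %.
#'
#' The genetic architecture is a line-level allele-frequency-contrast model:
#' \code{n_causal} markers have allele frequency \code{causal_freq_high} in
#' high-vigor lines and \code{causal_freq_low} in low-vigor lines; the
#' remaining markers draw a shared base frequency from a symmetric
#' Beta(\code{base_freq_shape}, \code{base_freq_shape}) (clipped to
#' \code{base_freq_range}) and per-line frequencies from a Beta centred on it
#' with concentration \code{drift_concentration}. Dosages are
#' Binomial(2, p) draws per plant and marker.
#'
#' @param n_samples,n_high,n_low Total plants and per-class counts.
#' @param n_lines_high,n_lines_low Number of high- and low-vigor lines.
#' @param n_markers,n_chromosomes Marker panel size and chromosome count
#'   (chromosomes assigned round-robin).
#' @param n_causal Number of class-informative markers.
#' @param causal_freq_high,causal_freq_low Causal allele frequency in high-
#'   and low-vigor lines.
#' @param base_freq_shape Shape of the symmetric Beta for background base
#'   frequencies.
#' @param base_freq_range,line_freq_range Clipping ranges keeping background
#'   markers clear of the rare-marker regime.
#' @param drift_concentration Beta concentration of per-line drift around the
#'   base frequency (larger = less drift).
#' @param elong_mean_high,elong_mean_low,elong_sd Root-elongation class means
#'   and common SD (mm/day).
#' @param elong_threshold Elongation threshold separating the classes
#'   (default midpoint of the class means).
#' @param n_missing_cells Total missing genotype calls to place.
#' @param low_callrate_missing Missing calls given to the single designated
#'   low-call-rate marker (21 of 123 pushes its call-rate to 0.829).
#' @param max_missing_per_marker Cap on missing calls for every other marker,
#'   so only the designated marker can fail an 85 % call-rate filter.
#' @param n_rare_markers Number of markers overwritten to be rare.
#' @param rare_max_copies Maximum minor-allele copies for a rare marker
#'   (6 of 246 alleles = MAF 0.0244).
#' @return A list of class \code{syn_config}.
#' @export
syn_config <- function(n_samples = 123L, n_high = 99L, n_low = 24L,
                       n_lines_high = 15L, n_lines_low = 3L,
                       n_markers = 192L, n_chromosomes = 9L,
                       n_causal = 40L,
                       causal_freq_high = 0.9, causal_freq_low = 0.1,
                       base_freq_shape = 2,
                       base_freq_range = c(0.15, 0.85),
                       line_freq_range = c(0.08, 0.92),
                       drift_concentration = 50,
                       elong_mean_high = 12.9, elong_mean_low = 2.6,
                       elong_sd = 1.5,
                       elong_threshold = (12.9 + 2.6) / 2,
                       n_missing_cells = 738L,
                       low_callrate_missing = 21L,
                       max_missing_per_marker = 15L,
                       n_rare_markers = 16L, rare_max_copies = 6L) {
  cfg <- as.list(environment())
  class(cfg) <- "syn_config"
  validate_syn_config(cfg)
  cfg
}

#' Read a generator configuration from JSON or YAML
#'
#' Any subset of the \code{\link{syn_config}} arguments may be given in the
#' file; unspecified values keep their defaults.
#'
#' @param path Path to a .json, .yml or .yaml file.
#' @return A validated \code{syn_config}.
#' @export
syn_config_from_file <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configurations")
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the jsonlite package is required to read JSON configurations")
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(syn_config)))
  if (length(unknown) > 0)
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  do.call(syn_config, vals)
}

validate_syn_config <- function(cfg) {
  with(cfg, {
    if (n_high + n_low != n_samples)
      stop("infeasible class counts: n_high + n_low != n_samples")
    if (n_causal + n_rare_markers > n_markers)
      stop("causal and rare marker sets cannot fit in the panel")
    if (n_missing_cells > n_samples * n_markers)
      stop("n_missing_cells exceeds the number of genotype cells")
    if (n_missing_cells < low_callrate_missing)
      stop("n_missing_cells smaller than the low-call-rate marker's share")
    if (low_callrate_missing > n_samples)
      stop("low_callrate_missing exceeds the number of samples")
    stopifnot(causal_freq_high >= 0, causal_freq_high <= 1,
              causal_freq_low >= 0, causal_freq_low <= 1,
              elong_sd > 0, rare_max_copies >= 0)
  })
  invisible(cfg)
}

# Even allocation of class totals over lines; remainders go to the first lines.
line_sizes <- function(total, n_lines) {
  base <- total %/% n_lines
  sizes <- rep(base, n_lines)
  extra <- total - base * n_lines
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Generate a synthetic population (genotypes + phenotypes)
#'
#' Draws a complete population under the line-level allele-frequency model of
#' \code{\link{syn_config}}: plants are allocated to lines, per-line allele
#' frequencies are drawn (contrast for causal markers, drifted base frequency
#' for background markers), dosages are Binomial(2, p) samples, and root
#' elongation is drawn from the class-specific normal distribution truncated
#' at the class threshold, so the binary vigor label (1 = high, the positive
#' majority class) always matches the plant's line class.
#'
#' @param config A \code{\link{syn_config}}.
#' @param seed Integer seed; the same (config, seed) pair reproduces the
#'   population exactly.
#' @return A list of class \code{syn_population} with elements
#'   \code{genotypes} (a \code{\link{geno_matrix}} with no missing cells),
#'   \code{phenotypes} (data frame: sample, line, elongation, label),
#'   \code{causal_markers} (indices), and bookkeeping slots filled by
#'   \code{\link{force_rare_markers}} / \code{\link{apply_missingness}}.
#' @export
generate_population <- function(config = syn_config(), seed = 1L) {
  validate_syn_config(config)
  with_seed(child_seed(seed, 101L), {
    n_lines <- config$n_lines_high + config$n_lines_low
    sizes <- c(line_sizes(config$n_high, config$n_lines_high),
               line_sizes(config$n_low, config$n_lines_low))
    line_of <- rep(seq_len(n_lines), sizes)
    line_is_high <- rep(c(TRUE, FALSE),
                        c(config$n_lines_high, config$n_lines_low))
    is_high <- line_is_high[line_of]

    map <- data.frame(
      marker_id = sprintf("SNP_%03d", seq_len(config$n_markers)),
      chromosome = ((seq_len(config$n_markers) - 1L) %% config$n_chromosomes) + 1L,
      stringsAsFactors = FALSE)

    causal <- sort(sample.int(config$n_markers, config$n_causal))

    # per-line allele frequencies: n_lines x n_markers
    base <- stats::rbeta(config$n_markers, config$base_freq_shape,
                         config$base_freq_shape)
    base <- pmin(pmax(base, config$base_freq_range[1]), config$base_freq_range[2])
    conc <- config$drift_concentration
    p_line <- matrix(0, n_lines, config$n_markers)
    for (l in seq_len(n_lines)) {
      p <- stats::rbeta(config$n_markers, base * conc, (1 - base) * conc)
      p_line[l, ] <- pmin(pmax(p, config$line_freq_range[1]),
                          config$line_freq_range[2])
    }
    p_line[line_is_high, causal] <- config$causal_freq_high
    p_line[!line_is_high, causal] <- config$causal_freq_low

    probs <- p_line[line_of, , drop = FALSE]
    dosage <- matrix(stats::rbinom(length(probs), 2L, probs),
                     nrow = config$n_samples)

    elong <- numeric(config$n_samples)
    elong[is_high] <- rtrunc_norm(sum(is_high), config$elong_mean_high,
                                  config$elong_sd,
                                  lower = config$elong_threshold)
    elong[!is_high] <- rtrunc_norm(sum(!is_high), config$elong_mean_low,
                                   config$elong_sd,
                                   upper = config$elong_threshold)

    pheno <- data.frame(
      sample = sprintf("S%03d", seq_len(config$n_samples)),
      line = line_of,
      elongation = round(elong, 3),
      label = as.integer(elong > config$elong_threshold),
      stringsAsFactors = FALSE)

    structure(list(
      genotypes = geno_matrix(dosage, map = map, samples = pheno$sample),
      phenotypes = pheno,
      causal_markers = causal,
      rare_markers = integer(0),
      low_callrate_marker = NA_integer_,
      config = config), class = "syn_population")
  })
}

# Truncated normal draws by rejection; the truncation point is >3 SD from the
# mean under the default configuration, so virtually all draws are accepted.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x > lower & x < upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' @export
print.syn_population <- function(x, ...) {
  cat(sprintf("syn_population: %d plants (%d high / %d low vigor), %d lines\n",
              nrow(x$phenotypes), sum(x$phenotypes$label == 1),
              sum(x$phenotypes$label == 0), length(unique(x$phenotypes$line))))
  print(x$genotypes)
  invisible(x)
}

#' Overwrite designated markers so they fall below the MAF threshold
#'
#' Picks \code{n_rare_markers} markers outside the causal set and rewrites
#' their genotype columns so each carries at most \code{rare_max_copies}
#' minor-allele copies (placed as heterozygotes in distinct random plants).
#' This plants the markers that a MAF <= 2.5 % filter must later remove.
#'
#' @inheritParams generate_population
#' @param pop A \code{syn_population} from \code{\link{generate_population}}.
#' @return The population with \code{rare_markers} filled in.
#' @export
force_rare_markers <- function(pop, config = pop$config, seed = 1L) {
  if (config$n_rare_markers == 0) return(pop)
  candidates <- setdiff(seq_len(config$n_markers), pop$causal_markers)
  if (length(candidates) < config$n_rare_markers)
    stop("rare markers would overlap the causal set")
  with_seed(child_seed(seed, 202L), {
    rare <- sort(sample(candidates, config$n_rare_markers))
    n <- config$n_samples
    for (j in rare) {
      col <- rep(0L, n)
      copies <- sample.int(config$rare_max_copies + 1L, 1L) - 1L
      if (copies > 0) col[sample.int(n, copies)] <- 1L
      keep_na <- is.na(pop$genotypes$dosage[, j])
      col[keep_na] <- NA_integer_
      pop$genotypes$dosage[, j] <- col
    }
    pop$rare_markers <- rare
    pop
  })
}

#' Mask genotype calls to emulate the panel's missingness pattern
#'
#' Sets exactly \code{n_missing_cells} genotype cells to \code{NA}: one
#' designated marker (chosen outside the causal and rare sets) receives
#' \code{low_callrate_missing} missing calls, pushing its call-rate below
#' 0.85; the remaining cells are placed uniformly at random over the other
#' markers, capped at \code{max_missing_per_marker} per marker so no second
#' marker can fail the call-rate filter, and no sample can lose more than
#' half of its genotypes.
#'
#' @inheritParams force_rare_markers
#' @return The population with missing cells masked and
#'   \code{low_callrate_marker} recorded.
#' @export
apply_missingness <- function(pop, config = pop$config, seed = 1L) {
  validate_syn_config(config)
  if (anyNA(pop$genotypes$dosage))
    stop("apply_missingness expects a fully observed genotype matrix")
  if (config$n_missing_cells == 0) {
    pop$low_callrate_marker <- NA_integer_
    return(pop)
  }
  with_seed(child_seed(seed, 303L), {
    n <- config$n_samples
    m <- config$n_markers
    candidates <- setdiff(seq_len(m), c(pop$causal_markers, pop$rare_markers))
    lc <- if (config$low_callrate_missing > 0) sample(candidates, 1L) else NA_integer_
    dosage <- pop$genotypes$dosage
    if (!is.na(lc))
      dosage[sample.int(n, config$low_callrate_missing), lc] <- NA_integer_

    remaining <- config$n_missing_cells - config$low_callrate_missing
    other <- setdiff(seq_len(m), lc)
    cells <- as.matrix(expand.grid(sample = seq_len(n), marker = other))
    for (try in 1:100) {
      pick <- cells[sample.int(nrow(cells), remaining), , drop = FALSE]
      per_marker <- tabulate(pick[, "marker"], nbins = m)
      per_sample <- tabulate(pick[, "sample"], nbins = n)
      if (!is.na(lc)) per_sample <- per_sample +
          tabulate(which(is.na(dosage[, lc])), nbins = n)
      if (max(per_marker) <= config$max_missing_per_marker &&
          max(per_sample) <= m %/% 2) break
      if (try == 100) stop("could not place missing cells within the caps")
    }
    dosage[pick] <- NA_integer_
    pop$genotypes$dosage <- dosage
    pop$low_callrate_marker <- lc
    pop
  })
}

#' Generate the default synthetic fixture in one call
#'
#' Convenience pipeline: \code{\link{generate_population}} then
#' \code{\link{force_rare_markers}} then \code{\link{apply_missingness}},
#' all driven by one master seed. The result is the standard input of the
#' QC and noise-ladder stages.
#'
#' @inheritParams generate_population
#' @return A \code{syn_population}.
#' @export
syn_beet_population <- function(config = syn_config(), seed = 1L) {
  pop <- generate_population(config, seed)
  pop <- force_rare_markers(pop, config, seed)
  apply_missingness(pop, config, seed)
}
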