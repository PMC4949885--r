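#' The default ladder of mislabelling proportions
#'
#' From the clean base scenario (0) through 12 intermediate steps up to the
#' theoretical maximum of 0.5, 14 levels in all.
#'
#' @return Strictly increasing numeric vector of 14 fractions.
#' @export
default_noise_ladder <- function() {
  c(0, 0.01, 0.025, 0.05, 0.075, 0.10, 0.125, 0.15, 0.175, 0.20,
    0.25, 0.30, 0.40, 0.50)
}

#' Flip a fraction of binary labels
#'
#' Samples exactly \code{round(p * n)} distinct positions uniformly without
#' replacement (half rounded away from zero) and inverts them (0 -> 1,
#' 1 -> 0). The input vector is not modified.
#'
#' @param y Binary (0/1) label vector.
#' @param p Fraction of labels to flip, in [0, 0.5].
#' @param seed Integer seed making the draw reproducible.
#' @return List with \code{labels} (the noisy vector) and \code{flipped}
#'   (sorted integer indices that were inverted).
#' @export
#' @examples
#' flip_labels(c(1, 1, 0, 0), p = 0.5, seed = 1)
flip_labels <- function(y, p, seed = NULL) {
  if (length(y) == 0 || !all(y %in% c(0, 1)))
    stop("labels must be a non-empty 0/1 vector")
  stopifnot(p >= 0, p <= 0.5)
  n_flip <- as.integer(round_half_away(p * length(y)))
  if (n_flip == 0) return(list(labels = y, flipped = integer(0)))
  idx <- with_seed(seed, sort(sample.int(length(y), n_flip)))
  noisy <- y
  noisy[idx] <- (if (is.integer(y)) 1L else 1) - noisy[idx]
  list(labels = noisy, flipped = idx)
}

#' Expected minority-class frequency after random label flipping
#'
#' When a fraction p of labels is flipped uniformly at random in a vector
#' whose minority class has frequency f, the expected frequency of the
#' (original) minority class becomes f (1 - p) + (1 - f) p = f + p (1 - 2f):
#' the classes drift toward balance, reaching 0.5 at p = 0.5.
#'
#' @param f Minority-class frequency in [0, 0.5].
#' @param p Flip fraction in [0, 0.5].
#' @return The expected post-flip minority frequency.
#' @export
#' @examples
#' expected_minority_frequency(24 / 123, 0.5) # 0.5
expected_minority_frequency <- function(f, p) {
  stopifnot(f >= 0, f <= 0.5, p >= 0, p <= 0.5)
  f + p * (1 - 2 * f)
}
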