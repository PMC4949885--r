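#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed plus any number of integer stream
#' identifiers to a new seed in \code{[1, 2^31 - 2]}, using a Lehmer-style
#' multiplicative congruential step per component. Every stochastic stage of
#' the pipeline (population generation, missingness placement, label
#' flipping, fold assignment, tree growing, ...) draws its seed through this
#' function so that one master seed reproduces an entire experiment while
#' stages remain statistically independent.
#'
#' @param seed Master seed (single integer).
#' @param ... Integer stream identifiers (e.g. noise-level index, replicate
#'   number, fold number).
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(42, 1, 3)
child_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  x <- as.double(seed %% m)
  ids <- c(...)
  if (length(ids) == 0) ids <- 0L
  for (k in as.double(ids)) {
    # 48271 * m < 2^53: exact in double arithmetic
    x <- (x * 48271 + (k %% m) * 7919 + 1) %% m
  }
  as.integer(x + 1)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so library functions that consume randomness do not
#' perturb the global stream.
#'
#' @param seed Integer seed; if \code{NULL} the code runs on the current stream.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
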