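# Internal helpers shared across modules.

# Tolerance for "is this count integral": file values like 3.0000000001 are
# still rejected downstream; this only absorbs representation noise.
.INT_TOL <- 1e-8

.is_wholenumber <- function(x, tol = .INT_TOL) {
  is.finite(x) & abs(x - round(x)) < tol
}

#' Derive independent child seeds from one root seed
#'
#' Randomized stages of the pipeline (null ensembles, annealing restarts,
#' ordination starts, permutation tests) each consume their own child seed so
#' that a single root seed makes the whole analysis reproducible while the
#' stages stay statistically independent.
#'
#' @param seed Integer root seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length \code{n}, each in \code{[1, 2^31 - 2]}.
#' @examples
#' childSeeds(42, 3)
#' @export
childSeeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed), n >= 1)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run expr under a given seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  expr
}

# x * log(x) with the 0 * log(0) := 0 convention.
.xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}

.match_guild <- function(guild) {
  match.arg(guild, c("plant", "ant"))
}
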