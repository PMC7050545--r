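# Degree-proportional Bernoulli null model (null model II / "Ce") and
# Monte Carlo significance testing for scalar network statistics.

#' Cell occurrence probabilities under null model II ("Ce")
#'
#' On the binarized matrix, the probability that cell \eqn{(i, j)} is
#' occupied is the mean of the row and column fill fractions,
#' \eqn{p_{ij} = (k_i/A + k_j/P)/2}: an interaction is the more likely the
#' more partners both species have. The mean of the probability table equals
#' the observed fill exactly, so the null preserves connectance in
#' expectation.
#'
#' @param x An [InteractionNetwork-class].
#' @return Matrix of probabilities in [0, 1], same dimnames as the network.
#' @references Bascompte et al. (2003) PNAS 100:9383-9387.
#' @export
cellProbabilities <- function(x) {
  stopifnot(is(x, "InteractionNetwork"))
  B <- (interactionCounts(x) > 0) + 0
  P <- nrow(B); A <- ncol(B)
  (outer(rowSums(B) / A, colSums(B) / P, "+")) / 2
}

#' Draw one binary null matrix
#'
#' Independent Bernoulli draws from a probability table. By default any
#' matrix with an all-zero row or column is rejected and redrawn, so the
#' null matrices keep the observed dimensions (the convention under which
#' the null means of nestedness statistics are comparable across studies);
#' note the conditioning biases the accepted fill slightly upward on sparse
#' matrices. Set \code{reject_degenerate = FALSE} for unconditioned draws,
#' whose expected fill equals \code{mean(prob)} exactly. Consumes the
#' caller's RNG stream; wrap in \code{set.seed()} for reproducibility.
#'
#' @param prob Probability matrix (e.g. from [cellProbabilities()]).
#' @param max_tries Retry bound before giving up (default 10000).
#' @param reject_degenerate Redraw matrices with empty rows/columns
#'   (default TRUE).
#' @return A binary matrix of the same dimensions.
#' @export
sampleNullMatrix <- function(prob, max_tries = 10000, reject_degenerate = TRUE) {
  stopifnot(is.matrix(prob), all(prob >= 0 & prob <= 1))
  for (k in seq_len(max_tries)) {
    B <- matrix(as.numeric(stats::runif(length(prob)) < prob),
                nrow(prob), ncol(prob), dimnames = dimnames(prob))
    if (!reject_degenerate) return(B)
    if (all(rowSums(B) > 0) && all(colSums(B) > 0)) return(B)
  }
  stop("could not draw a null matrix without empty rows/columns in ",
       max_tries, " tries; the matrix is probably too sparse")
}

# Named statistics usable by nullTest on binary matrices.
.null_statistics <- function(name) {
  switch(name,
    nodf = function(B) nodf(interactionNetwork(B)),
    connectance = function(B) mean(B > 0),
    fill = function(B) mean(B > 0),
    stop("unknown statistic: ", name)
  )
}

#' Monte Carlo null-model test of a network statistic
#'
#' Computes a scalar statistic on the observed (binarized) network and on
#' \code{n_reps} draws from null model II, and reports the add-one Monte
#' Carlo p-value \eqn{(\#\{null \ge obs\} + 1)/(n_{reps} + 1)} (for the
#' default one-sided "greater" alternative, the direction of the nestedness
#' hypothesis). Each replicate runs under its own child seed derived from
#' \code{seed}, so results are reproducible and replicates independent.
#'
#' @param x An [InteractionNetwork-class].
#' @param statistic Either a name (\code{"nodf"}, \code{"connectance"},
#'   \code{"fill"}) or a function taking a binary matrix and returning a
#'   scalar.
#' @param n_reps Number of null replicates (default 1000).
#' @param seed Integer root seed.
#' @param alternative \code{"greater"} (default), \code{"less"} or
#'   \code{"two.sided"}.
#' @return A [NullEnsemble-class].
#' @examples
#' net <- generateNetwork(syntheticConfig(n_plants = 12, n_ants = 8, seed = 1))$network
#' nullTest(net, "nodf", n_reps = 99, seed = 7)
#' @export
nullTest <- function(x, statistic = "nodf", n_reps = 1000, seed = 1,
                     alternative = c("greater", "less", "two.sided")) {
  stopifnot(is(x, "InteractionNetwork"), n_reps >= 1)
  alternative <- match.arg(alternative)
  stat_name <- if (is.character(statistic)) statistic else
    deparse(substitute(statistic))[1]
  stat_fun <- if (is.character(statistic)) .null_statistics(statistic) else statistic
  B_obs <- (interactionCounts(x) > 0) + 0
  observed <- stat_fun(B_obs)
  prob <- cellProbabilities(x)
  seeds <- childSeeds(seed, n_reps)
  null_values <- vapply(seeds, function(s)
    .with_seed(s, stat_fun(sampleNullMatrix(prob))), numeric(1))
  p <- .mc_pvalue(observed, null_values, alternative)
  new("NullEnsemble", statistic = stat_name, observed = observed,
      null_values = null_values, p_value = p, alternative = alternative,
      seed = as.integer(seed))
}

# Add-one Monte Carlo p-value.
.mc_pvalue <- function(observed, null_values, alternative) {
  n <- length(null_values)
  p_ge <- (sum(null_values >= observed) + 1) / (n + 1)
  p_le <- (sum(null_values <= observed) + 1) / (n + 1)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}
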