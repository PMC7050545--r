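# Auxiliary univariate statistics: Spearman rank correlation, chi-square
# goodness of fit, one-way ANOVA, Sorensen floristic similarity. These wrap
# the standard stats implementations behind a uniform surface.

#' Spearman rank correlation (mid-ranks, t approximation)
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), with a
#' two-sided p-value from the t approximation — adequate at the sample sizes
#' typical of species-level trait tests.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return An object of class \code{htest} with \code{estimate} (rho),
#'   \code{p.value} and \code{statistic}.
#' @examples
#' spearmanTest(c(1, 2, 2, 4), c(10, 20, 30, 40))$estimate  # 0.9487
#' @export
spearmanTest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  stats::cor.test(x, y, method = "spearman", exact = FALSE)
}

#' Chi-square goodness of fit
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with \eqn{k - 1} degrees of freedom.
#' Expected counts default to uniform across categories.
#'
#' @param observed Vector of observed counts.
#' @param expected Optional vector of expected counts (same length,
#'   all > 0); defaults to uniform.
#' @return An \code{htest} with \code{statistic}, \code{parameter} (df) and
#'   \code{p.value}.
#' @examples
#' chisqGof(c(10, 20))$statistic  # 3.333, df = 1
#' @export
chisqGof <- function(observed, expected = NULL) {
  stopifnot(length(observed) >= 2, all(observed >= 0))
  if (is.null(expected)) {
    stats::chisq.test(observed)
  } else {
    stopifnot(length(expected) == length(observed))
    if (any(expected <= 0)) stop("all expected counts must be > 0")
    stats::chisq.test(observed, p = expected / sum(expected))
  }
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA:
#' \eqn{F = MS_{between}/MS_{within}} on \eqn{(k - 1, N - k)} degrees of
#' freedom.
#'
#' @param groups A list of numeric vectors, one per group (>= 2 groups).
#' @return An \code{htest} with \code{statistic} (F), \code{parameter}
#'   (both df) and \code{p.value}.
#' @examples
#' anovaOneway(list(c(1, 2, 3), c(4, 5, 6)))$statistic  # F = 13.5
#' @export
anovaOneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  values <- unlist(groups)
  if (stats::var(values) == 0) stop("all values identical: ANOVA undefined")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  stats::oneway.test(values ~ g, var.equal = TRUE)
}

#' Sorensen similarity of two species sets
#'
#' \eqn{QS = 2|A \cap B| / (|A| + |B|)}: 1 for identical sets, 0 for
#' disjoint ones. On presence/absence data this equals one minus the
#' Bray-Curtis dissimilarity of the corresponding indicator vectors.
#'
#' @param list_a,list_b Non-empty character vectors of species names
#'   (duplicates ignored).
#' @return Similarity in [0, 1].
#' @examples
#' sorensen(c("a", "b", "c"), c("b", "c", "d"))  # 0.667
#' @export
sorensen <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  stopifnot(length(a) > 0, length(b) > 0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
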