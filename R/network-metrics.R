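# Network-level structure: connectance, binary and weighted NODF,
# dependence asymmetry, Horn niche overlap.

#' Connectance
#'
#' The proportion of realized interactions among all possible plant-ant
#' pairs, \eqn{C = L / (P \times A)}.
#'
#' @param x An [InteractionNetwork-class].
#' @return A fraction in [0, 1].
#' @examples
#' net <- interactionNetwork(matrix(c(2, 0, 1, 3), 2, 2,
#'   dimnames = list(c("P1", "P2"), c("A1", "A2"))))
#' connectance(net)  # 0.75
#' @export
connectance <- function(x) {
  stopifnot(is(x, "InteractionNetwork"))
  linkCount(x) / prod(dim(x))
}

# NODF contribution of all ordered pairs within one margin of a binary
# matrix (rows of B). Decreasing-fill condition: a pair scores only when the
# two degrees differ; the score is the paired overlap of the sparser member.
.nodf_margin_binary <- function(B) {
  n <- nrow(B)
  if (n < 2) return(0)
  deg <- rowSums(B)
  shared <- B %*% t(B)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (deg[i] == deg[j]) next
    lo <- if (deg[i] < deg[j]) i else j
    total <- total + 100 * shared[i, j] / deg[lo]
  }
  total
}

# Weighted NODF margin: the sparser member is the one with the smaller
# marginal total; a cell counts when 0 < w_lo < w_hi.
.nodf_margin_weighted <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  tot <- rowSums(W)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (tot[i] == tot[j]) next
    hi <- if (tot[i] > tot[j]) i else j
    lo <- if (hi == i) j else i
    n_lo <- sum(W[lo, ] > 0)
    if (n_lo == 0) next
    filled <- sum(W[lo, ] > 0 & W[lo, ] < W[hi, ])
    total <- total + 100 * filled / n_lo
  }
  total
}

#' Nestedness based on Overlap and Decreasing Fill (NODF)
#'
#' Binary NODF: for each unordered pair of rows (and of columns), the member
#' with the strictly larger degree contributes \eqn{100 \times} the fraction
#' of the sparser member's partners it shares; equal-degree pairs contribute
#' zero (the decreasing-fill condition). The score is the pair total divided
#' by \eqn{P(P-1)/2 + A(A-1)/2}, ranging 0 (no nesting) to 100 (strict
#' nesting).
#'
#' Weighted NODF (\code{weighted = TRUE}) replaces presence overlap with the
#' count of partner cells where the sparser member's weight is positive but
#' strictly below the larger-total member's weight, the "larger" member
#' being the one with the larger marginal total (zero contribution on ties).
#'
#' @param x An [InteractionNetwork-class] with at least 2 rows and 2 columns.
#' @param weighted Use the weighted (WNODF) variant. Default \code{FALSE}.
#' @return A score in [0, 100].
#' @references Almeida-Neto et al. (2008) Oikos 117:1227-1239;
#'   Almeida-Neto & Ulrich (2011) Env. Mod. Soft. 26:173-178.
#' @examples
#' nested <- interactionNetwork(matrix(c(1,1,1, 1,1,0, 1,0,0), 3, 3, byrow = TRUE,
#'   dimnames = list(paste0("P", 1:3), paste0("A", 1:3))))
#' nodf(nested)  # 100
#' @export
nodf <- function(x, weighted = FALSE) {
  stopifnot(is(x, "InteractionNetwork"))
  W <- interactionCounts(x)
  if (nrow(W) < 2 || ncol(W) < 2)
    stop("NODF undefined for a single-row or single-column matrix")
  npairs <- choose(nrow(W), 2) + choose(ncol(W), 2)
  if (weighted) {
    as.numeric(.nodf_margin_weighted(W) + .nodf_margin_weighted(t(W))) / npairs
  } else {
    B <- (W > 0) + 0
    as.numeric(.nodf_margin_binary(B) + .nodf_margin_binary(t(B))) / npairs
  }
}

#' Dependence matrix of one guild on the other
#'
#' The dependence of plant \eqn{i} on ant \eqn{j} is the fraction of plant
#' \eqn{i}'s total interaction frequency contributed by \eqn{j}
#' (\code{guild = "plant"}: rows normalized); conversely for ants
#' (\code{guild = "ant"}: columns normalized). Each species' dependences sum
#' to one.
#'
#' @param x An [InteractionNetwork-class].
#' @param guild Whose dependences: \code{"plant"} or \code{"ant"}.
#' @return A plants x ants matrix of dependences.
#' @export
dependenceMatrix <- function(x, guild = c("plant", "ant")) {
  guild <- match.arg(guild)
  w <- interactionCounts(x)
  if (guild == "plant") sweep(w, 1, rowSums(w), "/")
  else sweep(w, 2, colSums(w), "/")
}

#' Mean dependence asymmetry
#'
#' For every realized link, the absolute difference between the plant's
#' dependence on the ant and the ant's dependence on the plant, normalized
#' by the larger of the two; averaged over all links. 0 means perfectly
#' reciprocal dependences, values near 1 strongly one-sided links.
#'
#' @param x An [InteractionNetwork-class].
#' @return Mean asymmetry in [0, 1].
#' @references Bascompte et al. (2006) Science 312:431-433.
#' @export
dependenceAsymmetry <- function(x) {
  stopifnot(is(x, "InteractionNetwork"))
  dp <- dependenceMatrix(x, "plant")
  da <- dependenceMatrix(x, "ant")
  nz <- interactionCounts(x) > 0
  mean(abs(dp[nz] - da[nz]) / pmax(dp[nz], da[nz]))
}

# Horn's information-theoretic overlap of two proportion profiles.
.horn_pair <- function(p, q) {
  (sum(.xlogx(p + q)) - sum(.xlogx(p)) - sum(.xlogx(q))) / (2 * log(2))
}

#' Mean within-guild niche overlap (Horn's index)
#'
#' For every unordered pair of species within a guild, Horn's
#' information-theoretic overlap of their partner-use proportion profiles,
#' \deqn{R_o = \frac{\sum (p+q)\ln(p+q) - \sum p\ln p - \sum q\ln q}{2\ln 2},}
#' with \eqn{0\ln 0 := 0}; 1 for identical profiles, 0 for disjoint partner
#' sets. Returns the mean over pairs. Invariant to rescaling either species'
#' weights by a positive constant.
#'
#' @param x An [InteractionNetwork-class].
#' @param guild Guild whose pairwise overlap is averaged.
#' @return Mean overlap in [0, 1].
#' @references Horn (1966) Am. Nat. 100:419-424.
#' @export
nicheOverlap <- function(x, guild = c("plant", "ant")) {
  guild <- match.arg(guild)
  w <- interactionCounts(x)
  profiles <- if (guild == "plant") w else t(w)
  profiles <- sweep(profiles, 1, rowSums(profiles), "/")
  n <- nrow(profiles)
  if (n < 2) stop("niche overlap needs at least two species in the guild")
  vals <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, .horn_pair(profiles[i, ], profiles[j, ]))
  mean(vals)
}

#' Network-level metrics report
#'
#' Computes the full set of network-level indices in one call:
#' connectance, binary NODF, weighted NODF, mean dependence asymmetry, and
#' mean Horn niche overlap within each guild.
#'
#' @param x An [InteractionNetwork-class].
#' @return One-row data.frame with columns \code{connectance}, \code{nodf},
#'   \code{wnodf}, \code{dependence_asymmetry}, \code{niche_overlap_ants},
#'   \code{niche_overlap_plants}.
#' @examples
#' net <- generateNetwork(syntheticConfig(n_plants = 12, n_ants = 8, seed = 1))$network
#' networkLevel(net)
#' @export
networkLevel <- function(x) {
  stopifnot(is(x, "InteractionNetwork"))
  data.frame(
    connectance = connectance(x),
    nodf = nodf(x, weighted = FALSE),
    wnodf = nodf(x, weighted = TRUE),
    dependence_asymmetry = dependenceAsymmetry(x),
    niche_overlap_ants = nicheOverlap(x, "ant"),
    niche_overlap_plants = nicheOverlap(x, "plant")
  )
}
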