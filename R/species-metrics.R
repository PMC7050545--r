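# Species-level metrics: degree, species strength, d' specialization,
# and core-periphery classification by standardized degree.

#' Binary species degrees
#'
#' Number of partners of each species in one guild.
#'
#' @param x An [InteractionNetwork-class].
#' @param guild Guild to report.
#' @return Named integer vector of partner counts.
#' @export
speciesDegrees <- function(x, guild = c("plant", "ant")) {
  guild <- match.arg(guild)
  w <- interactionCounts(x)
  if (guild == "plant") rowSums(w > 0) else colSums(w > 0)
}

#' Species strength
#'
#' The strength of an ant species is the sum over its partner plants of
#' those plants' dependences on it (and vice versa for plants): a
#' quantitative extension of degree measuring how much the opposite guild
#' relies on the species. Strengths within a guild always sum exactly to the
#' size of the opposite guild.
#'
#' @param x An [InteractionNetwork-class].
#' @param guild Guild whose strengths are returned.
#' @return Named numeric vector of strengths (>= 0).
#' @references Bascompte et al. (2006) Science 312:431-433.
#' @examples
#' net <- interactionNetwork(matrix(c(2, 0, 1, 3), 2, 2,
#'   dimnames = list(c("P1", "P2"), c("A1", "A2"))))
#' speciesStrength(net, "ant")  # sums to 2, the number of plants
#' @export
speciesStrength <- function(x, guild = c("plant", "ant")) {
  guild <- match.arg(guild)
  if (guild == "ant") colSums(dependenceMatrix(x, "plant"))
  else rowSums(dependenceMatrix(x, "ant"))
}

# Kullback-Leibler divergence of an integer allocation `alloc` (partner use)
# from availability q, at total `tot`.
.dfun_d <- function(alloc, q, tot) {
  p <- alloc / tot
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

# Minimum achievable d for an integer allocation of `tot` visits given
# availabilities q: marginal-allocation (greedy add-one) algorithm, optimal
# because the objective is separable and convex in the per-partner counts.
.dfun_min <- function(tot, q) {
  m <- length(q)
  alloc <- integer(m)
  # term(n_j) = (n_j/tot) * log(n_j/(tot*q_j)); delta of adding one unit
  term <- function(n, qj) ifelse(n == 0, 0, (n / tot) * log(n / (tot * qj)))
  for (step in seq_len(tot)) {
    delta <- term(alloc + 1L, q) - term(alloc, q)
    j <- which.min(delta)
    alloc[j] <- alloc[j] + 1L
  }
  .dfun_d(alloc, q, tot)
}

# Maximum achievable d: greedily monopolize the most exclusive (lowest
# availability) partners, each up to its observed marginal total.
.dfun_max <- function(tot, q, capacity) {
  ord <- order(q)
  alloc <- numeric(length(q))
  remaining <- tot
  for (j in ord) {
    take <- min(remaining, capacity[j])
    alloc[j] <- take
    remaining <- remaining - take
    if (remaining <= 0) break
  }
  .dfun_d(alloc, q, tot)
}

#' Standardized Kullback-Leibler specialization d'
#'
#' For each species, the divergence of its partner-use proportions from the
#' partners' overall availability (partner marginal totals over the grand
#' total), \eqn{d_i = \sum_j p'_{ij} \ln(p'_{ij}/q_j)}, standardized between
#' the minimum and maximum divergence achievable by integer reallocations of
#' the species' observed total: \eqn{d' = (d - d_{min})/(d_{max} - d_{min})},
#' clamped to [0, 1]. The minimum is found by optimal marginal allocation
#' toward the availability profile; the maximum by greedy monopolization of
#' the most exclusive partners up to their observed totals. 0 means
#' opportunistic use in proportion to availability; 1 maximal selectivity.
#' When no discrimination is possible (\eqn{d_{max} = d_{min}}) d' is 0.
#'
#' @param x An [InteractionNetwork-class].
#' @param guild Guild whose specialization is computed.
#' @return Named numeric vector of d' values in [0, 1].
#' @references Bluethgen, Menzel & Bluethgen (2006) BMC Ecology 6:9.
#' @export
dPrime <- function(x, guild = c("plant", "ant")) {
  guild <- match.arg(guild)
  w <- interactionCounts(x)
  if (guild == "ant") w <- t(w)
  grand <- sum(w)
  q <- colSums(w) / grand              # partner availability
  capacity <- colSums(w)               # at most a partner's observed total
  out <- numeric(nrow(w))
  names(out) <- rownames(w)
  for (i in seq_len(nrow(w))) {
    tot <- sum(w[i, ])
    d_obs <- .dfun_d(w[i, ], q, tot)
    d_min <- .dfun_min(tot, q)
    d_max <- .dfun_max(tot, q, capacity)
    out[i] <- if (d_max - d_min < 1e-12) 0
              else min(1, max(0, (d_obs - d_min) / (d_max - d_min)))
  }
  out
}

#' Core-periphery classification by standardized degree
#'
#' Standardized degree \eqn{G_c = (k_i - \bar k)/\mathrm{sd}(k)} within a
#' guild, using binary degrees and (by default) the sample standard
#' deviation. Species with \eqn{G_c \ge 1} form the generalist core, the
#' rest the periphery.
#'
#' @param x An [InteractionNetwork-class].
#' @param guild Guild to classify.
#' @param sd_type \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"}.
#' @return data.frame with columns \code{species}, \code{degree}, \code{Gc},
#'   \code{core} (logical).
#' @references Dattilo, Guimaraes & Izzo (2013) Oikos 122:1643-1648.
#' @examples
#' net <- generateNetwork(syntheticConfig(n_plants = 12, n_ants = 8, seed = 1))$network
#' corePeriphery(net, "ant")
#' @export
corePeriphery <- function(x, guild = c("plant", "ant"), sd_type = c("sample", "population")) {
  guild <- match.arg(guild)
  sd_type <- match.arg(sd_type)
  k <- speciesDegrees(x, guild)
  if (length(k) < 2 || stats::var(k) == 0)
    stop("core/periphery undefined: zero degree variance in ", guild, " guild")
  s <- stats::sd(k)
  if (sd_type == "population") s <- s * sqrt((length(k) - 1) / length(k))
  gc <- (k - mean(k)) / s
  data.frame(species = names(k), degree = as.integer(k), Gc = as.numeric(gc),
             core = as.numeric(gc) >= 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Species-level metrics report for both guilds
#'
#' Degree, species strength, d' specialization, standardized degree
#' \eqn{G_c} and core membership for every plant and ant.
#'
#' @param x An [InteractionNetwork-class].
#' @return data.frame with columns \code{species}, \code{guild},
#'   \code{degree}, \code{strength}, \code{dprime}, \code{Gc}, \code{core}.
#' @export
speciesLevel <- function(x) {
  stopifnot(is(x, "InteractionNetwork"))
  out <- lapply(c("plant", "ant"), function(g) {
    cp <- corePeriphery(x, g)
    data.frame(species = cp$species, guild = g, degree = cp$degree,
               strength = as.numeric(speciesStrength(x, g)[cp$species]),
               dprime = as.numeric(dPrime(x, g)[cp$species]),
               Gc = cp$Gc, core = cp$core, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
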