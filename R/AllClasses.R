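#' @import methods
NULL

# ---------------------------------------------------------------------------
# InteractionNetwork
# ---------------------------------------------------------------------------

#' Weighted bipartite plant-ant interaction network
#'
#' The central data container of the package: a labeled non-negative integer
#' matrix of interaction frequencies with plant species as rows and ant
#' species as columns. Cell \eqn{w_{ij}} is the number of censuses in which
#' ants of species \eqn{j} were recorded feeding on extrafloral nectar of
#' plant species \eqn{i} (or, generically, any bipartite count of pairwise
#' interactions).
#'
#' Validity requires: all weights finite, non-negative and integral; unique
#' non-empty labels within each guild; no all-zero row or column; a positive
#' grand total.
#'
#' @slot counts Numeric matrix of non-negative integral weights with
#'   \code{dimnames}; rows are plants, columns are ants.
#'
#' @seealso [interactionNetwork()] for construction,
#'   [readInteractionMatrix()] for file input.
#' @export
setClass("InteractionNetwork", representation(counts = "matrix"))

setValidity("InteractionNetwork", function(object) {
  w <- object@counts
  if (!is.numeric(w)) return("counts must be numeric")
  if (nrow(w) < 1 || ncol(w) < 1) return("matrix must have at least one row and column")
  if (is.null(rownames(w)) || is.null(colnames(w)))
    return("matrix must carry plant (row) and ant (column) labels")
  if (anyNA(w) || any(!is.finite(w))) return("all weights must be finite")
  if (any(w < 0)) return("all weights must be non-negative")
  if (!all(.is_wholenumber(w))) return("all weights must be integral counts")
  rl <- rownames(w); cl <- colnames(w)
  if (any(rl == "") || any(cl == "")) return("empty species label")
  if (anyDuplicated(rl)) return(sprintf("duplicate plant label: '%s'", rl[duplicated(rl)][1]))
  if (anyDuplicated(cl)) return(sprintf("duplicate ant label: '%s'", cl[duplicated(cl)][1]))
  if (sum(w) <= 0) return("matrix has no interactions")
  if (any(rowSums(w) == 0)) return(sprintf("all-zero row: '%s'", rl[rowSums(w) == 0][1]))
  if (any(colSums(w) == 0)) return(sprintf("all-zero column: '%s'", cl[colSums(w) == 0][1]))
  TRUE
})

#' Construct an InteractionNetwork from a labeled count matrix
#'
#' @param counts Numeric matrix of non-negative integral interaction counts;
#'   rows are plants, columns are ants, both with unique labels. Row or column
#'   names missing from the matrix may be supplied through \code{plants} /
#'   \code{ants}.
#' @param plants,ants Optional character vectors of species labels.
#' @return A validated [InteractionNetwork-class] object.
#' @examples
#' m <- matrix(c(2, 0, 1, 3), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("A1", "A2")))
#' net <- interactionNetwork(m)
#' linkCount(net)
#' @export
interactionNetwork <- function(counts, plants = NULL, ants = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(plants)) rownames(counts) <- plants
  if (!is.null(ants)) colnames(counts) <- ants
  if (!is.null(rownames(counts))) rownames(counts) <- trimws(rownames(counts))
  if (!is.null(colnames(counts))) colnames(counts) <- trimws(colnames(counts))
  storage.mode(counts) <- "double"
  new("InteractionNetwork", counts = counts)
}

# ---------------------------------------------------------------------------
# SpeciesAttributes
# ---------------------------------------------------------------------------

#' Per-species attribute table for one guild
#'
#' Categorical and continuous covariates for the species of one guild,
#' keyed by species label. Recognized plant columns: \code{efn} (extrafloral
#' nectary distribution, \code{"C"} circumscribed / \code{"D"} disperse),
#' \code{habitat} (\code{"O"} open / \code{"S"} shaded / \code{"B"} both) and
#' \code{cover} (percent line cover, > 0). Recognized ant columns:
#' \code{invasive} (\code{"INV"} / \code{"NO"}), \code{dominance}
#' (behavioral dominance class \code{"A"}--\code{"F"}) and
#' \code{head_length} (mm, > 0). Extra columns are carried along untouched.
#'
#' @slot guild Either \code{"plant"} or \code{"ant"}.
#' @slot data A data.frame with species labels as row names.
#' @export
setClass("SpeciesAttributes",
         representation(guild = "character", data = "data.frame"))

.ATTR_LEVELS <- list(
  efn = c("C", "D"),
  habitat = c("O", "S", "B"),
  invasive = c("INV", "NO"),
  dominance = LETTERS[1:6]
)

setValidity("SpeciesAttributes", function(object) {
  if (!object@guild %in% c("plant", "ant")) return("guild must be 'plant' or 'ant'")
  d <- object@data
  if (nrow(d) == 0) return("no species rows")
  labs <- rownames(d)
  if (is.null(labs) || anyDuplicated(labs))
    return("species labels must be unique row names")
  for (col in intersect(names(.ATTR_LEVELS), names(d))) {
    vals <- d[[col]]
    bad <- !is.na(vals) & !vals %in% .ATTR_LEVELS[[col]]
    if (any(bad))
      return(sprintf("unknown %s level: '%s'", col, vals[bad][1]))
  }
  for (col in intersect(c("cover", "head_length"), names(d))) {
    vals <- d[[col]]
    if (!is.numeric(vals)) return(sprintf("%s must be numeric", col))
    bad <- !is.na(vals) & (!is.finite(vals) | vals <= 0)
    if (any(bad)) return(sprintf("%s must be finite and > 0", col))
  }
  TRUE
})

#' Construct a SpeciesAttributes table
#'
#' @param data A data.frame of per-species attributes. Species labels are
#'   taken from a \code{species} column if present, else from row names.
#' @param guild \code{"plant"} or \code{"ant"}.
#' @return A validated [SpeciesAttributes-class] object.
#' @examples
#' speciesAttributes(data.frame(species = c("a", "b"),
#'                              habitat = c("O", "S"),
#'                              cover = c(10, 20)), guild = "plant")
#' @export
speciesAttributes <- function(data, guild = c("plant", "ant")) {
  guild <- match.arg(guild)
  data <- as.data.frame(data)
  if ("species" %in% names(data)) {
    rownames(data) <- trimws(as.character(data$species))
    data$species <- NULL
  }
  new("SpeciesAttributes", guild = guild, data = data)
}

# ---------------------------------------------------------------------------
# NullEnsemble
# ---------------------------------------------------------------------------

#' Monte Carlo null-ensemble test result
#'
#' Result of comparing an observed scalar network statistic against an
#' ensemble of degree-proportional Bernoulli (null model II / "Ce") random
#' matrices. The p-value follows the add-one permutation convention
#' \eqn{p = (\#\{null \ge obs\} + 1)/(n + 1)} for one-sided "greater" tests,
#' so it is never exactly zero.
#'
#' @slot statistic Name of the statistic.
#' @slot observed Observed value on the data.
#' @slot null_values Numeric vector, the full null ensemble.
#' @slot p_value Add-one Monte Carlo p-value.
#' @slot alternative One of \code{"greater"}, \code{"less"}, \code{"two.sided"}.
#' @slot seed Root seed used for the ensemble.
#' @export
setClass("NullEnsemble",
         representation(statistic = "character", observed = "numeric",
                        null_values = "numeric", p_value = "numeric",
                        alternative = "character", seed = "integer"))

setValidity("NullEnsemble", function(object) {
  if (length(object@null_values) < 1) return("n_reps must be >= 1")
  if (!is.finite(mean(object@null_values))) return("null mean must be finite")
  if (object@p_value <= 0 || object@p_value > 1) return("p_value must lie in (0, 1]")
  TRUE
})

# ---------------------------------------------------------------------------
# ModulePartition
# ---------------------------------------------------------------------------

#' Bipartite module partition with its Barber modularity score
#'
#' Assignment of every plant and ant to a module, together with the Barber
#' bipartite modularity \eqn{Q_B} of the assignment and, when produced by the
#' simulated-annealing optimizer, the trace of best-so-far scores per
#' temperature.
#'
#' @slot membership Named integer vector over all species (plants then ants);
#'   module ids are \code{1..n_modules} with no empty module.
#' @slot guild Character vector parallel to \code{membership}
#'   (\code{"plant"} / \code{"ant"}).
#' @slot qb Barber modularity of the partition.
#' @slot trace Numeric matrix with columns \code{temperature} and
#'   \code{best_qb} (zero rows for non-annealed partitions).
#' @export
setClass("ModulePartition",
         representation(membership = "integer", guild = "character",
                        qb = "numeric", trace = "matrix"))

setValidity("ModulePartition", function(object) {
  m <- object@membership
  if (is.null(names(m)) || anyNA(m)) return("membership must be a complete named assignment")
  if (length(object@guild) != length(m)) return("guild vector must parallel membership")
  ids <- sort(unique(m))
  if (!identical(ids, seq_along(ids))) return("module ids must be 1..n_modules with no gaps")
  if (object@qb > 1 + 1e-12) return("Q_B cannot exceed 1")
  TRUE
})

# ---------------------------------------------------------------------------
# NetworkOrdination
# ---------------------------------------------------------------------------

#' Two-dimensional NMDS ordination of a bipartite network
#'
#' Non-metric multidimensional scaling of among-plant Bray-Curtis
#' dissimilarities (Kruskal stress-1), with ant species placed at the
#' interaction-weighted averages of their partner plants' coordinates.
#' Plant scores are centered and rotated to principal axes.
#'
#' @slot plant_scores Numeric matrix (plants x 2), columns NMDS1/NMDS2.
#' @slot ant_scores Numeric matrix (ants x 2), weighted-average positions.
#' @slot stress Kruskal stress-1 of the best start, in [0, 1].
#' @slot n_starts Number of random starts tried.
#' @slot best_start Index of the start that achieved the returned solution.
#' @slot converged TRUE when a second start agreed with the best within the
#'   Procrustes tolerance.
#' @slot trace Stress per iteration of the best start.
#' @export
setClass("NetworkOrdination",
         representation(plant_scores = "matrix", ant_scores = "matrix",
                        stress = "numeric", n_starts = "integer",
                        best_start = "integer", converged = "logical",
                        trace = "numeric"))

setValidity("NetworkOrdination", function(object) {
  if (object@stress < 0 || object@stress > 1) return("stress must lie in [0, 1]")
  if (ncol(object@plant_scores) != 2) return("plant scores must be two-dimensional")
  TRUE
})

# ---------------------------------------------------------------------------
# EnvFit
# ---------------------------------------------------------------------------

#' Permutation-based fit of attributes onto an ordination
#'
#' For each attribute, the squared correlation of the attribute with the
#' ordination scores (vector fit for continuous variables, among-level
#' centroid separation for factors) together with an add-one permutation
#' p-value.
#'
#' @slot table data.frame with columns \code{attribute}, \code{kind},
#'   \code{r2}, \code{p_value}, \code{n_used}, \code{n_dropped}.
#' @slot centroids Named list of per-level 2-D centroids for factor fits.
#' @slot vectors Named list of unit direction cosines for vector fits.
#' @slot n_perm Number of permutations.
#' @slot seed Root seed for the permutations.
#' @export
setClass("EnvFit",
         representation(table = "data.frame", centroids = "list",
                        vectors = "list", n_perm = "integer", seed = "integer"))

setValidity("EnvFit", function(object) {
  t <- object@table
  if (any(t$r2 < -1e-12 | t$r2 > 1 + 1e-12)) return("r2 must lie in [0, 1]")
  if (any(t$p_value <= 0 | t$p_value > 1)) return("p_value must lie in (0, 1]")
  TRUE
})
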