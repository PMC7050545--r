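# Accessors and show methods for the package's S4 classes.

#' @describeIn interactionNetwork-accessors Plant (row) species labels.
#' @export
setGeneric("plantNames", function(x) standardGeneric("plantNames"))

#' @describeIn interactionNetwork-accessors Ant (column) species labels.
#' @export
setGeneric("antNames", function(x) standardGeneric("antNames"))

#' @describeIn interactionNetwork-accessors The count matrix itself.
#' @export
setGeneric("interactionCounts", function(x) standardGeneric("interactionCounts"))

#' @describeIn interactionNetwork-accessors Number of links L (nonzero cells).
#' @export
setGeneric("linkCount", function(x) standardGeneric("linkCount"))

#' @describeIn interactionNetwork-accessors Total interaction frequency F.
#' @export
setGeneric("totalFrequency", function(x) standardGeneric("totalFrequency"))

#' Accessors for InteractionNetwork objects
#'
#' @param x An [InteractionNetwork-class].
#' @return \code{plantNames}/\code{antNames} return character vectors;
#'   \code{interactionCounts} the numeric count matrix; \code{linkCount} the
#'   number of realized links \eqn{L}; \code{totalFrequency} the grand total
#'   \eqn{F} of interaction counts; \code{dim} gives \code{c(P, A)}.
#' @name interactionNetwork-accessors
#' @aliases plantNames antNames interactionCounts linkCount totalFrequency
#' @examples
#' net <- interactionNetwork(matrix(c(2, 0, 1, 3), 2, 2,
#'   dimnames = list(c("P1", "P2"), c("A1", "A2"))))
#' plantNames(net); linkCount(net); totalFrequency(net)
NULL

#' @rdname interactionNetwork-accessors
#' @export
setMethod("plantNames", "InteractionNetwork", function(x) rownames(x@counts))

#' @rdname interactionNetwork-accessors
#' @export
setMethod("antNames", "InteractionNetwork", function(x) colnames(x@counts))

#' @rdname interactionNetwork-accessors
#' @export
setMethod("interactionCounts", "InteractionNetwork", function(x) x@counts)

#' @rdname interactionNetwork-accessors
#' @export
setMethod("linkCount", "InteractionNetwork", function(x) sum(x@counts > 0))

#' @rdname interactionNetwork-accessors
#' @export
setMethod("totalFrequency", "InteractionNetwork", function(x) sum(x@counts))

#' @rdname interactionNetwork-accessors
#' @export
setMethod("dim", "InteractionNetwork", function(x) dim(x@counts))

setMethod("show", "InteractionNetwork", function(object) {
  w <- object@counts
  cat(sprintf("InteractionNetwork: %d plants x %d ants\n", nrow(w), ncol(w)))
  cat(sprintf("  links L = %d, total frequency F = %d, connectance = %.3f\n",
              sum(w > 0), as.integer(sum(w)), mean(w > 0)))
})

#' @describeIn speciesAttributes-accessors Guild of the table.
#' @export
setGeneric("guild", function(x) standardGeneric("guild"))

#' Accessors for SpeciesAttributes objects
#'
#' @param x A [SpeciesAttributes-class].
#' @name speciesAttributes-accessors
#' @aliases guild
#' @return \code{guild} returns the guild string; \code{attributeTable} the
#'   underlying data.frame (species labels as row names);
#'   \code{speciesNames} the labels.
NULL

#' @rdname speciesAttributes-accessors
#' @export
setMethod("guild", "SpeciesAttributes", function(x) x@guild)

#' @rdname speciesAttributes-accessors
#' @export
setGeneric("attributeTable", function(x) standardGeneric("attributeTable"))

#' @rdname speciesAttributes-accessors
#' @export
setMethod("attributeTable", "SpeciesAttributes", function(x) x@data)

#' @rdname speciesAttributes-accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname speciesAttributes-accessors
#' @export
setMethod("speciesNames", "SpeciesAttributes", function(x) rownames(x@data))

setMethod("show", "SpeciesAttributes", function(object) {
  cat(sprintf("SpeciesAttributes: %d %s species, columns: %s\n",
              nrow(object@data), object@guild,
              paste(names(object@data), collapse = ", ")))
})

#' @describeIn nullEnsemble-accessors Observed statistic value.
#' @export
setGeneric("observedValue", function(x) standardGeneric("observedValue"))

#' @describeIn nullEnsemble-accessors The full null ensemble.
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))

#' @describeIn nullEnsemble-accessors Monte Carlo p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Accessors for NullEnsemble objects
#'
#' @param x A [NullEnsemble-class].
#' @name nullEnsemble-accessors
#' @aliases observedValue nullValues pValue
#' @return Scalars or the numeric ensemble, as named.
NULL

#' @rdname nullEnsemble-accessors
#' @export
setMethod("observedValue", "NullEnsemble", function(x) x@observed)

#' @rdname nullEnsemble-accessors
#' @export
setMethod("nullValues", "NullEnsemble", function(x) x@null_values)

#' @rdname nullEnsemble-accessors
#' @export
setMethod("pValue", "NullEnsemble", function(x) x@p_value)

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble test of %s (%s)\n", object@statistic, object@alternative))
  cat(sprintf("  observed = %.4f, null mean = %.4f (sd %.4f), n_reps = %d\n",
              object@observed, mean(object@null_values), stats::sd(object@null_values),
              length(object@null_values)))
  cat(sprintf("  p = %.4g (add-one Monte Carlo), seed = %d\n",
              object@p_value, object@seed))
})

#' @describeIn modulePartition-accessors Module id of every species.
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))

#' @describeIn modulePartition-accessors Number of (non-empty) modules.
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))

#' @describeIn modulePartition-accessors Barber modularity of the partition.
#' @export
setGeneric("qbValue", function(x) standardGeneric("qbValue"))

#' Accessors for ModulePartition objects
#'
#' @param x A [ModulePartition-class].
#' @name modulePartition-accessors
#' @aliases moduleMembership nModules qbValue
#' @return \code{moduleMembership} a named integer vector;
#'   \code{nModules} an integer; \code{qbValue} the Q_B score.
NULL

#' @rdname modulePartition-accessors
#' @export
setMethod("moduleMembership", "ModulePartition", function(x) x@membership)

#' @rdname modulePartition-accessors
#' @export
setMethod("nModules", "ModulePartition", function(x) length(unique(x@membership)))

#' @rdname modulePartition-accessors
#' @export
setMethod("qbValue", "ModulePartition", function(x) x@qb)

setMethod("show", "ModulePartition", function(object) {
  cat(sprintf("ModulePartition: %d modules over %d species, Q_B = %.4f\n",
              length(unique(object@membership)), length(object@membership),
              object@qb))
})

#' @describeIn networkOrdination-accessors Plant NMDS scores.
#' @export
setGeneric("plantScores", function(x) standardGeneric("plantScores"))

#' @describeIn networkOrdination-accessors Ant weighted-average scores.
#' @export
setGeneric("antScores", function(x) standardGeneric("antScores"))

#' @describeIn networkOrdination-accessors Kruskal stress-1 of the solution.
#' @export
setGeneric("ordinationStress", function(x) standardGeneric("ordinationStress"))

#' Accessors for NetworkOrdination objects
#'
#' @param x A [NetworkOrdination-class].
#' @name networkOrdination-accessors
#' @aliases plantScores antScores ordinationStress
#' @return Score matrices (species x 2) or the stress scalar.
NULL

#' @rdname networkOrdination-accessors
#' @export
setMethod("plantScores", "NetworkOrdination", function(x) x@plant_scores)

#' @rdname networkOrdination-accessors
#' @export
setMethod("antScores", "NetworkOrdination", function(x) x@ant_scores)

#' @rdname networkOrdination-accessors
#' @export
setMethod("ordinationStress", "NetworkOrdination", function(x) x@stress)

setMethod("show", "NetworkOrdination", function(object) {
  cat(sprintf("NetworkOrdination (2-D NMDS): %d plants, %d ants\n",
              nrow(object@plant_scores), nrow(object@ant_scores)))
  cat(sprintf("  stress-1 = %.4f over %d starts (best: start %d), converged: %s\n",
              object@stress, object@n_starts, object@best_start,
              object@converged))
})

#' @describeIn envFit-accessors Per-attribute result table.
#' @export
setGeneric("fitTable", function(x) standardGeneric("fitTable"))

#' Accessors for EnvFit objects
#'
#' @param x An [EnvFit-class].
#' @name envFit-accessors
#' @aliases fitTable
#' @return \code{fitTable} returns the per-attribute data.frame with
#'   \code{r2} and permutation \code{p_value}.
NULL

#' @rdname envFit-accessors
#' @export
setMethod("fitTable", "EnvFit", function(x) x@table)

setMethod("show", "EnvFit", function(object) {
  cat(sprintf("EnvFit: %d attributes, %d permutations\n",
              nrow(object@table), object@n_perm))
  t <- object@table
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-14s %-6s r2 = %.3f  p = %.4g\n",
                t$attribute[i], t$kind[i], t$r2[i], t$p_value[i]))
})
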