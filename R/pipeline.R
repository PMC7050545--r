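# End-to-end analysis pipeline: read/filter -> network metrics -> nestedness
# null test -> modularity + significance -> species metrics -> NMDS ->
# attribute fitting -> trait-degree correlation -> machine-readable report.

#' Run the full ant-plant network analysis
#'
#' Executes the complete analysis in order: input validation, exclusion of
#' rarely recorded interactions, network-level metrics, NODF nestedness with
#' null-model significance, Barber modularity with annealing optimization
#' and null-model significance, species-level metrics with core-periphery
#' classification, Bray-Curtis NMDS of the plant interaction profiles with
#' ant species at weighted-average positions, permutation fitting of plant
#' attributes on plant scores and ant attributes on ant scores (habitat
#' level \code{"B"}, both, is treated as missing in the open-vs-shaded
#' contrast), and the Spearman correlation between ant head length and
#' degree. All randomized stages consume child seeds derived from the one
#' root seed, so the report is exactly reproducible.
#'
#' @param x An [InteractionNetwork-class] or a path readable by
#'   [readInteractionMatrix()].
#' @param plant_attributes,ant_attributes Optional [SpeciesAttributes-class]
#'   objects or file paths; attribute-dependent stages are skipped when
#'   absent.
#' @param min_count Rare-interaction threshold passed to
#'   [filterRareInteractions()] (default 3; the filter is idempotent, so
#'   matrices already filtered at the same threshold pass unchanged). Use 1
#'   to disable.
#' @param n_null Null replicates for the nestedness test (default 1000).
#' @param n_null_modularity Null replicates for the modularity test
#'   (default 200; each replicate is a full annealing run).
#' @param n_perm Permutations for attribute fitting (default 1000).
#' @param n_starts NMDS random starts (default 20).
#' @param sa_restarts Annealing restarts for the observed network (default 3).
#' @param autotransform Count transformation before Bray-Curtis (see
#'   [transformCounts()]).
#' @param seed Integer root seed.
#' @return A list of class \code{"antplantReport"} with components
#'   \code{input} (dimensions, L, F), \code{network_metrics},
#'   \code{nestedness} ([NullEnsemble-class]), \code{modularity} (list:
#'   \code{partition}, \code{significance}), \code{species}
#'   (per-species data.frame), \code{ordination}
#'   ([NetworkOrdination-class]), \code{envfit_plants}, \code{envfit_ants}
#'   ([EnvFit-class] or NULL), \code{headlength_degree} (\code{htest} or
#'   NULL), and \code{config}.
#' @examples
#' sim <- generateNetwork(syntheticConfig(n_plants = 14, n_ants = 8, seed = 1))
#' rep <- runPipeline(sim$network, sim$plants, sim$ants,
#'                    n_null = 49, n_null_modularity = 19, n_perm = 99,
#'                    n_starts = 5, seed = 1)
#' rep$network_metrics
#' @export
runPipeline <- function(x, plant_attributes = NULL, ant_attributes = NULL,
                        min_count = 3, n_null = 1000, n_null_modularity = 200,
                        n_perm = 1000, n_starts = 20, sa_restarts = 3,
                        autotransform = TRUE, seed = 1) {
  if (is.character(x)) x <- readInteractionMatrix(x)
  stopifnot(is(x, "InteractionNetwork"))
  if (is.character(plant_attributes))
    plant_attributes <- readSpeciesAttributes(plant_attributes, "plant")
  if (is.character(ant_attributes))
    ant_attributes <- readSpeciesAttributes(ant_attributes, "ant")
  seeds <- childSeeds(seed, 6)

  net <- if (min_count > 1) filterRareInteractions(x, min_count) else x
  if (!is.null(plant_attributes)) matchAttributes(x, plant_attributes)
  if (!is.null(ant_attributes)) matchAttributes(x, ant_attributes)

  input <- list(n_plants = dim(net)[1], n_ants = dim(net)[2],
                links = linkCount(net), total_frequency = totalFrequency(net))

  metrics <- networkLevel(net)
  nested <- nullTest(net, "nodf", n_reps = n_null, seed = seeds[1])
  partition <- optimizeModules(net, restarts = sa_restarts, seed = seeds[2])
  mod_sig <- modularitySignificance(net, n_reps = n_null_modularity,
                                    seed = seeds[3], partition = partition)
  species <- speciesLevel(net)
  ord <- ordinateNetwork(net, n_starts = n_starts, seed = seeds[4],
                         autotransform = autotransform)

  envfit_plants <- NULL
  if (!is.null(plant_attributes)) {
    tab <- attributeTable(plant_attributes)
    if ("habitat" %in% names(tab))
      tab$habitat[tab$habitat == "B"] <- NA  # open-vs-shaded contrast
    envfit_plants <- suppressWarnings(
      fitAttributes(plantScores(ord), tab, n_perm = n_perm, seed = seeds[5]))
  }
  envfit_ants <- NULL
  headlength_degree <- NULL
  if (!is.null(ant_attributes)) {
    tab <- attributeTable(ant_attributes)
    if ("habitat" %in% names(tab)) tab$habitat[tab$habitat == "B"] <- NA
    envfit_ants <- suppressWarnings(
      fitAttributes(antScores(ord), tab, n_perm = n_perm, seed = seeds[6]))
    if ("head_length" %in% names(tab)) {
      deg <- speciesDegrees(net, "ant")
      shared <- intersect(names(deg), rownames(tab))
      hl <- tab[shared, "head_length"]
      ok <- !is.na(hl)
      if (sum(ok) >= 3)
        headlength_degree <- spearmanTest(hl[ok], as.numeric(deg[shared])[ok])
    }
  }

  structure(list(input = input, network_metrics = metrics,
                 nestedness = nested,
                 modularity = list(partition = partition,
                                   significance = mod_sig),
                 species = species, ordination = ord,
                 envfit_plants = envfit_plants, envfit_ants = envfit_ants,
                 headlength_degree = headlength_degree,
                 config = list(min_count = min_count, n_null = n_null,
                               n_null_modularity = n_null_modularity,
                               n_perm = n_perm, n_starts = n_starts,
                               sa_restarts = sa_restarts,
                               autotransform = autotransform, seed = seed)),
            class = "antplantReport")
}

#' @export
print.antplantReport <- function(x, ...) {
  cat("Ant-plant network analysis report\n")
  cat(sprintf("  input: %d plants x %d ants, L = %d, F = %d\n",
              x$input$n_plants, x$input$n_ants, x$input$links,
              x$input$total_frequency))
  m <- x$network_metrics
  cat(sprintf("  connectance = %.3f, NODF = %.2f (null mean %.2f, p = %.4g)\n",
              m$connectance, m$nodf, mean(nullValues(x$nestedness)),
              pValue(x$nestedness)))
  cat(sprintf("  WNODF = %.2f, dependence asymmetry = %.3f\n",
              m$wnodf, m$dependence_asymmetry))
  cat(sprintf("  niche overlap: ants %.3f, plants %.3f\n",
              m$niche_overlap_ants, m$niche_overlap_plants))
  cat(sprintf("  modularity: Q_B = %.3f in %d modules (p = %.4g)\n",
              qbValue(x$modularity$partition),
              nModules(x$modularity$partition),
              pValue(x$modularity$significance)))
  cat(sprintf("  core: %d plants, %d ants\n",
              sum(x$species$core & x$species$guild == "plant"),
              sum(x$species$core & x$species$guild == "ant")))
  cat(sprintf("  NMDS stress = %.3f (%d starts)\n",
              ordinationStress(x$ordination), x$ordination@n_starts))
  if (!is.null(x$envfit_plants)) { cat("  plant attribute fit:\n"); show(x$envfit_plants) }
  if (!is.null(x$envfit_ants)) { cat("  ant attribute fit:\n"); show(x$envfit_ants) }
  if (!is.null(x$headlength_degree))
    cat(sprintf("  head length ~ degree: rho = %.3f, p = %.4g\n",
                x$headlength_degree$estimate, x$headlength_degree$p.value))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Serializes a pipeline report as diffable flat files: \code{report.json}
#' (all scalar results plus configuration and seeds), \code{species.tsv}
#' (per-species metrics), \code{scores.tsv} (NMDS coordinates of both
#' guilds), \code{modules.tsv} (module membership) and
#' \code{null_nodf.tsv} / \code{null_qb.tsv} (the null ensembles).
#'
#' @param report An \code{"antplantReport"} from [runPipeline()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "antplantReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                           row.names = FALSE, quote = FALSE)
  tsv(report$species, "species.tsv")
  ord <- report$ordination
  scores <- rbind(
    data.frame(species = rownames(plantScores(ord)), guild = "plant",
               plantScores(ord), row.names = NULL),
    data.frame(species = rownames(antScores(ord)), guild = "ant",
               antScores(ord), row.names = NULL))
  tsv(scores, "scores.tsv")
  part <- report$modularity$partition
  tsv(data.frame(species = names(moduleMembership(part)),
                 guild = part@guild, module = moduleMembership(part),
                 row.names = NULL), "modules.tsv")
  tsv(data.frame(nodf = nullValues(report$nestedness)), "null_nodf.tsv")
  tsv(data.frame(qb = nullValues(report$modularity$significance)), "null_qb.tsv")

  envfit_to_list <- function(ef) if (is.null(ef)) NULL else fitTable(ef)
  json <- list(
    input = report$input,
    network_metrics = as.list(report$network_metrics),
    nestedness = list(observed = observedValue(report$nestedness),
                      null_mean = mean(nullValues(report$nestedness)),
                      null_sd = stats::sd(nullValues(report$nestedness)),
                      n_reps = length(nullValues(report$nestedness)),
                      p_value = pValue(report$nestedness)),
    modularity = list(qb = qbValue(part), n_modules = nModules(part),
                      p_value = pValue(report$modularity$significance),
                      n_reps = length(nullValues(report$modularity$significance))),
    core = list(plants = sum(report$species$core & report$species$guild == "plant"),
                ants = sum(report$species$core & report$species$guild == "ant")),
    ordination = list(stress = ordinationStress(report$ordination),
                      n_starts = report$ordination@n_starts,
                      best_start = report$ordination@best_start,
                      converged = report$ordination@converged),
    envfit_plants = envfit_to_list(report$envfit_plants),
    envfit_ants = envfit_to_list(report$envfit_ants),
    headlength_degree = if (is.null(report$headlength_degree)) NULL else
      list(rho = unname(report$headlength_degree$estimate),
           p_value = report$headlength_degree$p.value),
    config = report$config)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
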