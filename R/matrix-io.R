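# Reading, validating, filtering and writing interaction matrices and
# per-species attribute tables.

# Detect comma vs tab delimiter from the header line.
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com && n_tab > 0) "\t" else ","
}

#' Read a labeled interaction matrix from CSV/TSV
#'
#' Reads a delimited file whose first column holds species labels of one
#' guild and whose header row holds the labels of the other. The delimiter
#' (comma or tab) is auto-detected. Whatever the file orientation, the
#' returned network always has plants as rows (the lower trophic level);
#' use \code{orientation = "ants_rows"} when the file stores ants as rows.
#'
#' Counts must be non-negative integers: any negative, non-numeric, or
#' fractional cell is rejected with its row/column coordinates, and
#' duplicate labels are rejected by name. Rows or columns that are entirely
#' zero fail validation (drop them at the source, or via
#' [filterRareInteractions()] with \code{min_count = 1}).
#'
#' @param path Path to a CSV or TSV file.
#' @param orientation \code{"plants_rows"} (default) or \code{"ants_rows"}.
#' @return A validated [InteractionNetwork-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("species,A1,A2", "P1,2,1", "P2,0,3"), f)
#' net <- readInteractionMatrix(f)
#' dim(net)
#' @export
readInteractionMatrix <- function(path, orientation = c("plants_rows", "ants_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file needs a label column plus at least one data column")
  if (nrow(raw) == 0) stop("empty matrix: file has no data rows")
  row_labels <- trimws(raw[[1]])
  col_labels <- trimws(colnames(raw)[-1])
  if (anyDuplicated(row_labels))
    stop(sprintf("duplicate label: '%s'", row_labels[duplicated(row_labels)][1]))
  if (anyDuplicated(col_labels))
    stop(sprintf("duplicate label: '%s'", col_labels[duplicated(col_labels)][1]))
  body <- as.matrix(raw[, -1, drop = FALSE])
  parsed <- suppressWarnings(matrix(as.numeric(trimws(body)), nrow = nrow(body)))
  bad <- which(is.na(parsed), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 row_labels[bad[1, 1]], col_labels[bad[1, 2]],
                 body[bad[1, 1], bad[1, 2]]))
  bad <- which(parsed < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative count at row '%s', column '%s'",
                 row_labels[bad[1, 1]], col_labels[bad[1, 2]]))
  bad <- which(!.is_wholenumber(parsed), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("fractional count at row '%s', column '%s' (counts must be integers)",
                 row_labels[bad[1, 1]], col_labels[bad[1, 2]]))
  dimnames(parsed) <- list(row_labels, col_labels)
  if (orientation == "ants_rows") parsed <- t(parsed)
  interactionNetwork(parsed)
}

#' Write an interaction matrix to CSV/TSV
#'
#' Inverse of [readInteractionMatrix()]: writes the labeled count matrix with
#' plants as rows. Round-trips exactly.
#'
#' @param x An [InteractionNetwork-class].
#' @param path Output path.
#' @param sep Field separator, \code{","} (default) or \code{"\t"}.
#' @return \code{path}, invisibly.
#' @export
writeInteractionMatrix <- function(x, path, sep = ",") {
  stopifnot(is(x, "InteractionNetwork"))
  w <- interactionCounts(x)
  df <- data.frame(species = rownames(w), w, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove rarely recorded interactions
#'
#' Sets to zero every cell recorded fewer than \code{min_count} times and
#' drops species left without any interaction. Rare pairwise records (fewer
#' than three occasions over all censuses, by default) inflate apparent
#' specialization, nestedness and strength asymmetry, and clutter the
#' ordination, so the analysis pipeline excludes them up front. The filter
#' is idempotent at a fixed threshold: a matrix that was already filtered
#' passes through unchanged.
#'
#' @param x An [InteractionNetwork-class].
#' @param min_count Minimum number of records for a pairwise interaction to
#'   be retained (default 3; 1 keeps everything).
#' @return A new, validated [InteractionNetwork-class]; the input is untouched.
#' @examples
#' net <- interactionNetwork(matrix(c(1, 3, 2, 5), 2, 2,
#'   dimnames = list(c("P1", "P2"), c("A1", "A2"))))
#' dim(filterRareInteractions(net, 3))
#' @export
filterRareInteractions <- function(x, min_count = 3) {
  stopifnot(is(x, "InteractionNetwork"), min_count >= 1)
  w <- interactionCounts(x)
  w[w < min_count] <- 0
  keep_r <- rowSums(w) > 0
  keep_c <- colSums(w) > 0
  if (!any(keep_r) || !any(keep_c))
    stop("no interactions survive filter (min_count = ", min_count, ")")
  interactionNetwork(w[keep_r, keep_c, drop = FALSE])
}

#' Read a per-species attribute table
#'
#' Reads a delimited table with a \code{species} label column and one column
#' per attribute. Categorical columns (\code{efn}, \code{habitat},
#' \code{invasive}, \code{dominance}) are validated against their allowed
#' level sets; continuous columns (\code{cover}, \code{head_length}) must be
#' positive. Matching against a network's labels is exact and case-sensitive
#' after whitespace trimming.
#'
#' @param path Path to a CSV or TSV file.
#' @param guild \code{"plant"} or \code{"ant"}.
#' @return A validated [SpeciesAttributes-class].
#' @examples
#' plants <- readSpeciesAttributes(
#'   system.file("extdata", "plant_attributes.tsv", package = "antplantnet"),
#'   guild = "plant")
#' head(attributeTable(plants))
#' @export
readSpeciesAttributes <- function(path, guild = c("plant", "ant")) {
  guild <- match.arg(guild)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  if (!"species" %in% names(df))
    stop("attribute table must have a 'species' column")
  if (ncol(df) < 2) stop("attribute table needs at least one attribute column")
  for (col in names(df))
    if (is.character(df[[col]])) df[[col]] <- trimws(df[[col]])
  speciesAttributes(df, guild = guild)
}

#' Check that attribute labels match a network's guild
#'
#' @param x An [InteractionNetwork-class].
#' @param attrs A [SpeciesAttributes-class] for one of its guilds.
#' @return \code{TRUE} invisibly; errors with the offending label otherwise.
#' @export
matchAttributes <- function(x, attrs) {
  stopifnot(is(x, "InteractionNetwork"), is(attrs, "SpeciesAttributes"))
  net_labels <- if (guild(attrs) == "plant") plantNames(x) else antNames(x)
  missing <- setdiff(speciesNames(attrs), net_labels)
  if (length(missing) > 0)
    stop(sprintf("%s label not present in network: '%s'", guild(attrs), missing[1]))
  invisible(TRUE)
}

#' Convert a network to a long edge list
#'
#' @param x An [InteractionNetwork-class].
#' @return data.frame with columns \code{plant}, \code{ant}, \code{weight};
#'   exactly \eqn{L} rows, all weights positive. Round-trips losslessly with
#'   [edgeListToNetwork()] up to species order.
#' @export
asEdgeList <- function(x) {
  stopifnot(is(x, "InteractionNetwork"))
  w <- interactionCounts(x)
  idx <- which(w > 0, arr.ind = TRUE)
  out <- data.frame(plant = rownames(w)[idx[, 1]],
                    ant = colnames(w)[idx[, 2]],
                    weight = w[idx],
                    stringsAsFactors = FALSE)
  out[order(out$plant, out$ant), , drop = FALSE]
}

#' Build a network from a (plant, ant, weight) edge list
#'
#' @param edges data.frame with columns \code{plant}, \code{ant},
#'   \code{weight} (positive integral counts).
#' @return An [InteractionNetwork-class]; species ordered by first appearance.
#' @export
edgeListToNetwork <- function(edges) {
  stopifnot(all(c("plant", "ant", "weight") %in% names(edges)))
  if (nrow(edges) == 0) stop("empty edge list")
  plants <- unique(trimws(as.character(edges$plant)))
  ants <- unique(trimws(as.character(edges$ant)))
  w <- matrix(0, length(plants), length(ants), dimnames = list(plants, ants))
  for (k in seq_len(nrow(edges))) {
    i <- trimws(as.character(edges$plant[k])); j <- trimws(as.character(edges$ant[k]))
    w[i, j] <- w[i, j] + edges$weight[k]
  }
  interactionNetwork(w)
}
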