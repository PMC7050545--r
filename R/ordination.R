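# Bray-Curtis dissimilarity, two-dimensional non-metric multidimensional
# scaling (Kruskal stress-1 with pool-adjacent-violators monotone
# regression), weighted-average scores for the second guild, and
# permutation-based fitting of attributes onto the ordination.

#' Community-style count transformation
#'
#' Square-root transform followed by Wisconsin double standardization
#' (species maxima, then site totals), applied automatically when the matrix
#' maximum exceeds 9 — the usual pre-treatment of heavily skewed count data
#' before Bray-Curtis/NMDS. With \code{autotransform = FALSE} counts pass
#' through unchanged.
#'
#' @param counts A numeric matrix (observations in rows).
#' @param autotransform Apply the conditional transformation (default TRUE).
#' @return The (possibly) transformed matrix.
#' @export
transformCounts <- function(counts, autotransform = TRUE) {
  if (!autotransform || max(counts) <= 9) return(counts)
  vegan::wisconsin(sqrt(counts))
}

#' Bray-Curtis dissimilarities among the species of one guild
#'
#' Pairwise Bray-Curtis dissimilarity
#' \eqn{d(x, y) = \sum_k |x_k - y_k| / \sum_k (x_k + y_k)} between the
#' partner-use count vectors of the species of one guild, computed through
#' \code{vegan::vegdist}. Joint absences do not contribute. Counts are
#' auto-transformed (see [transformCounts()]) unless disabled.
#'
#' @param x An [InteractionNetwork-class].
#' @param guild Guild whose pairwise dissimilarities are wanted.
#' @param autotransform Passed to [transformCounts()].
#' @return A \code{dist} object with values in [0, 1].
#' @export
brayCurtis <- function(x, guild = c("plant", "ant"), autotransform = TRUE) {
  guild <- match.arg(guild)
  w <- interactionCounts(x)
  if (guild == "ant") w <- t(w)
  if (nrow(w) < 2) stop("need at least two species in the guild")
  vegan::vegdist(transformCounts(w, autotransform), method = "bray")
}

#' Pool-adjacent-violators isotonic regression
#'
#' Least-squares monotone (non-decreasing) fit to \code{y} in the given
#' order, with optional weights; adjacent violating blocks are pooled to
#' their (weighted) mean. This is the monotone-regression step of Kruskal's
#' NMDS.
#'
#' @param y Numeric vector (already sorted by the predictor).
#' @param w Optional positive weights.
#' @return The fitted non-decreasing vector, same length as \code{y}.
#' @export
pava <- function(y, w = NULL) {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(w) == n, all(w > 0))
  if (n <= 1) return(y)
  # stack of blocks: value, weight, size
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      val[top - 1L] <- (val[top - 1L] * wt[top - 1L] + val[top] * wt[top]) /
        (wt[top - 1L] + wt[top])
      wt[top - 1L] <- wt[top - 1L] + wt[top]
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], times = sz[seq_len(top)])
}

# One Guttman-transform update of configuration X toward disparities dhat.
.guttman_update <- function(X, dhat_m, delta_m) {
  n <- nrow(X)
  ratio <- ifelse(delta_m > 0, dhat_m / delta_m, 0)
  Bm <- -ratio
  diag(Bm) <- -rowSums(Bm)
  (Bm %*% X) / n
}

.stress1 <- function(delta, dhat) {
  sqrt(sum((delta - dhat)^2) / sum(delta^2))
}

# Disparities: isotonic regression of configuration distances on the rank
# order of the input dissimilarities; ties in d are ordered by delta
# ascending (primary tie treatment).
.disparities <- function(dvec, delta) {
  ord <- order(dvec, delta)
  dhat <- numeric(length(dvec))
  dhat[ord] <- pava(delta[ord])
  dhat
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in \code{k} dimensions by minimizing
#' Kruskal's stress-1
#' \deqn{S = \sqrt{\sum_{i<j} (\delta_{ij} - \hat d_{ij})^2 /
#'       \sum_{i<j} \delta_{ij}^2},}
#' where \eqn{\delta} are configuration distances and \eqn{\hat d} the
#' monotone (isotonic, pool-adjacent-violators, ties by configuration
#' distance) regression of \eqn{\delta} on the rank order of the input
#' dissimilarities. Each random start alternates monotone regression with a
#' Guttman configuration update, step-halving whenever a step would raise
#' the stress, so the per-iteration stress trace is non-increasing. The
#' lowest-stress start is returned, centered and rotated to principal axes.
#' Convergence is declared when some other start agrees with the best one
#' within a symmetric Procrustes tolerance.
#'
#' @param d A \code{dist} or symmetric dissimilarity matrix, n >= 4.
#' @param k Number of dimensions (default 2).
#' @param n_starts Random starts (default 20).
#' @param maxit Iteration cap per start (default 300).
#' @param tol Relative stress-improvement tolerance (default 1e-8).
#' @param seed Integer root seed (one child seed per start).
#' @param procrustes_tol Agreement threshold between starts (default 1e-3,
#'   symmetric Procrustes sum of squares).
#'
#' @details The first start is the classical (metric) scaling configuration,
#'   the conventional informed start; the remaining starts are random. For
#'   dissimilarities that are exactly embeddable Euclidean distances the
#'   metric start already sits at zero stress, so the original shape is
#'   recovered rather than an arbitrary monotone warp of it.
#' @return List with \code{points} (n x k, centered, principal-axis
#'   rotated), \code{stress}, \code{trace} (stress per iteration of the best
#'   start), \code{best_start}, \code{n_starts}, \code{converged}.
#' @references Kruskal (1964) Psychometrika 29:1-27.
#' @examples
#' xy <- cbind(runif(6), runif(6))
#' fit <- nmdsFit(dist(xy), n_starts = 5, seed = 1)
#' fit$stress  # ~0: exact planar distances embed perfectly
#' @export
nmdsFit <- function(d, k = 2, n_starts = 20, maxit = 300, tol = 1e-8,
                    seed = 1, procrustes_tol = 1e-3) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 4) stop("NMDS needs at least 4 objects")
  labels <- rownames(dm)
  dvec <- dm[lower.tri(dm)]
  seeds <- childSeeds(seed, n_starts)
  # start 1: classical (metric) scaling, the conventional informed start;
  # remaining starts random
  X_metric <- tryCatch(stats::cmdscale(dm, k = k), error = function(e) NULL)
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    X <- if (s == 1 && !is.null(X_metric) && ncol(X_metric) == k) X_metric
         else .with_seed(seeds[s], matrix(stats::runif(n * k, -1, 1), n, k))
    trace <- numeric(0)
    delta_m <- as.matrix(stats::dist(X))
    delta <- delta_m[lower.tri(delta_m)]
    dhat <- .disparities(dvec, delta)
    stress <- .stress1(delta, dhat)
    for (it in seq_len(maxit)) {
      trace <- c(trace, stress)
      dhat_m <- matrix(0, n, n)
      dhat_m[lower.tri(dhat_m)] <- dhat
      dhat_m <- dhat_m + t(dhat_m)
      X_prop <- .guttman_update(X, dhat_m, delta_m)
      # step-halving: accept only stress-reducing configurations
      accepted <- FALSE
      for (h in 0:10) {
        X_try <- X + (X_prop - X) / 2^h
        delta_try_m <- as.matrix(stats::dist(X_try))
        delta_try <- delta_try_m[lower.tri(delta_try_m)]
        dhat_try <- .disparities(dvec, delta_try)
        stress_try <- .stress1(delta_try, dhat_try)
        if (stress_try <= stress) {
          X <- X_try; delta_m <- delta_try_m; delta <- delta_try
          dhat <- dhat_try
          improvement <- stress - stress_try
          stress <- stress_try
          accepted <- TRUE
          break
        }
      }
      if (!accepted || improvement < tol * max(stress, 1e-12)) break
    }
    runs[[s]] <- list(X = X, stress = stress, trace = trace)
  }
  stresses <- vapply(runs, `[[`, numeric(1), "stress")
  best <- which.min(stresses)
  Xb <- scale(runs[[best]]$X, center = TRUE, scale = FALSE)
  Xb <- Xb %*% svd(Xb)$v  # principal-axis rotation
  rownames(Xb) <- labels
  colnames(Xb) <- paste0("NMDS", seq_len(k))
  converged <- FALSE
  for (s in seq_len(n_starts)) {
    if (s == best) next
    pr <- vegan::procrustes(Xb, runs[[s]]$X, symmetric = TRUE)
    if (pr$ss < procrustes_tol) { converged <- TRUE; break }
  }
  list(points = Xb, stress = stresses[best], trace = runs[[best]]$trace,
       best_start = as.integer(best), n_starts = as.integer(n_starts),
       converged = converged)
}

#' Place the second guild at weighted averages of its partners
#'
#' Each ant is positioned at the interaction-count-weighted average of the
#' coordinates of the plants it visits: an ant visiting a single plant
#' coincides with it, one visiting two plants equally sits at their
#' midpoint.
#'
#' @param x An [InteractionNetwork-class].
#' @param plant_scores Numeric matrix of plant coordinates (rows named by
#'   plant species).
#' @return Matrix of ant coordinates (ants x columns of
#'   \code{plant_scores}).
#' @export
secondGuildScores <- function(x, plant_scores) {
  stopifnot(is(x, "InteractionNetwork"))
  w <- interactionCounts(x)
  plant_scores <- plant_scores[plantNames(x), , drop = FALSE]
  out <- sweep(t(w) %*% plant_scores, 1, colSums(w), "/")
  rownames(out) <- antNames(x)
  out
}

#' Ordinate a network: Bray-Curtis NMDS of plants plus ant scores
#'
#' The full ordination stage: among-plant Bray-Curtis dissimilarities of the
#' (auto-transformed) interaction profiles, 2-D NMDS with multiple random
#' starts, and ant species placed at interaction-weighted averages of their
#' partner plants' coordinates (on the raw counts).
#'
#' @param x An [InteractionNetwork-class] with at least 4 plants.
#' @param n_starts,maxit,tol,seed Passed to [nmdsFit()].
#' @param autotransform Passed to [brayCurtis()].
#' @return A [NetworkOrdination-class].
#' @examples
#' net <- generateNetwork(syntheticConfig(n_plants = 12, n_ants = 8, seed = 1))$network
#' ord <- ordinateNetwork(net, n_starts = 5, seed = 1)
#' ordinationStress(ord)
#' @export
ordinateNetwork <- function(x, n_starts = 20, maxit = 300, tol = 1e-8,
                            seed = 1, autotransform = TRUE) {
  stopifnot(is(x, "InteractionNetwork"))
  d <- brayCurtis(x, "plant", autotransform = autotransform)
  fit <- nmdsFit(d, k = 2, n_starts = n_starts, maxit = maxit, tol = tol,
                 seed = seed)
  ants <- secondGuildScores(x, fit$points)
  colnames(ants) <- colnames(fit$points)
  new("NetworkOrdination", plant_scores = fit$points, ant_scores = ants,
      stress = fit$stress, n_starts = fit$n_starts,
      best_start = fit$best_start, converged = fit$converged,
      trace = fit$trace)
}

# r2 of one attribute on a 2-D score matrix.
.envfit_r2 <- function(scores, v) {
  if (is.numeric(v)) {
    vc <- v - mean(v)
    Xc <- scale(scores, center = TRUE, scale = FALSE)
    b <- solve(crossprod(Xc), crossprod(Xc, vc))
    rss <- sum((vc - Xc %*% b)^2)
    tss <- sum(vc^2)
    if (tss <= 0) stop("constant vector attribute")
    list(r2 = 1 - rss / tss, coef = as.numeric(b))
  } else {
    f <- factor(v)
    if (nlevels(f) < 2) stop("factor attribute with a single level")
    grand <- colMeans(scores)
    tss <- sum(sweep(scores, 2, grand)^2)
    wss <- 0
    cents <- matrix(NA_real_, nlevels(f), ncol(scores),
                    dimnames = list(levels(f), colnames(scores)))
    for (lv in levels(f)) {
      rows <- scores[f == lv, , drop = FALSE]
      cents[lv, ] <- colMeans(rows)
      wss <- wss + sum(sweep(rows, 2, cents[lv, ])^2)
    }
    list(r2 = 1 - wss / tss, centroids = cents)
  }
}

#' Fit species attributes onto ordination scores (permutation test)
#'
#' For each attribute column: continuous variables are fitted as vectors
#' (\eqn{r^2} = coefficient of determination of the best linear combination
#' of the two axes predicting the variable, direction cosines reported);
#' categorical variables as factors (\eqn{r^2 = 1 - SS_{within}/SS_{total}}
#' of the scores about the level centroids). Significance is assessed by
#' permuting the attribute values \code{n_perm} times and reporting the
#' add-one fraction of permutations with \eqn{r^2} at least the observed
#' one. Missing values are dropped per attribute (a count of dropped rows is
#' reported; a warning is raised when any are dropped).
#'
#' @param scores Numeric matrix of 2-D coordinates, rows named by species.
#' @param attributes A [SpeciesAttributes-class] or a data.frame with
#'   species as row names; character/factor columns are fitted as factors,
#'   numeric columns as vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer root seed.
#' @return An [EnvFit-class].
#' @examples
#' net <- generateNetwork(syntheticConfig(n_plants = 15, n_ants = 8, seed = 1))
#' ord <- ordinateNetwork(net$network, n_starts = 5, seed = 2)
#' fitAttributes(plantScores(ord),
#'               attributeTable(net$plants)[rownames(plantScores(ord)), ],
#'               n_perm = 99, seed = 3)
#' @export
fitAttributes <- function(scores, attributes, n_perm = 1000, seed = 1) {
  if (is(attributes, "SpeciesAttributes")) attributes <- attributeTable(attributes)
  attributes <- as.data.frame(attributes)
  common <- intersect(rownames(scores), rownames(attributes))
  if (length(common) < 3) stop("fewer than 3 species shared between scores and attributes")
  scores <- scores[common, , drop = FALSE]
  attributes <- attributes[common, , drop = FALSE]
  seeds <- childSeeds(seed, ncol(attributes))
  rows <- list(); cents <- list(); vecs <- list()
  for (ci in seq_along(attributes)) {
    a_name <- names(attributes)[ci]
    v <- attributes[[ci]]
    keep <- !is.na(v)
    n_dropped <- sum(!keep)
    if (n_dropped > 0)
      warning(sprintf("%s: dropped %d species with missing values", a_name, n_dropped))
    v_use <- v[keep]
    sc_use <- scores[keep, , drop = FALSE]
    kind <- if (is.numeric(v_use)) "vector" else "factor"
    obs <- .envfit_r2(sc_use, v_use)
    perm_r2 <- .with_seed(seeds[ci], vapply(seq_len(n_perm), function(p)
      .envfit_r2(sc_use, sample(v_use))$r2, numeric(1)))
    pval <- (sum(perm_r2 >= obs$r2) + 1) / (n_perm + 1)
    rows[[a_name]] <- data.frame(attribute = a_name, kind = kind,
                                 r2 = obs$r2, p_value = pval,
                                 n_used = sum(keep), n_dropped = n_dropped,
                                 stringsAsFactors = FALSE)
    if (kind == "factor") cents[[a_name]] <- obs$centroids
    else vecs[[a_name]] <- obs$coef / sqrt(sum(obs$coef^2))
  }
  new("EnvFit", table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      centroids = cents, vectors = vecs,
      n_perm = as.integer(n_perm), seed = as.integer(seed))
}
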