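# Fixture builders and independent brute-force oracles. Each oracle is a
# direct transcription of the defining formula, written as plainly as
# possible and sharing no code with the implementation it checks.

make_net <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("P", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("A", seq_len(ncol(m)))
  interactionNetwork(m)
}

# Random count matrix guaranteed free of empty rows/columns.
rand_net <- function(P, A, fill = 0.5, max_w = 5) {
  repeat {
    m <- matrix(rpois(P * A, max_w / 2) * (runif(P * A) < fill), P, A)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0) && sum(m) > 0)
      return(make_net(m))
  }
}

write_net_csv <- function(m, sep = ",") {
  f <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  header <- paste(c("species", colnames(m)), collapse = sep)
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], m[i, ]), collapse = sep), character(1))
  writeLines(c(header, rows), f)
  f
}

# --- network-level oracles -------------------------------------------------

oracle_nodf <- function(B) {
  B <- (B > 0) + 0
  pair_score <- function(u, v) {
    du <- sum(u); dv <- sum(v)
    if (du == dv) return(0)
    lo <- if (du < dv) u else v
    hi <- if (du < dv) v else u
    100 * sum(lo == 1 & hi == 1) / sum(lo)
  }
  tot <- 0; np <- 0
  for (i in seq_len(nrow(B) - 1)) for (j in (i + 1):nrow(B)) {
    tot <- tot + pair_score(B[i, ], B[j, ]); np <- np + 1
  }
  for (i in seq_len(ncol(B) - 1)) for (j in (i + 1):ncol(B)) {
    tot <- tot + pair_score(B[, i], B[, j]); np <- np + 1
  }
  tot / np
}

oracle_asymmetry <- function(w) {
  vals <- c()
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w))) {
    if (w[i, j] == 0) next
    dp <- w[i, j] / sum(w[i, ])
    da <- w[i, j] / sum(w[, j])
    vals <- c(vals, abs(dp - da) / max(dp, da))
  }
  mean(vals)
}

oracle_horn_mean <- function(w, margin) {
  profiles <- if (margin == "row") w else t(w)
  xlx <- function(v) sum(ifelse(v > 0, v * log(v), 0))
  vals <- c()
  for (i in seq_len(nrow(profiles) - 1)) for (j in (i + 1):nrow(profiles)) {
    p <- profiles[i, ] / sum(profiles[i, ])
    q <- profiles[j, ] / sum(profiles[j, ])
    vals <- c(vals, (xlx(p + q) - xlx(p) - xlx(q)) / (2 * log(2)))
  }
  mean(vals)
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# --- species-level oracles -------------------------------------------------

oracle_strength_ants <- function(w) {
  out <- numeric(ncol(w))
  for (j in seq_len(ncol(w)))
    for (i in seq_len(nrow(w)))
      out[j] <- out[j] + w[i, j] / sum(w[i, ])
  out
}

oracle_gc <- function(k) (k - mean(k)) / sd(k)

# Independent d' for one row. d_min: enumerate every integer allocation of
# the row total over the partners (the true minimum, a non-trivial check of
# the marginal-allocation algorithm). d_max: the defining procedure is the
# greedy monopolization of the most exclusive partners up to their observed
# totals; transcribed here independently with cumulative sums instead of a
# fill loop.
oracle_dprime_row <- function(w, i) {
  tot <- sum(w[i, ]); grand <- sum(w)
  q <- colSums(w) / grand
  cap <- colSums(w)
  m <- ncol(w)
  dval <- function(alloc) {
    p <- alloc / tot
    sum(ifelse(p > 0, p * log(p / q), 0))
  }
  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    out <- NULL
    for (first in 0:total)
      out <- rbind(out, cbind(first, compositions(total - first, parts - 1)))
    out
  }
  d_min <- min(apply(compositions(tot, m), 1, dval))
  ord <- order(q)
  cap_s <- cap[ord]
  already <- c(0, cumsum(cap_s))[seq_len(m)]
  alloc_s <- pmin(cap_s, pmax(0, tot - already))
  alloc <- numeric(m); alloc[ord] <- alloc_s
  d_max <- dval(alloc)
  d_obs <- dval(w[i, ])
  if (d_max - d_min < 1e-12) 0 else
    min(1, max(0, (d_obs - d_min) / (d_max - d_min)))
}

# --- modularity oracle -----------------------------------------------------

oracle_qb <- function(B, membership, plant_names, ant_names) {
  B <- (B > 0) + 0
  Fb <- sum(B)
  total <- 0
  for (i in seq_len(nrow(B))) for (j in seq_len(ncol(B))) {
    if (membership[plant_names[i]] != membership[ant_names[j]]) next
    total <- total + B[i, j] - sum(B[i, ]) * sum(B[, j]) / Fb
  }
  total / Fb
}

# --- isotonic-regression oracle -------------------------------------------

# The least-squares monotone fit is a piecewise-constant vector whose
# blocks are consecutive and whose block means are non-decreasing;
# enumerate all 2^(n-1) block compositions and keep the feasible one with
# minimal squared error.
oracle_isotonic <- function(y) {
  n <- length(y)
  best_sse <- Inf; best_fit <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n); means <- c()
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means <- c(means, mean(y[idx]))
      fit[idx] <- mean(y[idx])
    }
    if (is.unsorted(means)) next
    sse <- sum((y - fit)^2)
    if (sse < best_sse) { best_sse <- sse; best_fit <- fit }
  }
  best_fit
}

# Procrustes-style disagreement after optimal rotation/reflection/scale.
procrustes_error <- function(X, Y) {
  pr <- vegan::procrustes(X, Y, symmetric = TRUE)
  sqrt(max(0, pr$ss))
}
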