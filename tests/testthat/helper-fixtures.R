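# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code under fixed seeds; nothing is read from disk.

# A random membership tensor: uniform draws normalized to sum to 1 per
# (gene, group), which is all the MembershipTensor contract requires.
randomTensor <- function(G = 20, C = 2, T = 3, L = 4, seed = 1) {
  set.seed(seed)
  conds <- paste0("t", seq_len(T))
  cls <- paste0("c", seq_len(C))
  grid <- expand.grid(cluster = cls, condition = conds,
                      stringsAsFactors = FALSE)
  mu <- array(runif(G * nrow(grid) * L),
              dim = c(G, nrow(grid), L),
              dimnames = list(sprintf("g%03d", seq_len(G)),
                              paste(grid$cluster, grid$condition, sep = ":"),
                              paste0("L", seq_len(L) - 1L)))
  mu <- sweep(mu, c(1, 2), apply(mu, c(1, 2), sum), "/")
  new("MembershipTensor", mu = mu,
      cluster = factor(grid$cluster),
      condition = factor(grid$condition, levels = conds),
      levels = paste0("L", seq_len(L) - 1L))
}

# Build a tensor from explicit per-(cluster, condition) membership rows:
# spec is a list cluster -> list(condition -> membership vector per gene
# matrix G x L).
tensorFromMemberships <- function(muByGroup, conds, levels) {
  cls <- names(muByGroup)
  grid <- expand.grid(cluster = cls, condition = conds,
                      stringsAsFactors = FALSE)
  G <- nrow(muByGroup[[1]][[1]])
  mu <- array(0, dim = c(G, nrow(grid), length(levels)),
              dimnames = list(rownames(muByGroup[[1]][[1]]),
                              paste(grid$cluster, grid$condition, sep = ":"),
                              levels))
  for (i in seq_len(nrow(grid)))
    mu[, i, ] <- muByGroup[[grid$cluster[i]]][[grid$condition[i]]]
  new("MembershipTensor", mu = mu,
      cluster = factor(grid$cluster),
      condition = factor(grid$condition, levels = conds),
      levels = levels)
}

# Brute-force flow-weight oracle: explicit loop over every path and every
# gene, indexing the membership array directly.  Independent of the
# package's factorized computation.
bruteForceWeights <- function(tensor, cluster, paths,
                              combiner = c("product", "min")) {
  combiner <- match.arg(combiner)
  mu <- memberships(tensor)
  conds <- conditionSeries(tensor)
  groupOf <- vapply(conds, function(tt)
    which(tensor@cluster == cluster & tensor@condition == tt), 0L)
  G <- dim(mu)[1]
  w <- numeric(nrow(paths))
  for (p in seq_len(nrow(paths))) {
    total <- 0
    for (g in seq_len(G)) {
      vals <- vapply(seq_along(conds), function(tt)
        mu[g, groupOf[tt], paths[p, tt]], 0)
      total <- total + if (combiner == "product") prod(vals) else min(vals)
    }
    w[p] <- total
  }
  w
}

# Exact hypergeometric upper-tail oracle by combinatorial summation.
hyperTailOracle <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Independent pseudobulk oracle: per-cell scale to `sf`, log1p, average.
pseudobulkOracle <- function(counts, sf = 1e4) {
  norm <- apply(counts, 2, function(col) {
    tot <- sum(col)
    if (tot > 0) log1p(col * sf / tot) else rep(0, length(col))
  })
  rowMeans(norm)
}

# A GroupedProfile with prescribed group means (one cluster, K conditions
# unless stated otherwise); detection defaults to fully detected.
profileFromMeans <- function(means, cluster = NULL, condition = NULL,
                             conds = NULL, detection = NULL) {
  K <- ncol(means)
  if (is.null(cluster)) cluster <- rep("k", K)
  if (is.null(condition)) condition <- paste0("t", seq_len(K))
  if (is.null(conds)) conds <- unique(condition)
  if (is.null(detection)) detection <- matrix(1, nrow(means), K)
  if (is.null(rownames(means)))
    rownames(means) <- sprintf("g%03d", seq_len(nrow(means)))
  colnames(means) <- paste(cluster, condition, sep = ":")
  dimnames(detection) <- dimnames(means)
  new("GroupedProfile", mean = means, detection = detection,
      nCells = rep(10L, K), cluster = factor(cluster),
      condition = factor(condition, levels = conds))
}

# Small, fast synthetic cohort for unit tests.
smallCohort <- function(seed = 11, ...) {
  args <- list(nGenes = 300L, nClusters = 2L, cellsPerSample = 40L,
               samplesPerCondition = 2L, plantedGenes = 10L, seed = seed)
  args <- utils::modifyList(args, list(...))
  simulateCiteSeq(do.call(syntheticSpec, args))
}
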