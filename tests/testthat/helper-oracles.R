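# Independent brute-force oracles used to cross-check the igraph-backed
# implementation paths. Deliberately written as plain loops over the
# definitions, not via any graph library.

# random symmetric connectivity matrix with zero diagonal
randomConnMatrix <- function(n, density = 0.5, wMin = 0.05, wMax = 1) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < density) {
      w[i, j] <- w[j, i] <- runif(1, wMin, wMax)
    }
  }
  w
}

# Floyd-Warshall all-pairs shortest paths over edge lengths 1/w
fwOracle <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Onnela clustering by exhaustive triple enumeration
onnelaOracle <- function(w) {
  n <- nrow(w)
  wh <- (w / max(w))^(1 / 3)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h)
        s <- s + wh[i, j] * wh[i, h] * wh[j, h]
    }
    ci[i] <- s / (k * (k - 1))
  }
  ci
}

# weighted Newman modularity by the direct double sum
qOracle <- function(w, membership) {
  n <- nrow(w)
  m2 <- sum(w)
  if (m2 == 0) return(0)
  s <- rowSums(w)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j])
      q <- q + w[i, j] - s[i] * s[j] / m2
  }
  q / m2
}

# connected components of an edge list by union-find; returns the edge
# count of each component
unionFindComponentSizes <- function(edges) {
  nodes <- unique(c(edges[, 1], edges[, 2]))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(as.character(edges[r, 1]))
    b <- find(as.character(edges[r, 2]))
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(as.character(edges[, 1]), find, character(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# small dense cohort generator used across tests (kept dense so every
# threshold of the default grid leaves the graph connected)
testCohort <- function(nPerGroup = 5, nNodes = 24, nModules = 3, seed = 1,
                       ...) {
  generateCohort(simulationConfig(
    nPerGroup = nPerGroup, nNodes = nNodes, nModules = nModules,
    pWithin = 0.6, pBetween = 0.2, seed = seed, ...))
}

# ring lattice with each node tied to `k` nearest neighbours per side and
# a fraction of edges rewired (small-world regime for small rewireFrac)
ringLattice <- function(n, k = 5, rewireFrac = 0.05) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k)) {
    j <- ((i + d - 1) %% n) + 1
    w[i, j] <- w[j, i] <- 1
  }
  if (rewireFrac > 0) {
    ut <- which(upper.tri(w) & w > 0)
    for (e in ut[runif(length(ut)) < rewireFrac]) {
      ij <- arrayInd(e, dim(w))
      repeat {
        b <- sample.int(n, 1)
        if (b != ij[1] && w[ij[1], b] == 0) break
      }
      w[ij[1], ij[2]] <- w[ij[2], ij[1]] <- 0
      w[ij[1], b] <- w[b, ij[1]] <- 1
    }
  }
  w
}

# Erdos-Renyi weighted graph with the given mean degree, unit-ish weights
erMatrix <- function(n, meanDegree = 8) {
  randomConnMatrix(n, density = meanDegree / (n - 1), wMin = 0.5, wMax = 1)
}
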