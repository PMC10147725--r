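#' Weighted clustering coefficient (Onnela geometric-mean form)
#'
#' Per node i: `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_ih
#' w'_jh)^{1/3}` with weights normalized by the graph maximum,
#' `w' = w / max(w)`. Nodes of degree < 2 have `C_i = 0`. The graph mean
#' over all nodes is the global clustering `C_p`.
#'
#' @param g a weighted undirected igraph graph.
#' @return A list: `perNode` (named numeric) and `mean`.
#' @export
clusteringOnnela <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  if (igraph::ecount(g) == 0L)
    return(list(perNode = stats::setNames(rep(0, n), igraph::V(g)$name),
                mean = 0))
  w <- .denseAdjacency(g)
  wn <- (w / max(w))^(1 / 3)
  num <- diag(wn %*% wn %*% wn)
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  names(ci) <- igraph::V(g)$name
  list(perNode = ci, mean = mean(ci))
}

#' All-pairs weighted shortest path lengths
#'
#' Edge lengths are the reciprocal weights `1/w` (the standard mapping for
#' probability-weighted connectomes: stronger connections are shorter).
#' Disconnected pairs have infinite distance.
#'
#' @param g a weighted undirected igraph graph.
#' @return Numeric distance matrix (Inf for disconnected pairs, 0 on the
#'   diagonal).
#' @export
shortestPathLengths <- function(g) {
  if (igraph::ecount(g) == 0L) {
    n <- igraph::vcount(g)
    d <- matrix(Inf, n, n, dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
    diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Weighted characteristic path length
#'
#' Mean shortest path length over connected pairs of distinct nodes;
#' infinite (disconnected) pairs are excluded and their count reported.
#'
#' @param g a weighted undirected igraph graph with >= 2 nodes.
#' @return A list: `lp` (mean finite distance) and `excludedPairs` (count
#'   of disconnected unordered pairs).
#' @export
characteristicPathLength <- function(g) {
  if (igraph::vcount(g) < 2L) stop("need at least 2 nodes")
  d <- shortestPathLengths(g)
  v <- d[upper.tri(d)]
  fin <- is.finite(v)
  if (!any(fin)) stop("no connected pair of nodes")
  list(lp = mean(v[fin]), excludedPairs = sum(!fin))
}

#' Nodal efficiency
#'
#' `E_nod(i) = (1/(N-1)) * sum_{j != i} 1/d_ij`, with `1/Inf = 0` for
#' disconnected pairs; lies in \[0,1\] for weights in \[0,1\].
#'
#' @param g a weighted undirected igraph graph with >= 2 nodes.
#' @return Named numeric vector of per-node efficiencies.
#' @export
nodalEfficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) stop("need at least 2 nodes")
  d <- shortestPathLengths(g)
  inv <- 1 / d      # 1/Inf = 0 handles disconnected pairs
  diag(inv) <- 0
  stats::setNames(rowSums(inv) / (n - 1), igraph::V(g)$name)
}

#' Direct evaluation of weighted Newman modularity for a given partition
#'
#' `Q = (1/2m) * sum_ij [w_ij - s_i s_j / 2m] delta(c_i, c_j)` where `s`
#' are node strengths and `2m` the total weight.
#'
#' @param g a weighted undirected igraph graph.
#' @param membership integer community label per node.
#' @return Modularity Q.
#' @export
modularityQ <- function(g, membership) {
  w <- .denseAdjacency(g)
  .plantedQ(w, membership)
}

#' Louvain community detection with restarts
#'
#' Runs seeded Louvain `restarts` times and keeps the partition with the
#' highest weighted modularity (ties: first found).
#'
#' @param g a weighted undirected igraph graph with >= 1 edge.
#' @param seed integer seed for the restart streams.
#' @param restarts number of restarts (default 20).
#' @return A list: `membership` (integer per node), `q` (modularity).
#' @export
modularityLouvain <- function(g, seed = 1L, restarts = 20L) {
  if (igraph::ecount(g) == 0L) stop("edgeless graph has no modular structure")
  best <- NULL
  bestQ <- -Inf
  for (r in seq_len(restarts)) {
    set.seed(deriveSeed(seed, paste0("louvain:", r)))
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    q <- modularityQ(g, igraph::membership(cl))
    if (q > bestQ) {
      bestQ <- q
      best <- as.integer(igraph::membership(cl))
    }
  }
  list(membership = stats::setNames(best, igraph::V(g)$name), q = bestQ)
}

# dense weighted adjacency via the edge list (faster than
# as_adjacency_matrix for repeated small-graph calls)
.denseAdjacency <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- matrix(0, n, n)
  w[el] <- igraph::E(g)$weight
  w[el[, 2:1, drop = FALSE]] <- igraph::E(g)$weight
  dimnames(w) <- list(igraph::V(g)$name, igraph::V(g)$name)
  w
}

# one degree-preserving rewired null: topology rewired, weights permuted on
.rewiredNull <- function(g) {
  ne <- igraph::ecount(g)
  gn <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * ne))
  igraph::E(gn)$weight <- sample(igraph::E(g)$weight)
  gn
}

#' Small-worldness with a cluster-correction guard
#'
#' `sigma = (C_p / C_rand) / (L_p / L_rand)` where the null values are
#' means over `nNull` degree-sequence-preserving (Maslov-Sneppen) rewired
#' graphs with the original weight multiset permuted onto the rewired
#' topology. The traditional sigma alone can label near-random graphs
#' small-world, so a cluster-correction flag additionally requires the
#' observed clustering to exceed the null 95th percentile.
#'
#' @param g a weighted undirected igraph graph whose largest connected
#'   component covers >= 90 percent of nodes.
#' @param nNull number of null graphs (>= 20; default 100).
#' @param seed integer seed.
#' @return A list: `sigma`, `sigmaClusterOk` (logical), `nullSummary`
#'   (mean/sd of null C and L), `nNull`.
#' @export
smallWorldness <- function(g, nNull = 100L, seed = 1L) {
  if (!.isCount(nNull, 20L)) stop("nNull must be an integer >= 20")
  comp <- igraph::components(g)
  if (max(comp$csize) < 0.9 * igraph::vcount(g))
    stop("largest connected component covers < 90% of nodes")
  cp <- clusteringOnnela(g)$mean
  lp <- characteristicPathLength(g)$lp
  set.seed(deriveSeed(seed, "smallworld"))
  nullC <- numeric(nNull)
  nullL <- numeric(nNull)
  n <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  w0 <- igraph::E(g)$weight
  wmax <- max(w0)
  for (b in seq_len(nNull)) {
    gn <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * ne))
    wPerm <- sample(w0)
    el <- igraph::as_edgelist(gn, names = FALSE)
    # Onnela clustering on the permuted-weight rewired topology
    wn <- matrix(0, n, n)
    wn[el] <- wPerm
    wn[el[, 2:1, drop = FALSE]] <- wPerm
    k <- rowSums(wn > 0)
    wn <- (wn / wmax)^(1 / 3)
    num <- diag(wn %*% wn %*% wn)
    nullC[b] <- mean(ifelse(k >= 2, num / (k * (k - 1)), 0))
    dn <- igraph::distances(gn, weights = 1 / wPerm)
    vn <- dn[upper.tri(dn)]
    nullL[b] <- mean(vn[is.finite(vn)])
  }
  sigma <- (cp / mean(nullC)) / (lp / mean(nullL))
  list(sigma = sigma,
       sigmaClusterOk = cp > stats::quantile(nullC, 0.95, names = FALSE),
       nullSummary = list(cMean = mean(nullC), cSd = stats::sd(nullC),
                          lMean = mean(nullL), lSd = stats::sd(nullL)),
       nNull = as.integer(nNull))
}

# percentile criteria: "high" = strict exceedance of the 80th percentile,
# "low" = at or below the 20th percentile (inclusive, so boundary ties are
# never split for the low-clustering criterion)
.topFifth <- function(x) x > stats::quantile(x, 0.8, names = FALSE)
.bottomFifthIncl <- function(x) x <= stats::quantile(x, 0.2, names = FALSE)

#' Composite hubness score
#'
#' Counts, per node, how many of four classic hub criteria are met: node
#' strength in the top 20 percent, weighted betweenness in the top 20
#' percent, weighted clustering in the bottom 20 percent, nodal efficiency
#' in the top 20 percent. Scores are integers 0-4. "Top" criteria require
#' strict exceedance of the 80th percentile; the "bottom" criterion is
#' inclusive at the 20th percentile, so fully tied graphs give every node
#' the same score.
#'
#' @param g a weighted undirected igraph graph with >= 5 nodes.
#' @return Named integer vector of scores in `{0,...,4}`.
#' @export
hubnessScore <- function(g) {
  n <- igraph::vcount(g)
  if (n < 5L) stop("need at least 5 nodes")
  w <- .denseAdjacency(g)
  strength <- rowSums(w)
  btw <- if (igraph::ecount(g) == 0L) rep(0, n) else
    igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  clust <- clusteringOnnela(g)$perNode
  enod <- nodalEfficiency(g)
  stats::setNames(.hubnessFromParts(strength, btw, clust, enod),
                  igraph::V(g)$name)
}

.hubnessFromParts <- function(strength, btw, clust, enod) {
  as.integer(.topFifth(strength) + .topFifth(btw) +
               .bottomFifthIncl(clust) + .topFifth(enod))
}

#' Compute every global and nodal topological attribute of one graph
#'
#' @param g a weighted undirected igraph graph.
#' @param seed integer seed (drives Louvain restarts and the rewired null
#'   ensemble).
#' @param nNull null graphs for small-worldness (default 100).
#' @param restarts Louvain restarts (default 20).
#' @return A list with `global` (cp, lp, excludedPairs, q, sigma,
#'   sigmaClusterOk, nNull, nullSummary) and `nodal` (data.frame: node,
#'   strength, betweenness, clustering, enod, hubness).
#' @export
computeAllMetrics <- function(g, seed = 1L, nNull = 100L, restarts = 20L) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  if (n < 5L) stop("need at least 5 nodes")
  cl <- clusteringOnnela(g)
  d <- shortestPathLengths(g)
  v <- d[upper.tri(d)]
  fin <- is.finite(v)
  if (!any(fin)) stop("no connected pair of nodes")
  pl <- list(lp = mean(v[fin]), excludedPairs = sum(!fin))
  inv <- 1 / d
  diag(inv) <- 0
  enod <- rowSums(inv) / (n - 1)
  lou <- modularityLouvain(g, seed = seed, restarts = restarts)
  sw <- smallWorldness(g, nNull = nNull, seed = seed)
  w <- .denseAdjacency(g)
  strength <- rowSums(w)
  btw <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  nodal <- data.frame(
    node = igraph::V(g)$name,
    strength = strength,
    betweenness = btw,
    clustering = cl$perNode,
    enod = enod,
    hubness = .hubnessFromParts(strength, btw, cl$perNode, enod),
    row.names = NULL)
  list(global = list(cp = cl$mean, lp = pl$lp,
                     excludedPairs = pl$excludedPairs, q = lou$q,
                     sigma = sw$sigma, sigmaClusterOk = sw$sigmaClusterOk,
                     nNull = sw$nNull, nullSummary = sw$nullSummary),
       nodal = nodal)
}
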