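#' Consensus threshold grid
#'
#' Equally spaced absolute edge-weight thresholds; the default grid runs
#' from 0.001 to 0.01 in steps of 0.001 (10 points), the consensus range
#' used for probability-weighted structural networks.
#'
#' @param start first threshold (>= 0).
#' @param stop last threshold (> start).
#' @param step increment (> 0).
#' @return Numeric vector of thresholds with class `"ThresholdGrid"`.
#' @export
#' @examples
#' thresholdGrid()          # 10 thresholds
thresholdGrid <- function(start = 0.001, stop = 0.01, step = 0.001) {
  if (!(start >= 0 && start < stop && step > 0))
    stop("require 0 <= start < stop and step > 0")
  taus <- seq(start, stop, by = step)
  if (length(taus) < 2L) stop("grid must have at least 2 points")
  structure(taus, class = "ThresholdGrid")
}

#' Threshold a connectivity matrix into a weighted graph
#'
#' Keeps edge (i,j), i != j, iff `w_ij >= tau` (ties at the threshold are
#' kept); surviving weights are unchanged. Returns an undirected igraph
#' graph with vertex names from the node ids, edge attribute `weight`, and
#' graph attribute `threshold`.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param tau absolute weight threshold (>= 0).
#' @return An igraph weighted undirected graph (possibly edgeless, with a
#'   warning).
#' @export
thresholdGraph <- function(cm, tau) {
  if (!is.numeric(tau) || tau < 0) stop("tau must be >= 0")
  w <- weightsMatrix(cm)
  w[w < tau] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0L)
    warning(sprintf("threshold %g removes all edges of subject '%s'",
                    tau, subjectId(cm)))
  g <- igraph::set_graph_attr(g, "threshold", tau)
  igraph::set_graph_attr(g, "subject", subjectId(cm))
}

#' Threshold a matrix at every grid point
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param grid a [thresholdGrid()].
#' @return A list of igraph graphs, one per threshold, in grid order; edge
#'   sets are nested (non-increasing in tau).
#' @export
gridGraphs <- function(cm, grid = thresholdGrid()) {
  stopifnot(inherits(grid, "ThresholdGrid"))
  lapply(as.numeric(grid), function(tau) thresholdGraph(cm, tau))
}
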