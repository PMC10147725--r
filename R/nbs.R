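# fit the group GLM columnwise and return observed stats plus the pieces
# needed for Freedman-Lane permutation
.glmFit <- function(Y, groupInd, Z) {
  n <- nrow(Y)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient covariate design")
  QZ <- qr.Q(qz)
  gPerp <- groupInd - QZ %*% crossprod(QZ, groupInd)
  gg <- sum(gPerp^2)
  if (gg < 1e-10 * sum(groupInd^2))
    stop("group indicator is collinear with the covariates")
  dfres <- n - ncol(Z) - 1L
  E <- Y - QZ %*% crossprod(QZ, Y)
  tOf <- function(Eb) {
    beta <- drop(crossprod(gPerp, Eb)) / gg
    rss <- pmax(colSums((Eb - QZ %*% crossprod(QZ, Eb))^2) - beta^2 * gg,
                1e-300)
    beta * sqrt(gg * dfres / rss)
  }
  list(t = tOf(E), E = E, tOf = tOf, dfres = dfres)
}

# subjects x edges response matrix over the masked upper-triangle edges
.edgeResponse <- function(coh, minPresence) {
  recs <- subjectRecords(coh)
  labs <- nodeIds(coh)
  n <- length(labs)
  ut <- which(upper.tri(matrix(0, n, n)))
  W <- vapply(recs$subject_id,
              function(sid) weightsMatrix(connMatrices(coh)[[sid]])[ut],
              numeric(length(ut)))
  W <- t(W)                                  # subjects x edges
  pat <- recs$group == "patient"
  presP <- colMeans(W[pat, , drop = FALSE] > 0)
  presC <- colMeans(W[!pat, , drop = FALSE] > 0)
  keep <- presP >= minPresence & presC >= minPresence
  if (!any(keep)) stop("no testable edges under the presence mask")
  ij <- arrayInd(ut[keep], c(n, n))
  list(Y = W[, keep, drop = FALSE],
       edges = data.frame(from = labs[ij[, 1L]], to = labs[ij[, 2L]]),
       groupInd = as.numeric(pat))
}

#' Edge-wise GLM statistics for the network-based statistic
#'
#' Tests every sufficiently present edge (nonzero in at least
#' `minPresence` of the subjects of each group) for a group difference in
#' connection weight, adjusting for covariates, and returns one-tailed
#' t-based p-values in the requested direction.
#'
#' @param coh a [Cohort-class].
#' @param covariates record columns to adjust for (default age, education,
#'   ftnd); `NULL` for none.
#' @param tail "patient>control" or "control>patient".
#' @param minPresence per-group presence fraction required to test an edge
#'   (default 0.5).
#' @return A list: `edges` (data.frame from/to), `t` (signed toward the
#'   tail), `p` (one-tailed), `df`.
#' @export
edgewiseStats <- function(coh, covariates = c("age", "education", "ftnd"),
                          tail = c("patient>control", "control>patient"),
                          minPresence = 0.5) {
  tail <- match.arg(tail)
  er <- .edgeResponse(coh, minPresence)
  recs <- subjectRecords(coh)
  Z <- cbind(intercept = rep(1, nrow(er$Y)),
             if (!is.null(covariates))
               as.matrix(recs[, covariates, drop = FALSE]))
  fit <- .glmFit(er$Y, er$groupInd, Z)
  tt <- if (tail == "patient>control") fit$t else -fit$t
  list(edges = er$edges, t = tt,
       p = stats::pt(tt, fit$dfres, lower.tail = FALSE), df = fit$dfres)
}

#' Connected components of the suprathreshold edge graph
#'
#' Edges with `p < alphaPrimary` are retained and their connected
#' components extracted; component size is the number of links.
#'
#' @param edges data.frame with columns `from`, `to`.
#' @param p one-tailed p-value per edge.
#' @param alphaPrimary primary threshold (default 0.05).
#' @return A list: `components` (list of integer vectors indexing `edges`)
#'   and `sizes` (links per component), both ordered by decreasing size.
#' @export
suprathresholdComponents <- function(edges, p, alphaPrimary = 0.05) {
  sel <- which(p < alphaPrimary)
  if (!length(sel)) return(list(components = list(), sizes = integer()))
  g <- igraph::graph_from_data_frame(edges[sel, c("from", "to")],
                                     directed = FALSE)
  memb <- igraph::components(g)$membership
  compOfEdge <- memb[edges$from[sel]]          # both endpoints share a comp
  comps <- split(sel, compOfEdge)
  sizes <- lengths(comps)
  ord <- order(sizes, decreasing = TRUE)
  list(components = unname(comps[ord]), sizes = as.integer(sizes[ord]))
}

#' Network-based statistic with max-component-size FWE control
#'
#' One-tailed edge-wise GLM tests, a primary threshold defining
#' suprathreshold edges, connected-component extraction, and a
#' Freedman-Lane permutation null (random group membership) of the maximum
#' component size. Each observed component receives
#' `fweP = (1 + #{null max size >= observed size}) / (1 + nPerm)`.
#'
#' @inheritParams edgewiseStats
#' @param alphaPrimary primary edge threshold (default 0.05).
#' @param nPerm permutations (default 5000).
#' @param seed integer seed.
#' @return An [NBSResult-class].
#' @export
nbsTest <- function(coh, alphaPrimary = 0.05, nPerm = 5000L, seed = 1L,
                    tail = c("patient>control", "control>patient"),
                    covariates = c("age", "education", "ftnd"),
                    minPresence = 0.5) {
  tail <- match.arg(tail)
  recs <- subjectRecords(coh)
  if (min(table(recs$group)) < 2L) stop("need >= 2 subjects per group")
  er <- .edgeResponse(coh, minPresence)
  Z <- cbind(intercept = rep(1, nrow(er$Y)),
             if (!is.null(covariates))
               as.matrix(recs[, covariates, drop = FALSE]))
  fit <- .glmFit(er$Y, er$groupInd, Z)
  sgn <- if (tail == "patient>control") 1 else -1
  tObs <- sgn * fit$t
  pObs <- stats::pt(tObs, fit$dfres, lower.tail = FALSE)
  obs <- suprathresholdComponents(er$edges, pObs, alphaPrimary)
  tCrit <- stats::qt(1 - alphaPrimary, fit$dfres)

  set.seed(deriveSeed(seed, "nbs"))
  n <- nrow(er$Y)
  nullMax <- integer(nPerm)
  for (b in seq_len(nPerm)) {
    tp <- sgn * fit$tOf(fit$E[sample.int(n), , drop = FALSE])
    sel <- which(tp > tCrit)
    nullMax[b] <- if (!length(sel)) 0L else {
      g <- igraph::graph_from_data_frame(er$edges[sel, ], directed = FALSE)
      memb <- igraph::components(g)$membership
      max(table(memb[er$edges$from[sel]]))
    }
  }
  comps <- lapply(obs$components, function(idx)
    data.frame(er$edges[idx, ], t = tObs[idx], p = pObs[idx],
               row.names = NULL))
  fwe <- vapply(obs$sizes,
                function(s) (1 + sum(nullMax >= s)) / (1 + nPerm),
                numeric(1))
  new("NBSResult", components = comps, sizes = obs$sizes, fweP = fwe,
      nullMaxSizes = nullMax,
      params = list(alphaPrimary = alphaPrimary, nPerm = as.integer(nPerm),
                    tail = tail, seed = as.integer(seed),
                    nEdgesTested = nrow(er$edges), df = fit$dfres))
}
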