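#' @include arg-core.R
NULL

.linkIndex <- function(links) {
  idx <- seq_len(nrow(links))
  names(idx) <- paste(links$parent, links$child)
  idx
}

.pathLabels <- function(P, sampleIds) {
  sm <- sampleIds[max.col(P, ties.method = "first")]
  k <- stats::ave(seq_along(sm), sm, FUN = seq_along)
  sprintf("s%d.%d", sm, k)
}

.newPathSet <- function(arg, pathNodes, pathLinks, pathSample, minimal) {
  rts <- rootIds(arg)
  np <- length(pathNodes)
  P <- matrix(0, np, length(arg@sampleIds),
              dimnames = list(NULL, as.character(arg@sampleIds)))
  R <- matrix(0, np, length(rts), dimnames = list(NULL, as.character(rts)))
  for (i in seq_len(np)) {
    P[i, match(pathSample[i], arg@sampleIds)] <- 1
    root <- pathNodes[[i]][length(pathNodes[[i]])]
    R[i, match(root, rts)] <- 1
  }
  lbl <- .pathLabels(P, arg@sampleIds)
  rownames(P) <- rownames(R) <- lbl
  new("PathSet", paths = pathNodes, linkPaths = pathLinks, P = P, R = R,
      sampleIds = arg@sampleIds, rootIds = as.integer(rts),
      minimal = minimal)
}

#' Enumerate every sample-to-root path
#'
#' Walks rootward from each sample, branching at every recombination node, and
#' returns all distinct paths.  The number of paths grows exponentially with
#' nested recombination, so this is mainly a reference for [minimalPaths()].
#'
#' @param arg a validated, chopped [SpatialARG-class].
#' @param maxPaths guard against path-count explosion (default 1e5).
#' @return a [PathSet-class] with \code{minimal = FALSE}.
#' @export
enumerateAllPaths <- function(arg, maxPaths = 1e5) {
  pm <- .parentMap(arg)
  links <- .argLinks(arg)
  li <- .linkIndex(links)
  pathNodes <- list(); pathLinks <- list(); pathSample <- integer()
  for (s in arg@sampleIds) {
    stack <- list(list(nodes = s, links = integer()))
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      v <- cur$nodes[length(cur$nodes)]
      ps <- pm[[as.character(v)]]
      if (!length(ps)) {
        pathNodes[[length(pathNodes) + 1L]] <- cur$nodes
        pathLinks[[length(pathLinks) + 1L]] <- cur$links
        pathSample <- c(pathSample, s)
        if (length(pathNodes) > maxPaths) {
          stop("more than ", maxPaths, " sample paths; use minimalPaths() ",
               "or raise maxPaths")
        }
      } else {
        for (p in rev(ps)) {  # smaller parent explored first
          stack[[length(stack) + 1L]] <- list(
            nodes = c(cur$nodes, p),
            links = c(cur$links, li[[paste(p, v)]]))
        }
      }
    }
  }
  .newPathSet(arg, pathNodes, pathLinks, pathSample, minimal = FALSE)
}

#' Minimal linearly sufficient set of sample paths
#'
#' Builds, in a single tip-to-root traversal, a set of
#' \code{ns + (number of recombination nodes)} paths whose induced sample
#' matrix equals that of the full path set.  Nodes are processed in increasing
#' time order; each live lineage carries its path up the graph, at a
#' recombination node one lineage is duplicated (one copy per parent edge,
#' yielding exactly one extra path), and ties are always broken towards the
#' smaller parent node id so output is deterministic.
#'
#' @param arg a validated, chopped [SpatialARG-class].
#' @return a [PathSet-class] with \code{minimal = TRUE}.
#' @export
minimalPaths <- function(arg) {
  pm <- .parentMap(arg)
  links <- .argLinks(arg)
  li <- .linkIndex(links)
  ns <- length(arg@sampleIds)
  pathNodes <- lapply(arg@sampleIds, function(s) s)
  pathLinks <- rep(list(integer()), ns)
  pathSample <- arg@sampleIds
  stubs <- new.env(parent = emptyenv())
  put <- function(v, p) {
    k <- as.character(v)
    assign(k, c(if (exists(k, stubs)) get(k, stubs) else integer(), p), stubs)
  }
  for (i in seq_len(ns)) put(arg@sampleIds[i], i)
  ord <- order(arg@nodes$time, arg@nodes$id)
  for (v in arg@nodes$id[ord]) {
    k <- as.character(v)
    if (!exists(k, stubs)) next
    here <- get(k, stubs)
    if (!length(here)) next
    ps <- pm[[k]]
    if (!length(ps)) next  # root: paths terminate here
    if (length(ps) == 1L) {
      l <- li[[paste(ps, v)]]
      for (p in here) {
        pathNodes[[p]] <- c(pathNodes[[p]], ps)
        pathLinks[[p]] <- c(pathLinks[[p]], l)
      }
      put(ps, here)
    } else {
      canon <- ps[1]; other <- ps[2]  # parents sorted ascending
      des <- min(here)
      newp <- length(pathNodes) + 1L
      pathNodes[[newp]] <- c(pathNodes[[des]], other)
      pathLinks[[newp]] <- c(pathLinks[[des]], li[[paste(other, v)]])
      pathSample <- c(pathSample, pathSample[des])
      l <- li[[paste(canon, v)]]
      for (p in here) {
        pathNodes[[p]] <- c(pathNodes[[p]], canon)
        pathLinks[[p]] <- c(pathLinks[[p]], l)
      }
      put(canon, here)
      put(other, newp)
    }
    rm(list = k, envir = stubs)
  }
  .newPathSet(arg, pathNodes, pathLinks, pathSample, minimal = TRUE)
}

#' Shared times between sample paths
#'
#' Entry (i, j) of the path matrix is the summed length of the edges the two
#' paths have in common; the diagonal is each path's total length.  Parallel
#' edge rows between the same parent-child pair (several genome intervals)
#' represent a single line of inheritance and are counted once.
#'
#' @param arg a [SpatialARG-class].
#' @param paths a [PathSet-class] for \code{arg}.
#' @return a [SharedTimeMatrix-class].
#' @export
sharedTimes <- function(arg, paths) {
  links <- .argLinks(arg)
  np <- length(paths@paths)
  A <- matrix(0, nrow(links), np)
  for (i in seq_len(np)) A[paths@linkPaths[[i]], i] <- 1
  Sp <- crossprod(A, links$length * A)
  dimnames(Sp) <- list(rownames(paths@P), rownames(paths@P))
  new("SharedTimeMatrix", Sp = Sp, pathSet = paths)
}

## Deterministic upward path (smaller parent id first) from a node to a root.
.canonicalUpwardPath <- function(arg, node, pm = .parentMap(arg),
                                 li = .linkIndex(.argLinks(arg))) {
  nodes <- node
  lks <- integer()
  v <- node
  repeat {
    ps <- pm[[as.character(v)]]
    if (!length(ps)) break
    p <- ps[1]
    lks <- c(lks, li[[paste(p, v)]])
    nodes <- c(nodes, p)
    v <- p
  }
  list(nodes = nodes, links = lks)
}

#' Shared times between one ancestor and the sample paths
#'
#' Chooses a deterministic path from \code{node} up to a root (always the
#' smaller parent id) and returns its vector of shared times with the paths of
#' \code{paths}, the time from the node to its root, and the index of that
#' root.  These are the ingredients of the conditional ancestor-location
#' distribution; the result does not depend on the choice of upward path in
#' exact arithmetic.
#'
#' @param arg a [SpatialARG-class].
#' @param node a node id present in \code{arg}.
#' @param paths a [PathSet-class] (normally the minimal set).
#' @return list with elements \code{sa} (numeric, one entry per path),
#'   \code{ta} (generations from the node to its root) and \code{rootIndex}
#'   (column of the path-root matrix R).
#' @export
ancestorSharedTimes <- function(arg, node, paths) {
  if (!node %in% arg@nodes$id) stop("node ", node, " not in the ARG")
  links <- .argLinks(arg)
  up <- .canonicalUpwardPath(arg, node, li = .linkIndex(links))
  root <- up$nodes[length(up$nodes)]
  ri <- match(root, paths@rootIds)
  if (is.na(ri)) stop("node ", node, " does not descend from a root of the path set")
  sa <- vapply(paths@linkPaths, function(lp) {
    sum(links$length[intersect(lp, up$links)])
  }, numeric(1))
  ta <- .nodeTime(arg, root) - .nodeTime(arg, node)
  list(sa = sa, ta = ta, rootIndex = ri)
}
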