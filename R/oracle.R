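#' @include path-matrix.R spatial-likelihood.R
NULL

#' Dense joint Gaussian over node locations (exact reference)
#'
#' Builds the unconstrained forward model in which every edge displacement is
#' an independent Gaussian: one coordinate per node, with each recombination
#' node duplicated into a left and a right copy (one per parental lineage),
#' each copy's location being the sum of displacements along a fixed upward
#' path to a root.  Conditioning the left and right copies to coincide
#' ([conditionOnLoops()]) then gives the exact law of the meeting model.  This
#' is an O(n^3), dense reference used to verify the path-matrix machinery; it
#' is deliberately slow and capped in size.
#'
#' @param arg a validated, chopped [SpatialARG-class].
#' @param mu root locations: one value per root (sorted root ids), or a single
#'   value recycled.  Single coordinate dimension.
#' @param sigma2 scalar dispersal rate.
#' @param rootVariance non-negative variance added between copies sharing a
#'   root (0 = roots fixed at \code{mu}).
#' @param maxCopies size guard (default 200 node copies).
#' @return a [JointGaussian-class].
#' @export
buildJoint <- function(arg, mu, sigma2 = 1, rootVariance = 0, maxCopies = 200) {
  links <- .argLinks(arg)
  li <- .linkIndex(links)
  pm <- .parentMap(arg)
  ids <- arg@nodes$id
  rts <- rootIds(arg)
  if (length(mu) == 1L) mu <- rep(mu, length(rts))
  stopifnot(length(mu) == length(rts))
  recs <- recombinationNodes(arg)
  ncopy <- length(ids) + length(recs)
  if (ncopy > maxCopies) {
    stop("ARG has ", ncopy, " node copies; the dense oracle is capped at ",
         maxCopies)
  }
  upaths <- vector("list", ncopy)
  copies <- data.frame(node = c(ids, recs),
                       side = c(rep(1L, length(ids)), rep(2L, length(recs))),
                       root = NA_integer_)
  for (i in seq_along(ids)) {
    upaths[[i]] <- .canonicalUpwardPath(arg, ids[i], pm, li)
  }
  for (j in seq_along(recs)) {
    ps <- pm[[as.character(recs[j])]]
    up <- .canonicalUpwardPath(arg, ps[2], pm, li)
    upaths[[length(ids) + j]] <- list(
      nodes = c(recs[j], up$nodes),
      links = c(li[[paste(ps[2], recs[j])]], up$links))
  }
  copies$root <- vapply(upaths, function(u) u$nodes[length(u$nodes)], numeric(1))
  mean <- mu[match(copies$root, rts)]
  cov <- matrix(0, ncopy, ncopy)
  for (i in seq_len(ncopy)) {
    for (j in i:ncopy) {
      s <- sum(links$length[intersect(upaths[[i]]$links, upaths[[j]]$links)])
      v <- sigma2 * s
      if (rootVariance > 0 && copies$root[i] == copies$root[j]) {
        v <- v + rootVariance
      }
      cov[i, j] <- cov[j, i] <- v
    }
  }
  A <- matrix(0, length(recs), ncopy)
  for (j in seq_along(recs)) {
    A[j, match(recs[j], copies$node[copies$side == 1L])] <- 1
    A[j, length(ids) + j] <- -1
  }
  new("JointGaussian", copies = copies, mean = mean, cov = cov,
      constraints = A, conditioned = FALSE, sigma2 = as.numeric(sigma2))
}

#' Index of a node's copy in a joint Gaussian
#'
#' @param jg a [JointGaussian-class].
#' @param node node id.
#' @param side 1 (canonical) or 2 (the extra recombination copy).
#' @return integer index into the mean/covariance.
#' @export
nodeCopyIndex <- function(jg, node, side = 1L) {
  i <- which(jg@copies$node == node & jg@copies$side == side)
  if (!length(i)) stop("no copy of node ", node, " with side ", side)
  i
}

#' Condition a joint Gaussian on the meeting constraints
#'
#' Exact linear-Gaussian conditioning on left copy = right copy at every
#' recombination node; degenerate directions are handled by the
#' pseudoinverse.  With no loops the object is returned unchanged (but
#' marked conditioned).
#'
#' @param jg a [JointGaussian-class] from [buildJoint()].
#' @return the conditioned [JointGaussian-class].
#' @export
conditionOnLoops <- function(jg) {
  A <- jg@constraints
  if (!nrow(A)) {
    jg@conditioned <- TRUE
    return(jg)
  }
  S <- jg@cov
  AS <- A %*% S
  G <- AS %*% t(A)
  Gg <- generalizedInverse(G)
  disc <- -A %*% jg@mean  # want A X = 0
  resid <- disc - G %*% (Gg %*% disc)
  if (max(abs(resid)) > 1e-8 * max(1, max(abs(disc)))) {
    stop("meeting constraints are inconsistent with the root locations")
  }
  jg@mean <- as.numeric(jg@mean + t(AS) %*% (Gg %*% disc))
  cov <- S - t(AS) %*% (Gg %*% AS)
  jg@cov <- (cov + t(cov)) / 2
  jg@conditioned <- TRUE
  jg
}

#' Exact conditional law of one node given the sample locations
#'
#' Gaussian conditioning of a node's coordinate on the observed sample
#' coordinates, within a loop-conditioned joint Gaussian (roots held fixed at
#' the \code{mu} the joint was built with).
#'
#' @param jg a conditioned [JointGaussian-class].
#' @param node node id (canonical copy is used).
#' @param locations sample locations: named vector or single-column matrix
#'   with node ids as names/rownames.
#' @return list with \code{mean} and \code{variance}.
#' @export
conditionalAncestor <- function(jg, node, locations) {
  if (!jg@conditioned) stop("condition the joint on its loops first")
  if (is.matrix(locations)) {
    l <- locations[, 1]
    names(l) <- rownames(locations)
  } else l <- locations
  sid <- as.integer(names(l))
  si <- vapply(sid, function(s) nodeCopyIndex(jg, s, 1L), integer(1))
  ai <- nodeCopyIndex(jg, node, 1L)
  Sss <- jg@cov[si, si, drop = FALSE]
  Sas <- jg@cov[ai, si, drop = FALSE]
  Sg <- generalizedInverse(Sss)
  w <- Sas %*% Sg
  m <- jg@mean[ai] + as.numeric(w %*% (l - jg@mean[si]))
  v <- jg@cov[ai, ai] - as.numeric(w %*% t(Sas))
  list(mean = m, variance = max(v, 0))
}

#' Brownian-bridge variance along a recombination loop
#'
#' A closed loop of total time \code{totalLoopTime} behaves as a Brownian
#' bridge from the loop's top node back to itself; the variance factor at a
#' point \code{tX} along the loop is \eqn{t_X (T - t_X) / T} (multiply by the
#' dispersal rate).  At the recombination node of a symmetric loop
#' (\eqn{t_X = T/2}) this is \eqn{T/4}, i.e. half the unconditioned
#' single-lineage variance.
#'
#' @param totalLoopTime total time around the loop (both sides), generations.
#' @param tX time from the loop's top node, in \code{[0, totalLoopTime]}.
#' @return variance factor in generations.
#' @export
bridgeVariance <- function(totalLoopTime, tX) {
  stopifnot(totalLoopTime > 0)
  if (any(tX < 0 | tX > totalLoopTime)) {
    stop("tX must lie within [0, totalLoopTime]")
  }
  tX * (totalLoopTime - tX) / totalLoopTime
}
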