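#' @include estimation.R
NULL

#' Midpoint-recombination covariance structure
#'
#' Alternate model of Brownian motion on an ARG in which the two parents of a
#' recombination node may end up any distance apart and the node sits at their
#' unweighted midpoint.  Every node's location is then a fixed weighted sum of
#' root locations and independent edge displacements; propagating the weights
#' root-to-tip gives the exact covariance of any pair of nodes as the
#' weight-product-weighted sum of shared edge lengths.  With no recombination
#' nodes the model coincides with the meeting model.
#'
#' @param arg a validated, chopped [SpatialARG-class].
#' @return list with elements \code{S} (samples x samples covariance
#'   structure, generations), \code{R} (samples x roots mean weights, rows sum
#'   to 1), \code{P} (identity; one "path" per sample),
#'   \code{edgeWeights} (nodes x links weight matrix, rownames node ids),
#'   \code{rootWeights} (nodes x roots) and \code{links}.
#' @seealso [midpointNodeVariance()], [fitArg()] with
#'   \code{variant = "midpoint"}.
#' @export
midpointSharedTimes <- function(arg) {
  links <- .argLinks(arg)
  pm <- .parentMap(arg)
  li <- .linkIndex(links)
  ids <- arg@nodes$id
  rts <- rootIds(arg)
  nl <- nrow(links)
  Wl <- matrix(0, length(ids), max(nl, 1),
               dimnames = list(as.character(ids), NULL))
  Wr <- matrix(0, length(ids), length(rts),
               dimnames = list(as.character(ids), as.character(rts)))
  ord <- order(-arg@nodes$time, ids)  # parents before children
  for (v in ids[ord]) {
    k <- as.character(v)
    ps <- pm[[k]]
    if (!length(ps)) {
      Wr[k, match(v, rts)] <- 1
    } else {
      w <- 1 / length(ps)
      for (p in ps) {
        pk <- as.character(p)
        Wl[k, ] <- Wl[k, ] + w * Wl[pk, ]
        Wl[k, li[[paste(p, v)]]] <- Wl[k, li[[paste(p, v)]]] + w
        Wr[k, ] <- Wr[k, ] + w * Wr[pk, ]
      }
    }
  }
  sk <- as.character(arg@sampleIds)
  Ws <- Wl[sk, , drop = FALSE]
  S <- Ws %*% (links$length * t(Ws))
  dimnames(S) <- list(sk, sk)
  list(S = S, R = Wr[sk, , drop = FALSE],
       P = diag(length(sk)), edgeWeights = Wl, rootWeights = Wr,
       links = links)
}

#' Marginal location variance of a node under the midpoint model
#'
#' @param mm output of [midpointSharedTimes()].
#' @param node node id.
#' @return variance factor in generations (multiply by the dispersal rate);
#'   root locations are treated as fixed.
#' @export
midpointNodeVariance <- function(mm, node) {
  w <- mm$edgeWeights[as.character(node), ]
  sum(w^2 * mm$links$length)
}

#' Per-tree composite-likelihood dispersal fits
#'
#' Fits the Brownian-motion model to every marginal tree separately and
#' averages the dispersal estimates (a composite likelihood over trees,
#' without importance sampling).  The running average as trees accumulate is
#' the classic baseline against which the whole-ARG estimate is compared: on
#' individual-based-simulation data it stabilizes while the ARG estimate keeps
#' rising.
#'
#' @param arg a [SpatialARG-class].
#' @param cutoff optional chop time applied to each marginal tree.
#' @param ks optional integer vector restricting which trees are fitted.
#' @param ... passed on to [fitArg()].
#' @return list with \code{perTree} (data.frame: tree, left, right, sigma2,
#'   loglik, nr), \code{runningAverage} (mean dispersal over the first k
#'   fitted trees) and \code{sigma2Average}.
#' @export
treeCompositeFit <- function(arg, cutoff = NULL, ks = NULL, ...) {
  bp <- treeBreakpoints(arg)
  nTrees <- length(bp) - 1L
  if (is.null(ks)) ks <- seq_len(nTrees)
  rows <- lapply(ks, function(k) {
    sub <- extractWindow(arg, bp[k], bp[k + 1L])
    fit <- suppressMessages(fitArg(sub, cutoff = cutoff, ...))
    data.frame(tree = k, left = bp[k], right = bp[k + 1L],
               sigma2 = mean(diag(fit@sigma2Hat)), loglik = fit@loglik,
               nr = fit@nr)
  })
  perTree <- do.call(rbind, rows)
  ra <- cumsum(perTree$sigma2) / seq_along(ks)
  list(perTree = perTree, runningAverage = ra,
       sigma2Average = mean(perTree$sigma2))
}

#' Averaging-up baseline ancestor locations
#'
#' Locates every node at the unweighted mean of its children's locations in a
#' single tip-to-root pass, ignoring branch lengths entirely.  Nodes with a
#' single child copy the child's value.  The ARG is simplified first (unary
#' pass-through chains removed) unless \code{simplify = FALSE}.  Because edge
#' lengths are ignored, the output is invariant to any change of node times.
#'
#' @param arg a [SpatialARG-class].
#' @param simplify remove pass-through nodes first (default TRUE).
#' @return numeric matrix (nodes x d) of point locations, rownames node ids;
#'   rows are NA for nodes with no sample descendants.
#' @export
averagingUp <- function(arg, simplify = TRUE) {
  if (simplify) arg <- simplifyArg(arg)
  cm <- .childMap(arg)
  nd <- arg@nodes
  d <- ncol(arg@locations)
  out <- matrix(NA_real_, nrow(nd), d, dimnames = list(as.character(nd$id), NULL))
  out[as.character(arg@sampleIds), ] <- arg@locations
  for (v in nd$id[order(nd$time, nd$id)]) {
    k <- as.character(v)
    if (!is.na(out[k, 1])) next  # samples keep their observed location
    ch <- cm[[k]]
    if (!length(ch)) next
    sub <- out[as.character(ch), , drop = FALSE]
    sub <- sub[!is.na(sub[, 1]), , drop = FALSE]
    if (nrow(sub)) out[k, ] <- colMeans(sub)
  }
  out
}
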