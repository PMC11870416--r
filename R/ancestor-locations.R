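#' @include estimation.R
NULL

#' Conditional mean of an ancestor's location
#'
#' \eqn{E[L_a] = \hat\mu_{r_a} + s_a^T S_p^- (P\ell^* - R\hat\mu)}: the
#' root-location estimate plus the shared-time-weighted pull of the sample
#' residuals.  Each coordinate dimension is handled independently.
#'
#' @param stm a [SharedTimeMatrix-class] on the minimal path basis.
#' @param sa,rootIndex shared-time vector and root index from
#'   [ancestorSharedTimes()] (computed on the same basis).
#' @param locations sample locations.
#' @param muHat root-location estimates, matrix (roots x d).
#' @param rtol passed to [generalizedInverse()].
#' @return numeric vector of length d.
#' @export
ancestorMean <- function(stm, sa, rootIndex, locations, muHat, rtol = NULL) {
  ps <- stm@pathSet
  loc <- .asLocations(locations, ps@sampleIds)
  d <- ncol(loc)
  if (is.null(dim(muHat))) muHat <- matrix(muHat, ncol = d)
  X <- ps@P %*% loc - ps@R %*% muHat
  Spg <- generalizedInverse(stm@Sp, rtol)
  as.numeric(muHat[rootIndex, ] + crossprod(X, Spg %*% sa))
}

#' Dispersal-free variance factor of an ancestor's location
#'
#' \eqn{V = (t_a - s_a^T S_p^- s_a) +
#' (e_{r_a} - R^T S_p^- s_a)^T (R^T S_p^- R)^{-1} (e_{r_a} - R^T S_p^- s_a)}:
#' the first term is the Brownian-motion variance left after conditioning on
#' the sample locations, the second the contribution of root-location
#' uncertainty.  Multiplying by the dispersal rate gives the location
#' variance.
#'
#' @inheritParams ancestorMean
#' @param ta time from the node to its root, from [ancestorSharedTimes()].
#' @return list with elements \code{V}, \code{bmComponent} and
#'   \code{rootComponent}.
#' @export
ancestorVariance <- function(stm, sa, ta, rootIndex, rtol = NULL) {
  ps <- stm@pathSet
  R <- ps@R
  Spg <- generalizedInverse(stm@Sp, rtol)
  bm <- as.numeric(ta - crossprod(sa, Spg %*% sa))
  scale <- max(ta, 1)
  if (bm < -1e-8 * scale) {
    stop("negative Brownian variance component (", bm,
         "); the shared-time vector is inconsistent with the path basis")
  }
  bm <- max(bm, 0)
  e <- numeric(ncol(R)); e[rootIndex] <- 1
  u <- e - crossprod(R, Spg %*% sa)
  FF <- crossprod(R, Spg %*% R)
  Finv <- tryCatch(solve(FF), error = function(e2) generalizedInverse(FF))
  rootc <- max(as.numeric(crossprod(u, Finv %*% u)), 0)
  list(V = bm + rootc, bmComponent = bm, rootComponent = rootc)
}

.ancestorLocation <- function(stm, sa, ta, rootIndex, locations, muHat, sigma2,
                              node, time, rtol = NULL) {
  m <- ancestorMean(stm, sa, rootIndex, locations, muHat, rtol)
  v <- ancestorVariance(stm, sa, ta, rootIndex, rtol)
  Sigma <- .asSigma(sigma2, length(m))
  new("AncestorLocation", node = as.integer(node), time = as.numeric(time),
      mean = m, V = v$V, bmComponent = v$bmComponent,
      rootComponent = v$rootComponent, totalVariance = Sigma * v$V,
      sigma2 = Sigma)
}

#' Location distribution of a named internal node
#'
#' @param arg a chopped [SpatialARG-class].
#' @param node node id.
#' @param fit a [FitResult-class] from [fitArg()] on the same (chopped) graph;
#'   supplies the root locations and, unless overridden, the dispersal rate.
#' @param sigma2 optional dispersal override (e.g. the true rate).
#' @param stm optional precomputed [SharedTimeMatrix-class] on the minimal
#'   basis, to avoid recomputation in loops over nodes.
#' @return an [AncestorLocation-class].
#' @export
locateNode <- function(arg, node, fit, sigma2 = NULL, stm = NULL) {
  if (is.null(stm)) stm <- sharedTimes(arg, minimalPaths(arg))
  a <- ancestorSharedTimes(arg, node, stm@pathSet)
  .ancestorLocation(stm, a$sa, a$ta, a$rootIndex, arg@locations,
                    fit@muHat, sigma2 %||% fit@sigma2Hat,
                    node, .nodeTime(arg, node))
}

#' Locate the ancestor of a sample at a genome position and time
#'
#' Follows the lineage of \code{sample} in the local tree at \code{position}
#' up to \code{time} and returns the location distribution of that point.  If
#' the time falls strictly inside an edge, the shared times accrue linearly
#' along the partial edge (Brownian motion accrues shared time linearly), so
#' mid-edge ancestors are supported exactly.
#'
#' @param arg a chopped [SpatialARG-class].
#' @param sample a sample node id.
#' @param position genome position in base pairs.
#' @param time generations before present.
#' @inheritParams locateNode
#' @return an [AncestorLocation-class].
#' @export
locateAncestor <- function(arg, sample, position, time, fit, sigma2 = NULL,
                           stm = NULL) {
  if (!sample %in% arg@sampleIds) stop("node ", sample, " is not a sample")
  if (position < 0 || position >= arg@sequenceLength) {
    stop("position ", position, " outside the sequence [0, ",
         arg@sequenceLength, ")")
  }
  if (time < 0) stop("time must be non-negative")
  if (is.null(stm)) stm <- sharedTimes(arg, minimalPaths(arg))
  ed <- arg@edges
  v <- sample
  repeat {
    tv <- .nodeTime(arg, v)
    if (time == tv) {
      return(locateNode(arg, v, fit, sigma2 = sigma2, stm = stm))
    }
    rows <- ed$child == v & ed$left <= position & ed$right > position
    if (!any(rows)) {
      stop("time ", time, " is above the root of sample ", sample,
           "'s lineage at position ", position)
    }
    p <- min(ed$parent[rows])  # recombination: intervals are disjoint, unique
    tp <- .nodeTime(arg, p)
    if (time < tp) break
    v <- p
  }
  ## point strictly inside the edge v -> p
  links <- .argLinks(arg)
  li <- .linkIndex(links)
  lk <- li[[paste(p, v)]]
  ps <- stm@pathSet
  a <- ancestorSharedTimes(arg, p, ps)
  onEdge <- vapply(ps@linkPaths, function(lp) lk %in% lp, logical(1))
  sa <- a$sa + (tp - time) * onEdge
  ta <- a$ta + (tp - time)
  .ancestorLocation(stm, sa, ta, a$rootIndex, arg@locations, fit@muHat,
                    sigma2 %||% fit@sigma2Hat, NA_integer_, time)
}

#' Gaussian confidence region for an ancestor location
#'
#' @param loc an [AncestorLocation-class].
#' @param level confidence level in (0, 1).
#' @return in one dimension, \code{c(lower, upper)}; in two, a list with the
#'   ellipse \code{center}, covariance \code{shape}, \code{radius}
#'   (chi-square quantile scaling) and principal \code{axes} (columns) with
#'   semi-axis \code{lengths}.
#' @export
confidenceRegion <- function(loc, level = 0.95) {
  stopifnot(is(loc, "AncestorLocation"), level > 0, level < 1)
  d <- length(loc@mean)
  if (d == 1L) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    hw <- z * sqrt(loc@totalVariance[1, 1])
    return(c(lower = loc@mean[1] - hw, upper = loc@mean[1] + hw))
  }
  r <- sqrt(stats::qchisq(level, df = 2))
  eg <- eigen(loc@totalVariance, symmetric = TRUE)
  list(center = loc@mean, shape = loc@totalVariance, radius = r,
       axes = eg$vectors, lengths = r * sqrt(pmax(eg$values, 0)))
}
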