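#' @include spatial-likelihood.R
NULL

## Generalized least squares core shared by the meeting and midpoint models.
## Sp: working covariance of the path tips (np x np); P: path-sample matrix;
## R: path-root design (may be fractional under the midpoint model).
.glsCore <- function(Sp, P, R, loc, denom, rtol = NULL) {
  Spg <- generalizedInverse(Sp, rtol)
  FF <- crossprod(R, Spg %*% R)
  ev <- eigen((FF + t(FF)) / 2, symmetric = TRUE, only.values = TRUE)$values
  rankF <- sum(abs(ev) > 1e-10 * max(abs(ev), 1e-300))
  if (rankF < ncol(R)) {
    warning("R' Sp^- R is rank deficient (rank ", rankF, " < ", ncol(R),
            "); root locations are not jointly identifiable, ",
            "returning the minimum-norm solution")
    Finv <- generalizedInverse(FF)
  } else {
    Finv <- solve(FF)
  }
  mu <- Finv %*% crossprod(R, Spg %*% (P %*% loc))
  X <- P %*% loc - R %*% mu
  Sigma <- crossprod(X, Spg %*% X) / denom
  Sigma <- (Sigma + t(Sigma)) / 2
  list(mu = mu, sigma2 = Sigma, Spg = Spg, rankF = rankF,
       conditionSp = {
         e <- eigen(Sp, symmetric = TRUE, only.values = TRUE)$values
         e <- abs(e); if (min(e) > 0) max(e) / min(e) else Inf
       })
}

#' Maximum-likelihood root locations
#'
#' Generalized-least-squares estimate
#' \eqn{\hat\mu = (R^T S_p^- R)^{-1} R^T S_p^- P \ell^*} of the location of
#' each root, treating root locations as fixed unknowns.
#'
#' @param stm a [SharedTimeMatrix-class] (add root variance first if wanted).
#' @param locations sample locations (see [spatialLogLik()]).
#' @param rtol passed to [generalizedInverse()].
#' @return numeric matrix (roots x d) with root ids as rownames.
#' @export
mleRootLocations <- function(stm, locations, rtol = NULL) {
  ps <- stm@pathSet
  loc <- .asLocations(locations, ps@sampleIds)
  g <- .glsCore(stm@Sp, ps@P, ps@R, loc, denom = length(ps@sampleIds), rtol = rtol)
  mu <- g$mu
  rownames(mu) <- as.character(ps@rootIds)
  mu
}

#' Maximum-likelihood dispersal rate
#'
#' The residual quadratic form
#' \eqn{(P\ell^* - R\hat\mu)^T S_p^- (P\ell^* - R\hat\mu) / n_s}; in two
#' dimensions the cross-products of the per-coordinate residuals give the full
#' 2 x 2 dispersal matrix.  The \eqn{n_s} denominator is the MLE; because the
#' root locations are estimated, its expectation is
#' \eqn{\sigma^2 (n_s - n_r)/n_s}, and \code{reml = TRUE} applies the
#' \eqn{n_s - n_r} denominator instead.
#'
#' @param stm a [SharedTimeMatrix-class].
#' @param locations sample locations.
#' @param muHat root locations as returned by [mleRootLocations()].
#' @param reml use the degrees-of-freedom-corrected denominator.
#' @param rtol passed to [generalizedInverse()].
#' @return d x d dispersal matrix (1 x 1 in one dimension).
#' @export
mleDispersal <- function(stm, locations, muHat, reml = FALSE, rtol = NULL) {
  ps <- stm@pathSet
  loc <- .asLocations(locations, ps@sampleIds)
  d <- ncol(loc)
  if (is.null(dim(muHat))) muHat <- matrix(muHat, ncol = d)
  ns <- length(ps@sampleIds)
  nr <- ncol(ps@R)
  denom <- if (reml) ns - nr else ns
  X <- ps@P %*% loc - ps@R %*% muHat
  Spg <- generalizedInverse(stm@Sp, rtol)
  Sigma <- crossprod(X, Spg %*% X) / denom
  (Sigma + t(Sigma)) / 2
}

.makeFit <- function(mu, sigma2, loglik, np, ns, nr, variant, diagnostics) {
  new("FitResult", muHat = as.matrix(mu), sigma2Hat = as.matrix(sigma2),
      loglik = as.numeric(loglik), np = as.integer(np), ns = as.integer(ns),
      nr = as.integer(nr), variant = variant, diagnostics = diagnostics)
}

#' Fit dispersal rate and root locations to an ARG
#'
#' Full pipeline: optionally chop the ARG, build the minimal path set and its
#' shared-time matrix, optionally relax the root-location variance, estimate
#' root locations and the dispersal rate in closed form, and evaluate the
#' log-likelihood at the estimates.  With \code{variant = "midpoint"} the
#' alternate model is used, in which each recombination node sits at the
#' unweighted average of its two parents' locations instead of requiring the
#' parents to meet.
#'
#' @param arg a [SpatialARG-class] with sample locations.
#' @param cutoff optional chop time (generations); \code{NULL} fits the graph
#'   as given.
#' @param variant \code{"meeting"} (default) or \code{"midpoint"}.
#' @param rootVariance non-negative scalar (or per-root vector) added variance
#'   on root locations; 0 keeps the fixed-root assumption.
#' @param reml use the \eqn{n_s - n_r} dispersal denominator.
#' @param rtol passed to [generalizedInverse()].
#' @return a [FitResult-class].
#' @examples
#' arg <- simulateModelArg(ns = 6, targetRecombinations = 2, seed = 1)
#' loc <- simulateLocations(arg, mu = 0, sigma2 = 1, seed = 2)
#' fit <- fitArg(withSampleLocations(arg, loc))
#' dispersalRate(fit)
#' @export
fitArg <- function(arg, cutoff = NULL, variant = c("meeting", "midpoint"),
                   rootVariance = 0, reml = FALSE, rtol = NULL) {
  variant <- match.arg(variant)
  if (!is.null(cutoff)) arg <- chopArg(arg, cutoff)
  loc <- arg@locations
  ns <- length(arg@sampleIds)
  nr <- length(rootIds(arg))
  if (variant == "meeting") {
    ps <- minimalPaths(arg)
    stm <- sharedTimes(arg, ps)
    if (any(rootVariance > 0)) stm <- addRootVariance(stm, rootVariance)
    g <- .glsCore(stm@Sp, ps@P, ps@R, loc,
                  denom = if (reml) ns - nr else ns, rtol = rtol)
    ll <- spatialLogLik(stm, loc, g$mu, g$sigma2, rtol = rtol)
    np <- length(ps@paths)
    diag <- list(conditionSp = g$conditionSp, rankRootDesign = g$rankF,
                 rootIds = ps@rootIds)
    if (nrow(arg@nodes) <= 500) {
      lp <- findLoops(arg)
      diag$openLoops <- attr(lp, "openLoops")
      diag$nLoops <- length(lp)
    }
    mu <- g$mu
    rownames(mu) <- as.character(ps@rootIds)
    return(.makeFit(mu, g$sigma2, ll, np, ns, nr, variant, diag))
  }
  ## midpoint model: sample-side covariance structure directly
  mm <- midpointSharedTimes(arg)
  P <- diag(ns)
  g <- .glsCore(mm$S, P, mm$R, loc,
                denom = if (reml) ns - nr else ns, rtol = rtol)
  d <- ncol(loc)
  X <- loc - mm$R %*% g$mu
  Spg <- g$Spg
  r <- attr(Spg, "rank")
  Q <- crossprod(X, Spg %*% X)
  cS <- chol(g$sigma2)
  ll <- -0.5 * (r * d * log(2 * pi) + d * attr(Spg, "logpdet") +
                r * 2 * sum(log(diag(cS))) + sum(diag(chol2inv(cS) %*% Q)))
  mu <- g$mu
  rownames(mu) <- as.character(colnames(mm$R))
  .makeFit(mu, g$sigma2, ll, ns, ns, nr, "midpoint",
           list(conditionSp = g$conditionSp, rankRootDesign = g$rankF))
}

#' Fit on a genomic window of trees
#'
#' Restricts the ARG to the \code{2 * halfWidthTrees + 1} local trees centred
#' on \code{focalTreeIndex} (fewer at chromosome ends) and fits that sub-ARG.
#' The window is defined in tree counts, not base pairs.  By default the
#' sub-ARG is chopped afresh at \code{cutoff}.
#'
#' @param arg a [SpatialARG-class].
#' @param focalTreeIndex 1-based index of the focal local tree.
#' @param halfWidthTrees number of trees kept on either side.
#' @param cutoff optional chop time applied to the sub-ARG.
#' @param ... passed on to [fitArg()].
#' @return a [FitResult-class].
#' @export
windowedFit <- function(arg, focalTreeIndex, halfWidthTrees, cutoff = NULL, ...) {
  bp <- treeBreakpoints(arg)
  nTrees <- length(bp) - 1L
  stopifnot(focalTreeIndex >= 1, focalTreeIndex <= nTrees, halfWidthTrees >= 0)
  lo <- max(1L, focalTreeIndex - halfWidthTrees)
  hi <- min(nTrees, focalTreeIndex + halfWidthTrees)
  sub <- extractWindow(arg, bp[lo], bp[hi + 1L])
  fitArg(sub, cutoff = cutoff, ...)
}

#' Dispersal estimates as a function of the number of trees
#'
#' Experiment driver: for each \code{k}, fits the sub-ARG spanned by the first
#' \code{k} local trees and records the dispersal estimate.  Under the meeting
#' model on data from an individual-based spatial simulation the estimate
#' rises systematically with \code{k} (each extra tree adds a recombination
#' loop), while the per-tree composite average ([treeCompositeFit()]) is flat.
#'
#' @param arg a [SpatialARG-class].
#' @param ks integer vector of tree counts; default every tree count.
#' @param cutoff optional chop time applied to each sub-ARG.
#' @param ... passed on to [fitArg()].
#' @return data.frame with columns \code{k}, \code{sigma2} (mean of the
#'   diagonal dispersal entries), \code{nRecombination} and \code{loglik}.
#' @export
dispersalByTrees <- function(arg, ks = NULL, cutoff = NULL, ...) {
  bp <- treeBreakpoints(arg)
  nTrees <- length(bp) - 1L
  if (is.null(ks)) ks <- seq_len(nTrees)
  stopifnot(all(ks >= 1), all(ks <= nTrees))
  out <- lapply(ks, function(k) {
    sub <- extractWindow(arg, bp[1], bp[k + 1L])
    fit <- fitArg(sub, cutoff = cutoff, ...)
    data.frame(k = k, sigma2 = mean(diag(fit@sigma2Hat)),
               nRecombination = length(recombinationNodes(
                 if (is.null(cutoff)) sub else suppressMessages(chopArg(sub, cutoff)))),
               loglik = fit@loglik)
  })
  do.call(rbind, out)
}
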