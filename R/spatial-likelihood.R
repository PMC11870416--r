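#' @include path-matrix.R
NULL

#' Moore-Penrose pseudoinverse of a symmetric PSD matrix
#'
#' Eigenvalues below \code{rtol} times the largest (in magnitude) are treated
#' as exactly zero.  Path matrices are singular whenever the path basis is
#' linearly dependent (e.g. the full path set), so the generalized inverse is
#' used throughout the likelihood machinery.
#'
#' @param M symmetric numeric matrix.
#' @param rtol relative truncation tolerance; default \code{1e-10 * nrow(M)}.
#' @return the pseudoinverse, with the numerical rank in \code{attr(,"rank")}.
#' @export
generalizedInverse <- function(M, rtol = NULL) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (nrow(M) == 0L) return(M)
  scale <- max(abs(M), 1e-300)
  if (max(abs(M - t(M))) > 1e-8 * scale) {
    stop("matrix is not symmetric within tolerance")
  }
  if (is.null(rtol)) rtol <- 1e-10 * nrow(M)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- abs(eg$values) > rtol * max(abs(eg$values), 1e-300)
  inv <- ifelse(keep, 1 / eg$values, 0)
  out <- eg$vectors %*% (inv * t(eg$vectors))
  dimnames(out) <- dimnames(M)
  attr(out, "rank") <- sum(keep)
  attr(out, "logpdet") <- sum(log(eg$values[keep & eg$values > 0]))
  out
}

#' Sample matrix from a path matrix
#'
#' Converts the shared-time matrix of (possibly redundant) sample paths into
#' the covariance structure of the sample locations themselves,
#' \eqn{S = (P^T S_p^- P)^{-1}}; multiplying by the dispersal rate gives the
#' covariance matrix of the sample locations after conditioning all paths to
#' the same sample to coincide.  For a tree, \code{S} equals \code{Sp}.
#'
#' @param stm a [SharedTimeMatrix-class].
#' @param rtol passed to [generalizedInverse()].
#' @return symmetric numeric matrix (samples x samples), in units of
#'   generations.
#' @export
sampleMatrix <- function(stm, rtol = NULL) {
  P <- stm@pathSet@P
  Spg <- generalizedInverse(stm@Sp, rtol)
  inner <- crossprod(P, Spg %*% P)
  ev <- eigen((inner + t(inner)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev))) {
    stop("P' Sp^- P is singular; the sample matrix is not defined -- ",
         "work with the path-space likelihood (spatialLogLik) instead")
  }
  S <- solve(inner)
  S <- (S + t(S)) / 2
  ids <- as.character(stm@pathSet@sampleIds)
  dimnames(S) <- list(ids, ids)
  S
}

#' Relax the zero-variance root assumption
#'
#' Adds a variance \code{v} to the covariance between every pair of paths
#' terminating at the same root (\eqn{S_p + R\,\mathrm{diag}(v)\,R^T}),
#' replacing the default assumption that each root location is known exactly.
#'
#' @param stm a [SharedTimeMatrix-class].
#' @param v non-negative scalar, or one value per root.
#' @return a [SharedTimeMatrix-class] with the inflated path matrix.
#' @export
addRootVariance <- function(stm, v) {
  R <- stm@pathSet@R
  nr <- ncol(R)
  if (length(v) == 1L) v <- rep(v, nr)
  stopifnot(length(v) == nr, all(v >= 0))
  new("SharedTimeMatrix", Sp = stm@Sp + R %*% (v * t(R)),
      pathSet = stm@pathSet)
}

#' Log-likelihood of sample locations given the ARG
#'
#' Density of the path-tip locations \eqn{P \ell^*} under
#' \eqn{N(R\mu, \sigma^2 S_p)}.  When \eqn{S_p} is singular the density is
#' evaluated on its support using the pseudoinverse and pseudo-determinant;
#' a residual outside the support (a violated meeting constraint) yields
#' \code{-Inf} with a \code{"supportViolation"} attribute.  In two dimensions
#' the dispersal matrix factorizes across coordinates (Kronecker structure),
#' so no \code{2 np x 2 np} matrix is ever formed.
#'
#' @param stm a [SharedTimeMatrix-class].
#' @param locations sample locations (matrix ordered as the path set's
#'   samples, or with rownames naming sample node ids).
#' @param mu root locations: matrix (roots x d) ordered as the path set's
#'   roots, or a vector in one dimension.
#' @param sigma2 dispersal rate: scalar, or d x d matrix.
#' @param rtol passed to [generalizedInverse()].
#' @return numeric(1) log-likelihood.
#' @export
spatialLogLik <- function(stm, locations, mu, sigma2, rtol = NULL) {
  ps <- stm@pathSet
  loc <- .asLocations(locations, ps@sampleIds)
  d <- ncol(loc)
  if (is.null(dim(mu))) mu <- matrix(mu, ncol = d)
  stopifnot(nrow(mu) == ncol(ps@R), ncol(mu) == d)
  Sigma <- .asSigma(sigma2, d)
  X <- ps@P %*% loc - ps@R %*% mu
  Spg <- generalizedInverse(stm@Sp, rtol)
  r <- attr(Spg, "rank")
  logpdet <- attr(Spg, "logpdet")
  resid <- X - stm@Sp %*% (Spg %*% X)
  tol <- 1e-6 * max(1, max(abs(X)))
  if (max(abs(resid)) > tol) {
    out <- -Inf
    attr(out, "supportViolation") <- max(abs(resid))
    return(out)
  }
  Q <- crossprod(X, Spg %*% X)  # d x d
  cS <- chol(Sigma)
  logdetSigma <- 2 * sum(log(diag(cS)))
  quad <- sum(diag(chol2inv(cS) %*% Q))
  -0.5 * (r * d * log(2 * pi) + d * logpdet + r * logdetSigma + quad)
}
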