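test_that("generalizedInverse satisfies the Penrose conditions", {
  expect_equal(generalizedInverse(diag(3)), diag(3), ignore_attr = TRUE)

  # rank-1 closed form
  M <- matrix(1, 2, 2)
  expect_equal(unname(generalizedInverse(M)), matrix(0.25, 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)

  set.seed(1)
  A <- matrix(rnorm(36), 6)
  M <- crossprod(A)
  G <- generalizedInverse(M)
  expect_lt(max(abs(M %*% G %*% M - M)), 1e-8)
  expect_lt(max(abs(G %*% M %*% G - G)), 1e-8)
  expect_lt(max(abs(M %*% G - t(M %*% G))), 1e-8)
  expect_lt(max(abs(G %*% M - t(G %*% M))), 1e-8)

  # a singular PSD matrix: agrees with an independent pseudoinverse
  B <- matrix(rnorm(18), 6, 3)
  M <- tcrossprod(B)  # rank 3
  expect_lt(max(abs(generalizedInverse(M) - MASS::ginv(M))), 1e-8)
  expect_equal(attr(generalizedInverse(M), "rank"), 3L)

  expect_error(generalizedInverse(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("the sample matrix collapses to the path matrix on a tree", {
  arg <- twoTipTree(T = 11)
  stm <- sharedTimes(arg, minimalPaths(arg))
  expect_equal(unname(sampleMatrix(stm)), unname(stm@Sp), tolerance = 1e-12)

  one <- spatialARG(data.frame(id = 0:1, time = c(0, 5),
                               is_sample = c(TRUE, FALSE)),
                    data.frame(parent = 1L, child = 0L, left = 0, right = 1),
                    data.frame(node_id = 0L, x = 0))
  expect_equal(unname(sampleMatrix(sharedTimes(one, minimalPaths(one)))),
               matrix(5, 1, 1))
})

test_that("sample matrix equals the conditioned joint-Gaussian covariance", {
  for (arg in list(oneLoopArg(), twoTreeArg(), symmetricLoopArg())) {
    stm <- sharedTimes(arg, minimalPaths(arg))
    S <- sampleMatrix(stm)
    jg <- conditionOnLoops(buildJoint(arg, mu = 0, sigma2 = 1))
    si <- vapply(sampleIds(arg), function(s) nodeCopyIndex(jg, s, 1L),
                 integer(1))
    expect_lt(max(abs(jg@cov[si, si] - S)), 1e-10)
  }
})

test_that("conditioning on loops clusters samples below recombination nodes", {
  # marginal variance of a sample under a loop is strictly smaller in the ARG
  # than in either marginal tree
  for (arg in list(oneLoopArg(), symmetricLoopArg())) {
    S <- sampleMatrix(sharedTimes(arg, minimalPaths(arg)))
    under <- as.character(sampleIds(arg)[1])  # sample below the loop
    bp <- treeBreakpoints(arg)
    for (k in seq_len(length(bp) - 1L)) {
      tr <- extractWindow(arg, bp[k], bp[k + 1L])
      St <- sampleMatrix(sharedTimes(tr, minimalPaths(tr)))
      expect_lt(S[under, under], St[under, under] - 1e-9)
    }
  }
})

test_that("root-variance relaxation adds v within same-root blocks", {
  arg <- oneLoopArg()
  stm <- sharedTimes(arg, minimalPaths(arg))
  expect_equal(addRootVariance(stm, 0)@Sp, stm@Sp)
  # single root: v is added everywhere
  expect_equal(addRootVariance(stm, 2.5)@Sp, stm@Sp + 2.5)

  # two roots: v added only within same-root blocks
  two <- suppressMessages(chopArg(twoTipTree(T = 100), 50))
  stm2 <- sharedTimes(two, minimalPaths(two))
  out <- addRootVariance(stm2, 3)@Sp
  expect_equal(unname(out), unname(stm2@Sp + diag(3, 2)))
  expect_error(addRootVariance(stm2, -1))
})

test_that("log-likelihood matches closed forms and the conditioning oracle", {
  # one sample at mu: log N(mu, sigma^2 T) at mu
  one <- spatialARG(data.frame(id = 0:1, time = c(0, 5),
                               is_sample = c(TRUE, FALSE)),
                    data.frame(parent = 1L, child = 0L, left = 0, right = 1),
                    data.frame(node_id = 0L, x = 2))
  stm1 <- sharedTimes(one, minimalPaths(one))
  expect_equal(spatialLogLik(stm1, matrix(2), mu = 2, sigma2 = 3),
               dnorm(0, sd = sqrt(3 * 5), log = TRUE))

  # tree: standard phylogenetic Brownian-motion likelihood (dense oracle)
  arg <- simulateModelArg(ns = 5, targetRecombinations = 0, seed = 4)
  arg <- withSampleLocations(arg, simulateLocations(arg, 0.3, 2, seed = 5))
  stm <- sharedTimes(arg, minimalPaths(arg))
  S <- sampleMatrix(stm)
  l <- sampleLocations(arg)[, 1]
  dense <- -0.5 * (5 * log(2 * pi) +
                   as.numeric(determinant(2 * S)$modulus) +
                   t(l - 0.3) %*% solve(2 * S) %*% (l - 0.3))
  expect_equal(spatialLogLik(stm, sampleLocations(arg), mu = 0.3, sigma2 = 2),
               as.numeric(dense), tolerance = 1e-10)

  # one-loop ARG: the path-space likelihood equals the oracle conditional
  # density of the samples plus the log-density of the meeting contrasts at
  # zero (the exact conditioning decomposition)
  arg2 <- simulateModelArg(ns = 4, targetRecombinations = 2, seed = 11)
  arg2 <- withSampleLocations(arg2, simulateLocations(arg2, -1, 0.5, seed = 12))
  ps2 <- minimalPaths(arg2)
  stm2 <- sharedTimes(arg2, ps2)
  jg <- conditionOnLoops(buildJoint(arg2, mu = -1, sigma2 = 0.5))
  si <- vapply(sampleIds(arg2), function(s) nodeCopyIndex(jg, s, 1L),
               integer(1))
  l2 <- sampleLocations(arg2)[, 1]
  dmvn <- function(x, m, V) {
    -0.5 * (length(x) * log(2 * pi) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(t(x - m) %*% solve(V) %*% (x - m)))
  }
  oracle <- dmvn(l2, jg@mean[si], jg@cov[si, si])
  D <- NULL
  for (s in seq_len(ncol(ps2@P))) {
    rows <- which(ps2@P[, s] == 1)
    for (j in rows[-1]) {
      d <- rep(0, nrow(ps2@P)); d[rows[1]] <- -1; d[j] <- 1
      D <- rbind(D, d)
    }
  }
  pd0 <- dmvn(rep(0, nrow(D)),
              as.numeric(D %*% ps2@R %*% matrix(-1, ncol(ps2@R))),
              0.5 * D %*% stm2@Sp %*% t(D))
  expect_equal(spatialLogLik(stm2, sampleLocations(arg2), -1, 0.5),
               oracle + pd0, tolerance = 1e-8)
})

test_that("likelihood is basis-, translation- and scale-consistent", {
  arg <- simulateModelArg(ns = 5, targetRecombinations = 3, seed = 31)
  arg <- withSampleLocations(arg, simulateLocations(arg, 0, 1, seed = 32))
  loc <- sampleLocations(arg)
  full <- enumerateAllPaths(arg)
  minp <- minimalPaths(arg)
  llf <- function(ps, loc, mu, s2) {
    spatialLogLik(sharedTimes(arg, ps), loc, mu, s2)
  }
  # invariance to the path basis, up to the fixed contrast normalization:
  # likelihood *differences* across parameter values must agree exactly
  d1 <- llf(minp, loc, 0, 1) - llf(minp, loc, 0.7, 1.3)
  d2 <- llf(full, loc, 0, 1) - llf(full, loc, 0.7, 1.3)
  expect_equal(d1, d2, tolerance = 1e-8)

  # joint translation of locations and mu changes nothing
  expect_equal(llf(minp, loc, 0.2, 1), llf(minp, loc + 5, 5.2, 1),
               tolerance = 1e-8)

  # rescaling locations by c and sigma^2 by c^2 shifts the log-likelihood by
  # -rank(Sp) * log(c)
  r <- attr(generalizedInverse(sharedTimes(arg, minp)@Sp), "rank")
  expect_equal(llf(minp, 3 * loc, 0, 9), llf(minp, loc, 0, 1) - r * log(3),
               tolerance = 1e-8)

  # a violated meeting constraint in a singular basis is flagged as -Inf
  stmF <- sharedTimes(arg, full)
  badloc <- loc
  ll <- spatialLogLik(stmF, badloc, 0, 1)
  expect_true(is.finite(ll))  # consistent tips lie on the support
})
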