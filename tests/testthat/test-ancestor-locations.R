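test_that("sample and root nodes are degenerate cases", {
  arg <- withSampleLocations(oneLoopArg(), matrix(c(-1, 0, 2), 3))
  fit <- fitArg(arg)
  stm <- sharedTimes(arg, minimalPaths(arg))

  s <- sampleIds(arg)[2]
  al <- locateNode(arg, s, fit, stm = stm)
  expect_equal(al@mean, unname(sampleLocations(arg)[2, ]), tolerance = 1e-9)
  expect_equal(al@V, 0, tolerance = 1e-9)

  r <- rootIds(arg)
  alr <- locateNode(arg, r, fit, stm = stm)
  expect_equal(alr@mean, unname(fit@muHat[1, ]), tolerance = 1e-10)
  expect_equal(alr@bmComponent, 0, tolerance = 1e-12)
  # single-root tree closed form: root component is (1' Sp^-1 1)^-1
  tree <- twoTipTree(T = 10)
  fitT <- fitArg(tree)
  stmT <- sharedTimes(tree, minimalPaths(tree))
  alT <- locateNode(tree, 2L, fitT, stm = stmT)
  ones <- rep(1, 2)
  expect_equal(alT@rootComponent,
               1 / as.numeric(t(ones) %*% solve(stmT@Sp) %*% ones),
               tolerance = 1e-12)
})

test_that("ancestor moments match dense joint-Gaussian conditioning", {
  # means and Brownian components against the conditioning oracle with roots
  # fixed at the GLS estimates; the full V against the exact mean-squared
  # error of the plug-in GLS predictor computed from oracle covariances
  for (seed in 1:8) {
    sim <- randomSpatialArg(seed, ns = sample(3:7, 1), recs = sample(0:4, 1))
    arg <- sim$arg
    ps <- minimalPaths(arg)
    stm <- sharedTimes(arg, ps)
    muHat <- mleRootLocations(stm, sampleLocations(arg))
    jg <- conditionOnLoops(buildJoint(arg, mu = muHat[, 1], sigma2 = 1))
    si <- vapply(sampleIds(arg), function(s) nodeCopyIndex(jg, s, 1L),
                 integer(1))
    C <- jg@cov[si, si]
    Spg <- generalizedInverse(stm@Sp)
    P <- ps@P; R <- ps@R
    M <- solve(crossprod(R, Spg %*% R)) %*% crossprod(R, Spg %*% P)
    for (a in setdiff(nodeTable(arg)$id, sampleIds(arg))) {
      at <- ancestorSharedTimes(arg, a, ps)
      m <- ancestorMean(stm, at$sa, at$rootIndex, sampleLocations(arg), muHat)
      v <- ancestorVariance(stm, at$sa, at$ta, at$rootIndex)
      o <- conditionalAncestor(jg, a, sampleLocations(arg))
      expect_equal(m, o$mean, tolerance = 1e-8)
      expect_equal(v$bmComponent, o$variance, tolerance = 1e-8)
      ai <- nodeCopyIndex(jg, a, 1L)
      w <- as.numeric(M[at$rootIndex, ] +
                      crossprod(at$sa, Spg %*% (P - R %*% M)))
      mse <- jg@cov[ai, ai] - 2 * sum(w * jg@cov[si, ai]) +
             as.numeric(t(w) %*% C %*% w)
      expect_equal(v$V, mse, tolerance = 1e-8)
    }
  }
})

test_that("the ancestor distribution does not depend on the path choice", {
  # recompute sa along the *other* parent of a node inside the loop and check
  # the moments agree (path-invariance in exact arithmetic)
  arg <- withSampleLocations(twoTreeArg(), matrix(c(-0.5, 0, 0.5, 1), 4))
  ps <- minimalPaths(arg)
  stm <- sharedTimes(arg, ps)
  muHat <- mleRootLocations(stm, sampleLocations(arg))
  a <- 5L  # the recombination node: two distinct upward paths exist
  at <- ancestorSharedTimes(arg, a, ps)
  # alternative path: via the larger parent (7), then canonically up
  pm <- argspace:::.parentMap(arg)
  other <- pm[[as.character(a)]][2]
  upOther <- argspace:::.canonicalUpwardPath(arg, other)
  altNodes <- c(a, upOther$nodes)
  saAlt <- vapply(ps@paths, function(p) bruteSharedTime(arg, altNodes, p),
                  numeric(1))
  taAlt <- nodeTable(arg)$time[match(altNodes[length(altNodes)],
                                     nodeTable(arg)$id)] -
           nodeTable(arg)$time[match(a, nodeTable(arg)$id)]
  m1 <- ancestorMean(stm, at$sa, at$rootIndex, sampleLocations(arg), muHat)
  m2 <- ancestorMean(stm, saAlt, at$rootIndex, sampleLocations(arg), muHat)
  v1 <- ancestorVariance(stm, at$sa, at$ta, at$rootIndex)
  v2 <- ancestorVariance(stm, saAlt, taAlt, at$rootIndex)
  expect_equal(m1, m2, tolerance = 1e-8)
  expect_equal(v1$V, v2$V, tolerance = 1e-8)
})

test_that("node timing moves ARG estimates but not the baselines", {
  # the averaging-up location of an inner node ignores node times entirely,
  # single-tree estimates ignore the timing of recombination nodes, and the
  # ARG estimate responds to both
  locH <- function(tE) {
    arg <- twoTreeArg(tE = tE)
    fit <- fitArg(arg)
    locateNode(arg, 4L, fit, sigma2 = matrix(1, 1, 1))@mean
  }
  expect_false(isTRUE(all.equal(locH(0.8), locH(1.3))))

  avg1 <- averagingUp(twoTreeArg(tE = 0.8))
  avg2 <- averagingUp(twoTreeArg(tE = 1.3, tG = 3.4))
  expect_equal(avg1["4", ], avg2["4", ], tolerance = 1e-12)

  # recombination-node timing does not alter marginal-tree shared times
  treeFitAt <- function(tE) {
    tr <- marginalTree(twoTreeArg(tE = tE), 10)
    fit <- fitArg(tr)
    locateNode(tr, 4L, fit, sigma2 = matrix(1, 1, 1))@mean
  }
  expect_equal(treeFitAt(0.8), treeFitAt(1.3), tolerance = 1e-10)
})

test_that("the ARG never locates shared-path ancestors less precisely than a tree", {
  # same dispersal rate: V from the full ARG <= V from the local tree, and
  # V never exceeds the unconditional sigma^2 * ta
  arg <- withSampleLocations(twoTreeArg(), matrix(c(-0.5, 0, 0.5, 1), 4))
  fit <- fitArg(arg)
  stm <- sharedTimes(arg, minimalPaths(arg))
  tr <- marginalTree(arg, 10)
  fitT <- fitArg(tr)
  stmT <- sharedTimes(tr, minimalPaths(tr))
  sig <- matrix(1, 1, 1)
  for (a in intersect(nodeTable(tr)$id, nodeTable(arg)$id)) {
    if (a %in% sampleIds(arg)) next
    vArg <- locateNode(arg, a, fit, sigma2 = sig, stm = stm)
    vTree <- locateNode(tr, a, fitT, sigma2 = sig, stm = stmT)
    expect_lte(vArg@V, vTree@V + 1e-9)
    at <- ancestorSharedTimes(arg, a, minimalPaths(arg))
    expect_lte(vArg@bmComponent, at$ta + 1e-9)
  }
})

test_that("locateAncestor follows the lineage at a genome position", {
  arg <- withSampleLocations(twoTreeArg(), matrix(c(-0.5, 0, 0.5, 1), 4))
  fit <- fitArg(arg)

  # time 0: the sample's own location with zero variance
  al0 <- locateAncestor(arg, 2L, position = 10, time = 0, fit = fit)
  expect_equal(al0@mean, 0.5, tolerance = 1e-9)
  expect_equal(al0@V, 0, tolerance = 1e-9)

  # time at a node on the lineage: identical to locating that node
  alE <- locateAncestor(arg, 2L, position = 10, time = 1, fit = fit)
  expect_equal(alE@mean, locateNode(arg, 5L, fit)@mean, tolerance = 1e-10)
  expect_equal(alE@V, locateNode(arg, 5L, fit)@V, tolerance = 1e-10)

  # sample 2's lineage at the left tree goes through F(6); on the right tree
  # through G(7): mid-edge points on the two sides differ
  l <- locateAncestor(arg, 2L, position = 10, time = 1.5, fit = fit)
  r <- locateAncestor(arg, 2L, position = 80, time = 1.5, fit = fit)
  expect_false(isTRUE(all.equal(l@mean, r@mean)))

  # mid-edge moments agree with the oracle: condition the joint Gaussian on
  # the samples after splitting the edge at the query time with an explicit
  # intermediate node
  split <- twoTreeArg()
  nd <- nodeTable(split); ed <- edgeTable(split)
  # put node 9 at time 1.5 inside the edge 6 -> 5 (left genome half)
  ed[ed$parent == 6 & ed$child == 5, "parent"] <- 9L
  ed <- rbind(ed, data.frame(parent = 6L, child = 9L, left = 0, right = 50))
  nd <- rbind(nd[, 1:3], data.frame(id = 9L, time = 1.5, is_sample = FALSE))
  argS <- withSampleLocations(
    spatialARG(nd, ed, data.frame(node_id = 0:3, x = 0), 100),
    matrix(c(-0.5, 0, 0.5, 1), 4))
  stmS <- sharedTimes(argS, minimalPaths(argS))
  muHatS <- mleRootLocations(stmS, sampleLocations(argS))
  jg <- conditionOnLoops(buildJoint(argS, mu = muHatS[, 1], sigma2 = 1))
  o <- conditionalAncestor(jg, 9L, sampleLocations(argS))
  expect_equal(l@mean, o$mean, tolerance = 1e-8)

  # errors: above the root, or off the sequence
  expect_error(locateAncestor(arg, 2L, 10, time = 99, fit = fit), "above the root")
  expect_error(locateAncestor(arg, 2L, 1e4, time = 1, fit = fit), "outside")
  expect_error(locateAncestor(arg, 7L, 10, time = 1, fit = fit), "not a sample")
})

test_that("confidence regions are central Gaussian intervals/ellipses", {
  arg <- withSampleLocations(oneLoopArg(), matrix(c(-1, 0, 2), 3))
  fit <- fitArg(arg)
  al <- locateNode(arg, 5L, fit, sigma2 = matrix(1, 1, 1))
  ci <- confidenceRegion(al, 0.95)
  expect_equal(unname(ci["upper"] - al@mean), 1.959964 * sqrt(al@V),
               tolerance = 1e-5)
  expect_error(confidenceRegion(al, 1.2))

  # V = 0 degenerates to a point
  s <- locateNode(arg, 0L, fit)
  ci0 <- confidenceRegion(s, 0.95)
  expect_equal(unname(ci0["lower"]), unname(ci0["upper"]), tolerance = 1e-6)

  # 2D: ellipse radius is the chi-square quantile scale
  sim <- randomSpatialArg(3, ns = 4, recs = 1, dims = 2)
  fit2 <- fitArg(sim$arg)
  a <- setdiff(nodeTable(sim$arg)$id,
               c(sampleIds(sim$arg), rootIds(sim$arg)))[1]
  al2 <- locateNode(sim$arg, a, fit2)
  e <- confidenceRegion(al2, 0.9)
  expect_equal(e$radius, sqrt(qchisq(0.9, 2)), tolerance = 1e-12)
  expect_length(e$lengths, 2L)
})
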