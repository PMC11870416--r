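#' @include simulate-model.R
NULL

## Intersect a segment matrix [l, r) with a set of disjoint intervals.
.intersectSegs <- function(s, ivs) {
  if (!nrow(s) || !nrow(ivs)) return(matrix(numeric(), 0, 2))
  out <- NULL
  for (i in seq_len(nrow(ivs))) {
    l <- pmax(s[, 1], ivs[i, 1])
    r <- pmin(s[, 2], ivs[i, 2])
    ok <- l < r
    if (any(ok)) out <- rbind(out, cbind(l[ok], r[ok]))
  }
  if (is.null(out)) matrix(numeric(), 0, 2) else out[order(out[, 1]), , drop = FALSE]
}

## Mosaic of a gamete: breakpoints bp and the parent genome providing
## position 0; returns the intervals inherited from parent `which` (1 or 2).
.mosaicIntervals <- function(bp, start, which, L) {
  cuts <- c(0, bp, L)
  sides <- rep(c(start, 3L - start), length.out = length(cuts) - 1L)
  keep <- sides == which
  cbind(cuts[-length(cuts)][keep], cuts[-1][keep])
}

.reflect <- function(x, lo, hi) {
  while (any(bad <- x < lo | x > hi)) {
    x[bad & x < lo] <- 2 * lo - x[bad & x < lo]
    bad2 <- x > hi
    x[bad2] <- 2 * hi - x[bad2]
  }
  x
}

#' Individual-based two-dimensional spatial simulation with ARG recording
#'
#' Discrete non-overlapping generations of hermaphroditic diploids in a finite
#' rectangular habitat.  Each individual acts once as a mother, choosing a
#' mate (selfing disallowed) with Gaussian kernel weights (variance
#' \code{sigmaM2}) among neighbours within 3 mating-kernel standard
#' deviations; with no mate in range it leaves no offspring.  The number of
#' offspring per mating is Poisson with mean \eqn{2 / (1 + C)}, where \eqn{C}
#' sums Gaussian competition strengths (variance \code{sigmaC2}, radius 3 sd)
#' over neighbours.  Offspring are displaced from the mother by independent
#' per-dimension Gaussian offsets (variance \code{sigmaD2}), reflected off the
#' habitat boundary until inside.  Gametes recombine with Poisson crossovers
#' at \code{recombRate} per bp per generation.
#'
#' The effective dispersal rate (average of maternal and paternal variances,
#' ignoring reflections) is \code{sigmaD2 + sigmaM2 / 2}; the realized rate,
#' which the reflecting boundary can only reduce, is measured from the
#' recorded ARG by [realizedDispersal()].
#'
#' At the end, \code{nSamples} individuals (two haploid sample genomes each,
#' sharing one coordinate) are drawn and their ARG extracted backward through
#' the recorded pedigree and crossover mosaics, retaining coalescent and
#' recombination nodes of the sample lineages and dropping pass-through
#' chains; lineages alive at the start of the simulation are capped by root
#' nodes there.
#'
#' @param n0 founding population size.
#' @param area habitat width and height, spatial units.
#' @param sigmaD2,sigmaM2,sigmaC2 dispersal, mating and competition kernel
#'   variances.
#' @param generations number of generations to run.
#' @param sequenceLength genome length in base pairs.
#' @param recombRate crossover rate per bp per generation.
#' @param nSamples individuals sampled at the end.
#' @param seed integer seed (optional); seeded runs are reproducible.
#' @return list with elements \code{arg} (a [SpatialARG-class]),
#'   \code{trueLocations} (matrix, all ARG nodes x 2, rownames node ids),
#'   \code{realizedDispersal} (per-dimension rate), \code{effectiveDispersal}
#'   and \code{populationSize} (per-generation trajectory).
#' @export
simulateIbd <- function(n0 = 400, area = c(25, 25), sigmaD2 = 0.25,
                        sigmaM2 = 0.25, sigmaC2 = 0.25, generations = 300,
                        sequenceLength = 1e5, recombRate = 1e-7,
                        nSamples = 50, seed = NULL) {
  stopifnot(sigmaD2 > 0, sigmaM2 > 0, sigmaC2 > 0, n0 >= 2, generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- sequenceLength
  rm3 <- 3 * sqrt(sigmaM2)
  rc3 <- 3 * sqrt(sigmaC2)

  gParent1 <- gParent2 <- integer(0)   # parent genome ids (NA for founders)
  gStart <- integer(0)                 # which parent genome at position 0
  gBp <- list()                        # crossover breakpoints
  gGen <- integer(0)
  gLoc <- matrix(numeric(), 0, 2)
  genomesByGen <- vector("list", generations + 1L)

  addGenomes <- function(p1, p2, start, bp, gen, loc) {
    n <- length(p1)
    ids <- length(gParent1) + seq_len(n)
    gParent1 <<- c(gParent1, p1)
    gParent2 <<- c(gParent2, p2)
    gStart <<- c(gStart, start)
    gBp <<- c(gBp, bp)
    gGen <<- c(gGen, rep(gen, n))
    gLoc <<- rbind(gLoc, loc)
    ids
  }

  x <- stats::runif(n0, 0, area[1])
  y <- stats::runif(n0, 0, area[2])
  ids1 <- addGenomes(rep(NA_integer_, n0), rep(NA_integer_, n0),
                     rep(1L, n0), rep(list(numeric()), n0), 0L, cbind(x, y))
  ids2 <- addGenomes(rep(NA_integer_, n0), rep(NA_integer_, n0),
                     rep(1L, n0), rep(list(numeric()), n0), 0L, cbind(x, y))
  genomesByGen[[1]] <- c(ids1, ids2)
  indGenomes <- cbind(ids1, ids2)
  popSize <- integer(generations + 1L)
  popSize[1] <- n0

  gamete <- function(ind) {
    ncx <- stats::rpois(1, recombRate * L)
    bp <- if (ncx) sort(stats::runif(ncx, 0, L)) else numeric()
    list(p1 = indGenomes[ind, 1], p2 = indGenomes[ind, 2],
         start = sample.int(2L, 1), bp = bp)
  }

  for (g in seq_len(generations)) {
    n <- length(x)
    D <- as.matrix(stats::dist(cbind(x, y)))
    diag(D) <- Inf
    mateW <- exp(-D^2 / (2 * sigmaM2)) * (D <= rm3)
    compS <- rowSums(exp(-D^2 / (2 * sigmaC2)) * (D <= rc3))
    lambda <- 2 / (1 + compS)
    offMother <- offFather <- integer(0)
    for (i in seq_len(n)) {
      w <- mateW[i, ]
      if (!any(w > 0)) next
      k <- stats::rpois(1, lambda[i])
      if (!k) next
      f <- sample.int(n, k, replace = TRUE, prob = w)
      offMother <- c(offMother, rep(i, k))
      offFather <- c(offFather, f)
    }
    m <- length(offMother)
    if (!m) stop("population went extinct at generation ", g)
    ox <- .reflect(x[offMother] + stats::rnorm(m, 0, sqrt(sigmaD2)), 0, area[1])
    oy <- .reflect(y[offMother] + stats::rnorm(m, 0, sqrt(sigmaD2)), 0, area[2])
    gm <- lapply(offMother, gamete)
    gf <- lapply(offFather, gamete)
    loc <- cbind(ox, oy)
    mids <- addGenomes(vapply(gm, `[[`, 0L, "p1"), vapply(gm, `[[`, 0L, "p2"),
                       vapply(gm, `[[`, 0L, "start"), lapply(gm, `[[`, "bp"),
                       g, loc)
    fids <- addGenomes(vapply(gf, `[[`, 0L, "p1"), vapply(gf, `[[`, 0L, "p2"),
                       vapply(gf, `[[`, 0L, "start"), lapply(gf, `[[`, "bp"),
                       g, loc)
    genomesByGen[[g + 1L]] <- c(mids, fids)
    indGenomes <- cbind(mids, fids)
    x <- ox; y <- oy
    popSize[g + 1L] <- m
  }

  ## ---- backward ARG extraction over the recorded pedigree ----
  n <- length(x)
  pick <- sample.int(n, min(nSamples, n))
  sampleGenomes <- as.integer(t(indGenomes[pick, , drop = FALSE]))

  nodeId <- integer(0); nodeTime <- numeric(0); nodeSample <- logical(0)
  nodeLoc <- matrix(numeric(), 0, 2)
  nodeOf <- integer(length(gParent1))  # 0 = no ARG node for this genome yet
  nextNode <- 0L
  newNode <- function(gid, isSample) {
    v <- nextNode; nextNode <<- nextNode + 1L
    nodeId <<- c(nodeId, v)
    nodeTime <<- c(nodeTime, generations - gGen[gid])
    nodeSample <<- c(nodeSample, isSample)
    nodeLoc <<- rbind(nodeLoc, gLoc[gid, ])
    nodeOf[gid] <<- v + 1L
    v
  }
  eParent <- eChild <- integer(0); eLeft <- eRight <- numeric(0)
  addEdges <- function(parent, child, segs) {
    eParent <<- c(eParent, rep(parent, nrow(segs)))
    eChild <<- c(eChild, rep(child, nrow(segs)))
    eLeft <<- c(eLeft, segs[, 1])
    eRight <<- c(eRight, segs[, 2])
  }

  active <- new.env(parent = emptyenv())  # gid -> list of list(segs, node)
  push <- function(gid, segs, node) {
    k <- as.character(gid)
    cur <- if (exists(k, active)) get(k, active) else list()
    assign(k, c(cur, list(list(segs = segs, node = node))), active)
  }
  for (s in sampleGenomes) {
    v <- newNode(s, TRUE)
    push(s, matrix(c(0, L), 1), v)
  }

  for (g in rev(seq_len(generations + 1L)) - 1L) {  # generations .. 0
    gids <- genomesByGen[[g + 1L]]
    gids <- gids[vapply(as.character(gids), exists, logical(1), envir = active)]
    for (gid in gids) {
      k <- as.character(gid)
      entries <- get(k, active)
      rm(list = k, envir = active)
      if (length(entries) > 1L) {
        ## entries that descend from the same ARG node are one lineage whose
        ## material momentarily split and rejoined: merge without a node (the
        ## loop is invisible in a simplified ARG)
        byNode <- split(entries, vapply(entries, `[[`, 0L, "node"))
        entries <- lapply(byNode, function(es) {
          segs <- es[[1]]$segs
          for (e2 in es[-1]) segs <- .mergeSegs(segs, e2$segs)
          list(segs = segs, node = es[[1]]$node)
        })
        names(entries) <- NULL
      }
      if (length(entries) > 1L) {
        ## several sample lineages meet in this genome: coalescent node
        v <- if (nodeOf[gid]) nodeOf[gid] - 1L else newNode(gid, FALSE)
        segs <- NULL
        for (e in entries) {
          if (e$node != v) addEdges(v, e$node, e$segs)
          segs <- if (is.null(segs)) e$segs else .mergeSegs(segs, e$segs)
        }
        entries <- list(list(segs = segs, node = v))
      }
      e <- entries[[1]]
      if (g == 0L) {
        ## founder: cap the lineage with a root node here
        if (!nodeOf[gid]) {
          v <- newNode(gid, FALSE)
          addEdges(v, e$node, e$segs)
        }
        next
      }
      ivA <- .mosaicIntervals(gBp[[gid]], gStart[gid], 1L, L)
      ivB <- .mosaicIntervals(gBp[[gid]], gStart[gid], 2L, L)
      sA <- .intersectSegs(e$segs, ivA)
      sB <- .intersectSegs(e$segs, ivB)
      if (nrow(sA) && nrow(sB)) {
        ## ancestral material splits between the two parent genomes:
        ## this genome is a recombination node
        v <- if (nodeOf[gid]) nodeOf[gid] - 1L else newNode(gid, FALSE)
        if (e$node != v) addEdges(v, e$node, e$segs)
        push(gParent1[gid], sA, v)
        push(gParent2[gid], sB, v)
      } else if (nrow(sA)) {
        push(gParent1[gid], e$segs, e$node)
      } else {
        push(gParent2[gid], e$segs, e$node)
      }
    }
  }

  nodes <- data.frame(id = nodeId, time = nodeTime, is_sample = nodeSample)
  edges <- data.frame(parent = eParent, child = eChild,
                      left = eLeft, right = eRight)
  loc <- nodeLoc[nodeSample, , drop = FALSE]
  rownames(loc) <- as.character(nodeId[nodeSample])
  arg <- spatialARG(nodes, edges, loc, sequenceLength)
  rownames(nodeLoc) <- as.character(nodeId)
  rd <- realizedDispersal(arg, nodeLoc)
  list(arg = arg, trueLocations = nodeLoc, realizedDispersal = rd,
       effectiveDispersal = sigmaD2 + sigmaM2 / 2, populationSize = popSize)
}

#' Realized dispersal rate from an ARG with known node locations
#'
#' Average squared parent-child displacement per unit time over all edges
#' (unique parent-child pairs), per dimension.  With reflecting habitat
#' boundaries this is at most the effective dispersal rate.
#'
#' @param arg a [SpatialARG-class].
#' @param nodeLocations matrix of true node coordinates, rownames node ids.
#' @return numeric vector, one rate per dimension.
#' @export
realizedDispersal <- function(arg, nodeLocations) {
  links <- .argLinks(arg)
  if (!nrow(links)) return(rep(NA_real_, ncol(nodeLocations)))
  dp <- nodeLocations[as.character(links$parent), , drop = FALSE] -
        nodeLocations[as.character(links$child), , drop = FALSE]
  colMeans(dp^2 / links$length)
}
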