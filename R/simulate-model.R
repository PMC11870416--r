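#' @include oracle.R
NULL

.mergeSegs <- function(a, b) {
  s <- rbind(a, b)
  s <- s[order(s[, 1]), , drop = FALSE]
  out <- s[1, , drop = FALSE]
  for (i in seq_len(nrow(s))[-1]) {
    if (s[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], s[i, 2])
    } else {
      out <- rbind(out, s[i, , drop = FALSE])
    }
  }
  out
}

.splitSegs <- function(s, b) {
  left <- s[s[, 1] < b, , drop = FALSE]
  left[, 2] <- pmin(left[, 2], b)
  right <- s[s[, 2] > b, , drop = FALSE]
  right[, 1] <- pmax(right[, 1], b)
  list(left = left, right = right)
}

#' Simulate a random ARG topology from a coalescent with recombination
#'
#' Event-driven backward simulation: lineages carrying genome segments
#' coalesce at rate \code{1/(2 Ne)} per pair and recombine at a rate a fixed
#' multiple of the coalescence rate, calibrated so the expected number of
#' recombination events equals \code{targetRecombinations} exactly (the event
#' counts satisfy #coalescences = ns - rootCount + #recombinations, so fixing
#' the per-event recombination probability pins the expectation).  A
#' recombination event
#' splits a lineage at a uniform breakpoint within its ancestral span,
#' creating two parent nodes at the event time; the lineage's head node thus
#' acquires two parents and becomes a recombination node.  The process stops
#' when \code{rootCount} lineages remain, whose heads become the roots.
#'
#' Sample locations are initialised to zero; attach coordinates with
#' [withSampleLocations()] (e.g. from [simulateLocations()]).
#'
#' @param ns number of samples (>= 1).
#' @param targetRecombinations expected number of recombination events.
#' @param rootCount stop when this many lineages remain (1 = run to the
#'   GMRCA).
#' @param seed integer seed (optional).
#' @param sequenceLength genome length in base pairs.
#' @param Ne effective size setting the coalescent timescale (generations).
#' @param dims dimensionality of the (placeholder) sample locations.
#' @return a [SpatialARG-class] topology.
#' @export
simulateModelArg <- function(ns, targetRecombinations = 0, rootCount = 1,
                             seed = NULL, sequenceLength = 1e4, Ne = 100,
                             dims = 1) {
  stopifnot(ns >= 1, rootCount >= 1, targetRecombinations >= 0)
  if (!is.null(seed)) set.seed(seed)
  ## Recombination competes with coalescence at fixed odds c, so each event is
  ## a recombination with probability c/(1+c).  Running until `rootCount`
  ## lineages remain forces #coalescences = ns - rootCount + #recombinations,
  ## hence E[#recombinations] = target exactly when
  ## c = target / (ns - rootCount + target).
  cc <- if (targetRecombinations > 0 && ns > rootCount) {
    targetRecombinations / (ns - rootCount + targetRecombinations)
  } else 0
  nodes <- data.frame(id = seq_len(ns) - 1L, time = 0,
                      is_sample = TRUE)
  edges <- data.frame(parent = integer(), child = integer(),
                      left = numeric(), right = numeric())
  lineages <- lapply(seq_len(ns) - 1L, function(i) {
    list(head = i, segs = matrix(c(0, sequenceLength), 1))
  })
  t <- 0
  nextId <- ns
  while (length(lineages) > rootCount) {
    k <- length(lineages)
    crate <- k * (k - 1) / (4 * Ne)
    rrate <- cc * crate
    t <- t + stats::rexp(1, crate + rrate)
    if (stats::runif(1) < crate / (crate + rrate)) {
      ij <- sample.int(k, 2)
      a <- lineages[[ij[1]]]; b <- lineages[[ij[2]]]
      v <- nextId; nextId <- nextId + 1L
      nodes <- rbind(nodes, data.frame(id = v, time = t, is_sample = FALSE))
      edges <- rbind(edges,
        data.frame(parent = v, child = a$head,
                   left = a$segs[, 1], right = a$segs[, 2]),
        data.frame(parent = v, child = b$head,
                   left = b$segs[, 1], right = b$segs[, 2]))
      lineages[[ij[1]]] <- list(head = v, segs = .mergeSegs(a$segs, b$segs))
      lineages[[ij[2]]] <- NULL
    } else {
      li <- sample.int(k, 1)
      l <- lineages[[li]]
      b <- stats::runif(1, min(l$segs[, 1]), max(l$segs[, 2]))
      sp <- .splitSegs(l$segs, b)
      p1 <- nextId; p2 <- nextId + 1L; nextId <- nextId + 2L
      nodes <- rbind(nodes,
        data.frame(id = c(p1, p2), time = t, is_sample = FALSE))
      edges <- rbind(edges,
        data.frame(parent = p1, child = l$head,
                   left = sp$left[, 1], right = sp$left[, 2]),
        data.frame(parent = p2, child = l$head,
                   left = sp$right[, 1], right = sp$right[, 2]))
      lineages[[li]] <- list(head = p1, segs = sp$left)
      lineages[[length(lineages) + 1L]] <- list(head = p2, segs = sp$right)
    }
  }
  loc <- matrix(0, ns, dims, dimnames = list(seq_len(ns) - 1L, NULL))
  spatialARG(nodes, edges, loc, sequenceLength)
}

#' Draw node locations from the spatial model on an ARG
#'
#' \code{variant = "meeting"} draws the full node-location vector exactly from
#' the joint Gaussian in which parental lineages meet at recombination nodes
#' (loops behave as Brownian bridges), via dense linear-Gaussian conditioning.
#' \code{variant = "midpoint"} runs the forward pass of the alternate model,
#' placing each recombination node at the unweighted average of its two
#' parents' proposed positions.  Root locations are fixed at \code{mu}.
#'
#' @param arg a validated, chopped [SpatialARG-class].
#' @param mu root locations: matrix (roots x d, sorted root ids), a vector of
#'   length d (shared by all roots), or a scalar.
#' @param sigma2 dispersal rate: scalar or d x d matrix.
#' @param variant "meeting" or "midpoint".
#' @param seed integer seed (optional).
#' @param dims number of coordinate dimensions (default: inferred from
#'   \code{mu}, else 1).
#' @return numeric matrix (all nodes x d), rownames node ids.  Use
#'   [withSampleLocations()] to attach the sample rows to the ARG.
#' @export
simulateLocations <- function(arg, mu, sigma2, variant = c("meeting", "midpoint"),
                              seed = NULL, dims = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  rts <- rootIds(arg)
  nr <- length(rts)
  if (is.null(dims)) dims <- if (is.matrix(mu)) ncol(mu) else 1L
  if (!is.matrix(mu)) {
    mu <- matrix(rep(mu, length.out = nr * dims), nr, dims,
                 byrow = length(mu) == dims)
  }
  stopifnot(nrow(mu) == nr, ncol(mu) == dims)
  Sigma <- .asSigma(sigma2, dims)
  B <- chol(Sigma + diag(1e-300, dims))
  ids <- arg@nodes$id
  if (variant == "meeting") {
    jgs <- lapply(seq_len(dims), function(d) {
      conditionOnLoops(buildJoint(arg, mu = mu[, d], sigma2 = 1,
                                  maxCopies = Inf))
    })
    can <- which(jgs[[1]]@copies$side == 1L)
    M <- vapply(jgs, function(j) j@mean[can], numeric(length(can)))
    C <- jgs[[1]]@cov[can, can, drop = FALSE]
    eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
    A <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
    Z <- matrix(stats::rnorm(length(can) * dims), length(can), dims)
    out <- M + A %*% Z %*% B
    rownames(out) <- as.character(jgs[[1]]@copies$node[can])
    return(out[as.character(ids), , drop = FALSE])
  }
  ## midpoint: forward pass, one independent displacement per link
  links <- .argLinks(arg)
  pm <- .parentMap(arg)
  li <- .linkIndex(links)
  eps <- matrix(stats::rnorm(nrow(links) * dims), max(nrow(links), 1), dims) %*% B
  eps <- eps * sqrt(links$length)
  out <- matrix(NA_real_, length(ids), dims,
                dimnames = list(as.character(ids), NULL))
  for (v in ids[order(-arg@nodes$time, ids)]) {
    k <- as.character(v)
    ps <- pm[[k]]
    if (!length(ps)) {
      out[k, ] <- mu[match(v, rts), ]
    } else {
      acc <- numeric(dims)
      for (p in ps) {
        acc <- acc + out[as.character(p), ] + eps[li[[paste(p, v)]], ]
      }
      out[k, ] <- acc / length(ps)
    }
  }
  out
}
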