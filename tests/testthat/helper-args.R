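# Fixture graphs built in code.  Node letters follow the usual toy-ARG
# conventions: samples at the bottom, a recombination node E with its loop
# closing at G.

# Plain two-sample tree: root 2 at time `T`, samples 0, 1 at +-1.
twoTipTree <- function(T = 10, locs = c(-1, 1)) {
  spatialARG(
    nodes = data.frame(id = 0:2, time = c(0, 0, T),
                       is_sample = c(TRUE, TRUE, FALSE)),
    edges = data.frame(parent = 2L, child = 0:1, left = 0, right = 100),
    locations = data.frame(node_id = 0:1, x = locs)
  )
}

# One-loop ARG with three samples: A(0), B(1) coalesce at D(3), pass the
# recombination node E(4) whose parents F(5) and G(6) rejoin at G; C(2)
# attaches at the root G.  Genome splits at `b`.
oneLoopArg <- function(b = 50, L = 100,
                      locs = c(A = -1, B = 0, C = 2)) {
  nodes <- data.frame(
    id = 0:6,
    time = c(0, 0, 0, 1, 2, 3, 4),
    is_sample = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  edges <- data.frame(
    parent = c(3L, 3L, 4L, 5L, 6L, 6L, 6L),
    child  = c(0L, 1L, 3L, 4L, 4L, 5L, 2L),
    left   = c(0, 0, 0, 0, b, 0, 0),
    right  = c(L, L, L, b, L, L, L)
  )
  spatialARG(nodes, edges, data.frame(node_id = 0:2, x = unname(locs)), L)
}

# Symmetric single-loop ARG: recombination node E(2) at time 1 with parents
# F(3) (left genome half) and G(4) (right half and loop top/root); both loop
# sides have total time t = 1.  Sample A(0) below E, sample C(1) below F.
symmetricLoopArg <- function(tE = 1, tF = 1.5, tG = 2, b = 50, L = 100,
                       locs = c(A = 0, C = 1)) {
  nodes <- data.frame(
    id = 0:4,
    time = c(0, 0, tE, tF, tG),
    is_sample = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  edges <- data.frame(
    parent = c(2L, 3L, 3L, 4L, 4L),
    child  = c(0L, 1L, 2L, 2L, 3L),
    left   = c(0, 0, 0, b, 0),
    right  = c(L, L, b, L, L)
  )
  spatialARG(nodes, edges, data.frame(node_id = 0:1, x = unname(locs)), L)
}

# Two-tree toy ARG with four samples for ancestor-location comparisons:
# samples A(0), B(1), C(2), D(3) at -0.5, 0, 0.5, 1.  A,B coalesce at H(4);
# H joins the recombination node E(5)'s left parent F(6); the loop closes at
# G(7); D attaches at the root R(8).
twoTreeArg <- function(tE = 1, tF = 2, tG = 3, tH = 1.5, tR = 4,
                      b = 50, L = 100) {
  nodes <- data.frame(
    id = 0:8,
    time = c(0, 0, 0, 0, tH, tE, tF, tG, tR),
    is_sample = c(rep(TRUE, 4), rep(FALSE, 5))
  )
  edges <- data.frame(
    parent = c(4L, 4L, 5L, 6L, 6L, 7L, 7L, 8L, 8L),
    child  = c(0L, 1L, 2L, 4L, 5L, 6L, 5L, 7L, 3L),
    left   = c(0, 0, 0, 0, 0, 0, b, 0, 0),
    right  = c(L, L, L, L, b, L, L, L, L)
  )
  spatialARG(nodes, edges,
             data.frame(node_id = 0:3, x = c(-0.5, 0, 0.5, 1)), L)
}

# Independent brute-force shared time between two node-id paths: sum the
# lengths of parent-child pairs present in both, computed from node times.
bruteSharedTime <- function(arg, pathA, pathB) {
  nd <- nodeTable(arg)
  pairs <- function(p) {
    if (length(p) < 2) return(character())
    paste(p[-1], p[-length(p)])
  }
  shared <- intersect(pairs(pathA), pairs(pathB))
  if (!length(shared)) return(0)
  sum(vapply(strsplit(shared, " "), function(pc) {
    diff(-nd$time[match(as.integer(pc), nd$id)])
  }, numeric(1)))
}

# Random model ARG with locations attached, for property sweeps.
randomSpatialArg <- function(seed, ns = NULL, recs = NULL, dims = 1,
                             sigma2 = 1, mu = 0) {
  set.seed(seed)
  if (is.null(ns)) ns <- sample(3:8, 1)
  if (is.null(recs)) recs <- sample(0:4, 1)
  arg <- simulateModelArg(ns = ns, targetRecombinations = recs,
                          seed = seed + 1000L, dims = dims)
  loc <- simulateLocations(arg, mu = mu, sigma2 = sigma2, seed = seed + 2000L,
                           dims = dims)
  list(arg = withSampleLocations(arg, loc), locations = loc)
}
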