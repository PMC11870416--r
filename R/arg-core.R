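#' @include AllClasses.R AllGenerics.R utils.R
NULL

## Structural role assignment.  Recombination detection is structural (two
## distinct parent nodes), so simplified ARGs lacking explicit flags work too.
.assignRoles <- function(nodes, edges) {
  ids <- nodes$id
  npar <- nchild <- integer(length(ids))
  if (nrow(edges)) {
    pm <- split(edges$parent, factor(edges$child, levels = ids))
    cm <- split(edges$child, factor(edges$parent, levels = ids))
    npar <- vapply(pm, function(p) length(unique(p)), integer(1))
    nchild <- vapply(cm, function(p) length(unique(p)), integer(1))
  }
  role <- rep("common-ancestor", length(ids))
  role[nchild >= 2] <- "coalescent"
  role[npar == 2] <- "recombination"
  role[npar == 0] <- "root"
  role[nodes$is_sample] <- "sample"
  role
}

#' Construct a spatial ARG from node, edge and location tables
#'
#' @param nodes data.frame with columns \code{id}, \code{time} and optionally
#'   \code{is_sample} (0/1 or logical).  When \code{is_sample} is absent the
#'   samples are taken to be the nodes present in \code{locations}.
#' @param edges data.frame with columns \code{parent}, \code{child},
#'   \code{left}, \code{right}.  May have zero rows (a single isolated node).
#' @param locations matrix or data.frame of sample coordinates; either has a
#'   \code{node_id} column / rownames naming sample nodes, or one row per
#'   sample in \code{nodes} order.
#' @param sequenceLength genome length in base pairs; defaults to the largest
#'   edge \code{right} coordinate.
#' @return a validated [SpatialARG-class] with roles assigned.
#' @examples
#' nodes <- data.frame(id = 0:2, time = c(0, 0, 10), is_sample = c(TRUE, TRUE, FALSE))
#' edges <- data.frame(parent = 2L, child = 0:1, left = 0, right = 100)
#' arg <- spatialARG(nodes, edges, data.frame(node_id = 0:1, x = c(-1, 1)))
#' @export
spatialARG <- function(nodes, edges, locations, sequenceLength = NULL) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  nodes$id <- as.integer(nodes$id)
  nodes$time <- as.numeric(nodes$time)
  if (nrow(edges)) {
    edges$parent <- as.integer(edges$parent)
    edges$child <- as.integer(edges$child)
    edges$left <- as.numeric(edges$left)
    edges$right <- as.numeric(edges$right)
  } else {
    edges <- data.frame(parent = integer(), child = integer(),
                        left = numeric(), right = numeric())
  }
  if (is.null(nodes$is_sample)) {
    locs <- locations
    if (is.data.frame(locs) && "node_id" %in% names(locs)) {
      sids <- as.integer(locs$node_id)
    } else if (!is.null(rownames(locs))) {
      sids <- as.integer(rownames(locs))
    } else {
      stop("cannot infer samples: provide nodes$is_sample or name the location rows")
    }
    nodes$is_sample <- nodes$id %in% sids
  }
  nodes$is_sample <- as.logical(nodes$is_sample)
  sampleIds <- nodes$id[nodes$is_sample]
  loc <- .asLocations(locations, sampleIds)
  if (is.null(sequenceLength)) {
    sequenceLength <- if (nrow(edges)) max(edges$right) else 1
  }
  nodes$role <- .assignRoles(nodes, edges)
  nodes <- nodes[order(nodes$time, nodes$id), c("id", "time", "is_sample", "role")]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  rownames(loc) <- as.character(sampleIds)
  new("SpatialARG", nodes = nodes, edges = edges,
      sampleIds = as.integer(sampleIds), locations = loc,
      sequenceLength = as.numeric(sequenceLength))
}

#' Replace the sample locations of an ARG
#'
#' @param arg a [SpatialARG-class].
#' @param locations matrix of coordinates; rownames (or a \code{node_id}
#'   column) may name node ids, in which case any superset of the samples is
#'   accepted (e.g. the all-node output of [simulateLocations()]).
#' @return the ARG with its sample coordinates replaced.
#' @export
withSampleLocations <- function(arg, locations) {
  loc <- .asLocations(locations, arg@sampleIds)
  rownames(loc) <- as.character(arg@sampleIds)
  arg@locations <- loc
  validObject(arg)
  arg
}

#' Chop an ARG at a past time
#'
#' Truncates every edge spanning \code{cutoff} at exactly that time, creating
#' a fresh root node per truncated lineage, and drops all structure strictly
#' older than the cutoff.  Restricting attention to the recent past avoids
#' relying on Brownian motion over timescales where lineages are well mixed or
#' poorly resolved.
#'
#' New root ids are assigned above all existing ids, in ascending order of the
#' (child, parent) pair they cap, so output is deterministic.  Chopping is
#' idempotent: chopping an already chopped graph at the same time returns an
#' identical graph.
#'
#' @param arg a [SpatialARG-class].
#' @param cutoff time in generations before present (> 0).
#' @return a chopped [SpatialARG-class] with one or more roots at or below
#'   \code{cutoff}.  If the cutoff is older than the oldest node the graph is
#'   returned unchanged with a message.
#' @export
chopArg <- function(arg, cutoff) {
  stopifnot(is(arg, "SpatialARG"), cutoff > 0)
  nd <- arg@nodes
  ed <- arg@edges
  if (cutoff >= max(nd$time)) {
    message("cutoff ", cutoff, " is older than the oldest node (",
            max(nd$time), "); ARG unchanged")
    return(arg)
  }
  tm <- nd$time[match(ed$parent, nd$id)]
  tc <- nd$time[match(ed$child, nd$id)]
  keep <- tm <= cutoff
  span <- tm > cutoff & tc < cutoff
  nd2 <- nd[nd$time <= cutoff, , drop = FALSE]
  ed2 <- ed[keep, , drop = FALSE]
  if (any(span)) {
    sp <- ed[span, , drop = FALSE]
    key <- paste(sp$child, sp$parent)
    uk <- unique(key[order(sp$child, sp$parent)])
    newid <- max(nd$id) + seq_along(uk)
    names(newid) <- uk
    sp$parent <- as.integer(newid[key])
    nd2 <- rbind(nd2, data.frame(id = as.integer(newid), time = cutoff,
                                 is_sample = FALSE, role = "root"))
    ed2 <- rbind(ed2, sp)
  }
  spatialARG(nd2[, c("id", "time", "is_sample")], ed2, arg@locations,
             arg@sequenceLength)
}

#' Find the loops of an ARG
#'
#' Each recombination node whose two parental lineages coalesce below the root
#' set closes a loop; the meeting model constrains the summed displacements
#' around the two sides of the loop to be equal.  Recombination nodes whose
#' parental lineages reach distinct roots leave the loop open and yield no
#' constraint; their ids are attached as \code{attr(, "openLoops")}.
#'
#' @param arg a validated [SpatialARG-class].
#' @return list of [LoopConstraint-class], one per closed loop.
#' @export
findLoops <- function(arg) {
  pm <- .parentMap(arg)
  recs <- recombinationNodes(arg)
  anc <- function(start) {
    seen <- integer(0)
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      queue <- c(queue, pm[[as.character(v)]])
    }
    seen
  }
  bfsPath <- function(from, to) {
    # shortest (in hops) upward path from `from` to `to`
    prev <- list(); prev[[as.character(from)]] <- NA_integer_
    queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == to) break
      for (p in pm[[as.character(v)]]) {
        if (is.null(prev[[as.character(p)]])) {
          prev[[as.character(p)]] <- v
          queue <- c(queue, p)
        }
      }
    }
    path <- to
    while (!is.na(prev[[as.character(path[1])]])) {
      path <- c(prev[[as.character(path[1])]], path)
    }
    rev(path)  # to (top) first, from last
  }
  out <- list()
  open <- integer(0)
  for (r in recs) {
    ps <- pm[[as.character(r)]]
    if (length(ps) != 2L) next
    common <- intersect(anc(ps[1]), anc(ps[2]))
    if (!length(common)) {
      open <- c(open, r)
      next
    }
    ct <- .nodeTime(arg, common)
    top <- common[order(ct, common)][1]
    out[[length(out) + 1L]] <- new("LoopConstraint",
      recombinationNode = as.integer(r), topNode = as.integer(top),
      leftPath = as.integer(c(bfsPath(ps[1], top), r)),
      rightPath = as.integer(c(bfsPath(ps[2], top), r)))
  }
  attr(out, "openLoops") <- open
  out
}

#' Genome breakpoints and marginal trees
#'
#' \code{treeBreakpoints} returns the sorted genome positions at which the
#' local tree changes; tree \code{k} spans \code{[bp[k], bp[k+1])}.
#' \code{treeIndexAt} maps a genome position to its tree index.
#'
#' @param arg a [SpatialARG-class].
#' @return numeric vector of breakpoints, starting at 0 and ending at the
#'   sequence length.
#' @export
treeBreakpoints <- function(arg) {
  ed <- arg@edges
  sort(unique(c(0, ed$left, ed$right, arg@sequenceLength)))
}

#' @rdname treeBreakpoints
#' @param position genome position in base pairs.
#' @export
treeIndexAt <- function(arg, position) {
  if (position < 0 || position >= arg@sequenceLength) {
    stop("position ", position, " outside the sequence [0, ",
         arg@sequenceLength, ")")
  }
  bp <- treeBreakpoints(arg)
  findInterval(position, bp, rightmost.closed = FALSE)
}

#' Restrict an ARG to a genomic window
#'
#' Keeps the edges whose genome interval intersects \code{[left, right)}
#' (clipped to the window), the nodes they touch, and all samples.
#'
#' @param arg a [SpatialARG-class].
#' @param left,right window bounds in base pairs.
#' @return a [SpatialARG-class]; roles are re-assigned on the restricted graph.
#' @export
extractWindow <- function(arg, left, right) {
  stopifnot(left < right)
  ed <- arg@edges
  keep <- ed$left < right & ed$right > left
  ed <- ed[keep, , drop = FALSE]
  ed$left <- pmax(ed$left, left)
  ed$right <- pmin(ed$right, right)
  ids <- union(arg@sampleIds, unique(c(ed$parent, ed$child)))
  nd <- arg@nodes[arg@nodes$id %in% ids, c("id", "time", "is_sample")]
  spatialARG(nd, ed, arg@locations, arg@sequenceLength)
}

#' @rdname extractWindow
#' @param position genome position whose local tree to extract.
#' @export
marginalTree <- function(arg, position) {
  bp <- treeBreakpoints(arg)
  k <- treeIndexAt(arg, position)
  extractWindow(arg, bp[k], bp[k + 1])
}

#' Remove pass-through nodes from an ARG
#'
#' Contracts nodes with exactly one distinct child and one distinct parent
#' (unary "common-ancestor" chains), splicing their edges together on the
#' intersected genome intervals.  Samples, roots, coalescent and recombination
#' nodes are always retained.
#'
#' @param arg a [SpatialARG-class].
#' @return a simplified [SpatialARG-class].
#' @export
simplifyArg <- function(arg) {
  repeat {
    pm <- .parentMap(arg)
    cm <- .childMap(arg)
    nd <- arg@nodes
    unary <- nd$id[!nd$is_sample &
                   vapply(pm[as.character(nd$id)], length, 1L) == 1L &
                   vapply(cm[as.character(nd$id)], length, 1L) == 1L]
    ## never contract a node whose removal would merge two distinct lineages
    ## into parallel edges between the same pair (it would erase a
    ## recombination loop, e.g. the unary node on the short side of a loop)
    unary <- Filter(function(u) {
      p <- pm[[as.character(u)]]
      ch <- cm[[as.character(u)]]
      !ch %in% cm[[as.character(p)]]
    }, unary)
    if (!length(unary)) break
    u <- unary[1]
    ed <- arg@edges
    up <- ed[ed$child == u, , drop = FALSE]    # u -> parent rows
    dn <- ed[ed$parent == u, , drop = FALSE]   # child -> u rows
    ed <- ed[ed$child != u & ed$parent != u, , drop = FALSE]
    for (i in seq_len(nrow(dn))) {
      l <- pmax(dn$left[i], up$left)
      r <- pmin(dn$right[i], up$right)
      ok <- l < r
      if (any(ok)) {
        ed <- rbind(ed, data.frame(parent = up$parent[ok], child = dn$child[i],
                                   left = l[ok], right = r[ok]))
      }
    }
    nd <- nd[nd$id != u, , drop = FALSE]
    arg <- spatialARG(nd[, c("id", "time", "is_sample")], ed, arg@locations,
                      arg@sequenceLength)
  }
  arg
}
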