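#' @import methods
NULL

#' Spatial ancestral recombination graph
#'
#' An ARG (node and edge tables with times and genome intervals) together with
#' the observed coordinates of its sample nodes.  Edges are directed from a
#' parent (older) node to a child (younger) node and carry the half-open genome
#' interval \code{[left, right)} they transmit, following tree-sequence
#' conventions.  Times are in generations before present (0 = present,
#' increasing into the past).
#'
#' @slot nodes data.frame with columns \code{id} (integer, unique),
#'   \code{time} (numeric, >= 0), \code{is_sample} (logical) and \code{role}
#'   (one of \code{"sample"}, \code{"root"}, \code{"recombination"},
#'   \code{"coalescent"}, \code{"common-ancestor"}).
#' @slot edges data.frame with columns \code{parent}, \code{child} (node ids)
#'   and \code{left}, \code{right} (genome interval in base pairs).
#' @slot sampleIds integer vector of sample node ids (fixed order; rows of
#'   \code{locations} follow it).
#' @slot locations numeric matrix, one row per sample, 1 or 2 columns.
#' @slot sequenceLength numeric(1), genome length in base pairs.
#'
#' @seealso [loadArg()], [chopArg()], [minimalPaths()], [fitArg()]
#' @export
setClass("SpatialARG",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    sampleIds = "integer",
    locations = "matrix",
    sequenceLength = "numeric"
  )
)

setValidity("SpatialARG", function(object) {
  msg <- character()
  nd <- object@nodes
  ed <- object@edges
  need <- c("id", "time", "is_sample", "role")
  if (!all(need %in% names(nd))) {
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(nd$id)) msg <- c(msg, "duplicated node ids")
  if (any(nd$time < 0)) msg <- c(msg, "negative node times")
  if (nrow(ed)) {
    if (!all(c("parent", "child", "left", "right") %in% names(ed))) {
      return("edges must have columns parent, child, left, right")
    }
    ip <- match(ed$parent, nd$id)
    ic <- match(ed$child, nd$id)
    if (anyNA(ip) || anyNA(ic)) {
      msg <- c(msg, "edge refers to unknown node id")
    } else if (any(nd$time[ip] <= nd$time[ic])) {
      msg <- c(msg, "every edge's parent must be strictly older than its child")
    }
    if (any(ed$left >= ed$right)) msg <- c(msg, "edge intervals must satisfy left < right")
    if (any(ed$right > object@sequenceLength + 1e-9)) {
      msg <- c(msg, "edge interval exceeds sequence length")
    }
    np <- table(factor(ed$parent, levels = nd$id))
    nparents <- vapply(split(ed$parent, factor(ed$child, levels = nd$id)),
                       function(p) length(unique(p)), integer(1))
    if (any(nparents > 2)) msg <- c(msg, "node with more than 2 parents")
  }
  if (length(object@sampleIds) != nrow(object@locations)) {
    msg <- c(msg, "one location row per sample is required")
  }
  if (!all(object@sampleIds %in% nd$id)) msg <- c(msg, "sample id not in node table")
  if (!ncol(object@locations) %in% c(1L, 2L)) {
    msg <- c(msg, "locations must have 1 or 2 columns")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Loop constraint induced by a recombination node
#'
#' The two parental lineages of a recombination node that coalesce below the
#' root set form a loop; under the meeting model the displacements around the
#' two sides must be equal.  Sides are stored as node-id sequences from the
#' loop's top node down to the recombination node.
#'
#' @slot recombinationNode integer node id.
#' @slot topNode integer node id where the two sides coalesce.
#' @slot leftPath,rightPath integer vectors of node ids (top to bottom).
#' @export
setClass("LoopConstraint",
  representation(
    recombinationNode = "integer",
    topNode = "integer",
    leftPath = "integer",
    rightPath = "integer"
  )
)

#' A set of sample-to-root paths through an ARG
#'
#' Paths run from a sample node up to a root node.  \code{P} and \code{R} are
#' the path-sample and path-root incidence matrices; each row of either has a
#' single 1.  \code{linkPaths} stores, per path, the indices into the link
#' table (unique parent-child pairs) used for shared-time computations.
#'
#' @slot paths list of integer vectors of node ids, sample first, root last.
#' @slot linkPaths list of integer vectors of link indices.
#' @slot P numeric matrix (paths x samples).
#' @slot R numeric matrix (paths x roots).
#' @slot sampleIds,rootIds integer vectors naming the columns of P and R.
#' @slot minimal logical; TRUE for the linearly sufficient minimal set.
#' @export
setClass("PathSet",
  representation(
    paths = "list",
    linkPaths = "list",
    P = "matrix",
    R = "matrix",
    sampleIds = "integer",
    rootIds = "integer",
    minimal = "logical"
  )
)

#' Matrix of shared times between sample paths
#'
#' Entry (i, j) is the total edge time shared by paths i and j; the diagonal
#' holds total path lengths (root time minus sample time).  \eqn{\sigma^2 S_p}
#' is the unconditional covariance of the path-tip locations.
#'
#' @slot Sp symmetric numeric matrix (paths x paths), generations.
#' @slot pathSet the [PathSet-class] the matrix was computed from.
#' @export
setClass("SharedTimeMatrix",
  representation(Sp = "matrix", pathSet = "PathSet")
)

#' Dispersal and root-location fit
#'
#' @slot muHat numeric matrix (roots x dimensions) of root-location MLEs.
#' @slot sigma2Hat numeric d x d dispersal matrix (1 x 1 in one dimension).
#' @slot loglik numeric(1) log-likelihood at the MLEs.
#' @slot np,ns,nr integer path, sample and root counts.
#' @slot variant "meeting" (lineages meet at recombination nodes) or
#'   "midpoint" (recombination node at the average of its parents).
#' @slot diagnostics list (condition numbers, ranks, open loops, ...).
#' @export
setClass("FitResult",
  representation(
    muHat = "matrix",
    sigma2Hat = "matrix",
    loglik = "numeric",
    np = "integer",
    ns = "integer",
    nr = "integer",
    variant = "character",
    diagnostics = "list"
  )
)

#' Location distribution of one genetic ancestor
#'
#' Conditional on the ARG, the sample locations, the dispersal rate and the
#' root-location MLEs, an ancestor's location is Gaussian.  \code{V} is the
#' dispersal-free variance factor, split into a Brownian-motion part and a
#' root-uncertainty part; the total variance is \code{sigma2 * V}.
#'
#' @slot node integer node id (NA for a mid-edge point).
#' @slot time numeric(1), generations before present.
#' @slot mean numeric vector, length d.
#' @slot V numeric(1) variance factor.
#' @slot bmComponent,rootComponent numeric(1) parts of V.
#' @slot totalVariance numeric d x d matrix.
#' @slot sigma2 numeric d x d dispersal matrix used.
#' @export
setClass("AncestorLocation",
  representation(
    node = "integer",
    time = "numeric",
    mean = "numeric",
    V = "numeric",
    bmComponent = "numeric",
    rootComponent = "numeric",
    totalVariance = "matrix",
    sigma2 = "matrix"
  )
)

#' Dense joint Gaussian over ARG node locations (reference computation)
#'
#' One coordinate per node; each recombination node is duplicated into a left
#' and a right copy (one per parent lineage).  Constraint rows encode
#' left copy - right copy = 0, the meeting condition.  Intended as an exact,
#' slow oracle for the path-matrix machinery, not for production use.
#'
#' @slot copies data.frame with columns \code{node} (id), \code{side}
#'   (1 or 2) and \code{root} (id of the root the copy's upward path reaches).
#' @slot mean numeric vector (copies).
#' @slot cov numeric matrix (copies x copies), includes the dispersal rate.
#' @slot constraints numeric matrix (constraints x copies).
#' @slot conditioned logical; TRUE after conditioning on the loops.
#' @slot sigma2 numeric(1) dispersal rate used (single coordinate dimension).
#' @export
setClass("JointGaussian",
  representation(
    copies = "data.frame",
    mean = "numeric",
    cov = "matrix",
    constraints = "matrix",
    conditioned = "logical",
    sigma2 = "numeric"
  )
)
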