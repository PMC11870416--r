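#' @include AllClasses.R
NULL

#' @rdname SpatialARG-class
#' @param object,x a \code{SpatialARG}
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))
#' @rdname SpatialARG-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname SpatialARG-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname SpatialARG-class
#' @export
setGeneric("sampleLocations", function(x) standardGeneric("sampleLocations"))
#' @rdname SpatialARG-class
#' @export
setGeneric("sequenceLength", function(x) standardGeneric("sequenceLength"))
#' @rdname SpatialARG-class
#' @export
setGeneric("rootIds", function(x) standardGeneric("rootIds"))
#' @rdname SpatialARG-class
#' @export
setGeneric("recombinationNodes", function(x) standardGeneric("recombinationNodes"))
#' @rdname SpatialARG-class
#' @export
setGeneric("nDimensions", function(x) standardGeneric("nDimensions"))

#' @export
setGeneric("pathMatrix", function(x) standardGeneric("pathMatrix"))
#' @export
setGeneric("pathSet", function(x) standardGeneric("pathSet"))

#' @export
setGeneric("rootLocations", function(x) standardGeneric("rootLocations"))
#' @export
setGeneric("dispersalRate", function(x) standardGeneric("dispersalRate"))

setMethod("nodeTable", "SpatialARG", function(x) x@nodes)
setMethod("edgeTable", "SpatialARG", function(x) x@edges)
setMethod("sampleIds", "SpatialARG", function(x) x@sampleIds)
setMethod("sampleLocations", "SpatialARG", function(x) x@locations)
setMethod("sequenceLength", "SpatialARG", function(x) x@sequenceLength)
setMethod("rootIds", "SpatialARG", function(x) {
  # any node without a parent edge is a root, even if it is also a sample
  sort(setdiff(x@nodes$id, x@edges$child))
})
setMethod("recombinationNodes", "SpatialARG", function(x) {
  # structural: any node with two distinct parents (samples included)
  ed <- x@edges
  pc <- unique(ed[, c("parent", "child")])
  cnt <- table(pc$child)
  sort(as.integer(names(cnt)[cnt == 2L]))
})
setMethod("nDimensions", "SpatialARG", function(x) ncol(x@locations))

setMethod("show", "SpatialARG", function(object) {
  nd <- object@nodes
  cat(sprintf(
    "SpatialARG: %d nodes, %d edge rows, %d samples (%dD), %d root(s), %d recombination node(s)\n",
    nrow(nd), nrow(object@edges), length(object@sampleIds),
    ncol(object@locations), length(rootIds(object)),
    length(recombinationNodes(object))
  ))
  cat(sprintf("  sequence length: %g bp; oldest node: %g generations\n",
              object@sequenceLength, max(nd$time)))
})

setMethod("show", "LoopConstraint", function(object) {
  cat(sprintf("LoopConstraint at recombination node %d (top node %d)\n",
              object@recombinationNode, object@topNode))
  cat("  left : ", paste(object@leftPath, collapse = " -> "), "\n")
  cat("  right: ", paste(object@rightPath, collapse = " -> "), "\n")
})

setMethod("show", "PathSet", function(object) {
  cat(sprintf("PathSet: %d paths (%s), %d samples, %d root(s)\n",
              length(object@paths),
              if (object@minimal) "minimal" else "full",
              length(object@sampleIds), length(object@rootIds)))
})

setMethod("pathSet", "SharedTimeMatrix", function(x) x@pathSet)
setMethod("pathMatrix", "SharedTimeMatrix", function(x) x@Sp)

setMethod("show", "SharedTimeMatrix", function(object) {
  cat(sprintf("SharedTimeMatrix: %d x %d (%s path basis)\n",
              nrow(object@Sp), ncol(object@Sp),
              if (object@pathSet@minimal) "minimal" else "full"))
})

setMethod("rootLocations", "FitResult", function(x) x@muHat)
setMethod("dispersalRate", "FitResult", function(x) x@sigma2Hat)

setMethod("show", "FitResult", function(object) {
  d <- ncol(object@muHat)
  cat(sprintf("FitResult (%s model): ns = %d, np = %d, nr = %d\n",
              object@variant, object@ns, object@np, object@nr))
  if (d == 1L) {
    cat(sprintf("  dispersal rate sigma^2 = %.6g\n", object@sigma2Hat[1, 1]))
  } else {
    cat(sprintf("  dispersal matrix: sx2 = %.6g, sy2 = %.6g, sxy = %.6g\n",
                object@sigma2Hat[1, 1], object@sigma2Hat[2, 2],
                object@sigma2Hat[1, 2]))
  }
  cat(sprintf("  log-likelihood = %.6g\n", object@loglik))
})

setMethod("show", "AncestorLocation", function(object) {
  lbl <- if (is.na(object@node)) "mid-edge point" else sprintf("node %d", object@node)
  cat(sprintf("AncestorLocation: %s at time %g\n", lbl, object@time))
  cat("  mean:", paste(sprintf("%.5g", object@mean), collapse = ", "), "\n")
  cat(sprintf("  V = %.6g (Brownian %.6g + root %.6g)\n",
              object@V, object@bmComponent, object@rootComponent))
})

setMethod("show", "JointGaussian", function(object) {
  cat(sprintf("JointGaussian: %d node copies, %d loop constraint(s)%s\n",
              nrow(object@copies), nrow(object@constraints),
              if (object@conditioned) " (conditioned)" else ""))
})
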