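#' @include arg-core.R
NULL

.readTable <- function(x) {
  if (is.data.frame(x)) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (!file.exists(x)) stop("file not found: ", x)
  first <- readLines(x, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Read a spatial ARG from plain-text tables
#'
#' Reads a node table (\code{id}, \code{time}, optional \code{is_sample}), an
#' edge table (\code{parent}, \code{child}, \code{left}, \code{right}) and a
#' sample location table (\code{node_id}, \code{x} and optionally \code{y}),
#' each as a TSV/CSV file or an in-memory data.frame.  The column layout
#' matches the text dump of tskit tables, so a tree sequence exported with
#' e.g. \code{ts.dump_text()} (plus a location CSV) loads directly.
#'
#' @param nodes,edges,locations file paths or data.frames.
#' @param sequenceLength optional genome length (bp).
#' @return a validated [SpatialARG-class].
#' @seealso [writeArg()] for the inverse operation.
#' @export
loadArg <- function(nodes, edges, locations, sequenceLength = NULL) {
  if (is.null(sequenceLength) && is.character(edges) && file.exists(edges)) {
    first <- readLines(edges, n = 1L)
    if (grepl("^#\\s*sequence_length", first)) {
      sequenceLength <- as.numeric(sub("^#\\s*sequence_length\\s+", "", first))
    }
  }
  spatialARG(.readTable(nodes), .readTable(edges), .readTable(locations),
             sequenceLength)
}

#' Write a spatial ARG as plain-text tables
#'
#' Writes \code{<prefix>.nodes.tsv}, \code{<prefix>.edges.tsv} and
#' \code{<prefix>.locations.csv}.  Numeric columns are written with 17
#' significant digits so a round trip through [loadArg()] reproduces the graph
#' bit-exactly.
#'
#' @param arg a [SpatialARG-class].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths written.
#' @export
writeArg <- function(arg, prefix) {
  nd <- arg@nodes
  ed <- arg@edges
  nodesFile <- paste0(prefix, ".nodes.tsv")
  edgesFile <- paste0(prefix, ".edges.tsv")
  locFile <- paste0(prefix, ".locations.csv")
  ndOut <- data.frame(id = nd$id, time = .fmt(nd$time),
                      is_sample = as.integer(nd$is_sample))
  edOut <- data.frame(parent = ed$parent, child = ed$child,
                      left = .fmt(ed$left), right = .fmt(ed$right))
  loc <- arg@locations
  locOut <- data.frame(node_id = arg@sampleIds)
  locOut$x <- .fmt(loc[, 1])
  if (ncol(loc) > 1) locOut$y <- .fmt(loc[, 2])
  utils::write.table(ndOut, nodesFile, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste("# sequence_length", .fmt(arg@sequenceLength)), edgesFile)
  suppressWarnings(utils::write.table(edOut, edgesFile, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  utils::write.table(locOut, locFile, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(c(nodes = nodesFile, edges = edgesFile, locations = locFile))
}
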