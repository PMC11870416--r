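## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Unique parent-child pairs ("links") with their time lengths.  Several edge
## rows may connect the same pair over different genome intervals; they
## represent a single line of inheritance and therefore a single displacement.
.argLinks <- function(arg) {
  ed <- arg@edges
  if (!nrow(ed)) {
    return(data.frame(parent = integer(), child = integer(), length = numeric()))
  }
  key <- !duplicated(paste(ed$parent, ed$child))
  ln <- data.frame(parent = ed$parent[key], child = ed$child[key])
  tm <- arg@nodes$time[match(c(ln$parent, ln$child), arg@nodes$id)]
  n <- nrow(ln)
  ln$length <- tm[seq_len(n)] - tm[n + seq_len(n)]
  ln[order(ln$child, ln$parent), , drop = FALSE]
}

## Distinct parent ids per node, sorted ascending; names are node ids.
.parentMap <- function(arg) {
  ids <- arg@nodes$id
  out <- rep(list(integer()), length(ids))
  names(out) <- as.character(ids)
  if (nrow(arg@edges)) {
    sp <- split(arg@edges$parent, as.character(arg@edges$child))
    sp <- lapply(sp, function(p) sort(unique(p)))
    out[names(sp)] <- sp
  }
  out
}

.childMap <- function(arg) {
  ids <- arg@nodes$id
  out <- rep(list(integer()), length(ids))
  names(out) <- as.character(ids)
  if (nrow(arg@edges)) {
    sp <- split(arg@edges$child, as.character(arg@edges$parent))
    sp <- lapply(sp, function(p) sort(unique(p)))
    out[names(sp)] <- sp
  }
  out
}

.nodeTime <- function(arg, id) arg@nodes$time[match(id, arg@nodes$id)]

## Normalise a dispersal argument to a d x d matrix.
.asSigma <- function(sigma2, d) {
  if (is.matrix(sigma2)) {
    stopifnot(nrow(sigma2) == d, ncol(sigma2) == d)
    return(sigma2)
  }
  if (length(sigma2) == 1L) return(diag(rep(sigma2, d), nrow = d))
  if (length(sigma2) == d) return(diag(sigma2, nrow = d))
  stop("cannot interpret 'sigma2' for ", d, " dimensions")
}

## Normalise sample locations to a matrix ordered like `ids`.
.asLocations <- function(locations, ids, d = NULL) {
  if (is.data.frame(locations)) {
    if ("node_id" %in% names(locations)) {
      rownames(locations) <- as.character(locations$node_id)
      locations$node_id <- NULL
    }
    locations <- as.matrix(locations)
  }
  if (is.null(dim(locations))) locations <- matrix(locations, ncol = 1)
  if (!is.null(rownames(locations))) {
    miss <- setdiff(as.character(ids), rownames(locations))
    if (length(miss)) {
      stop("missing location for sample node(s): ", paste(miss, collapse = ", "))
    }
    locations <- locations[as.character(ids), , drop = FALSE]
  } else if (nrow(locations) != length(ids)) {
    stop("location table has ", nrow(locations), " rows but there are ",
         length(ids), " samples")
  }
  storage.mode(locations) <- "double"
  if (!is.null(d) && ncol(locations) != d) {
    stop("expected ", d, "-dimensional locations")
  }
  colnames(locations) <- c("x", "y")[seq_len(ncol(locations))]
  locations
}

## Draw from N(mean, cov) with a PSD (possibly singular) covariance.
.rmvn <- function(n, mean, cov) {
  p <- length(mean)
  eg <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  A <- eg$vectors %*% (sqrt(ev) * t(eg$vectors))
  t(mean + A %*% matrix(stats::rnorm(n * p), p, n))
}

.fmt <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%.0f", x), sprintf("%.17g", x))
}
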