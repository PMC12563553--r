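#' ChainAlignment: one gapped co-linear alignment between two genomes
#'
#' Represents a single record of a UCSC chain file: a scored, gapped,
#' co-linear alignment between a target and a query sequence.  Coordinates
#' are 0-based half-open as in the chain format itself.  For minus-strand
#' queries the query coordinates are kept in the chain-native (reversed)
#' frame; \code{\link{queryToForward}} converts positions to the forward
#' strand (\code{pos_fwd = qSize - pos_rev}).
#'
#' The \code{blocks} slot is an integer matrix with columns \code{size},
#' \code{dt}, \code{dq} (aligned block length, gap to the next block on the
#' target, gap on the query); the final row has \code{dt = dq = 0}.
#'
#' Validity enforces the chain arithmetic identities
#' \code{sum(size) + sum(dt) == tEnd - tStart} and
#' \code{sum(size) + sum(dq) == qEnd - qStart}.
#'
#' @slot score numeric alignment score.
#' @slot id integer chain id.
#' @slot tName,tSize,tStrand,tStart,tEnd target sequence name, length,
#'   strand (always \code{"+"}), span.
#' @slot qName,qSize,qStrand,qStart,qEnd query sequence name, length,
#'   strand, span (reversed frame when \code{qStrand == "-"}).
#' @slot blocks integer matrix (\code{size}, \code{dt}, \code{dq}).
#'
#' @examples
#' ch <- ChainAlignment(score = 100, id = 1L,
#'   tName = "chrA", tSize = 1000L, tStart = 0L, tEnd = 1000L,
#'   qName = "chrB", qSize = 1000L, qStrand = "+", qStart = 0L, qEnd = 1000L,
#'   blocks = cbind(size = 1000L, dt = 0L, dq = 0L))
#' ch
#' @export ChainAlignment
#' @exportClass ChainAlignment
ChainAlignment <- setClass("ChainAlignment",
  representation(
    score = "numeric", id = "integer",
    tName = "character", tSize = "integer", tStrand = "character",
    tStart = "integer", tEnd = "integer",
    qName = "character", qSize = "integer", qStrand = "character",
    qStart = "integer", qEnd = "integer",
    blocks = "matrix"),
  prototype(score = 0, id = 0L, tStrand = "+", qStrand = "+"))

setValidity("ChainAlignment", function(object) {
  b <- object@blocks
  msgs <- character(0)
  if (!is.numeric(b) || ncol(b) != 3L)
    return("blocks must be a numeric matrix with columns size, dt, dq")
  if (nrow(b) == 0L)
    return("chain must contain at least one block")
  if (any(b[, 1L] <= 0))
    msgs <- c(msgs, "block sizes must be positive")
  if (any(b[, 2:3] < 0))
    msgs <- c(msgs, "gap lengths must be non-negative")
  if (b[nrow(b), 2L] != 0 || b[nrow(b), 3L] != 0)
    msgs <- c(msgs, "final block must have dt = dq = 0")
  tSpan <- object@tEnd - object@tStart
  qSpan <- object@qEnd - object@qStart
  if (sum(b[, 1L]) + sum(b[, 2L]) != tSpan)
    msgs <- c(msgs, sprintf(
      "chain %d: block arithmetic does not match target span (%d vs %d)",
      object@id, sum(b[, 1L]) + sum(b[, 2L]), tSpan))
  if (sum(b[, 1L]) + sum(b[, 3L]) != qSpan)
    msgs <- c(msgs, sprintf(
      "chain %d: block arithmetic does not match query span (%d vs %d)",
      object@id, sum(b[, 1L]) + sum(b[, 3L]), qSpan))
  if (object@tStrand != "+")
    msgs <- c(msgs, "target strand must be '+' (UCSC convention)")
  if (!object@qStrand %in% c("+", "-"))
    msgs <- c(msgs, "query strand must be '+' or '-'")
  if (object@tStart < 0 || object@tEnd > object@tSize ||
      object@qStart < 0 || object@qEnd > object@qSize)
    msgs <- c(msgs, "span exceeds sequence bounds")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ChainAlignment", function(object) {
  cat(sprintf(
    "ChainAlignment %d  score=%s\n  target %s:%d-%d (%s, size %d)\n  query  %s:%d-%d (%s, size %d)\n  %d block(s), %d aligned bp\n",
    object@id, format(object@score), object@tName, object@tStart,
    object@tEnd, object@tStrand, object@tSize, object@qName, object@qStart,
    object@qEnd, object@qStrand, object@qSize, nrow(object@blocks),
    sum(object@blocks[, 1L])))
})

#' ChainSet: a list of ChainAlignment objects
#'
#' Simple container for the chains of one liftover direction, as returned
#' by \code{\link{readChain}}.
#'
#' @param chains a list of \linkS4class{ChainAlignment} objects.
#' @return A \code{ChainSet}.
#' @export ChainSet
#' @exportClass ChainSet
ChainSet <- function(chains = list()) {
  new("ChainSet", S4Vectors::SimpleList(chains))
}

setClass("ChainSet", contains = "SimpleList")

setValidity("ChainSet", function(object) {
  if (!all(vapply(object, is, logical(1), "ChainAlignment")))
    return("all elements must be ChainAlignment objects")
  TRUE
})

setMethod("show", "ChainSet", function(object) {
  cat(sprintf("ChainSet with %d chain(s) on target sequence(s): %s\n",
    length(object),
    paste(unique(vapply(object, function(c) c@tName, character(1))),
      collapse = ", ")))
})

#' Accessors for ChainAlignment
#'
#' @param x a \linkS4class{ChainAlignment}.
#' @return \code{chainBlocks}: the block matrix; \code{chainScore},
#'   \code{chainId}: score and id; \code{targetName}, \code{queryName}:
#'   sequence names.
#' @aliases chainBlocks chainScore chainId targetName queryName
#' @name chain-accessors
#' @export chainBlocks chainScore chainId targetName queryName
NULL

setGeneric("chainBlocks", function(x) standardGeneric("chainBlocks"))
setGeneric("chainScore", function(x) standardGeneric("chainScore"))
setGeneric("chainId", function(x) standardGeneric("chainId"))
setGeneric("targetName", function(x) standardGeneric("targetName"))
setGeneric("queryName", function(x) standardGeneric("queryName"))

setMethod("chainBlocks", "ChainAlignment", function(x) x@blocks)
setMethod("chainScore", "ChainAlignment", function(x) x@score)
setMethod("chainId", "ChainAlignment", function(x) x@id)
setMethod("targetName", "ChainAlignment", function(x) x@tName)
setMethod("queryName", "ChainAlignment", function(x) x@qName)

#' TemporalClustering: a fuzzy partition of temporal expression profiles
#'
#' Result container for \code{\link{fuzzyCMeans}}.  Rows of
#' \code{membership} sum to 1; \code{assigned} is the arg-max cluster per
#' profile; \code{objective} records the (non-increasing) Bezdek objective
#' value at each iteration.
#'
#' @slot centers k x T matrix of cluster center profiles.
#' @slot membership n x k membership matrix in [0, 1], rows summing to 1.
#' @slot m fuzzifier (> 1).
#' @slot k number of clusters.
#' @slot assigned integer arg-max cluster per profile.
#' @slot converged logical; FALSE if \code{maxIter} was reached first.
#' @slot iterations number of iterations performed.
#' @slot objective objective value per iteration.
#' @export
#' @exportClass TemporalClustering
setClass("TemporalClustering",
  representation(
    centers = "matrix", membership = "matrix", m = "numeric",
    k = "integer", assigned = "integer", converged = "logical",
    iterations = "integer", objective = "numeric"))

setValidity("TemporalClustering", function(object) {
  msgs <- character(0)
  if (nrow(object@centers) != object@k)
    msgs <- c(msgs, "centers must have k rows")
  if (ncol(object@membership) != object@k)
    msgs <- c(msgs, "membership must have k columns")
  if (any(abs(rowSums(object@membership) - 1) > 1e-9))
    msgs <- c(msgs, "membership rows must sum to 1 (+/- 1e-9)")
  if (any(object@membership < -1e-12 | object@membership > 1 + 1e-12))
    msgs <- c(msgs, "memberships must lie in [0, 1]")
  if (object@m <= 1)
    msgs <- c(msgs, "fuzzifier m must be > 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TemporalClustering", function(object) {
  cat(sprintf(
    "TemporalClustering: %d profiles, k = %d, m = %g, %s after %d iteration(s)\n",
    nrow(object@membership), object@k, object@m,
    if (object@converged) "converged" else "NOT converged",
    object@iterations))
  cat("cluster sizes (arg-max):",
    paste(tabulate(object@assigned, object@k), collapse = ", "), "\n")
})

#' Accessors for TemporalClustering
#'
#' @param x a \linkS4class{TemporalClustering}.
#' @return \code{centers}: k x T center matrix; \code{membership}: n x k
#'   membership matrix; \code{clusterAssignments}: integer arg-max cluster
#'   per profile.
#' @aliases centers membership clusterAssignments
#' @name clustering-accessors
#' @export centers membership clusterAssignments
NULL

setGeneric("centers", function(x) standardGeneric("centers"))
setGeneric("membership", function(x) standardGeneric("membership"))
setGeneric("clusterAssignments",
  function(x) standardGeneric("clusterAssignments"))

setMethod("centers", "TemporalClustering", function(x) x@centers)
setMethod("membership", "TemporalClustering", function(x) x@membership)
setMethod("clusterAssignments", "TemporalClustering",
  function(x) x@assigned)

#' MotifModel: a position weight matrix with an id
#'
#' Probability matrix over A/C/G/T (rows) by motif position (columns);
#' every column sums to 1.  Built by \code{\link{motifModel}} or read from
#' JASPAR/MEME files by \code{\link{readMotifs}}.
#'
#' @slot id motif identifier.
#' @slot pwm 4 x L probability matrix with rownames A, C, G, T.
#' @exportClass MotifModel
setClass("MotifModel",
  representation(id = "character", pwm = "matrix"))

setValidity("MotifModel", function(object) {
  p <- object@pwm
  if (!identical(rownames(p), c("A", "C", "G", "T")))
    return("pwm rows must be named A, C, G, T")
  if (ncol(p) < 1L)
    return("pwm must have at least one column")
  if (any(p < 0))
    return("pwm entries must be non-negative")
  if (any(abs(colSums(p) - 1) > 1e-9))
    return("every pwm column must sum to 1 (+/- 1e-9)")
  TRUE
})

#' Construct a MotifModel
#'
#' @param id motif identifier.
#' @param pwm 4 x L matrix of probabilities (rows A, C, G, T) or
#'   non-negative counts; counts are normalized column-wise.
#' @return A \linkS4class{MotifModel}.
#' @examples
#' m <- motifModel("toy", matrix(c(8, 0, 0, 0,  0, 8, 0, 0), nrow = 4,
#'   dimnames = list(c("A", "C", "G", "T"), NULL)))
#' m
#' @export
motifModel <- function(id, pwm) {
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  cs <- colSums(pwm)
  if (any(cs <= 0)) .stopf("motif '%s': empty pwm column", id)
  if (any(abs(cs - 1) > 1e-9)) pwm <- sweep(pwm, 2, cs, "/")
  new("MotifModel", id = as.character(id), pwm = pwm)
}

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel '%s', %d positions\n", object@id,
    ncol(object@pwm)))
})

#' Accessors for MotifModel
#'
#' @param x a \linkS4class{MotifModel}.
#' @return \code{motifId}: the identifier; \code{motifMatrix}: the 4 x L
#'   probability matrix.
#' @aliases motifId motifMatrix
#' @name motif-accessors
#' @export motifId motifMatrix
NULL

setGeneric("motifId", function(x) standardGeneric("motifId"))
setGeneric("motifMatrix", function(x) standardGeneric("motifMatrix"))
setMethod("motifId", "MotifModel", function(x) x@id)
setMethod("motifMatrix", "MotifModel", function(x) x@pwm)
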