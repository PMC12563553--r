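#' Read a UCSC chain file
#'
#' Parses all chains from a UCSC-format chain file into a
#' \linkS4class{ChainSet}.  Every chain is validated against the block
#' arithmetic identities (\code{sum(size) + sum(dt) == tEnd - tStart},
#' \code{sum(size) + sum(dq) == qEnd - qStart}); a mismatch raises an
#' error naming the chain id.  Minus-strand query coordinates are kept in
#' the chain-native reversed frame (see \code{\link{queryToForward}}).
#'
#' @param path path to a chain file.
#' @return A \linkS4class{ChainSet}.
#' @examples
#' f <- tempfile(fileext = ".chain")
#' writeLines(c("chain 100 chrA 1000 + 0 1000 chrB 1000 + 0 1000 1",
#'   "1000", ""), f)
#' readChain(f)
#' @seealso \code{\link{writeChain}}, \code{\link{invertChain}},
#'   \code{\link{mapInterval}}
#' @export
readChain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    hdr <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (hdr[1L] != "chain" || length(hdr) != 13L)
      .stopf("chain parse error at line %d of '%s': malformed header", i, path)
    num <- suppressWarnings(as.numeric(hdr[c(2, 4, 6, 7, 9, 11, 12, 13)]))
    if (anyNA(num))
      .stopf("chain parse error at line %d of '%s': non-numeric header field",
        i, path)
    blocks <- list()
    i <- i + 1L
    repeat {
      if (i > n)
        .stopf("chain parse error in '%s': truncated block list for chain %s",
          path, hdr[13L])
      ln <- trimws(lines[i])
      if (!nzchar(ln))
        .stopf("chain parse error at line %d of '%s': truncated block list for chain %s",
          i, path, hdr[13L])
      v <- suppressWarnings(as.integer(strsplit(ln, "[ \t]+")[[1L]]))
      if (anyNA(v) || !length(v) %in% c(1L, 3L))
        .stopf("chain parse error at line %d of '%s': malformed block line", i, path)
      if (length(v) == 1L) v <- c(v, 0L, 0L)
      blocks[[length(blocks) + 1L]] <- v
      i <- i + 1L
      if (v[2L] == 0L && v[3L] == 0L && length(strsplit(ln, "[ \t]+")[[1L]]) == 1L)
        break
    }
    b <- do.call(rbind, blocks)
    colnames(b) <- c("size", "dt", "dq")
    ch <- try(ChainAlignment(
      score = as.numeric(hdr[2L]), id = as.integer(hdr[13L]),
      tName = hdr[3L], tSize = as.integer(hdr[4L]), tStrand = hdr[5L],
      tStart = as.integer(hdr[6L]), tEnd = as.integer(hdr[7L]),
      qName = hdr[8L], qSize = as.integer(hdr[9L]), qStrand = hdr[10L],
      qStart = as.integer(hdr[11L]), qEnd = as.integer(hdr[12L]),
      blocks = b), silent = TRUE)
    if (inherits(ch, "try-error"))
      .stopf("chain validation error for chain id %s in '%s': %s",
        hdr[13L], path, attr(ch, "condition")$message)
    chains[[length(chains) + 1L]] <- ch
  }
  ChainSet(chains)
}

#' Write a ChainSet as a UCSC chain file
#'
#' Inverse of \code{\link{readChain}}; round trips are byte-identical.
#'
#' @param chains a \linkS4class{ChainSet} or list of
#'   \linkS4class{ChainAlignment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeChain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in as.list(chains)) {
    writeLines(sprintf("chain %s %s %d %s %d %d %s %d %s %d %d %d",
      .fmtNum(ch@score), ch@tName, ch@tSize, ch@tStrand, ch@tStart,
      ch@tEnd, ch@qName, ch@qSize, ch@qStrand, ch@qStart, ch@qEnd,
      ch@id), con)
    b <- ch@blocks
    if (nrow(b) > 1L)
      writeLines(sprintf("%d %d %d", b[-nrow(b), 1L], b[-nrow(b), 2L],
        b[-nrow(b), 3L]), con)
    writeLines(c(sprintf("%d", b[nrow(b), 1L]), ""), con)
  }
  invisible(path)
}

#' Convert chain-native query coordinates to forward-strand coordinates
#'
#' For a minus-strand query, chain block coordinates live in the reversed
#' frame of the query sequence; a reversed-frame half-open interval
#' \code{[s, e)} corresponds to the forward interval
#' \code{[qSize - e, qSize - s)}.  Plus-strand coordinates are returned
#' unchanged.
#'
#' @param chain a \linkS4class{ChainAlignment}.
#' @param start0,end1 0-based half-open interval in the chain-native query
#'   frame (vectors allowed).
#' @return A two-column matrix \code{start0}, \code{end1} of forward-frame
#'   coordinates.
#' @export
queryToForward <- function(chain, start0, end1) {
  if (chain@qStrand == "-") {
    fwd <- cbind(start0 = chain@qSize - end1, end1 = chain@qSize - start0)
  } else {
    fwd <- cbind(start0 = start0, end1 = end1)
  }
  fwd
}

#' Invert a chain (swap target and query)
#'
#' Produces the chain describing the same alignment with target and query
#' roles exchanged, following the UCSC convention that the target strand
#' of the result is \code{"+"}.  For a minus-strand query the block order
#' is reversed and the old target is expressed in its reversed frame.
#' Inverting twice returns the original chain.
#'
#' @param chain a \linkS4class{ChainAlignment}.
#' @return A \linkS4class{ChainAlignment} for the opposite direction.
#' @export
invertChain <- function(chain) {
  b <- chain@blocks
  if (chain@qStrand == "+") {
    nb <- b[, c(1L, 3L, 2L), drop = FALSE]
    colnames(nb) <- c("size", "dt", "dq")
    return(ChainAlignment(
      score = chain@score, id = chain@id,
      tName = chain@qName, tSize = chain@qSize, tStrand = "+",
      tStart = chain@qStart, tEnd = chain@qEnd,
      qName = chain@tName, qSize = chain@tSize, qStrand = "+",
      qStart = chain@tStart, qEnd = chain@tEnd, blocks = nb))
  }
  # minus-strand query: new target = old query on its forward strand.
  # Reversed-frame [qStart, qEnd) maps to forward [qSize-qEnd, qSize-qStart);
  # ascending forward order is the reverse of the chain-native block order.
  nBlk <- nrow(b)
  rev_i <- rev(seq_len(nBlk))
  sizes <- b[rev_i, 1L]
  # gap after new block j (old block n-j+1) is the old gap before that block
  olddt <- b[, 2L]; olddq <- b[, 3L]
  ndt <- c(if (nBlk > 1L) olddq[rev(seq_len(nBlk - 1L))], 0L)
  ndq <- c(if (nBlk > 1L) olddt[rev(seq_len(nBlk - 1L))], 0L)
  nb <- cbind(size = sizes, dt = as.integer(ndt), dq = as.integer(ndq))
  ChainAlignment(
    score = chain@score, id = chain@id,
    tName = chain@qName, tSize = chain@qSize, tStrand = "+",
    tStart = chain@qSize - chain@qEnd, tEnd = chain@qSize - chain@qStart,
    qName = chain@tName, qSize = chain@tSize, qStrand = "-",
    qStart = chain@tSize - chain@tEnd, qEnd = chain@tSize - chain@tStart,
    blocks = nb)
}
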