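#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' Parses a 10-column narrowPeak file into a \link[GenomicRanges]{GRanges}.
#' Coordinates are converted from the BED 0-based half-open convention to
#' the 1-based closed GRanges convention; \code{\link{writeNarrowPeak}}
#' converts back, so a read/write round trip is byte-identical.  Input
#' order is preserved (no sorting).
#'
#' Metadata columns: \code{name}, \code{score}, \code{signalValue} (fold
#' enrichment over input), \code{pValue}, \code{qValue} (-log10 scale),
#' \code{peak} (summit offset from the BED start; -1 when no summit was
#' called).
#'
#' Malformed records are rejected, never repaired: a wrong column count,
#' non-numeric coordinate, \code{start >= end}, or a summit offset outside
#' the peak raises an error naming the offending line.
#'
#' @param path path to a narrowPeak file.
#' @return A \code{GRanges} with the metadata columns above.
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t200\tp1\t0\t.\t5.5\t3\t2.5\t50", f)
#' readNarrowPeak(f)
#' @seealso \code{\link{writeNarrowPeak}}
#' @export
readNarrowPeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = character(0), score = integer(0), signalValue = numeric(0),
      pValue = numeric(0), qValue = numeric(0), peak = integer(0))
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L))
    .stopf("narrowPeak parse error at line %d of '%s': expected 10 columns, found %d",
      which(nf != 10L)[1L], path, nf[nf != 10L][1L])
  m <- do.call(rbind, fields)
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end1 <- suppressWarnings(as.integer(m[, 3L]))
  sig <- suppressWarnings(as.numeric(m[, 7L]))
  pv <- suppressWarnings(as.numeric(m[, 8L]))
  qv <- suppressWarnings(as.numeric(m[, 9L]))
  peak <- suppressWarnings(as.integer(m[, 10L]))
  bad <- which(is.na(start0) | is.na(end1) | is.na(sig) | is.na(pv) |
    is.na(qv) | is.na(peak))
  if (length(bad))
    .stopf("narrowPeak parse error at line %d of '%s': non-numeric field",
      bad[1L], path)
  bad <- which(start0 < 0L | start0 >= end1)
  if (length(bad))
    .stopf("narrowPeak validation error at line %d of '%s': start (%d) must satisfy 0 <= start < end (%d)",
      bad[1L], path, start0[bad[1L]], end1[bad[1L]])
  bad <- which(peak != -1L & (peak < 0L | peak >= end1 - start0))
  if (length(bad))
    .stopf("narrowPeak validation error at line %d of '%s': summit offset %d outside peak of length %d",
      bad[1L], path, peak[bad[1L]], end1[bad[1L]] - start0[bad[1L]])
  strand <- m[, 6L]
  strand[strand == "."] <- "*"
  if (!all(strand %in% c("+", "-", "*")))
    .stopf("narrowPeak validation error in '%s': unknown strand '%s'",
      path, setdiff(strand, c("+", "-", "*"))[1L])
  gr <- .grFromBed(m[, 1L], start0, end1, strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = m[, 4L], score = suppressWarnings(as.integer(m[, 5L])),
    signalValue = sig, pValue = pv, qValue = qv, peak = peak)
  gr
}

#' Write a GRanges of peaks as narrowPeak
#'
#' Inverse of \code{\link{readNarrowPeak}}.  Missing metadata columns get
#' narrowPeak placeholder values (\code{name = "."}, \code{score = 0},
#' \code{pValue = qValue = -1}, \code{peak = -1}).
#'
#' @param gr a \code{GRanges}; metadata columns \code{name}, \code{score},
#'   \code{signalValue}, \code{pValue}, \code{qValue}, \code{peak} are used
#'   when present.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNarrowPeak <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  n <- length(gr)
  col <- function(nm, default) {
    if (nm %in% colnames(mc)) mc[[nm]] else rep(default, n)
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  lines <- paste(
    as.character(GenomicRanges::seqnames(gr)),
    .bedStart(gr), .bedEnd(gr),
    col("name", "."), col("score", 0L), strand,
    .fmtNum(col("signalValue", 0)), .fmtNum(col("pValue", -1)),
    .fmtNum(col("qValue", -1)), col("peak", -1L),
    sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
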