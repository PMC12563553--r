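#' Reproducible consensus peaks from two biological replicates
#'
#' Implements the replicate-reproducibility rule used to define consensus
#' peaks: a peak from one replicate is supported when some peak of the
#' other replicate overlaps it by at least \code{minFrac} of its own
#' length.  Peak pairs that satisfy the rule mutually (the overlap is
#' >= \code{minFrac} of \emph{both} peak lengths) are union-merged,
#' transitively, into a single consensus peak spanning all members.
#'
#' Each consensus peak records \code{support} (number of contributing
#' replicate peaks, always >= 2), \code{signalValue} (mean fold enrichment
#' of the members) and \code{peak} (summit offset taken from the member
#' with the highest fold enrichment; a member summit of -1 means the
#' member midpoint is used).  The operation is symmetric in its replicate
#' arguments.
#'
#' @param rep1,rep2 \code{GRanges} of replicate peaks as returned by
#'   \code{\link{readNarrowPeak}}.
#' @param minFrac minimum overlap fraction of a peak's own length, in
#'   (0, 1]; default 0.5.
#' @return A \code{GRanges} of consensus peaks (sorted), with metadata
#'   columns \code{name}, \code{score} (= support), \code{signalValue},
#'   \code{pValue}, \code{qValue}, \code{peak}, \code{support}.
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300),
#'   signalValue = 4, peak = 50L)
#' reproduciblePeaks(r, r)
#' @export
reproduciblePeaks <- function(rep1, rep2, minFrac = 0.5) {
  .checkFraction(minFrac, "minFrac")
  n1 <- length(rep1)
  n2 <- length(rep2)
  all <- c(GenomicRanges::granges(rep1), GenomicRanges::granges(rep2))
  fold <- c(.mcolOr(rep1, "signalValue", 0), .mcolOr(rep2, "signalValue", 0))
  summit <- c(.mcolOr(rep1, "peak", -1L), .mcolOr(rep2, "peak", -1L))
  hits <- GenomicRanges::findOverlaps(rep1, rep2, ignore.strand = TRUE)
  edges <- matrix(integer(0), ncol = 2)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ow <- GenomicRanges::width(GenomicRanges::pintersect(
      GenomicRanges::granges(rep1)[q], GenomicRanges::granges(rep2)[s]))
    mutual <- ow >= minFrac * GenomicRanges::width(rep1)[q] &
      ow >= minFrac * GenomicRanges::width(rep2)[s]
    edges <- cbind(q[mutual], n1 + s[mutual])
  }
  comp <- .components(n1 + n2, edges)
  keep <- which(comp %in% comp[duplicated(comp)])
  if (!length(keep)) {
    res <- GenomicRanges::GRanges()
    S4Vectors::mcols(res) <- S4Vectors::DataFrame(name = character(0),
      score = integer(0), signalValue = numeric(0), pValue = numeric(0),
      qValue = numeric(0), peak = integer(0), support = integer(0))
    return(res)
  }
  groups <- split(keep, comp[keep])
  agg <- .aggregateGroups(groups, all, fold, summit)
  res <- .grFromBed(agg$chrom, agg$start0, agg$end1)
  S4Vectors::mcols(res) <- S4Vectors::DataFrame(
    name = NA_character_, score = agg$size, signalValue = agg$meanFold,
    pValue = -1, qValue = -1, peak = agg$summitOff, support = agg$size)
  res <- res[order(as.character(GenomicRanges::seqnames(res)),
    GenomicRanges::start(res), GenomicRanges::end(res))]
  res$name <- sprintf("consensus_%d", seq_along(res))
  res
}

# vectorized per-group aggregation: union span, mean fold, summit offset
# from the highest-fold member (midpoint when the member summit is -1)
.aggregateGroups <- function(groups, all, fold, summit) {
  memb <- unlist(groups, use.names = FALSE)
  gf <- rep(seq_along(groups), lengths(groups))
  s0 <- GenomicRanges::start(all)[memb] - 1L
  e1 <- GenomicRanges::end(all)[memb]
  chromAll <- as.character(GenomicRanges::seqnames(all))[memb]
  gStart <- as.integer(tapply(s0, gf, min))
  gEnd <- as.integer(tapply(e1, gf, max))
  gChrom <- chromAll[!duplicated(gf)]
  best <- vapply(groups, function(idx) idx[which.max(fold[idx])],
    integer(1))
  bs0 <- GenomicRanges::start(all)[best] - 1L
  bestSummit0 <- ifelse(summit[best] == -1L,
    bs0 + GenomicRanges::width(all)[best] %/% 2L, bs0 + summit[best])
  list(chrom = gChrom, start0 = gStart, end1 = gEnd,
    size = as.integer(lengths(groups)),
    meanFold = as.numeric(tapply(fold[memb], gf, mean)),
    summitOff = as.integer(bestSummit0 - gStart))
}

.mcolOr <- function(gr, nm, default) {
  mc <- S4Vectors::mcols(gr)
  if (nm %in% colnames(mc)) mc[[nm]] else rep(default, length(gr))
}

#' Fixed-width window centered on a peak summit
#'
#' Returns the \code{width}-bp window centered on each peak's summit
#' (metadata column \code{peak}; -1 means "summit unknown", in which case
#' the interval midpoint is used), clipped at chromosome bounds when
#' sequence lengths are available.  These windows are the units lifted
#' between genomes in the cross-species comparison.
#'
#' @param peaks a \code{GRanges} with a \code{peak} summit-offset column.
#' @param width window width in bp; must be even and >= 2.
#' @param seqlen optional named vector of chromosome lengths used for
#'   right-side clipping (left clipping at position 0 always applies).
#' @return A \code{GRanges} of summit windows carrying the input metadata.
#' @section Errors:
#' A window falling entirely off its chromosome raises an error.
#' @export
summitWindow <- function(peaks, width = 100L, seqlen = NULL) {
  if (width < 2L || width %% 2L != 0L)
    .stopf("'width' must be an even number >= 2")
  off <- .mcolOr(peaks, "peak", -1L)
  s0 <- .bedStart(peaks)
  summit0 <- ifelse(off == -1L, s0 + GenomicRanges::width(peaks) %/% 2L,
    s0 + off)
  ws <- summit0 - width %/% 2L
  we <- summit0 + width %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  if (!is.null(seqlen)) {
    lim <- unname(seqlen[chrom])
    if (any(!is.na(lim) & ws >= lim))
      .stopf("summit window entirely beyond chromosome end for peak %d",
        which(!is.na(lim) & ws >= lim)[1L])
    we <- ifelse(!is.na(lim), pmin(we, lim), we)
  }
  if (any(we <= 0))
    .stopf("summit window entirely before chromosome start for peak %d",
      which(we <= 0)[1L])
  ws <- pmax(ws, 0L)
  out <- .grFromBed(chrom, ws, we, as.character(GenomicRanges::strand(peaks)))
  S4Vectors::mcols(out) <- S4Vectors::mcols(peaks)
  out
}
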