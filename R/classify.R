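#' Classify consensus peaks into putative promoters and enhancers
#'
#' Applies the mark co-occupancy rules used to define putative regulatory
#' elements from H3K4me3 and H3K27ac consensus peaks:
#' \itemize{
#'   \item an H3K4me3 peak with no H3K27ac overlap is a \strong{promoter}
#'     (marks \code{H3K4me3});
#'   \item an H3K27ac peak with no H3K4me3 overlap is an
#'     \strong{enhancer} (marks \code{H3K27ac});
#'   \item an H3K4me3/H3K27ac pair whose overlap is at least
#'     \code{recipFrac} of \emph{both} peak lengths (reciprocal test,
#'     inclusive) is merged into a single \strong{promoter} spanning the
#'     union, marked by both, with the mean of the two fold enrichments;
#'     mutually qualifying peaks are union-merged transitively;
#'   \item overlapping pairs that fail the reciprocal test are labeled
#'     \strong{ambiguous} and are excluded from downstream sets.
#' }
#' No peak is lost or double-counted: every input peak contributes to
#' exactly one output element.
#'
#' @param k4,k27 \code{GRanges} of H3K4me3 and H3K27ac consensus peaks
#'   from the same genome (see \code{\link{reproduciblePeaks}}).
#' @param recipFrac reciprocal overlap fraction in (0, 1]; default 0.5.
#' @return A sorted \code{GRanges} with metadata columns
#'   \code{element_id}, \code{element_class} (\code{"promoter"},
#'   \code{"enhancer"} or \code{"ambiguous"}), \code{marks}
#'   (comma-collapsed), \code{signalValue} (mean fold enrichment),
#'   \code{peak} (summit offset from the highest-fold member) and
#'   \code{n_k4}, \code{n_k27} (contributing peak counts).
#' @examples
#' k4 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300),
#'   signalValue = 5, peak = -1L)
#' k27 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 350),
#'   signalValue = 3, peak = -1L)
#' classifyElements(k4, k27)  # one merged promoter [100,350)
#' @export
classifyElements <- function(k4, k27, recipFrac = 0.5) {
  .checkFraction(recipFrac, "recipFrac")
  n4 <- length(k4)
  n27 <- length(k27)
  all <- c(GenomicRanges::granges(k4), GenomicRanges::granges(k27))
  isK4 <- c(rep(TRUE, n4), rep(FALSE, n27))
  fold <- c(.mcolOr(k4, "signalValue", 0), .mcolOr(k27, "signalValue", 0))
  summit <- c(.mcolOr(k4, "peak", -1L), .mcolOr(k27, "peak", -1L))
  hits <- GenomicRanges::findOverlaps(k4, k27, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  recip <- logical(length(hits))
  if (length(hits)) {
    ow <- GenomicRanges::width(GenomicRanges::pintersect(
      GenomicRanges::granges(k4)[q], GenomicRanges::granges(k27)[s]))
    recip <- ow >= recipFrac * GenomicRanges::width(k4)[q] &
      ow >= recipFrac * GenomicRanges::width(k27)[s]
  }
  overlapped <- rep(FALSE, n4 + n27)
  overlapped[unique(q)] <- TRUE
  overlapped[n4 + unique(s)] <- TRUE
  inRecip <- rep(FALSE, n4 + n27)
  inRecip[unique(q[recip])] <- TRUE
  inRecip[n4 + unique(s[recip])] <- TRUE
  edges <- cbind(q[recip], n4 + s[recip])
  comp <- .components(n4 + n27, edges)

  # merged promoters: components joined by >= 1 reciprocal edge
  mergedIdx <- which(inRecip)
  groups <- if (length(mergedIdx)) split(mergedIdx, comp[mergedIdx])
    else list()
  classes <- rep("promoter", length(groups))
  marks <- rep("H3K4me3,H3K27ac", length(groups))
  single <- which(!inRecip)
  groups <- c(groups, as.list(single))
  classes <- c(classes, ifelse(overlapped[single], "ambiguous",
    ifelse(isK4[single], "promoter", "enhancer")))
  marks <- c(marks, ifelse(isK4[single], "H3K4me3", "H3K27ac"))
  if (!length(groups)) {
    res <- GenomicRanges::GRanges()
    S4Vectors::mcols(res) <- S4Vectors::DataFrame(
      element_id = character(0), element_class = character(0),
      marks = character(0), signalValue = numeric(0), peak = integer(0),
      n_k4 = integer(0), n_k27 = integer(0))
    return(res)
  }
  agg <- .aggregateGroups(groups, all, fold, summit)
  nK4 <- vapply(groups, function(idx) sum(isK4[idx]), integer(1))
  res <- .grFromBed(agg$chrom, agg$start0, agg$end1)
  S4Vectors::mcols(res) <- S4Vectors::DataFrame(
    element_id = NA_character_, element_class = classes, marks = marks,
    signalValue = agg$meanFold, peak = agg$summitOff,
    n_k4 = nK4, n_k27 = agg$size - nK4)
  res <- res[order(as.character(GenomicRanges::seqnames(res)),
    GenomicRanges::start(res), GenomicRanges::end(res),
    res$element_class)]
  res$element_id <- sprintf("elem_%d", seq_along(res))
  res
}

#' Nearest-TSS annotation with signed distances
#'
#' Annotates each element with its nearest gene TSS.  The distance is 0
#' when a TSS falls inside the element; otherwise it is the gap (bp)
#' between the TSS and the closer element edge, signed negative when the
#' TSS lies 5' of the element along the gene's strand.  Ties in absolute
#' distance are broken by the lexicographically smallest \code{gene_id};
#' elements on chromosomes without genes get \code{NA}.
#'
#' @param elements a \code{GRanges} of elements.
#' @param genes a gene-model \code{GRanges} (width-1 TSS positions; see
#'   \code{\link{readGeneModels}}).
#' @return \code{elements} with metadata columns \code{nearest_gene} and
#'   \code{tss_distance} added.
#' @examples
#' genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 501),
#'   strand = "+", gene_id = "g1", gene_length = 1000L,
#'   ortholog_id = NA_character_)
#' e <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' nearestTSS(e, genes)$tss_distance  # +300
#' @export
nearestTSS <- function(elements, genes) {
  nearest_gene <- rep(NA_character_, length(elements))
  tss_distance <- rep(NA_integer_, length(elements))
  if (length(genes)) {
    gChrom <- as.character(GenomicRanges::seqnames(genes))
    gTss0 <- GenomicRanges::start(genes) - 1L
    gStrand <- as.character(GenomicRanges::strand(genes))
    gId <- genes$gene_id
    eChrom <- as.character(GenomicRanges::seqnames(elements))
    s0 <- .bedStart(elements)
    e0 <- .bedEnd(elements)
    for (i in seq_along(elements)) {
      onChrom <- which(gChrom == eChrom[i])
      if (!length(onChrom)) next
      tss <- gTss0[onChrom]
      mag <- ifelse(tss >= s0[i] & tss < e0[i], 0L,
        ifelse(tss >= e0[i], tss - e0[i], s0[i] - tss))
      # order by |distance|, then gene_id
      ord <- onChrom[order(mag, gId[onChrom])]
      j <- ord[1L]
      m <- mag[order(mag, gId[onChrom])][1L]
      # sign: negative when the TSS is 5' of the element on the gene strand
      tssj <- gTss0[j]
      sgn <- if (m == 0L) 1L
        else if (gStrand[j] == "+") (if (tssj < s0[i]) -1L else 1L)
        else (if (tssj >= e0[i]) -1L else 1L)
      nearest_gene[i] <- gId[j]
      tss_distance[i] <- sgn * m
    }
  }
  elements$nearest_gene <- nearest_gene
  elements$tss_distance <- tss_distance
  elements
}

#' Split promoters into high-confidence and distal sets by TSS distance
#'
#' Promoters within \code{maxTssDistance} (inclusive) of their nearest
#' TSS are high-confidence; more distal promoter-like elements are
#' returned separately rather than discarded.  Enhancers (and ambiguous
#' elements) pass through untouched in the \code{other} slot.
#'
#' @param elements a \code{GRanges} with \code{element_class} and
#'   \code{tss_distance} columns (see \code{\link{nearestTSS}}).
#' @param maxTssDistance distance threshold in bp; default 3000.
#' @return A list with \code{highConfidence}, \code{distal} (both
#'   promoters) and \code{other} (all non-promoter elements).
#' @export
filterPromoters <- function(elements, maxTssDistance = 3000L) {
  isProm <- elements$element_class == "promoter"
  d <- abs(elements$tss_distance)
  hc <- isProm & !is.na(d) & d <= maxTssDistance
  list(
    highConfidence = elements[hc],
    distal = elements[isProm & !hc],
    other = elements[!isProm])
}

#' Link elements to their nearest gene within a distance bound
#'
#' An element is linked to its nearest gene when the absolute TSS
#' distance does not exceed \code{maxLinkDistance} (default 1 Mbp) and
#' the gene belongs to \code{genes} (pass an ortholog-filtered gene set
#' for cross-species use).  Elements beyond the bound, or whose nearest
#' gene is not in \code{genes}, are unlinked.
#'
#' @param elements a \code{GRanges} with \code{element_id},
#'   \code{element_class}, \code{nearest_gene} and \code{tss_distance}
#'   columns.
#' @param genes gene-model \code{GRanges} defining the linkable universe.
#' @param maxLinkDistance maximum |TSS distance| in bp; default 1e6.
#' @return A data.frame with one row per linked element: columns
#'   \code{element_id}, \code{element_class}, \code{gene_id},
#'   \code{tss_distance}.
#' @export
linkToGenes <- function(elements, genes, maxLinkDistance = 1e6) {
  ok <- !is.na(elements$nearest_gene) &
    abs(elements$tss_distance) <= maxLinkDistance &
    elements$nearest_gene %in% genes$gene_id
  data.frame(
    element_id = elements$element_id[ok],
    element_class = elements$element_class[ok],
    gene_id = elements$nearest_gene[ok],
    tss_distance = elements$tss_distance[ok],
    stringsAsFactors = FALSE)
}
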