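#' Map intervals to another genome through alignment chains
#'
#' Projects each interval through the single best-scoring chain covering
#' it (ties broken by the smaller chain id), mirroring the behaviour of
#' UCSC liftOver.  Bases falling in aligned blocks are projected to query
#' coordinates; the mapped interval is the \code{[min, max)} envelope of
#' the projected bases on the query's forward strand.  An interval whose
#' aligned fraction is below \code{minMatch} is reported
#' \code{"unmapped"}.  A \code{"split"} status is reserved for
#' projections landing on more than one query chromosome or strand; with
#' single-best-chain semantics a single chain carries one query sequence
#' and strand, so it does not occur in practice.
#'
#' @param iv a \code{GRanges} of intervals in the target genome of
#'   \code{chains}.
#' @param chains a \linkS4class{ChainSet} (target -> query direction).
#' @param minMatch minimum aligned fraction in (0, 1] for a successful
#'   mapping; default 0.95 (the liftOver same-species default).
#' @return A data.frame with one row per input interval: columns
#'   \code{chrom}, \code{start0}, \code{end1} (mapped query interval,
#'   0-based half-open; NA unless mapped), \code{strand} (query strand of
#'   the chain used), \code{mapped_fraction}, \code{status}
#'   (\code{"mapped"}/\code{"unmapped"}) and \code{chain_id}.
#' @seealso \code{\link{mappedGRanges}} to extract the mapped rows as a
#'   \code{GRanges}, \code{\link{reciprocalFilter}},
#'   \code{\link{conservedActivity}}.
#' @export
mapInterval <- function(iv, chains, minMatch = 0.95) {
  .checkFraction(minMatch, "minMatch")
  chains <- as.list(chains)
  tNames <- vapply(chains, function(c) c@tName, character(1))
  scores <- vapply(chains, function(c) c@score, numeric(1))
  ids <- vapply(chains, function(c) c@id, integer(1))
  n <- length(iv)
  out <- data.frame(
    chrom = rep(NA_character_, n), start0 = rep(NA_integer_, n),
    end1 = rep(NA_integer_, n), strand = rep(NA_character_, n),
    mapped_fraction = rep(0, n), status = rep("unmapped", n),
    chain_id = rep(NA_integer_, n), stringsAsFactors = FALSE)
  if (!n) return(out)
  ivChrom <- as.character(GenomicRanges::seqnames(iv))
  s0 <- .bedStart(iv)
  e1 <- .bedEnd(iv)
  for (i in seq_len(n)) {
    cand <- which(tNames == ivChrom[i])
    if (!length(cand)) next
    # chains overlapping the interval at all
    ovl <- vapply(cand, function(k)
      chains[[k]]@tStart < e1[i] && chains[[k]]@tEnd > s0[i], logical(1))
    cand <- cand[ovl]
    if (!length(cand)) next
    best <- cand[order(-scores[cand], ids[cand])][1L]
    ch <- chains[[best]]
    b <- ch@blocks
    tb <- ch@tStart + cumsum(c(0, (b[, 1L] + b[, 2L])[-nrow(b)]))
    qb <- ch@qStart + cumsum(c(0, (b[, 1L] + b[, 3L])[-nrow(b)]))
    lo <- pmax(s0[i], tb)
    hi <- pmin(e1[i], tb + b[, 1L])
    cov <- pmax(hi - lo, 0)
    aligned <- sum(cov)
    frac <- aligned / (e1[i] - s0[i])
    out$mapped_fraction[i] <- frac
    out$chain_id[i] <- ch@id
    if (aligned == 0 || frac < minMatch) next
    use <- cov > 0
    qlo <- qb[use] + (lo[use] - tb[use])
    qhi <- qb[use] + (hi[use] - tb[use])
    fwd <- queryToForward(ch, qlo, qhi)
    out$chrom[i] <- ch@qName
    out$start0[i] <- min(fwd[, "start0"])
    out$end1[i] <- max(fwd[, "end1"])
    out$strand[i] <- ch@qStrand
    out$status[i] <- "mapped"
  }
  out
}

#' Extract the successfully mapped rows of a mapInterval result
#'
#' @param mapped the data.frame returned by \code{\link{mapInterval}}.
#' @param mcolsFrom optional \code{GRanges} parallel to the original
#'   input whose metadata columns are carried over.
#' @return A \code{GRanges} of the \code{status == "mapped"} rows, with a
#'   \code{source_index} column pointing back to the input row.
#' @export
mappedGRanges <- function(mapped, mcolsFrom = NULL) {
  ok <- which(mapped$status == "mapped")
  gr <- .grFromBed(mapped$chrom[ok], mapped$start0[ok], mapped$end1[ok],
    mapped$strand[ok])
  gr$source_index <- ok
  gr$mapped_fraction <- mapped$mapped_fraction[ok]
  if (!is.null(mcolsFrom))
    S4Vectors::mcols(gr) <- cbind(S4Vectors::mcols(gr),
      S4Vectors::mcols(mcolsFrom)[ok, , drop = FALSE])
  gr
}

#' Reciprocal liftover filter with the same-nearest-gene rule
#'
#' An element is \emph{alignable} when it maps to the other genome and
#' back (\code{A -> B -> A}, both legs \code{status == "mapped"}) and the
#' round-trip interval has the same nearest gene call, in genome A, as
#' the interval that was lifted.  Both calls are computed on the lifted
#' unit itself (important when 100-bp summit windows are lifted: a
#' window's nearest gene can differ from the full element's), so with
#' mutually inverse chains every fully covered element is kept.
#'
#' @param elements a \code{GRanges} of genome-A elements (any carried
#'   metadata columns, e.g. \code{element_id}, are preserved).
#' @param chainAB,chainBA \linkS4class{ChainSet}s for the two liftover
#'   directions.
#' @param genesA genome-A gene models used for the nearest-gene call.
#' @param minMatch minimum aligned fraction per leg; default 0.95.
#' @return \code{elements} with columns \code{alignable} (logical),
#'   \code{own_gene} (the lifted interval's nearest gene),
#'   \code{mapped_chrom}, \code{mapped_start0}, \code{mapped_end1},
#'   \code{mapped_strand} (the A-in-B coordinates for elements whose
#'   first leg mapped) and \code{roundtrip_gene} added.
#' @export
reciprocalFilter <- function(elements, chainAB, chainBA, genesA,
    minMatch = 0.95) {
  ownGene <- nearestTSS(GenomicRanges::granges(elements),
    genesA)$nearest_gene
  fwd <- mapInterval(elements, chainAB, minMatch)
  elements$mapped_chrom <- fwd$chrom
  elements$mapped_start0 <- fwd$start0
  elements$mapped_end1 <- fwd$end1
  elements$mapped_strand <- fwd$strand
  alignable <- rep(FALSE, length(elements))
  rtGene <- rep(NA_character_, length(elements))
  okF <- which(fwd$status == "mapped")
  if (length(okF)) {
    inB <- .grFromBed(fwd$chrom[okF], fwd$start0[okF], fwd$end1[okF])
    back <- mapInterval(inB, chainBA, minMatch)
    okB <- which(back$status == "mapped")
    if (length(okB)) {
      rt <- .grFromBed(back$chrom[okB], back$start0[okB], back$end1[okB])
      rt <- nearestTSS(rt, genesA)
      rtGene[okF[okB]] <- rt$nearest_gene
      alignable[okF[okB]] <- !is.na(rt$nearest_gene) &
        !is.na(ownGene[okF[okB]]) &
        rt$nearest_gene == ownGene[okF[okB]]
    }
  }
  elements$own_gene <- ownGene
  elements$roundtrip_gene <- rtGene
  elements$alignable <- alignable
  elements
}

#' Call conserved versus species-specific regulatory activity
#'
#' Intersects genome-A elements mapped into genome B with the genome-B
#' elements of each developmental stage.  An element is conserved at a
#' stage when its mapped interval overlaps (>= 1 bp) any same-class
#' element of that stage; matches across classes (e.g. a mapped enhancer
#' over a B promoter) are recorded separately and do not count as
#' conserved activity.  An alignable element conserved at no stage is
#' species-A specific.
#'
#' @param mappedA a \code{GRanges} of genome-A elements in genome-B
#'   coordinates, carrying \code{element_id} and \code{element_class}
#'   (e.g. from \code{\link{mappedGRanges}} after
#'   \code{\link{reciprocalFilter}}).
#' @param elementsBByStage named list (stage -> \code{GRanges} with
#'   \code{element_class}) of genome-B elements.
#' @param classFilter restrict matches to the same element class;
#'   default TRUE.
#' @return A data.frame with one row per mapped element: columns
#'   \code{element_id}, \code{element_class}, one logical
#'   \code{conserved_<stage>} column per stage, \code{cross_class_only}
#'   (overlapped only different-class elements at every stage) and
#'   \code{status} (\code{"conserved"} if conserved at any stage, else
#'   \code{"species_specific"}).
#' @export
conservedActivity <- function(mappedA, elementsBByStage,
    classFilter = TRUE) {
  stopifnot(is.list(elementsBByStage), length(elementsBByStage) >= 1)
  stages <- names(elementsBByStage)
  n <- length(mappedA)
  res <- data.frame(element_id = mappedA$element_id,
    element_class = mappedA$element_class, stringsAsFactors = FALSE)
  anyCons <- rep(FALSE, n)
  anyCross <- rep(FALSE, n)
  for (st in stages) {
    eb <- elementsBByStage[[st]]
    hits <- GenomicRanges::findOverlaps(mappedA, eb,
      ignore.strand = TRUE, minoverlap = 1L)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    same <- mappedA$element_class[q] == eb$element_class[s]
    cons <- rep(FALSE, n)
    if (classFilter) {
      cons[unique(q[same])] <- TRUE
      anyCross[unique(q[!same])] <- TRUE
    } else {
      cons[unique(q)] <- TRUE
    }
    res[[paste0("conserved_", st)]] <- cons
    anyCons <- anyCons | cons
  }
  res$cross_class_only <- anyCross & !anyCons
  res$status <- ifelse(anyCons, "conserved", "species_specific")
  res
}
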