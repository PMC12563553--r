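#' SimulatedGenomePair: two toy genomes with planted regulatory truth
#'
#' Container returned by \code{\link{simulateGenomePair}}: gene models
#' and planted regulatory elements for two genomes (A and B), mutually
#' inverse liftover chains consistent with the planted orthology, and the
#' conserved-segment map the chains were built from.
#'
#' @slot genesA,genesB gene-model \code{GRanges} (TSS positions with
#'   \code{gene_id}, \code{gene_length}, \code{ortholog_id}).
#' @slot elementsA,elementsB planted element \code{GRanges} with
#'   \code{element_id}, \code{true_class} (\code{"promoter"}/
#'   \code{"enhancer"}) and \code{conservation} (\code{"conserved"},
#'   \code{"speciesA_specific"}, \code{"speciesB_specific"}).  Conserved
#'   elements appear in both slots with the same id.
#' @slot chainAB,chainBA \linkS4class{ChainSet}s for the two liftover
#'   directions (B->A is the exact inverse of A->B).
#' @slot orthologs data.frame (\code{gene_a}, \code{gene_b}), one-to-one.
#' @slot segments data.frame describing each conserved segment in both
#'   genomes.
#' @slot seqlenA,seqlenB named chromosome-length vectors.
#' @slot params the generator parameters, for the manifest.
#' @exportClass SimulatedGenomePair
setClass("SimulatedGenomePair",
  representation(
    genesA = "GRanges", genesB = "GRanges",
    elementsA = "GRanges", elementsB = "GRanges",
    chainAB = "ChainSet", chainBA = "ChainSet",
    orthologs = "data.frame", segments = "data.frame",
    seqlenA = "numeric", seqlenB = "numeric", params = "list"))

setMethod("show", "SimulatedGenomePair", function(object) {
  cat(sprintf(
    "SimulatedGenomePair: %d + %d genes, %d + %d planted elements, %d chains/direction\n",
    length(object@genesA), length(object@genesB),
    length(object@elementsA), length(object@elementsB),
    length(object@chainAB)))
  cat(sprintf("  conserved elements: %d; A-specific: %d; B-specific: %d\n",
    sum(object@elementsA$conservation == "conserved"),
    sum(object@elementsA$conservation == "speciesA_specific"),
    sum(object@elementsB$conservation == "speciesB_specific")))
})

#' Accessors for SimulatedGenomePair
#'
#' @param x a \linkS4class{SimulatedGenomePair}.
#' @param species \code{"A"} or \code{"B"}.
#' @param direction \code{"AB"} or \code{"BA"}.
#' @return \code{simGenes}/\code{simElements}: \code{GRanges};
#'   \code{simChains}: a \linkS4class{ChainSet}; \code{simOrthologs}: the
#'   ortholog data.frame; \code{simSeqlen}: named chromosome lengths;
#'   \code{simParams}: generator parameters.
#' @aliases simGenes simElements simChains simOrthologs simSeqlen
#'   simParams
#' @name sim-accessors
#' @export simGenes simElements simChains simOrthologs simSeqlen simParams
NULL

setGeneric("simGenes", function(x, species = "A") standardGeneric("simGenes"))
setGeneric("simElements",
  function(x, species = "A") standardGeneric("simElements"))
setGeneric("simChains",
  function(x, direction = "AB") standardGeneric("simChains"))
setGeneric("simOrthologs", function(x) standardGeneric("simOrthologs"))
setGeneric("simSeqlen", function(x, species = "A") standardGeneric("simSeqlen"))
setGeneric("simParams", function(x) standardGeneric("simParams"))

setMethod("simGenes", "SimulatedGenomePair", function(x, species = "A")
  if (match.arg(species, c("A", "B")) == "A") x@genesA else x@genesB)
setMethod("simElements", "SimulatedGenomePair", function(x, species = "A")
  if (match.arg(species, c("A", "B")) == "A") x@elementsA else x@elementsB)
setMethod("simChains", "SimulatedGenomePair", function(x, direction = "AB")
  if (match.arg(direction, c("AB", "BA")) == "AB") x@chainAB else x@chainBA)
setMethod("simOrthologs", "SimulatedGenomePair", function(x) x@orthologs)
setMethod("simSeqlen", "SimulatedGenomePair", function(x, species = "A")
  if (match.arg(species, c("A", "B")) == "A") x@seqlenA else x@seqlenB)
setMethod("simParams", "SimulatedGenomePair", function(x) x@params)

# project a 0-based half-open genome-A interval through the conserved
# segment table; returns forward-strand B coordinates (NA when the
# interval is not fully inside one conserved segment)
.projectToB <- function(segments, chrom, s0, e1) {
  out <- matrix(NA_integer_, length(s0), 2,
    dimnames = list(NULL, c("start0", "end1")))
  strandB <- rep(NA_character_, length(s0))
  chromB <- rep(NA_character_, length(s0))
  for (i in seq_along(s0)) {
    seg <- segments[segments$chromA == chrom[i] &
      segments$aStart <= s0[i] & segments$aEnd >= e1[i], , drop = FALSE]
    if (!nrow(seg)) next
    seg <- seg[1L, ]
    o1 <- s0[i] - seg$aStart
    o2 <- e1[i] - seg$aStart
    if (seg$flip) {
      segLen <- seg$aEnd - seg$aStart
      out[i, ] <- c(seg$bStartF + (segLen - o2), seg$bStartF + (segLen - o1))
      strandB[i] <- "-"
    } else {
      out[i, ] <- c(seg$bStartF + o1, seg$bStartF + o2)
      strandB[i] <- "+"
    }
    chromB[i] <- seg$chromB
  }
  data.frame(chrom = chromB, start0 = out[, 1L], end1 = out[, 2L],
    strand = strandB, stringsAsFactors = FALSE)
}

#' Simulate a pair of toy genomes with chains and planted elements
#'
#' Builds two genomes related by co-linear conserved segments separated
#' by diverged gaps of independent (indel-bearing) lengths, optionally
#' with one whole-chromosome inversion.  Chain files for both liftover
#' directions are generated directly from the segment map (the B->A set
#' is the exact inverse of A->B), so liftover of any interval inside a
#' conserved segment is exactly invertible.  Genes are placed on a
#' spaced grid; genes inside conserved segments receive one-to-one
#' orthologs at the projected position (strand-flipped on the inverted
#' chromosome), the remainder are lineage-specific.  Regulatory elements
#' are planted at grid sites inside conserved segments: promoters
#' containing the TSS of a conserved gene, enhancers at distal sites.
#' Conserved elements get an exact partner interval in genome B;
#' species-A-specific elements are alignable but absent from B;
#' additional B-specific enhancers occupy otherwise unused B sites.
#'
#' All randomness derives from \code{seed} through named per-component
#' streams, so equal seeds give identical objects.
#'
#' @param seed integer seed.
#' @param nChrom number of chromosomes; default 3.
#' @param chromLen chromosome length (bp) in genome A; default 2.5e6.
#' @param nGenes total genes in genome A; default 200.
#' @param conservedFrac fraction of each chromosome covered by conserved
#'   segments; default 0.7.
#' @param nElements planted genome-A elements; default 500.
#' @param elementConservedFrac fraction of genome-A elements with
#'   conserved activity; default 0.3.
#' @param promoterFrac fraction of genome-A elements that are promoters;
#'   default 0.3 (each promoter needs its own conserved gene).
#' @param nElementsBSpecific extra genome-B-only enhancers; default 100.
#' @param orthologFrac fraction of genes with a one-to-one ortholog;
#'   default 0.9.
#' @param nSegments conserved segments per chromosome; default 4.
#' @param spacing site grid spacing (bp) inside segments; default 6000.
#' @param flip invert the last chromosome in genome B; default TRUE.
#' @return A \linkS4class{SimulatedGenomePair}.
#' @section Errors:
#' If the grid cannot host the requested genes and elements, an error is
#' raised (increase \code{chromLen} or reduce the counts).
#' @examples
#' sim <- simulateGenomePair(seed = 1, nGenes = 40, nElements = 60,
#'   chromLen = 1e6, nElementsBSpecific = 10)
#' sim
#' @export
simulateGenomePair <- function(seed, nChrom = 3L, chromLen = 2.5e6,
    nGenes = 200L, conservedFrac = 0.7, nElements = 500L,
    elementConservedFrac = 0.3, promoterFrac = 0.3,
    nElementsBSpecific = 100L, orthologFrac = 0.9, nSegments = 4L,
    spacing = 6000L, flip = TRUE) {
  .checkFraction(conservedFrac, "conservedFrac")
  .checkFraction(elementConservedFrac, "elementConservedFrac",
    lowerOpen = FALSE)
  .checkFraction(promoterFrac, "promoterFrac", lowerOpen = FALSE)
  .checkFraction(orthologFrac, "orthologFrac", lowerOpen = FALSE)
  params <- as.list(environment())

  # --- segment map and chains -------------------------------------------
  set.seed(.streamSeed(seed, "segments"))
  segLen <- as.integer(conservedFrac * chromLen / nSegments)
  gapBudget <- chromLen - nSegments * segLen
  segRows <- list()
  chainsAB <- list()
  seqlenA <- seqlenB <- stats::setNames(numeric(nChrom), character(nChrom))
  for (ci in seq_len(nChrom)) {
    chromA <- sprintf("chrA%d", ci)
    chromB <- sprintf("chrB%d", ci)
    flipThis <- flip && ci == nChrom
    drawGaps <- function() {
      w <- stats::runif(nSegments + 1L, 0.5, 1.5)
      g <- floor(gapBudget * w / sum(w))
      g[1L] <- g[1L] + (gapBudget - sum(g))
      as.integer(g)
    }
    gapsA <- drawGaps()
    gapsB <- drawGaps()
    aStart <- cumsum(gapsA[seq_len(nSegments)]) +
      (seq_len(nSegments) - 1L) * segLen
    aEnd <- aStart + segLen
    bStartN <- cumsum(gapsB[seq_len(nSegments)]) +
      (seq_len(nSegments) - 1L) * segLen
    bEndN <- bStartN + segLen
    tSize <- as.integer(aEnd[nSegments] + gapsA[nSegments + 1L])
    qSize <- as.integer(bEndN[nSegments] + gapsB[nSegments + 1L])
    seqlenA[ci] <- tSize; names(seqlenA)[ci] <- chromA
    seqlenB[ci] <- qSize; names(seqlenB)[ci] <- chromB
    bStartF <- if (flipThis) qSize - bEndN else bStartN
    segRows[[ci]] <- data.frame(chromA = chromA, chromB = chromB,
      aStart = as.integer(aStart), aEnd = as.integer(aEnd),
      bStartF = as.integer(bStartF),
      bEndF = as.integer(bStartF + segLen), flip = flipThis,
      stringsAsFactors = FALSE)
    dt <- c(aStart[-1L] - aEnd[-nSegments], 0L)
    dq <- c(bStartN[-1L] - bEndN[-nSegments], 0L)
    chainsAB[[ci]] <- ChainAlignment(
      score = 1000 * segLen, id = ci,
      tName = chromA, tSize = tSize, tStrand = "+",
      tStart = as.integer(aStart[1L]), tEnd = as.integer(aEnd[nSegments]),
      qName = chromB, qSize = qSize,
      qStrand = if (flipThis) "-" else "+",
      qStart = as.integer(bStartN[1L]), qEnd = as.integer(bEndN[nSegments]),
      blocks = cbind(size = rep(as.integer(segLen), nSegments),
        dt = as.integer(dt), dq = as.integer(dq)))
  }
  segments <- do.call(rbind, segRows)
  chainAB <- ChainSet(chainsAB)
  chainBA <- ChainSet(lapply(chainsAB, invertChain))

  # --- site grids --------------------------------------------------------
  consSites <- do.call(rbind, lapply(seq_len(nrow(segments)), function(r) {
    s <- segments[r, ]
    pos <- seq(s$aStart + 2000L, s$aEnd - 2000L, by = spacing)
    data.frame(chrom = s$chromA, pos = as.integer(pos),
      stringsAsFactors = FALSE)
  }))
  emptySites <- data.frame(chrom = character(0), pos = integer(0),
    stringsAsFactors = FALSE)
  gapSites <- do.call(rbind, lapply(seq_len(nChrom), function(ci) {
    chromA <- sprintf("chrA%d", ci)
    segs <- segments[segments$chromA == chromA, ]
    gaps <- rbind(c(0L, segs$aStart[1L]),
      cbind(segs$aEnd[-nrow(segs)], segs$aStart[-1L]),
      c(segs$aEnd[nrow(segs)], seqlenA[[chromA]]))
    do.call(rbind, lapply(seq_len(nrow(gaps)), function(g) {
      lo <- gaps[g, 1L] + 2000L
      hi <- gaps[g, 2L] - 2000L
      if (hi - lo < spacing) return(NULL)
      data.frame(chrom = chromA,
        pos = as.integer(seq(lo, hi, by = spacing)),
        stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(gapSites)) gapSites <- emptySites

  nGenesCons <- round(orthologFrac * nGenes)
  nGenesGap <- nGenes - nGenesCons
  nProm <- round(promoterFrac * nElements)
  nEnh <- nElements - nProm
  if (nProm > nGenesCons)
    .stopf("infeasible placement: %d promoters need distinct conserved genes but only %d available",
      nProm, nGenesCons)
  needCons <- nGenesCons + nEnh + nElementsBSpecific
  if (needCons > nrow(consSites))
    .stopf("infeasible placement: %d conserved-segment sites needed, %d available",
      needCons, nrow(consSites))
  if (nGenesGap > nrow(gapSites))
    .stopf("infeasible placement: %d gap sites needed, %d available",
      nGenesGap, nrow(gapSites))

  set.seed(.streamSeed(seed, "placement"))
  consSites <- consSites[sample.int(nrow(consSites)), , drop = FALSE]
  gapSites <- gapSites[sample.int(nrow(gapSites)), , drop = FALSE]
  geneConsIdx <- seq_len(nGenesCons)
  enhIdx <- nGenesCons + seq_len(nEnh)
  bSpecIdx <- nGenesCons + nEnh + seq_len(nElementsBSpecific)

  # --- genes -------------------------------------------------------------
  set.seed(.streamSeed(seed, "genes"))
  gCons <- consSites[geneConsIdx, , drop = FALSE]
  gGap <- gapSites[seq_len(nGenesGap), , drop = FALSE]
  gAll <- rbind(gCons, gGap)
  geneIds <- sprintf("gA%04d", seq_len(nGenes))
  strands <- sample(c("+", "-"), nGenes, replace = TRUE)
  geneLen <- sample(1000:10000, nGenes, replace = TRUE)
  orthoB <- c(sprintf("gB%04d", seq_len(nGenesCons)),
    rep(NA_character_, nGenesGap))
  genesA <- GenomicRanges::GRanges(gAll$chrom,
    IRanges::IRanges(gAll$pos + 1L, width = 1L), strand = strands,
    gene_id = geneIds, gene_length = geneLen, ortholog_id = orthoB)
  projG <- .projectToB(segments, gCons$chrom, gCons$pos, gCons$pos + 1L)
  strandB <- ifelse(projG$strand == "-",
    ifelse(strands[geneConsIdx] == "+", "-", "+"), strands[geneConsIdx])
  genesB <- GenomicRanges::GRanges(projG$chrom,
    IRanges::IRanges(projG$start0 + 1L, width = 1L), strand = strandB,
    gene_id = orthoB[geneConsIdx], gene_length = geneLen[geneConsIdx],
    ortholog_id = geneIds[geneConsIdx])
  orthologs <- data.frame(gene_a = geneIds[geneConsIdx],
    gene_b = orthoB[geneConsIdx], stringsAsFactors = FALSE)

  # --- elements ----------------------------------------------------------
  set.seed(.streamSeed(seed, "elements"))
  nCons <- round(elementConservedFrac * nElements)
  conservation <- sample(c(rep("conserved", nCons),
    rep("speciesA_specific", nElements - nCons)))
  # promoters sit on conserved genes (distinct gene each)
  promGene <- sample(geneConsIdx, nProm)
  promWidth <- sample(800:1600, nProm, replace = TRUE)
  promTss <- gAll$pos[promGene]
  promOff <- vapply(promWidth, function(w) sample(200:(w - 200), 1L),
    integer(1))
  promStart <- promTss - promOff
  enhWidth <- sample(300:800, nEnh, replace = TRUE)
  enhPos <- consSites[enhIdx, , drop = FALSE]
  enhStart <- enhPos$pos - enhWidth %/% 2L
  elemChrom <- c(gAll$chrom[promGene], enhPos$chrom)
  elemStart <- as.integer(c(promStart, enhStart))
  elemEnd <- as.integer(c(promStart + promWidth, enhStart + enhWidth))
  trueClass <- c(rep("promoter", nProm), rep("enhancer", nEnh))
  elemIds <- sprintf("el%04d", seq_len(nElements))
  elementsA <- .grFromBed(elemChrom, elemStart, elemEnd)
  elementsA$element_id <- elemIds
  elementsA$true_class <- trueClass
  elementsA$conservation <- conservation
  elementsA$gene_id <- c(geneIds[promGene], rep(NA_character_, nEnh))

  consEl <- which(conservation == "conserved")
  projE <- .projectToB(segments, elemChrom[consEl], elemStart[consEl],
    elemEnd[consEl])
  if (anyNA(projE$start0))
    .stopf("internal error: conserved element outside a conserved segment")
  bsPos <- consSites[bSpecIdx, , drop = FALSE]
  bsWidth <- sample(300:800, nElementsBSpecific, replace = TRUE)
  bsStartA <- bsPos$pos - bsWidth %/% 2L
  projBS <- .projectToB(segments, bsPos$chrom, bsStartA,
    bsStartA + bsWidth)
  elementsB <- .grFromBed(c(projE$chrom, projBS$chrom),
    c(projE$start0, projBS$start0), c(projE$end1, projBS$end1))
  elementsB$element_id <- c(elemIds[consEl],
    sprintf("elB%04d", seq_len(nElementsBSpecific)))
  elementsB$true_class <- c(trueClass[consEl],
    rep("enhancer", nElementsBSpecific))
  elementsB$conservation <- c(rep("conserved", length(consEl)),
    rep("speciesB_specific", nElementsBSpecific))
  elementsB$gene_id <- NA_character_

  new("SimulatedGenomePair",
    genesA = genesA, genesB = genesB,
    elementsA = elementsA, elementsB = elementsB,
    chainAB = chainAB, chainBA = chainBA,
    orthologs = orthologs, segments = segments,
    seqlenA = seqlenA, seqlenB = seqlenB,
    params = params[!vapply(params, is.null, logical(1))])
}
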