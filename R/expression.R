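#' TPM and CPM normalization
#'
#' Computes transcripts per million
#' (\code{tpm = 1e6 * (count/length) / sum(count/length)}) and counts per
#' million (\code{cpm = 1e6 * count / sum(count)}) per sample.  Both
#' normalizations satisfy the column-sum identity
#' \code{sum_genes(x) == 1e6} exactly (up to floating point).
#'
#' @param counts a gene x sample matrix of non-negative counts, or a
#'   \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{"counts"} assay and a \code{gene_length} rowData column.
#' @param geneLengths gene lengths in bp (ignored for a
#'   SummarizedExperiment input).
#' @return For a matrix input, a list with matrices \code{tpm} and
#'   \code{cpm}; for a SummarizedExperiment, the same object with
#'   \code{tpm} and \code{cpm} assays added.
#' @section Errors:
#' A sample with all-zero counts raises an error naming the sample; a
#' gene with non-positive length is rejected.
#' @examples
#' counts <- matrix(c(100, 100), 2, 1,
#'   dimnames = list(c("a", "b"), "s1"))
#' normalizeExpression(counts, geneLengths = c(1000, 2000))$tpm
#' @export
normalizeExpression <- function(counts, geneLengths = NULL) {
  if (methods::is(counts, "SummarizedExperiment")) {
    se <- counts
    m <- SummarizedExperiment::assay(se, "counts")
    geneLengths <- SummarizedExperiment::rowData(se)$gene_length
    res <- normalizeExpression(m, geneLengths)
    SummarizedExperiment::assays(se)$tpm <- res$tpm
    SummarizedExperiment::assays(se)$cpm <- res$cpm
    return(se)
  }
  counts <- as.matrix(counts)
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (is.null(geneLengths) || length(geneLengths) != nrow(counts))
    .stopf("'geneLengths' must have one entry per gene")
  if (any(geneLengths <= 0)) .stopf("gene lengths must be positive")
  libSize <- colSums(counts)
  if (any(libSize == 0)) {
    nm <- colnames(counts)[libSize == 0][1L]
    .stopf("sample '%s' has all-zero counts",
      if (is.null(nm)) which(libSize == 0)[1L] else nm)
  }
  rate <- counts / geneLengths
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  cpm <- sweep(counts, 2, libSize, "/") * 1e6
  list(tpm = tpm, cpm = cpm)
}

#' Genes reproducibly expressed across replicates
#'
#' A gene is reproducibly expressed when its TPM exceeds \code{threshold}
#' (strictly) in \emph{every} replicate of the given species/stage.
#'
#' @param tpm gene x replicate TPM matrix for one species/stage (>= 2
#'   replicates).
#' @param threshold TPM threshold; default 1 (strict \code{>}).
#' @return Character vector of reproducibly expressed gene ids (rownames
#'   of \code{tpm}).
#' @export
reproduciblyExpressed <- function(tpm, threshold = 1) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) < 2L) .stopf("need at least 2 replicates")
  rownames(tpm)[rowSums(tpm > threshold) == ncol(tpm)]
}

#' Low-expression CPM filter
#'
#' Keeps genes with CPM above \code{threshold} (strictly) in at least
#' \code{minReps} replicates, the standard pre-filter before temporal
#' analysis.
#'
#' @param cpm gene x replicate CPM matrix.
#' @param threshold CPM threshold; default 2.
#' @param minReps minimum number of qualifying replicates; default 2.
#' @return Character vector of retained gene ids.
#' @export
cpmFilter <- function(cpm, threshold = 2, minReps = 2L) {
  cpm <- as.matrix(cpm)
  if (ncol(cpm) < minReps) .stopf("fewer replicates than 'minReps'")
  rownames(cpm)[rowSums(cpm > threshold) >= minReps]
}

#' Genes highly expressed only in species A
#'
#' Selects genes with mean TPM above \code{high} in species A and mean
#' TPM below \code{low} at \emph{every} species-B stage, through a
#' one-to-one ortholog map.  Genes without an ortholog are excluded and
#' counted.
#'
#' @param tpmA gene x replicate TPM matrix for species A (one stage).
#' @param tpmB gene x sample TPM matrix for species B (B gene ids as
#'   rownames).
#' @param stagesB factor/character of length \code{ncol(tpmB)} giving the
#'   stage of each B sample.
#' @param orthologs data.frame with columns \code{gene_a}, \code{gene_b}
#'   (one-to-one).
#' @param high species-A mean TPM threshold; default 10 (strict
#'   \code{>}).
#' @param low species-B per-stage mean TPM bound; default 1 (strict
#'   \code{<}).
#' @return A list: \code{genes} (species-A gene ids),
#'   \code{nMissingOrtholog} (A genes in \code{tpmA} skipped for lack of
#'   an ortholog or of B data).
#' @export
speciesSpecificGenes <- function(tpmA, tpmB, stagesB, orthologs,
    high = 10, low = 1) {
  if (anyDuplicated(orthologs$gene_a) || anyDuplicated(orthologs$gene_b))
    .stopf("ortholog map must be one-to-one")
  tpmA <- as.matrix(tpmA)
  tpmB <- as.matrix(tpmB)
  meanA <- rowMeans(tpmA)
  stagesB <- as.character(stagesB)
  stageMeanB <- vapply(unique(stagesB), function(st)
    rowMeans(tpmB[, stagesB == st, drop = FALSE]),
    numeric(nrow(tpmB)))
  hit <- character(0)
  nMissing <- 0L
  for (g in rownames(tpmA)) {
    gb <- orthologs$gene_b[match(g, orthologs$gene_a)]
    if (is.na(gb) || !gb %in% rownames(tpmB)) {
      nMissing <- nMissing + 1L
      next
    }
    if (meanA[g] > high && all(stageMeanB[gb, ] < low))
      hit <- c(hit, g)
  }
  list(genes = hit, nMissingOrtholog = nMissing)
}

#' Element/gene expression linkage report
#'
#' Summarizes, per element class, the fraction of elements linked to a
#' reproducibly expressed gene, and per expressed gene whether it is
#' linked to an enhancer only, a promoter only, both, or neither.
#'
#' @param elements a \code{GRanges} (or data.frame) with
#'   \code{element_id} and \code{element_class} columns listing every
#'   element under consideration.
#' @param links link table from \code{\link{linkToGenes}}.
#' @param expressedGenes character vector of reproducibly expressed gene
#'   ids.
#' @return A list: \code{elementSummary} data.frame (\code{class},
#'   \code{n}, \code{n_linked_expressed}, \code{fraction}, and
#'   \code{percent} on the 0-100 scale) and \code{geneCategories}
#'   data.frame (\code{gene_id}, \code{category}).
#' @export
elementExpressionReport <- function(elements, links, expressedGenes) {
  ed <- data.frame(element_id = elements$element_id,
    element_class = elements$element_class, stringsAsFactors = FALSE)
  linkedExpr <- links[links$gene_id %in% expressedGenes, , drop = FALSE]
  classes <- sort(unique(ed$element_class))
  elementSummary <- do.call(rbind, lapply(classes, function(cl) {
    ids <- ed$element_id[ed$element_class == cl]
    nle <- sum(ids %in% linkedExpr$element_id)
    data.frame(class = cl, n = length(ids), n_linked_expressed = nle,
      fraction = if (length(ids)) nle / length(ids) else NA_real_,
      percent = if (length(ids)) 100 * nle / length(ids) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  enhG <- unique(links$gene_id[links$element_class == "enhancer"])
  promG <- unique(links$gene_id[links$element_class == "promoter"])
  category <- ifelse(expressedGenes %in% enhG & expressedGenes %in% promG,
    "both", ifelse(expressedGenes %in% enhG, "enhancer_only",
      ifelse(expressedGenes %in% promG, "promoter_only", "neither")))
  list(elementSummary = elementSummary,
    geneCategories = data.frame(gene_id = expressedGenes,
      category = category, stringsAsFactors = FALSE))
}
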