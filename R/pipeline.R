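#' Default pipeline configuration
#'
#' Returns the full threshold set of the pipeline with its documented
#' defaults: \code{min_frac} (replicate overlap fraction, 0.5),
#' \code{recip_frac} (reciprocal mark overlap, 0.5),
#' \code{max_tss_distance} (high-confidence promoter bound, 3000 bp),
#' \code{max_link_distance} (element-gene linking bound, 1 Mbp),
#' \code{min_match} (liftover aligned fraction, 0.95),
#' \code{summit_width} (lifted window, 100 bp), \code{tpm_high} (10),
#' \code{tpm_low} (1), \code{tpm_expressed} (1), \code{cpm} (2),
#' \code{min_reps} (2), \code{logfc} (2), \code{pseudocount} (0.5),
#' \code{k} (5), \code{m} (2), \code{fdr} (0.01), \code{seed} (1).
#'
#' @param ... named overrides of any default.
#' @return Named list of thresholds; overrides are recorded alongside the
#'   defaults in the run manifest written by \code{\link{runPipeline}}.
#' @export
pipelineDefaults <- function(...) {
  def <- list(min_frac = 0.5, recip_frac = 0.5, max_tss_distance = 3000,
    max_link_distance = 1e6, min_match = 0.95, summit_width = 100,
    tpm_high = 10, tpm_low = 1, tpm_expressed = 1, cpm = 2, min_reps = 2,
    logfc = 2, pseudocount = 0.5, k = 5, m = 2, fdr = 0.01, seed = 1)
  ov <- list(...)
  bad <- setdiff(names(ov), names(def))
  if (length(bad)) .stopf("unknown threshold(s): %s",
    paste(bad, collapse = ", "))
  def[names(ov)] <- ov
  attr(def, "overridden") <- names(ov)
  def
}

.readCountsTSV <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
    check.names = FALSE)
  genes <- tab[[1L]]
  lens <- tab[[2L]]
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(m) <- genes
  list(counts = m, gene_length = lens)
}

.writeCountsTSV <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "counts")
  tab <- data.frame(gene_id = rownames(m),
    gene_length = SummarizedExperiment::rowData(se)$gene_length, m,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

.elementsToBed <- function(elements, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(elements)),
    start = .bedStart(elements), end = .bedEnd(elements),
    element_id = elements$element_id, element_class =
      elements$element_class, marks = elements$marks,
    signalValue = elements$signalValue,
    nearest_gene = elements$nearest_gene,
    tss_distance = elements$tss_distance, stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full cross-species comparison pipeline
#'
#' Executes the stage sequence consensus -> classify -> crossmap ->
#' express -> temporal -> enrichment on file inputs, writing plain
#' TSV/BED artifacts per stage plus a JSON run manifest (thresholds with
#' their defaults and overrides, seed, input checksums, per-stage row
#' counts) into \code{outDir}.  Reruns with an identical configuration
#' produce byte-identical outputs.
#'
#' The \code{config} list (or YAML file with the same structure) names
#' the inputs:
#' \preformatted{
#' species_a:
#'   k4_rep1/k4_rep2/k27_rep1/k27_rep2: narrowPeak paths
#'   genes: gene table (TSV or GFF3)
#'   counts: counts TSV (gene_id, gene_length, one column per sample
#'           named <anything>_<stage>_rep<i>)
#' species_b:
#'   stages:                     # named list, one block per stage
#'     E10.5: {k4_rep1: ..., k27_rep2: ...}
#'   genes: ...
#'   counts: ...
#' chains: {ab: ..., ba: ...}
#' thresholds: optional overrides of \code{\link{pipelineDefaults}}
#' }
#' Stage labels for count columns are taken from the sample names
#' (second-to-last underscore field).
#'
#' @param config configuration list or path to a YAML file.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with the principal in-memory results
#'   (elements, conservation calls, expression summaries, clustering,
#'   enrichment tables) and \code{manifest}.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  th <- do.call(pipelineDefaults, if (is.null(config$thresholds))
    list() else config$thresholds)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rowCounts <- list()
  inputFiles <- unlist(config[c("species_a", "species_b", "chains")])
  inputFiles <- inputFiles[file.exists(as.character(inputFiles))]

  consensusOne <- function(paths, label) {
    k4 <- reproduciblePeaks(readNarrowPeak(paths$k4_rep1),
      readNarrowPeak(paths$k4_rep2), th$min_frac)
    k27 <- reproduciblePeaks(readNarrowPeak(paths$k27_rep1),
      readNarrowPeak(paths$k27_rep2), th$min_frac)
    writeNarrowPeak(k4, file.path(outDir,
      sprintf("consensus_%s_H3K4me3.narrowPeak", label)))
    writeNarrowPeak(k27, file.path(outDir,
      sprintf("consensus_%s_H3K27ac.narrowPeak", label)))
    rowCounts[[paste0("consensus_", label)]] <<-
      c(H3K4me3 = length(k4), H3K27ac = length(k27))
    list(k4 = k4, k27 = k27)
  }
  classifyOne <- function(cons, genes, label) {
    el <- classifyElements(cons$k4, cons$k27, th$recip_frac)
    el <- nearestTSS(el, genes)
    parts <- filterPromoters(el, th$max_tss_distance)
    keep <- sort(c(parts$highConfidence,
      parts$other[parts$other$element_class == "enhancer"]),
      ignore.strand = TRUE)
    .elementsToBed(el, file.path(outDir,
      sprintf("elements_%s_all.tsv", label)))
    .elementsToBed(keep, file.path(outDir,
      sprintf("elements_%s.tsv", label)))
    rowCounts[[paste0("classify_", label)]] <<- c(
      promoter = sum(el$element_class == "promoter"),
      high_confidence_promoter =
        length(parts$highConfidence),
      enhancer = sum(el$element_class == "enhancer"),
      ambiguous = sum(el$element_class == "ambiguous"))
    keep
  }

  # --- consensus + classify ---------------------------------------------
  consA <- .stage("consensus", consensusOne(config$species_a, "A"))
  genesA <- .stage("classify", readGeneModels(config$species_a$genes))
  elemsA <- .stage("classify", classifyOne(consA, genesA, "A"))
  stagesB <- names(config$species_b$stages)
  genesB <- .stage("classify", readGeneModels(config$species_b$genes))
  elemsB <- list()
  for (st in stagesB) {
    consB <- .stage("consensus",
      consensusOne(config$species_b$stages[[st]], paste0("B_", st)))
    elemsB[[st]] <- .stage("classify",
      classifyOne(consB, genesB, paste0("B_", st)))
  }

  # --- crossmap ----------------------------------------------------------
  cross <- .stage("crossmap", {
    chainAB <- readChain(config$chains$ab)
    chainBA <- readChain(config$chains$ba)
    win <- summitWindow(elemsA, th$summit_width)
    win <- reciprocalFilter(win, chainAB, chainBA, genesA, th$min_match)
    alignable <- win[win$alignable]
    mappedB <- .grFromBed(alignable$mapped_chrom,
      alignable$mapped_start0, alignable$mapped_end1)
    S4Vectors::mcols(mappedB) <- S4Vectors::mcols(alignable)
    calls <- conservedActivity(mappedB, elemsB)
    unal <- win[!win$alignable]
    .writeTSV(data.frame(
      chrom = as.character(GenomicRanges::seqnames(unal)),
      start = .bedStart(unal), end = .bedEnd(unal),
      element_id = unal$element_id, stringsAsFactors = FALSE),
      file.path(outDir, "crossmap_unalignable.tsv"))
    .writeTSV(calls, file.path(outDir, "crossmap_conservation.tsv"))
    rowCounts[["crossmap"]] <- c(alignable = length(alignable),
      unalignable = length(unal),
      conserved = sum(calls$status == "conserved"),
      species_specific = sum(calls$status == "species_specific"))
    list(calls = calls, alignable = alignable)
  })

  # --- express -----------------------------------------------------------
  expr <- .stage("express", {
    parseStages <- function(m) {
      f <- strsplit(colnames(m), "_", fixed = TRUE)
      vapply(f, function(x) x[length(x) - 1L], character(1))
    }
    rawA <- .readCountsTSV(config$species_a$counts)
    rawB <- .readCountsTSV(config$species_b$counts)
    normA <- normalizeExpression(rawA$counts, rawA$gene_length)
    normB <- normalizeExpression(rawB$counts, rawB$gene_length)
    stagesOfB <- parseStages(rawB$counts)
    exprA <- reproduciblyExpressed(normA$tpm, th$tpm_expressed)
    orth <- data.frame(gene_a = genesA$gene_id,
      gene_b = genesA$ortholog_id, stringsAsFactors = FALSE)
    orth <- orth[!is.na(orth$gene_b), , drop = FALSE]
    spec <- speciesSpecificGenes(normA$tpm, normB$tpm, stagesOfB, orth,
      th$tpm_high, th$tpm_low)
    links <- linkToGenes(elemsA, genesA, th$max_link_distance)
    report <- elementExpressionReport(elemsA, links, exprA)
    .writeTSV(report$elementSummary,
      file.path(outDir, "expression_element_summary.tsv"))
    .writeTSV(report$geneCategories,
      file.path(outDir, "expression_gene_categories.tsv"))
    .writeTSV(data.frame(gene_id = spec$genes, stringsAsFactors = FALSE),
      file.path(outDir, "expression_species_specific_genes.tsv"))
    rowCounts[["express"]] <- c(expressed_A = length(exprA),
      species_specific = length(spec$genes), links = nrow(links))
    list(normA = normA, normB = normB, stagesOfB = stagesOfB,
      expressedA = exprA, speciesSpecific = spec, links = links,
      report = report, orthologs = orth)
  })

  # --- temporal ----------------------------------------------------------
  temporal <- .stage("temporal", {
    cpmB <- expr$normB$cpm
    keep <- cpmFilter(cpmB, th$cpm, th$min_reps)
    dyn <- dynamicGenes(cpmB[keep, , drop = FALSE], expr$stagesOfB,
      th$logfc, th$pseudocount)
    stageLev <- unique(expr$stagesOfB)
    stageMean <- vapply(stageLev, function(st)
      rowMeans(log2(cpmB[dyn, expr$stagesOfB == st, drop = FALSE] +
        th$pseudocount)), numeric(length(dyn)))
    z <- zScale(stageMean)
    cl <- fuzzyCMeans(z, k = th$k, m = th$m, seed = th$seed)
    rep <- clusterReport(cl)
    .writeTSV(rep$genes, file.path(outDir, "temporal_membership.tsv"))
    .writeTSV(data.frame(cluster = rownames(rep$centers), rep$centers,
      check.names = FALSE), file.path(outDir, "temporal_centers.tsv"))
    rowCounts[["temporal"]] <- c(cpm_filtered = length(keep),
      dynamic = length(dyn))
    list(dynamic = dyn, clustering = cl, report = rep)
  })

  # --- enrichment --------------------------------------------------------
  enrich <- .stage("enrichment", {
    clusters <- split(temporal$report$genes$gene_id,
      temporal$report$genes$cluster)
    names(clusters) <- paste0("cluster_", names(clusters))
    universe <- temporal$report$genes$gene_id
    exprAinB <- expr$orthologs$gene_b[
      expr$orthologs$gene_a %in% expr$expressedA]
    qs <- intersect(exprAinB, universe)
    # a degenerate 2x2 (empty or exhaustive gene set) carries no signal
    clEnrich <- if (length(qs) > 0 && length(qs) < length(universe))
      clusterEnrichment(qs, clusters, universe) else NULL
    if (!is.null(clEnrich))
      .writeTSV(clEnrich, file.path(outDir, "enrichment_clusters.tsv"))
    geneSets <- c(
      list(A_near_elements = unique(expr$links$gene_id)),
      lapply(elemsB, function(e) {
        l <- linkToGenes(nearestTSS(e, genesB), genesB,
          th$max_link_distance)
        unique(l$gene_id)
      }))
    names(geneSets) <- c("A", paste0("B_", names(elemsB)))
    inter <- setIntersections(geneSets)
    .writeTSV(inter, file.path(outDir, "enrichment_intersections.tsv"))
    rowCounts[["enrichment"]] <- c(
      cluster_tests = if (is.null(clEnrich)) 0L else nrow(clEnrich),
      intersections = nrow(inter))
    list(clusterEnrichment = clEnrich, intersections = inter)
  })

  manifest <- list(
    package = "regcompare",
    version = as.character(utils::packageVersion("regcompare")),
    thresholds = th[],
    overridden = attr(th, "overridden"),
    seed = th$seed,
    inputs = as.list(tools::md5sum(as.character(inputFiles))),
    row_counts = lapply(rowCounts, as.list))
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(elementsA = elemsA, elementsB = elemsB,
    conservation = cross$calls, expression = expr, temporal = temporal,
    enrichment = enrich, manifest = manifest))
}
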