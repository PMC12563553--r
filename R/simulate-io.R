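#' Write a simulated data set to disk in the pipeline's input formats
#'
#' Serializes a \linkS4class{SimulatedGenomePair} plus its peak and
#' expression simulations into the exact file formats the pipeline
#' consumes (narrowPeak, 6-column gene TSV, UCSC chain, counts TSV), a
#' truth manifest TSV per component, and returns a ready-to-run
#' \code{\link{runPipeline}} configuration list.
#'
#' @param sim a \linkS4class{SimulatedGenomePair}.
#' @param peaks result of \code{\link{simulatePeakReplicates}}.
#' @param expr result of \code{\link{simulateExpression}}.
#' @param dir output directory (created if needed).
#' @return The configuration list (paths + empty threshold overrides).
#' @export
writeSimulatedInputs <- function(sim, peaks, expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))
  cfgA <- list()
  for (mk in names(peaks$A)) {
    for (r in names(peaks$A[[mk]])) {
      key <- sprintf("%s_%s", if (mk == "H3K4me3") "k4" else "k27", r)
      path <- p("A_", mk, "_", r, ".narrowPeak")
      writeNarrowPeak(peaks$A[[mk]][[r]], path)
      cfgA[[key]] <- path
    }
  }
  stages <- list()
  for (st in names(peaks$B)) {
    blk <- list()
    for (mk in names(peaks$B[[st]])) {
      for (r in names(peaks$B[[st]][[mk]])) {
        key <- sprintf("%s_%s", if (mk == "H3K4me3") "k4" else "k27", r)
        path <- p("B_", st, "_", mk, "_", r, ".narrowPeak")
        writeNarrowPeak(peaks$B[[st]][[mk]][[r]], path)
        blk[[key]] <- path
      }
    }
    stages[[st]] <- blk
  }
  writeGeneModels(sim@genesA, p("genes_A.tsv"))
  writeGeneModels(sim@genesB, p("genes_B.tsv"))
  writeChain(sim@chainAB, p("chain_AB.chain"))
  writeChain(sim@chainBA, p("chain_BA.chain"))
  .writeCountsTSV(expr$A, p("counts_A.tsv"))
  .writeCountsTSV(expr$B, p("counts_B.tsv"))
  # truth manifests
  truthEl <- function(gr, species) data.frame(
    element_id = gr$element_id, species = species,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = .bedStart(gr), end = .bedEnd(gr),
    true_class = gr$true_class, conservation = gr$conservation,
    stringsAsFactors = FALSE)
  .writeTSV(rbind(truthEl(sim@elementsA, "A"), truthEl(sim@elementsB, "B")),
    p("truth_elements.tsv"))
  .writeTSV(expr$geneTruth, p("truth_genes.tsv"))
  .writeTSV(peaks$emission, p("truth_peak_emission.tsv"))
  c(
    list(species_a = c(cfgA, list(genes = p("genes_A.tsv"),
        counts = p("counts_A.tsv"))),
      species_b = list(stages = stages, genes = p("genes_B.tsv"),
        counts = p("counts_B.tsv")),
      chains = list(ab = p("chain_AB.chain"), ba = p("chain_BA.chain"))))
}
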