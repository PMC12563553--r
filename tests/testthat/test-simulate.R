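smallSim <- function(seed = 2, ...) simulateGenomePair(seed = seed,
  nGenes = 40, nElements = 60, chromLen = 1e6, nElementsBSpecific = 10,
  ...)

test_that("equal seeds give byte-identical serialized outputs", {
  sim1 <- smallSim()
  sim2 <- smallSim()
  pk1 <- simulatePeakReplicates(sim1, seed = 2)
  pk2 <- simulatePeakReplicates(sim2, seed = 2)
  ex1 <- simulateExpression(sim1, seed = 2)
  ex2 <- simulateExpression(sim2, seed = 2)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  writeSimulatedInputs(sim1, pk1, ex1, d1)
  writeSimulatedInputs(sim2, pk2, ex2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
      readLines(file.path(d2, f)), info = f)
  }
  # different seed changes the data
  sim3 <- smallSim(seed = 3)
  expect_false(identical(start(simElements(sim1, "A")),
    start(simElements(sim3, "A"))))
})

test_that("generated chains parse, validate and are reciprocal", {
  sim <- smallSim()
  f <- tempfile()
  writeChain(simChains(sim, "AB"), f)
  cs <- readChain(f)          # validity runs per chain
  expect_length(cs, 3)
  # A -> B -> A is the identity for intervals inside conserved segments
  seg <- sim@segments[1, ]
  iv <- GRanges(seg$chromA, IRanges(seg$aStart + 101, seg$aStart + 300))
  fwd <- mapInterval(iv, simChains(sim, "AB"))
  expect_equal(fwd$status, "mapped")
  back <- mapInterval(GRanges(fwd$chrom, IRanges(fwd$start0 + 1,
    fwd$end1)), simChains(sim, "BA"))
  expect_equal(back$start0, seg$aStart + 100)
})

test_that("conservedFrac = 1 with one segment gives an identity chain", {
  sim <- simulateGenomePair(seed = 4, nGenes = 30, nElements = 40,
    chromLen = 1e6, nElementsBSpecific = 5, conservedFrac = 1,
    orthologFrac = 1, nSegments = 1, flip = FALSE)
  ch <- simChains(sim, "AB")[[1]]
  expect_equal(nrow(chainBlocks(ch)), 1L)
  expect_equal(ch@tStart, 0L)
  expect_equal(ch@tEnd, ch@tSize)
  iv <- GRanges("chrA1", IRanges(5001, 6000))
  m <- mapInterval(iv, simChains(sim, "AB"))
  expect_equal(m$start0, 5000)
  expect_equal(m$end1, 6000)
})

test_that("intervals in diverged gaps fail to lift over", {
  sim <- smallSim()
  # the region before the first conserved segment is unaligned
  seg1 <- sim@segments[sim@segments$chromA == "chrA1", ][1, ]
  iv <- GRanges("chrA1", IRanges(1, min(200, seg1$aStart - 1)))
  m <- mapInterval(iv, simChains(sim, "AB"))
  expect_equal(m$status, "unmapped")
  expect_equal(m$mapped_fraction, 0)
})

test_that("planted fractions and orthology invariants hold", {
  sim <- smallSim()
  elA <- simElements(sim, "A")
  expect_equal(length(elA), 60L)
  expect_equal(sum(elA$conservation == "conserved"),
    round(0.3 * 60))
  expect_equal(sum(elA$true_class == "promoter"), round(0.3 * 60))
  orth <- simOrthologs(sim)
  expect_false(anyDuplicated(orth$gene_a) > 0)
  expect_false(anyDuplicated(orth$gene_b) > 0)
  expect_equal(nrow(orth), round(0.9 * 40))
  # every conserved element has a same-id partner interval in B
  consA <- elA[elA$conservation == "conserved"]
  elB <- simElements(sim, "B")
  expect_true(all(consA$element_id %in% elB$element_id))
  # partner intervals have equal widths (projection is rigid)
  m <- match(consA$element_id, elB$element_id)
  expect_equal(width(consA), width(elB[m]))
})

test_that("zero jitter and dropout reproduce the planted intervals", {
  sim <- smallSim()
  pk <- simulatePeakReplicates(sim, jitterSd = 0, dropout = 0, seed = 2)
  elA <- simElements(sim, "A")
  k27 <- pk$A$H3K27ac$rep1
  expect_equal(length(k27), length(elA))
  expect_equal(start(k27), start(elA))
  expect_equal(end(k27), end(elA))
  expect_equal(as.character(seqnames(k27)), as.character(seqnames(elA)))
  k4 <- pk$A$H3K4me3$rep1
  expect_equal(length(k4), sum(elA$true_class == "promoter"))
  expect_error(simulatePeakReplicates(sim, dropout = 1, seed = 1),
    "dropout")
  expect_error(simulatePeakReplicates(sim, jitterSd = -1, seed = 1),
    "jitterSd")
})

test_that("dropout thins replicates at the requested rate", {
  sim <- simulateGenomePair(seed = 6, nGenes = 200, nElements = 300,
    chromLen = 4e6, nElementsBSpecific = 10)
  pk <- simulatePeakReplicates(sim, jitterSd = 0, dropout = 0.2, seed = 6)
  em <- pk$emission
  rate <- 1 - mean(em$emitted)
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(em)) + 0.01)
})

test_that("near-zero dispersion counts approach the Poisson limit", {
  sim <- smallSim()
  ex <- simulateExpression(sim, dispersion = 0, reps = 2, seed = 2)
  cnt <- SummarizedExperiment::assay(ex$A, "counts")
  mu <- rowMeans(cnt)
  keep <- mu > 50
  cv2 <- apply(cnt[keep, ], 1, var) / mu[keep]^2
  # Poisson: CV^2 ~ 1/mu; check the median ratio is near 1
  expect_lt(median(cv2 * mu[keep]), 3)
})

test_that("planted flat profiles are excluded by the fold-change filter", {
  sim <- smallSim()
  ex <- simulateExpression(sim, dispersion = 0.05, seed = 2)
  norm <- normalizeExpression(ex$B)
  cpm <- SummarizedExperiment::assay(norm, "cpm")
  stages <- SummarizedExperiment::colData(ex$B)$stage
  dyn <- dynamicGenes(cpm, stages)
  truth <- ex$geneTruth[ex$geneTruth$species == "B", ]
  planted <- truth$gene_id[!is.na(truth$cluster)]
  flat <- setdiff(truth$gene_id, planted)
  expect_lt(mean(flat %in% dyn), 0.02)     # flat genes stay out
  expect_gt(mean(planted %in% dyn), 0.95)  # planted dynamics get in
})
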