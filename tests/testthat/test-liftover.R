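identityChain <- function(len = 1000L, t = "chrA", q = "chrB", id = 1L) {
  ChainSet(list(ChainAlignment(score = 100, id = id, tName = t,
    tSize = len, tStart = 0L, tEnd = len, qName = q, qSize = len,
    qStrand = "+", qStart = 0L, qEnd = len,
    blocks = cbind(size = len, dt = 0L, dq = 0L))))
}

test_that("a gap inside the interval lowers the aligned fraction", {
  # blocks (50, dt=50), (200): interval [100,200) covers 50 aligned bases
  ch <- ChainSet(list(ChainAlignment(score = 10, id = 1L,
    tName = "chrA", tSize = 1000L, tStart = 50L, tEnd = 350L,
    qName = "chrB", qSize = 1000L, qStrand = "+", qStart = 0L,
    qEnd = 250L, blocks = cbind(size = c(50L, 200L), dt = c(50L, 0L),
      dq = c(0L, 0L)))))
  m <- mapInterval(GRanges("chrA", IRanges(101, 200)), ch,
    minMatch = 0.95)
  expect_equal(m$status, "unmapped")
  expect_equal(m$mapped_fraction, 0.5)
  # lowering minMatch below the aligned fraction maps it
  m2 <- mapInterval(GRanges("chrA", IRanges(101, 200)), ch,
    minMatch = 0.4)
  expect_equal(m2$status, "mapped")
})

test_that("mapInterval equals the base-by-base projector on synthetic chains", {
  sim <- simulateGenomePair(seed = 5, nGenes = 30, nElements = 40,
    chromLen = 1e6, nElementsBSpecific = 5)
  chains <- simChains(sim, "AB")
  set.seed(99)
  for (rep in 1:20) {
    chrom <- sprintf("chrA%d", sample(3, 1))
    s0 <- sample.int(simSeqlen(sim, "A")[[chrom]] - 500L, 1)
    e1 <- s0 + sample(50:400, 1)
    got <- mapInterval(GRanges(chrom, IRanges(s0 + 1, e1)), chains,
      minMatch = 0.9)
    want <- bfProject(chrom, s0, e1, chains, 0.9)
    expect_equal(got$status, want$status)
    expect_equal(got$mapped_fraction, want$frac, tolerance = 1e-12)
    if (want$status == "mapped") {
      expect_equal(got$chrom, want$chrom)
      expect_equal(got$start0, want$start0)
      expect_equal(got$end1, want$end1)
    }
  }
})

test_that("round trip through mutually inverse chains is the identity", {
  sim <- simulateGenomePair(seed = 5, nGenes = 30, nElements = 40,
    chromLen = 1e6, nElementsBSpecific = 5)
  el <- simElements(sim, "A")
  fwd <- mapInterval(el, simChains(sim, "AB"), minMatch = 1)
  ok <- fwd$status == "mapped"
  expect_gt(sum(ok), 0)
  back <- mapInterval(GRanges(fwd$chrom[ok],
    IRanges(fwd$start0[ok] + 1, fwd$end1[ok])), simChains(sim, "BA"),
    minMatch = 1)
  expect_true(all(back$status == "mapped"))
  expect_equal(back$chrom,
    as.character(seqnames(el))[ok])
  expect_equal(back$start0, start(el)[ok] - 1L)
  expect_equal(back$end1, end(el)[ok])
})

test_that("inverting a chain twice returns the original", {
  sim <- simulateGenomePair(seed = 5, nGenes = 30, nElements = 40,
    chromLen = 1e6, nElementsBSpecific = 5, flip = TRUE)
  for (ch in as.list(simChains(sim, "AB"))) {
    twice <- invertChain(invertChain(ch))
    expect_equal(chainBlocks(twice), chainBlocks(ch))
    expect_equal(twice@tStart, ch@tStart)
    expect_equal(twice@qStart, ch@qStart)
    expect_equal(twice@qStrand, ch@qStrand)
  }
})

test_that("higher-scoring chains win, ties broken by chain id", {
  mk <- function(score, id, qoff) ChainAlignment(score = score, id = id,
    tName = "chrA", tSize = 1000L, tStart = 0L, tEnd = 500L,
    qName = "chrB", qSize = 2000L, qStrand = "+", qStart = qoff,
    qEnd = qoff + 500L, blocks = cbind(size = 500L, dt = 0L, dq = 0L))
  cs <- ChainSet(list(mk(10, 2L, 0L), mk(99, 3L, 600L), mk(99, 1L, 1200L)))
  m <- mapInterval(GRanges("chrA", IRanges(1, 100)), cs)
  expect_equal(m$chain_id, 1L)      # highest score, smallest id
  expect_equal(m$start0, 1200)
})

test_that("reciprocal filter keeps identity-mapped elements, drops deletions and rearrangements", {
  genes <- GRanges("chrA", IRanges(c(101, 5001), width = 1),
    strand = "+", gene_id = c("g1", "g2"), gene_length = 1000L,
    ortholog_id = NA_character_)
  el <- GRanges("chrA", IRanges(121, 220), element_id = "e1",
    element_class = "enhancer")
  el <- nearestTSS(el, genes)

  idAB <- identityChain(10000L, "chrA", "chrB")
  idBA <- identityChain(10000L, "chrB", "chrA")
  r <- reciprocalFilter(el, idAB, idBA, genes)
  expect_true(r$alignable)

  # chain pair deleting the element's locus in B -> unmapped -> dropped
  delAB <- ChainSet(list(ChainAlignment(score = 1, id = 1L,
    tName = "chrA", tSize = 10000L, tStart = 1000L, tEnd = 10000L,
    qName = "chrB", qSize = 9000L, qStrand = "+", qStart = 0L,
    qEnd = 9000L, blocks = cbind(size = 9000L, dt = 0L, dq = 0L))))
  r <- reciprocalFilter(el, delAB, idBA, genes)
  expect_false(r$alignable)

  # rearranged return leg: round trip lands near g2 -> dropped
  shiftBA <- ChainSet(list(ChainAlignment(score = 1, id = 1L,
    tName = "chrB", tSize = 10000L, tStart = 0L, tEnd = 5000L,
    qName = "chrA", qSize = 10000L, qStrand = "+", qStart = 4900L,
    qEnd = 9900L, blocks = cbind(size = 5000L, dt = 0L, dq = 0L))))
  r <- reciprocalFilter(el, idAB, shiftBA, genes)
  expect_false(r$alignable)
  expect_equal(r$roundtrip_gene, "g2")
})

test_that("lowering minMatch never decreases the alignable count", {
  sim <- simulateGenomePair(seed = 9, nGenes = 40, nElements = 60,
    chromLen = 1e6, nElementsBSpecific = 5)
  el <- nearestTSS(simElements(sim, "A"), simGenes(sim, "A"))
  counts <- vapply(c(1, 0.95, 0.5, 0.1), function(mm)
    sum(reciprocalFilter(el, simChains(sim, "AB"), simChains(sim, "BA"),
      simGenes(sim, "A"), mm)$alignable), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("conserved activity calls follow same-class >= 1 bp overlap", {
  mapped <- GRanges("chrB1", IRanges(c(1001, 9001), width = 100),
    element_id = c("e1", "e2"), element_class = "enhancer")
  eb <- GRanges("chrB1", IRanges(1001, width = 100),
    element_class = "enhancer")
  calls <- conservedActivity(mapped, list(S1 = eb))
  expect_equal(calls$status, c("conserved", "species_specific"))

  # cross-class overlap is recorded but not conserved
  ebP <- GRanges("chrB1", IRanges(1001, width = 100),
    element_class = "promoter")
  calls <- conservedActivity(mapped, list(S1 = ebP))
  expect_equal(calls$status[1], "species_specific")
  expect_true(calls$cross_class_only[1])

  # partition: every element gets exactly one status
  expect_true(all(calls$status %in% c("conserved", "species_specific")))
})

test_that("planted conservation labels are recovered exactly at zero jitter", {
  sim <- simulateGenomePair(seed = 13, nGenes = 60, nElements = 80,
    chromLen = 1.5e6, nElementsBSpecific = 10)
  pk <- simulatePeakReplicates(sim, jitterSd = 0, dropout = 0, seed = 13)
  el <- nearestTSS(classifyElements(
    reproduciblePeaks(pk$A$H3K4me3$rep1, pk$A$H3K4me3$rep2),
    reproduciblePeaks(pk$A$H3K27ac$rep1, pk$A$H3K27ac$rep2)),
    simGenes(sim, "A"))
  rf <- reciprocalFilter(summitWindow(el, 100), simChains(sim, "AB"),
    simChains(sim, "BA"), simGenes(sim, "A"))
  expect_true(all(rf$alignable))
  al <- rf[rf$alignable]
  mB <- GRanges(al$mapped_chrom, IRanges(al$mapped_start0 + 1,
    al$mapped_end1))
  mcols(mB) <- mcols(al)
  elB <- classifyElements(
    reproduciblePeaks(pk$B$S1$H3K4me3$rep1, pk$B$S1$H3K4me3$rep2),
    reproduciblePeaks(pk$B$S1$H3K27ac$rep1, pk$B$S1$H3K27ac$rep2))
  calls <- conservedActivity(mB, list(S1 = elB))
  ev <- evaluateRecovery(sim, pk$emission, el, calls)
  expect_equal(ev$classAccuracy, 1)
  expect_equal(ev$conservationAccuracy, 1)
  expect_equal(ev$detectionRate, 1)
  expect_equal(ev$unconditionalAccuracy, 1)
})
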