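mkPeaks <- function(start0, end1, chrom = "chr1", fold = 1) {
  gr <- GRanges(rep(chrom, length(start0)),
    IRanges(start0 + 1L, end1))
  gr$signalValue <- rep(fold, length(start0))
  gr$peak <- as.integer((end1 - start0) %/% 2L)
  gr
}

test_that("mark co-occupancy rules classify the worked examples", {
  # lone K27 peak -> enhancer
  el <- classifyElements(mkPeaks(integer(0), integer(0)),
    mkPeaks(100, 300))
  expect_equal(el$element_class, "enhancer")
  expect_equal(c(start(el) - 1L, end(el)), c(100L, 300L))

  # K4 [100,300) + K27 [150,350): overlap 150 = 75% of each -> merged
  el <- classifyElements(mkPeaks(100, 300), mkPeaks(150, 350))
  expect_equal(el$element_class, "promoter")
  expect_equal(el$marks, "H3K4me3,H3K27ac")
  expect_equal(c(start(el) - 1L, end(el)), c(100L, 350L))

  # K4 [0,1000) + K27 [900,1000): 10% of K4 -> both ambiguous
  el <- classifyElements(mkPeaks(0, 1000), mkPeaks(900, 1000))
  expect_equal(sort(el$element_class), c("ambiguous", "ambiguous"))

  # reciprocal test is inclusive at exactly 50%
  el <- classifyElements(mkPeaks(0, 100), mkPeaks(50, 150))
  expect_equal(el$element_class, "promoter")
})

test_that("no peak is lost or double-counted in classification", {
  set.seed(5)
  for (rep in 1:10) {
    k4 <- randomPeaksDF(30)
    k27 <- randomPeaksDF(30)
    el <- classifyElements(dfToGR(k4), dfToGR(k27))
    expect_equal(sum(el$n_k4), 30L)
    expect_equal(sum(el$n_k27), 30L)
  }
})

test_that("classification matches the brute-force oracle on random fixtures", {
  set.seed(21)
  for (rep in 1:15) {
    k4 <- randomPeaksDF(sample(15:50, 1))
    k27 <- randomPeaksDF(sample(15:50, 1))
    for (f in c(0.25, 0.5, 0.75)) {
      got <- elementsToDF(classifyElements(dfToGR(k4), dfToGR(k27), f))
      want <- bfClassify(k4, k27, f)
      rownames(want) <- NULL
      expect_equal(got, want, info = sprintf("rep %d frac %.2f", rep, f))
    }
  }
})

mkGenes <- function(tss0, strand = "+", ids = NULL, chrom = "chr1") {
  GRanges(chrom, IRanges(tss0 + 1L, width = 1L), strand = strand,
    gene_id = if (is.null(ids)) sprintf("g%02d", seq_along(tss0)) else ids,
    gene_length = 1000L, ortholog_id = NA_character_)
}

test_that("nearest TSS distances are signed along the gene strand", {
  el <- GRanges("chr1", IRanges(101, 200))  # [100, 200)

  # TSS inside -> 0
  r <- nearestTSS(el, mkGenes(150))
  expect_equal(r$tss_distance, 0L)

  # TSS at 500, + strand: element 5' of TSS -> +300
  r <- nearestTSS(el, mkGenes(500))
  expect_equal(r$tss_distance, 300L)
  # same TSS on - strand: element is 3' of the TSS -> -300
  r <- nearestTSS(el, mkGenes(500, "-"))
  expect_equal(r$tss_distance, -300L)
  # TSS at 50 upstream-left, + strand: TSS 5' of element -> -50
  r <- nearestTSS(el, mkGenes(50))
  expect_equal(r$tss_distance, -50L)

  # equidistant tie (300 bp either side) broken by smallest gene id
  r <- nearestTSS(el, mkGenes(c(500, -200), ids = c("gB", "gA")))
  expect_equal(r$nearest_gene, "gA")

  # no gene on the chromosome -> NA
  r <- nearestTSS(el, mkGenes(100, chrom = "chr9"))
  expect_true(is.na(r$nearest_gene))
})

test_that("promoter distance filter partitions exhaustively at <= 3 kb", {
  d <- c(0L, 10L, 2999L, 3000L, 3001L, 10000L, -3000L, -5000L)
  el <- GRanges("chr1", IRanges(seq_along(d) * 10000, width = 100),
    element_id = sprintf("e%d", seq_along(d)),
    element_class = "promoter", nearest_gene = "g1", tss_distance = d)
  parts <- filterPromoters(el)
  expect_equal(parts$highConfidence$element_id,
    c("e1", "e2", "e3", "e4", "e7"))  # boundary 3000 kept (<= rule)
  expect_equal(parts$distal$element_id, c("e5", "e6", "e8"))
  expect_length(parts$other, 0)
  expect_equal(length(parts$highConfidence) + length(parts$distal) +
    length(parts$other), length(el))
})

test_that("gene linking matches a brute-force nearest-gene scan", {
  set.seed(31)
  genes <- mkGenes(sort(sample.int(3e6, 25)))
  el <- GRanges("chr1",
    IRanges(sort(sample.int(3e6, 30)), width = 200),
    element_id = sprintf("e%02d", 1:30),
    element_class = sample(c("enhancer", "promoter"), 30, TRUE))
  el <- nearestTSS(el, genes)
  links <- linkToGenes(el, genes, maxLinkDistance = 5e5)
  # brute force: per element, nearest TSS by edge distance
  for (i in seq_along(el)) {
    s0 <- start(el)[i] - 1L; e1 <- end(el)[i]
    tss <- start(genes) - 1L
    d <- ifelse(tss >= s0 & tss < e1, 0L,
      ifelse(tss >= e1, tss - e1, s0 - tss))
    j <- which.min(d)
    inLinks <- el$element_id[i] %in% links$element_id
    expect_equal(inLinks, d[j] <= 5e5)
    if (inLinks)
      expect_equal(links$gene_id[links$element_id == el$element_id[i]],
        genes$gene_id[j])
  }
  # 2 Mb away -> unlinked
  far <- nearestTSS(GRanges("chr1", IRanges(6e6, width = 100),
    element_id = "far", element_class = "enhancer"), genes)
  expect_equal(nrow(linkToGenes(far, genes)), 0L)
})
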