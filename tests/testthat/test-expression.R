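test_that("TPM follows the closed-form definition", {
  counts <- matrix(c(100, 100), 2, 1, dimnames = list(c("a", "b"), "s1"))
  r <- normalizeExpression(counts, geneLengths = c(1000, 1000))
  expect_equal(unname(r$tpm[, 1]), c(5e5, 5e5))

  r <- normalizeExpression(counts, geneLengths = c(1000, 2000))
  expect_equal(unname(r$tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(unname(r$cpm[, 1]), c(5e5, 5e5))
})

test_that("TPM and CPM column sums are 1e6 on random matrices", {
  set.seed(3)
  counts <- matrix(rpois(5000, 50), 1000, 5)
  counts[sample(5000, 500)] <- 0
  r <- normalizeExpression(counts, geneLengths = sample(500:5000, 1000))
  expect_equal(unname(colSums(r$tpm)), rep(1e6, 5), tolerance = 1e-6)
  expect_equal(unname(colSums(r$cpm)), rep(1e6, 5), tolerance = 1e-6)
})

test_that("all-zero samples are rejected by name", {
  counts <- matrix(c(1, 2, 0, 0), 2, 2,
    dimnames = list(NULL, c("ok", "empty")))
  expect_error(normalizeExpression(counts, c(100, 100)), "empty")
})

test_that("CPM agrees with edgeR's unnormalized cpm", {
  skip_if_not_installed("edgeR")
  set.seed(8)
  counts <- matrix(rpois(3000, 40) + 1, 500, 6)
  r <- normalizeExpression(counts, rep(1000, 500))
  ref <- edgeR::cpm(counts, log = FALSE)
  expect_equal(unname(r$cpm), unname(ref), tolerance = 1e-9)
})

test_that("reproducible expression requires strict > threshold in every replicate", {
  tpm <- rbind(g1 = c(1.5, 2.0, 3.0), g2 = c(1.5, 0.9, 3.0),
    g3 = c(1.5, 1.0, 3.0))  # g3 sits exactly at the boundary
  expect_equal(reproduciblyExpressed(tpm), "g1")
})

test_that("CPM filter keeps genes above threshold in >= minReps replicates", {
  cpm <- rbind(g1 = c(3, 3, 0), g2 = c(3, 0, 0), g3 = c(2, 2, 2))
  expect_equal(cpmFilter(cpm), "g1")  # strict >, g3 at boundary drops
  set.seed(2)
  cpm <- matrix(rexp(300, 1 / 3), 100, 3,
    dimnames = list(sprintf("g%03d", 1:100), NULL))
  got <- cpmFilter(cpm, threshold = 2, minReps = 2)
  want <- rownames(cpm)[vapply(1:100, function(i)
    sum(cpm[i, ] > 2) >= 2, logical(1))]
  expect_equal(got, want)
})

test_that("species-specific selection applies the high/low TPM rules", {
  orth <- data.frame(gene_a = c("a1", "a2", "a3"),
    gene_b = c("b1", "b2", "b3"))
  tpmA <- rbind(a1 = c(50, 50), a2 = c(50, 50), a4 = c(50, 50))
  tpmB <- rbind(b1 = c(0.2, 0.2, 0.2, 0.2),
    b2 = c(0.2, 0.2, 5, 5), b3 = c(0.1, 0.1, 0.1, 0.1))
  stages <- c("E1", "E1", "E2", "E2")
  r <- speciesSpecificGenes(tpmA, tpmB, stages, orth)
  expect_equal(r$genes, "a1")          # a2 fails the E2 low bound
  expect_equal(r$nMissingOrtholog, 1L) # a4 has no ortholog
})

test_that("planted species-specific genes are recovered at zero dispersion", {
  sim <- simulateGenomePair(seed = 17, nGenes = 80, nElements = 60,
    chromLen = 1.5e6, nElementsBSpecific = 5)
  ex <- simulateExpression(sim, dispersion = 0, seed = 17)
  tpmA <- normalizeExpression(ex$A)
  tpmB <- normalizeExpression(ex$B)
  orth <- simOrthologs(sim)
  stagesB <- SummarizedExperiment::colData(ex$B)$stage
  r <- speciesSpecificGenes(SummarizedExperiment::assay(tpmA, "tpm"),
    SummarizedExperiment::assay(tpmB, "tpm"), stagesB, orth)
  planted <- ex$geneTruth$gene_id[ex$geneTruth$species_specific]
  expect_setequal(r$genes, planted)
})

test_that("element expression report matches a hand tally", {
  el <- data.frame(
    element_id = sprintf("e%d", 1:6),
    element_class = c("enhancer", "enhancer", "enhancer", "promoter",
      "promoter", "promoter"))
  links <- data.frame(
    element_id = c("e1", "e2", "e4", "e5"),
    element_class = c("enhancer", "enhancer", "promoter", "promoter"),
    gene_id = c("g1", "g2", "g1", "g3"))
  expressed <- c("g1", "g3", "g9")
  r <- elementExpressionReport(el, links, expressed)
  s <- r$elementSummary
  # e1 (g1) expressed; e2 (g2) not -> enhancers 1/3
  expect_equal(s$fraction[s$class == "enhancer"], 1 / 3)
  # e4 (g1), e5 (g3) expressed -> promoters 2/3
  expect_equal(s$fraction[s$class == "promoter"], 2 / 3)
  gc <- r$geneCategories
  expect_equal(gc$category[gc$gene_id == "g1"], "both")
  expect_equal(gc$category[gc$gene_id == "g3"], "promoter_only")
  expect_equal(gc$category[gc$gene_id == "g9"], "neither")

  # degenerate cases
  r0 <- elementExpressionReport(el, links[0, ], expressed)
  expect_true(all(r0$elementSummary$fraction == 0))
  expect_true(all(r0$geneCategories$category == "neither"))
})
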