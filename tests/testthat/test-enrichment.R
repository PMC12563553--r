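test_that("Fisher exact matches worked examples", {
  r <- fisherExact2x2(10, 10, 10, 10)
  expect_equal(r$oddsRatio, 1)
  expect_equal(r$p, 1)

  # (5,0,0,5): two-sided p = 2 * 1/choose(10,5) = 2/252
  r <- fisherExact2x2(5, 0, 0, 5)
  expect_equal(r$p, 2 / 252, tolerance = 1e-12)
  expect_error(fisherExact2x2(0, 0, 1, 1), "margin")
})

test_that("Fisher p equals exhaustive enumeration and fisher.test on random tables", {
  set.seed(30)
  for (i in 1:100) {
    repeat {
      cells <- as.integer(rmultinom(1, sample(8:60, 1), rep(0.25, 4)))
      a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
      if ((a + b) > 0 && (c + d) > 0 && (a + c) > 0 && (b + d) > 0) break
    }
    got <- fisherExact2x2(a, b, c, d)$p
    expect_equal(got, bfFisherP(a, b, c, d), tolerance = 1e-9)
    ref <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(got, ref, tolerance = 1e-7)
  }
})

test_that("Woolf CI brackets the sample odds ratio", {
  r <- fisherExact2x2(20, 10, 10, 20)
  expect_equal(r$oddsRatio, 4)
  se <- sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)
  expect_equal(r$ciLow, exp(log(4) - qnorm(0.975) * se))
  expect_equal(r$ciHigh, exp(log(4) + qnorm(0.975) * se))
  # Haldane-Anscombe correction on zero cells
  r0 <- fisherExact2x2(5, 0, 0, 5)
  expect_equal(r0$oddsRatio, (5.5 * 5.5) / (0.5 * 0.5))
})

test_that("Holm and BH adjustments reproduce hand-worked examples", {
  expect_equal(holmAdjust(0.03), 0.03)
  expect_equal(holmAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_error(holmAdjust(c(0.5, 1.2)), "0, 1")

  p <- c(0.01, 0.02, 0.03, 0.04, 0.9)
  # BH: p * m / rank, cummin from the largest
  want <- c(0.05, 0.05, 0.05, 0.05, 0.9)
  expect_equal(bhAdjust(p), want)
  # monotone already-adjusted input is a fixed point of the step rule
  expect_true(all(bhAdjust(want) >= want - 1e-12))
  expect_true(all(holmAdjust(p) >= p))
})

test_that("cluster enrichment builds the right tables and Holm-adjusts", {
  universe <- sprintf("g%03d", 1:100)
  clusters <- list(c1 = universe[1:20], c2 = universe[21:40])
  gs <- universe[1:20]
  r <- clusterEnrichment(gs, clusters, universe)
  expect_equal(r$a[r$cluster == "c1"], 20L)
  expect_equal(r$b[r$cluster == "c1"], 0L)
  expect_equal(r$d[r$cluster == "c1"], 80L)
  expect_lt(r$p[r$cluster == "c1"], 1e-10)
  expect_equal(r$p_adj, holmAdjust(r$p))
  # OR for the perfect-overlap table uses the +0.5 correction (finite)
  expect_true(is.finite(r$odds_ratio[1]))
  expect_error(clusterEnrichment(gs, list(c1 = c("nope")), universe),
    "universe")
  expect_error(
    clusterEnrichment(gs, list(c1 = universe[1:5], c2 = universe[5:9]),
      universe), "disjoint")
})

test_that("null cluster enrichment is calibrated near the nominal rate", {
  set.seed(40)
  universe <- sprintf("g%04d", 1:2000)
  clusters <- list(c1 = universe[1:500])
  hits <- replicate(1000, {
    gs <- sample(universe, 500)
    clusterEnrichment(gs, clusters, universe)$p[1] < 0.05
  })
  rate <- mean(hits)
  # binomial 99% CI around 0.05 with n = 1000 draws
  expect_gt(rate, 0.05 - 2.576 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(rate, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 1000))
})

test_that("planted over-representation is recovered with a sane OR", {
  set.seed(42)
  universe <- sprintf("g%04d", 1:2000)
  cluster <- universe[1:400]
  ok <- replicate(50, {
    # independent inclusion with 2x odds for cluster members:
    # outside p = 0.25 (odds 1/3), inside p = 0.4 (odds 2/3)
    p <- ifelse(universe %in% cluster, 0.4, 0.25)
    gs <- universe[runif(2000) < p]
    r <- clusterEnrichment(gs, list(c1 = cluster), universe)
    r$odds_ratio[1] >= 1.6 && r$odds_ratio[1] <= 2.5
  })
  expect_gte(mean(ok), 0.9)
})

test_that("hypergeometric gene-set enrichment matches the closed form", {
  universe <- sprintf("g%04d", 1:1000)
  ann <- list(inset = universe[1:50], other = universe[900:949])
  query <- universe[1:100]  # contains all of 'inset'
  r <- geneSetEnrichment(query, ann, universe)
  # closed-form tail: sum_{x=50} C(50,x) C(950,100-x) / C(1000,100)
  want <- choose(50, 50) * choose(950, 50) / choose(1000, 100)
  expect_equal(r$p[r$set_id == "inset"], want, tolerance = 1e-9)
  expect_true(r$significant[r$set_id == "inset"])
  expect_equal(r$p_adj, bhAdjust(r$p))

  # query = universe: nothing can be enriched
  r2 <- geneSetEnrichment(universe, ann, universe)
  expect_true(all(r2$p == 1))
  expect_warning(
    geneSetEnrichment(query, list(empty = character(0)), universe),
    "skipped")
})

test_that("exclusive set intersections sum to the union size", {
  r <- setIntersections(list(A = 1:4, B = 3:6))
  expect_setequal(r$combination, c("A", "B", "A&B"))
  expect_equal(r$size[r$combination == "A&B"], 2L)
  expect_equal(sum(r$size), 6L)

  # disjoint and identical edge cases
  r2 <- setIntersections(list(A = 1:3, B = 7:9))
  expect_setequal(r2$combination, c("A", "B"))
  r3 <- setIntersections(list(A = 1:5, B = 1:5))
  expect_equal(r3$combination, "A&B")
  expect_equal(r3$size, 5L)

  set.seed(44)
  sets <- lapply(stats::setNames(1:7, paste0("S", 1:7)), function(i)
    sample(500, sample(50:200, 1)))
  r7 <- setIntersections(sets)
  want <- bfIntersections(sets)
  expect_equal(sum(r7$size), length(unique(unlist(sets))))
  for (k in seq_len(nrow(r7)))
    expect_equal(r7$size[k], as.integer(want[[r7$combination[k]]]))
})
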