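#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value by summing the hypergeometric
#' probabilities of all tables with the observed margins that are as or
#' less probable than the observed table.  The effect estimate is the
#' \emph{sample} odds ratio \code{(a*d)/(b*c)}, with the
#' Haldane-Anscombe +0.5 correction applied to every cell when any cell
#' is zero, and a Woolf 95\% confidence interval
#' \code{exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))} on the
#' (corrected) cells.  This differs by design from the conditional-MLE
#' odds ratio reported by \code{\link[stats]{fisher.test}}; the two agree
#' closely for large, balanced tables.
#'
#' The table layout is \code{rbind(c(a, b), c(c, d))}: \code{a} in-set
#' and in-target, \code{b} in-set only, \code{c} in-target only, \code{d}
#' neither.
#'
#' @param a,b,c,d non-negative cell counts; both margins must be
#'   positive.
#' @return A list: \code{oddsRatio}, \code{ciLow}, \code{ciHigh},
#'   \code{p}, and the \code{table}.
#' @examples
#' fisherExact2x2(10, 10, 10, 10)$p  # 1
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    .stopf("cell counts must be non-negative integers")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    .stopf("both margins of the 2x2 table must be positive")
  m <- a + c          # first-column margin
  nn <- b + d         # second-column margin
  kk <- a + b         # first-row margin
  support <- max(0, kk - nn):min(kk, m)
  probs <- stats::dhyper(support, m, nn, kk)
  pObs <- stats::dhyper(a, m, nn, kk)
  p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  cc <- if (any(cells == 0)) cells + 0.5 else cells
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(oddsRatio = unname(or), ciLow = ci[1L], ciHigh = ci[2L], p = p,
    table = matrix(c(a, b, c, d), 2, byrow = TRUE))
}

#' Holm step-down adjustment
#'
#' Family-wise error control by Holm's method (delegates to
#' \code{\link[stats]{p.adjust}}), with input validation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
holmAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Benjamini-Hochberg adjustment
#'
#' False-discovery-rate control by the BH step-up method (delegates to
#' \code{\link[stats]{p.adjust}}), with input validation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fisher/Holm enrichment of a gene set across clusters
#'
#' For each cluster, tests the 2x2 association between cluster membership
#' and membership of \code{geneSet} over \code{universe} with the
#' two-sided Fisher exact test (\code{\link{fisherExact2x2}}), then
#' adjusts across clusters with the Holm method.
#'
#' @param geneSet character vector of gene ids (must lie in
#'   \code{universe}).
#' @param clusters named list (cluster id -> gene ids); clusters must be
#'   disjoint subsets of \code{universe}.
#' @param universe character vector of background gene ids.
#' @return A data.frame with one row per cluster: \code{cluster},
#'   \code{a}, \code{b}, \code{c}, \code{d}, \code{odds_ratio},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{p_adj}.
#' @export
clusterEnrichment <- function(geneSet, clusters, universe) {
  universe <- unique(universe)
  geneSet <- unique(geneSet)
  if (!all(geneSet %in% universe))
    .stopf("gene set contains genes outside the universe")
  allClust <- unlist(clusters, use.names = FALSE)
  if (!all(allClust %in% universe))
    .stopf("cluster gene '%s' is not in the universe",
      setdiff(allClust, universe)[1L])
  if (anyDuplicated(allClust))
    .stopf("clusters must be disjoint")
  N <- length(universe)
  rows <- lapply(names(clusters), function(cl) {
    inC <- unique(clusters[[cl]])
    a <- length(intersect(geneSet, inC))
    b <- length(geneSet) - a
    cc <- length(inC) - a
    d <- N - a - b - cc
    ft <- fisherExact2x2(a, b, cc, d)
    data.frame(cluster = cl, a = a, b = b, c = cc, d = d,
      odds_ratio = ft$oddsRatio, ci_low = ft$ciLow, ci_high = ft$ciHigh,
      p = ft$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- holmAdjust(res$p)
  res
}

#' Hypergeometric gene-set over-representation with BH FDR
#'
#' One-sided hypergeometric (over-representation) test of a query gene
#' list against each annotation set, adjusted across sets with
#' Benjamini-Hochberg; sets with \code{p_adj < fdr} are flagged
#' significant.  Empty annotation sets are skipped with a warning.
#'
#' @param queryGenes character vector of query gene ids (subset of
#'   \code{universe}).
#' @param annotation named list (set id -> gene ids); genes outside the
#'   universe are ignored.
#' @param universe background gene ids.
#' @param fdr significance threshold on the adjusted p; default 0.01.
#' @return A data.frame per set: \code{set_id}, \code{a} (overlap),
#'   \code{set_size}, \code{query_size}, \code{universe_size}, \code{p},
#'   \code{p_adj}, \code{significant}.
#' @export
geneSetEnrichment <- function(queryGenes, annotation, universe,
    fdr = 0.01) {
  universe <- unique(universe)
  queryGenes <- unique(queryGenes)
  if (!all(queryGenes %in% universe))
    .stopf("query genes must be a subset of the universe")
  N <- length(universe)
  nQ <- length(queryGenes)
  keep <- vapply(annotation, function(g)
    length(intersect(g, universe)) > 0, logical(1))
  if (any(!keep))
    warning(sprintf("%d empty annotation set(s) skipped", sum(!keep)))
  annotation <- annotation[keep]
  rows <- lapply(names(annotation), function(id) {
    setG <- intersect(unique(annotation[[id]]), universe)
    K <- length(setG)
    a <- length(intersect(queryGenes, setG))
    p <- stats::phyper(a - 1, K, N - K, nQ, lower.tail = FALSE)
    data.frame(set_id = id, a = a, set_size = K, query_size = nQ,
      universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bhAdjust(res$p)
  res$significant <- res$p_adj < fdr
  res
}

#' Exclusive intersection sizes of named sets (upset-style)
#'
#' Tallies, for every non-empty combination of the input sets, the number
#' of elements belonging to exactly that combination.  The sizes sum to
#' the cardinality of the union.
#'
#' @param sets named list (>= 2) of vectors.
#' @return A data.frame: \code{combination} (set names joined by
#'   \code{"&"}), \code{degree} (number of sets in the combination) and
#'   \code{size}, sorted by decreasing size.
#' @examples
#' setIntersections(list(A = 1:4, B = 3:6))
#' @export
setIntersections <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)))
    .stopf("'sets' must be a named list of at least two sets")
  sets <- lapply(sets, unique)
  un <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) un %in% s, logical(length(un)))
  if (length(un) == 1L) memb <- matrix(memb, nrow = 1L,
    dimnames = list(NULL, names(sets)))
  sig <- apply(memb, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  tab <- table(sig)
  res <- data.frame(combination = names(tab),
    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
    size = as.integer(tab), stringsAsFactors = FALSE)
  res[order(-res$size, res$combination), , drop = FALSE]
}
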