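#' Temporally dynamic genes by fold change from the first stage
#'
#' A gene is dynamic when its largest absolute log2 fold change between
#' any later stage and the first stage exceeds \code{logfcThreshold}.
#' Stage levels are replicate means of CPM; a pseudocount stabilizes the
#' ratio at low counts.  This fold-change rule is the clustering input
#' selector; it deliberately performs no dispersion modelling.
#'
#' @param cpm gene x sample CPM matrix.
#' @param stages factor/character of length \code{ncol(cpm)}; the first
#'   level (in order of appearance) is the baseline stage.
#' @param logfcThreshold |log2 FC| threshold; default 2 (strict
#'   \code{>}).
#' @param pseudocount added to both stage means; default 0.5.
#' @return Character vector of dynamic gene ids.
#' @export
dynamicGenes <- function(cpm, stages, logfcThreshold = 2,
    pseudocount = 0.5) {
  cpm <- as.matrix(cpm)
  stages <- as.character(stages)
  lev <- unique(stages)
  if (length(lev) < 2L) .stopf("need at least 2 stages")
  stageMean <- vapply(lev, function(st)
    rowMeans(cpm[, stages == st, drop = FALSE]), numeric(nrow(cpm)))
  base <- stageMean[, 1L]
  lfc <- log2(sweep(stageMean[, -1L, drop = FALSE] + pseudocount, 1,
    base + pseudocount, "/"))
  rownames(cpm)[apply(abs(lfc), 1L, max) > logfcThreshold]
}

#' Row-wise z-scaling with the population standard deviation
#'
#' Scales each profile (row) to mean 0 and standard deviation 1, using
#' the population formula (\code{sqrt(mean((x - mean(x))^2))}), matching
#' the convention of soft-clustering tools for temporal expression.
#'
#' @param profiles gene x timepoint numeric matrix.
#' @return The z-scaled matrix.
#' @section Errors:
#' A zero-variance row raises an error naming the gene; exclude flat
#' genes upstream (see \code{\link{dynamicGenes}}).
#' @export
zScale <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2L) .stopf("need at least 2 timepoints")
  mu <- rowMeans(profiles)
  ctr <- profiles - mu
  sdp <- sqrt(rowMeans(ctr^2))
  if (any(sdp == 0)) {
    g <- rownames(profiles)[sdp == 0][1L]
    .stopf("zero-variance profile for gene '%s'",
      if (is.null(g) || is.na(g)) which(sdp == 0)[1L] else g)
  }
  ctr / sdp
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' Standard Bezdek fuzzy c-means with Euclidean distance: memberships
#' \code{u_ij = 1 / sum_l (d_ij / d_lj)^(2/(m-1))} and centers
#' \code{c_i = sum_j u_ij^m x_j / sum_j u_ij^m}, iterated until the
#' largest center coordinate shift falls below \code{tol}.  A point
#' coincident with a center receives membership 1 there (split equally
#' across coincident centers in the degenerate multi-center case).
#' Initial centers are \code{k} distinct profiles drawn under
#' \code{seed}, so results are reproducible.  The objective
#' \code{sum_ij u_ij^m d_ij^2} is recorded per iteration and is
#' non-increasing.
#'
#' @param x profile matrix (rows clustered), typically z-scaled log-CPM.
#' @param k number of clusters (\code{1 <= k <= nrow(x)}).
#' @param m fuzzifier > 1; default 2.
#' @param tol convergence tolerance on the center shift; default 1e-6.
#' @param maxIter iteration cap; default 500 (a warning flags
#'   non-convergence).
#' @param seed integer seed for center initialization.
#' @return A \linkS4class{TemporalClustering}.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
#' fuzzyCMeans(x, k = 2, seed = 1)
#' @export
fuzzyCMeans <- function(x, k = 5L, m = 2, tol = 1e-6, maxIter = 500L,
    seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1L || k > n) .stopf("'k' must be in [1, nrow(x)]")
  if (m <= 1) .stopf("fuzzifier 'm' must be > 1")
  set.seed(seed)
  ctr <- x[sample.int(n, k), , drop = FALSE]
  d2 <- function(ctr) {
    # n x k squared Euclidean distances
    outer(rowSums(x^2), rep(1, k)) +
      outer(rep(1, n), rowSums(ctr^2)) - 2 * x %*% t(ctr)
  }
  obj <- numeric(0)
  conv <- FALSE
  it <- 0L
  u <- NULL
  repeat {
    it <- it + 1L
    D <- pmax(d2(ctr), 0)
    zero <- D < 1e-300
    u <- (D + (D == 0)) ^ (-1 / (m - 1))
    u[zero] <- 0
    anyZero <- rowSums(zero) > 0
    if (any(anyZero)) {
      u[anyZero, ] <- zero[anyZero, , drop = FALSE] /
        rowSums(zero[anyZero, , drop = FALSE])
    }
    u[!anyZero, ] <- u[!anyZero, , drop = FALSE] /
      rowSums(u[!anyZero, , drop = FALSE])
    obj <- c(obj, sum(u^m * D))
    um <- u^m
    newCtr <- (t(um) %*% x) / colSums(um)
    shift <- max(abs(newCtr - ctr))
    ctr <- newCtr
    if (shift < tol) { conv <- TRUE; break }
    if (it >= maxIter) break
  }
  if (!conv)
    warning(sprintf("fuzzy c-means did not converge in %d iterations",
      maxIter))
  dimnames(u) <- list(rownames(x), paste0("cluster_", seq_len(k)))
  dimnames(ctr) <- list(paste0("cluster_", seq_len(k)), colnames(x))
  new("TemporalClustering", centers = ctr, membership = u, m = m,
    k = as.integer(k), assigned = apply(u, 1L, which.max),
    converged = conv, iterations = it, objective = obj)
}

#' Calinski-Harabasz selection of the cluster count
#'
#' For each candidate \code{k >= 2}, partitions the profiles with hard
#' k-means (seeded, \code{nRestarts} random starts) and computes the
#' Calinski-Harabasz index
#' \code{CH(k) = [B(k)/(k-1)] / [W(k)/(n-k)]}, the ratio of
#' between-cluster to within-cluster dispersion.  \code{k = 1} is
#' reported with an undefined (NA) score and excluded from the arg-max.
#' The final soft clustering is then run separately at the chosen
#' \code{k} (see \code{\link{fuzzyCMeans}}), mirroring the common
#' two-tool procedure of hard selection plus fuzzy assignment.
#'
#' @param x profile matrix.
#' @param kRange candidate cluster counts; default \code{1:10}.
#' @param nRestarts k-means restarts per k; default 10.
#' @param seed integer seed.
#' @return A list: \code{bestK}, \code{scores} (named numeric, NA for
#'   k = 1), and \code{assignments} (list of hard partitions per k).
#' @export
calinskiSelect <- function(x, kRange = 1:10, nRestarts = 10L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  kRange <- kRange[kRange >= 1 & kRange <= n - 1L]
  if (!length(kRange)) .stopf("'kRange' must lie within [1, n-1]")
  scores <- stats::setNames(rep(NA_real_, length(kRange)),
    as.character(kRange))
  assignments <- stats::setNames(vector("list", length(kRange)),
    as.character(kRange))
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    if (k == 1L) {
      assignments[[i]] <- rep(1L, n)
      next
    }
    set.seed(.streamSeed(seed, paste0("calinski_k", k)))
    km <- stats::kmeans(x, centers = k, nstart = nRestarts,
      iter.max = 100L)
    B <- km$betweenss
    W <- km$tot.withinss
    scores[i] <- (B / (k - 1)) / (W / (n - k))
    assignments[[i]] <- km$cluster
  }
  valid <- which(!is.na(scores))
  bestK <- kRange[valid[which.max(scores[valid])]]
  list(bestK = bestK, scores = scores, assignments = assignments)
}

#' Per-cluster report of a fuzzy clustering
#'
#' @param clustering a \linkS4class{TemporalClustering}.
#' @param geneSets optional named list of gene-id vectors; per-cluster
#'   overlap counts with each set are added to the cluster summary.
#' @return A list: \code{genes} data.frame (\code{gene_id},
#'   \code{cluster}, \code{membership} of the assigned cluster),
#'   \code{centers} (k x T matrix) and \code{summary} data.frame with
#'   per-cluster sizes (plus one column per gene set).
#' @export
clusterReport <- function(clustering, geneSets = NULL) {
  u <- membership(clustering)
  assigned <- clusterAssignments(clustering)
  ids <- rownames(u)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(u)))
  genes <- data.frame(gene_id = ids, cluster = assigned,
    membership = u[cbind(seq_len(nrow(u)), assigned)],
    stringsAsFactors = FALSE)
  summary <- data.frame(cluster = seq_len(clustering@k),
    size = tabulate(assigned, clustering@k))
  if (!is.null(geneSets)) {
    for (nm in names(geneSets)) {
      summary[[nm]] <- vapply(seq_len(clustering@k), function(c)
        sum(ids[assigned == c] %in% geneSets[[nm]]), integer(1))
    }
  }
  list(genes = genes, centers = centers(clustering), summary = summary)
}
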