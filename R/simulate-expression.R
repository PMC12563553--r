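# Planted temporal expression shapes (log2 amplitude relative to each
# gene's baseline).  The five canonical patterns cover a late spike, a
# single interior peak, monotone decline, monotone rise and an early
# peak; shapes are linearly interpolated for other stage counts.
.clusterShapes <- function(k, timepoints, amp = 4) {
  base <- list(
    c(0, 0, 0, 0, 0, 1),
    c(0, 0, 0, 0, 1, 0),
    c(1, .8, .6, .4, .2, 0),
    c(0, .2, .4, .6, .8, 1),
    c(0, 1, .8, .4, .2, 0))
  if (k > length(base))
    .stopf("at most %d planted cluster shapes available", length(base))
  t(vapply(base[seq_len(k)], function(s)
    amp * stats::approx(seq(0, 1, length.out = length(s)), s,
      xout = seq(0, 1, length.out = timepoints))$y,
    numeric(timepoints)))
}

# counts ~ NegBin(mu = libSize * w / sum(w), size = 1/dispersion) with w
# the within-sample relative abundance; dispersion 0 is the Poisson limit
.nbCounts <- function(w, libSize, dispersion) {
  mu <- libSize * w / sum(w)
  if (dispersion <= 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate expression matrices with planted thresholds and clusters
#'
#' Generates negative-binomial count matrices for both species of a
#' \linkS4class{SimulatedGenomePair}.  Species A gets a single stage
#' (\code{"P0"}); species B gets a stage series.  Planted structure:
#' \itemize{
#'   \item a fraction \code{speciesSpecificFrac} of ortholog pairs is
#'     species-A specific: planted mean above \code{30} TPM in A and
#'     \code{0.1} TPM in B at every stage;
#'   \item a fraction \code{dynamicFrac} of genome-B genes carries one of
#'     \code{nClusters} temporal shapes (log2 amplitude 4 relative to
#'     baseline); remaining genes are flat and are excluded by the
#'     |log2 FC| > 2 baseline filter by construction;
#'   \item other baselines are log-normal, mostly above the 1-TPM
#'     reproducibility threshold.
#' }
#'
#' @param sim a \linkS4class{SimulatedGenomePair}.
#' @param stagesB genome-B stage labels; default
#'   \code{c("E10.5", ..., "E15.5")}.
#' @param reps replicates per species/stage; default 3.
#' @param dispersion negative-binomial dispersion (1/size); 0 gives the
#'   Poisson limit; default 0.05.
#' @param libSize expected library size; default 1e6.
#' @param nClusters planted temporal clusters; default 5.
#' @param dynamicFrac fraction of B genes that are dynamic; default 0.5.
#' @param speciesSpecificFrac fraction of ortholog pairs planted
#'   species-A specific; default 0.1.
#' @param nFiller flat "rest-of-transcriptome" filler genes per species
#'   that absorb the remaining per-million mass, so planted TPM values
#'   land on the true TPM scale; default 300.
#' @param seed integer seed.
#' @return A list: \code{A}, \code{B}
#'   (\link[SummarizedExperiment]{SummarizedExperiment}s with a
#'   \code{counts} assay, \code{gene_length} rowData and
#'   species/stage/replicate colData), \code{geneTruth} (data.frame:
#'   \code{gene_id}, \code{species}, \code{cluster} [NA for flat genes],
#'   \code{species_specific}, \code{planted_tpm_base}) and
#'   \code{manifest} (parameter list including the shape matrix).
#' @export
simulateExpression <- function(sim,
    stagesB = c("E10.5", "E11.5", "E12.5", "E13.5", "E14.5", "E15.5"),
    reps = 3L, dispersion = 0.05, libSize = 1e6, nClusters = 5L,
    dynamicFrac = 0.5, speciesSpecificFrac = 0.1, nFiller = 300L,
    seed = 1L) {
  if (reps < 2L) .stopf("'reps' must be >= 2")
  if (length(stagesB) < 2L) .stopf("need >= 2 genome-B stages")
  genesA <- sim@genesA
  genesB <- sim@genesB
  nA <- length(genesA)
  nB <- length(genesB)

  set.seed(.streamSeed(seed, "expression_plan"))
  # baseline TPM (per gene, log-normal around ~20 TPM)
  baseA <- stats::rlnorm(nA, log(20), 0.8)
  baseB <- stats::rlnorm(nB, log(20), 0.8)
  # species-A-specific ortholog pairs
  orthoIdxA <- which(!is.na(genesA$ortholog_id))
  nSpec <- round(speciesSpecificFrac * length(orthoIdxA))
  specA <- sample(orthoIdxA, nSpec)
  baseA[specA] <- stats::runif(nSpec, 30, 60)
  specB <- match(genesA$ortholog_id[specA], genesB$gene_id)
  baseB[specB] <- 0.1
  # planted temporal clusters in genome B
  shapes <- .clusterShapes(nClusters, length(stagesB))
  eligible <- setdiff(seq_len(nB), specB)
  nDyn <- round(dynamicFrac * nB)
  nDyn <- min(nDyn, length(eligible))
  dynIdx <- sample(eligible, nDyn)
  clusterOf <- rep(NA_integer_, nB)
  clusterOf[dynIdx] <- rep_len(seq_len(nClusters), nDyn)

  # expected TPM per gene and stage
  tpmB <- matrix(baseB, nB, length(stagesB))
  for (i in dynIdx)
    tpmB[i, ] <- baseB[i] * 2^shapes[clusterOf[i], ]
  tpmA <- matrix(baseA, nA, 1L)

  # filler genes absorb the remaining per-million mass so that planted
  # TPM values are (to within a fraction of a percent) the measured ones
  fillerLen <- 2000L
  fillerTpm <- function(realTpm, n, species) {
    spare <- 1e6 - mean(colSums(realTpm))
    if (spare <= 0) .stopf("planted TPM mass exceeds 1e6")
    w <- stats::rlnorm(n, 0, 0.5)
    spare * w / sum(w)
  }
  fillA <- fillerTpm(tpmA, nFiller, "A")
  fillB <- fillerTpm(tpmB, nFiller, "B")
  tpmA <- rbind(tpmA, matrix(fillA, nFiller, ncol(tpmA)))
  tpmB <- rbind(tpmB, matrix(fillB, nFiller, ncol(tpmB)))
  fillerIdsA <- sprintf("fillerA%03d", seq_len(nFiller))
  fillerIdsB <- sprintf("fillerB%03d", seq_len(nFiller))
  idsA <- c(genesA$gene_id, fillerIdsA)
  idsB <- c(genesB$gene_id, fillerIdsB)
  lensA <- c(genesA$gene_length, rep(fillerLen, nFiller))
  lensB <- c(genesB$gene_length, rep(fillerLen, nFiller))

  drawCounts <- function(tpmMat, lens, stages, species) {
    cols <- list()
    cn <- character(0)
    for (si in seq_along(stages)) {
      w <- tpmMat[, si] * lens
      for (r in seq_len(reps)) {
        set.seed(.streamSeed(seed,
          paste("counts", species, stages[si], r, sep = "_")))
        cols[[length(cols) + 1L]] <- .nbCounts(w, libSize, dispersion)
        cn <- c(cn, sprintf("%s_%s_rep%d", species, stages[si], r))
      }
    }
    m <- do.call(cbind, cols)
    colnames(m) <- cn
    m
  }
  cntA <- drawCounts(tpmA, lensA, "P0", "A")
  rownames(cntA) <- idsA
  cntB <- drawCounts(tpmB, lensB, stagesB, "B")
  rownames(cntB) <- idsB

  makeSE <- function(cnt, ids, lens, stages, species) {
    cd <- S4Vectors::DataFrame(
      species = species,
      stage = rep(stages, each = reps),
      replicate = rep(sprintf("rep%d", seq_len(reps)), length(stages)),
      row.names = colnames(cnt))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = cnt),
      rowData = S4Vectors::DataFrame(gene_id = ids,
        gene_length = lens, row.names = ids),
      colData = cd)
  }
  geneTruth <- rbind(
    data.frame(gene_id = idsA, species = "A",
      cluster = NA_integer_,
      species_specific = seq_len(nA + nFiller) %in% specA,
      planted_tpm_base = c(baseA, fillA), stringsAsFactors = FALSE),
    data.frame(gene_id = idsB, species = "B",
      cluster = c(clusterOf, rep(NA_integer_, nFiller)),
      species_specific = FALSE,
      planted_tpm_base = c(baseB, fillB), stringsAsFactors = FALSE))
  list(
    A = makeSE(cntA, idsA, lensA, "P0", "A"),
    B = makeSE(cntB, idsB, lensB, stagesB, "B"),
    geneTruth = geneTruth,
    manifest = list(stagesB = stagesB, reps = reps,
      dispersion = dispersion, libSize = libSize, nClusters = nClusters,
      dynamicFrac = dynamicFrac, speciesSpecificFrac = speciesSpecificFrac,
      shapes = shapes, seed = seed))
}

#' Simulate a standalone count matrix with planted temporal clusters
#'
#' Generates \code{k * nPerCluster} genes whose expected log2-CPM
#' profiles follow the planted cluster shapes (see
#' \code{\link{simulateExpression}}), with negative-binomial replicate
#' noise.  Used to exercise the clustering machinery at scale.
#'
#' @param nPerCluster genes per planted cluster; default 500.
#' @param k planted cluster count (max 5); default 5.
#' @param timepoints number of stages; default 6.
#' @param reps replicates per stage; default 3.
#' @param dispersion negative-binomial dispersion; default 0.05.
#' @param libSize expected library size; default 1e6.
#' @param seed integer seed.
#' @return A list: \code{counts} (gene x sample), \code{stages} (per
#'   sample), \code{cluster} (planted id per gene) and \code{shapes}.
#' @export
simulateTemporalCounts <- function(nPerCluster = 500L, k = 5L,
    timepoints = 6L, reps = 3L, dispersion = 0.05, libSize = 1e6,
    seed = 1L) {
  n <- nPerCluster * k
  shapes <- .clusterShapes(k, timepoints)
  set.seed(.streamSeed(seed, "temporal_plan"))
  base <- stats::rlnorm(n, log(50), 0.6)
  cluster <- rep(seq_len(k), each = nPerCluster)
  expected <- base * 2^shapes[cluster, , drop = FALSE]
  stages <- rep(sprintf("T%d", seq_len(timepoints)), each = reps)
  cols <- list()
  for (si in seq_len(timepoints)) {
    for (r in seq_len(reps)) {
      set.seed(.streamSeed(seed, sprintf("temporal_counts_%d_%d", si, r)))
      cols[[length(cols) + 1L]] <- .nbCounts(expected[, si], libSize,
        dispersion)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- sprintf("g%05d", seq_len(n))
  colnames(counts) <- sprintf("%s_rep%d", stages,
    rep(seq_len(reps), timepoints))
  list(counts = counts, stages = stages, cluster = cluster,
    shapes = shapes)
}
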