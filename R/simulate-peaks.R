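#' Simulate replicate narrowPeak sets from planted elements
#'
#' Emits H3K4me3 and H3K27ac peak replicates for both species of a
#' \linkS4class{SimulatedGenomePair}, following the mark model of the
#' classifier: promoters emit both marks co-located, enhancers emit
#' H3K27ac only.  Each planted element yields one peak per replicate
#' with endpoints jittered by \code{round(rnorm(0, jitterSd))},
#' independently dropped with probability \code{dropout}; fold
#' enrichment is log-normal (\code{meanlog}, \code{sdlog} recorded in
#' the manifest).  Genome-B peaks are emitted once per requested stage
#' with independent jitter and dropout, modelling a stage series in
#' which every planted B element is active at every stage.
#'
#' One named pseudo-random stream per (species, stage, mark, replicate)
#' file derives from \code{seed}, so equal seeds give identical output.
#'
#' @param sim a \linkS4class{SimulatedGenomePair}.
#' @param jitterSd endpoint jitter standard deviation (bp), >= 0;
#'   default 5.
#' @param dropout per-replicate peak dropout probability in [0, 1);
#'   default 0.1.
#' @param seed integer seed.
#' @param stagesB stage labels for the genome-B series; default
#'   \code{"S1"}.
#' @param reps replicates per mark; default 2.
#' @param foldMeanLog,foldSdLog log-normal fold-enrichment parameters;
#'   defaults 1.5 and 0.4.
#' @return A list: \code{A} (list mark -> list rep -> \code{GRanges}),
#'   \code{B} (list stage -> mark -> rep -> \code{GRanges}),
#'   \code{emission} (data.frame of which element/mark/rep peaks were
#'   emitted vs dropped) and \code{manifest} (parameter list).
#' @examples
#' sim <- simulateGenomePair(seed = 1, nGenes = 40, nElements = 60,
#'   chromLen = 1e6, nElementsBSpecific = 10)
#' pk <- simulatePeakReplicates(sim, jitterSd = 0, dropout = 0, seed = 1)
#' length(pk$A$H3K27ac$rep1)
#' @export
simulatePeakReplicates <- function(sim, jitterSd = 5, dropout = 0.1,
    seed = 1L, stagesB = "S1", reps = 2L,
    foldMeanLog = 1.5, foldSdLog = 0.4) {
  if (jitterSd < 0) .stopf("'jitterSd' must be >= 0")
  if (dropout < 0 || dropout >= 1) .stopf("'dropout' must be in [0, 1)")
  emission <- list()
  makeSet <- function(elements, seqlen, species, stage) {
    marks <- list(
      H3K4me3 = which(elements$true_class == "promoter"),
      H3K27ac = seq_along(elements))
    out <- list()
    for (mk in names(marks)) {
      idx <- marks[[mk]]
      out[[mk]] <- list()
      for (r in seq_len(reps)) {
        repNm <- paste0("rep", r)
        set.seed(.streamSeed(seed,
          paste(species, stage, mk, repNm, sep = "_")))
        keep <- stats::runif(length(idx)) >= dropout
        emission[[length(emission) + 1L]] <<- data.frame(
          element_id = elements$element_id[idx], species = species,
          stage = stage, mark = mk, rep = repNm, emitted = keep,
          stringsAsFactors = FALSE)
        el <- elements[idx]
        s0 <- .bedStart(el) + round(stats::rnorm(length(el), 0, jitterSd))
        e1 <- .bedEnd(el) + round(stats::rnorm(length(el), 0, jitterSd))
        lim <- unname(seqlen[as.character(GenomicRanges::seqnames(el))])
        s0 <- pmax(0L, as.integer(s0))
        e1 <- as.integer(pmin(pmax(e1, s0 + 50L), lim))
        fold <- stats::rlnorm(length(el), foldMeanLog, foldSdLog)
        qv <- stats::runif(length(el), 2, 10)
        gr <- .grFromBed(as.character(GenomicRanges::seqnames(el)), s0, e1)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
          name = sprintf("%s_%s_%s", elements$element_id[idx], mk, repNm),
          score = 0L, signalValue = round(fold, 3),
          pValue = -1, qValue = round(qv, 3),
          peak = as.integer((e1 - s0) %/% 2L))
        out[[mk]][[repNm]] <- gr[keep]
      }
    }
    out
  }
  A <- makeSet(sim@elementsA, sim@seqlenA, "A", "P0")
  B <- lapply(stats::setNames(stagesB, stagesB), function(st)
    makeSet(sim@elementsB, sim@seqlenB, "B", st))
  list(A = A, B = B, emission = do.call(rbind, emission),
    manifest = list(jitterSd = jitterSd, dropout = dropout, seed = seed,
      stagesB = stagesB, reps = reps, foldMeanLog = foldMeanLog,
      foldSdLog = foldSdLog))
}
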