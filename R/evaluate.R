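#' Evaluate class and conservation recovery against planted truth
#'
#' Compares the pipeline's classification and conservation calls for
#' genome A with the planted truth of a
#' \linkS4class{SimulatedGenomePair}.  Called elements are matched to
#' planted elements by overlap (planted elements are spaced far apart,
#' so the match is unique).
#'
#' Two accuracy views are reported.  The \emph{unconditional} view
#' scores every planted element, so peaks deleted by replicate dropout
#' count as errors even though no method could recover them.  The
#' \emph{observable-conditional} view, the package's primary recovery
#' metric, scores only elements whose required evidence survived
#' dropout: an element is \emph{class-observable} when its
#' class-defining mark (H3K4me3 for promoters, H3K27ac for enhancers)
#' was emitted in both genome-A replicates, and
#' \emph{conservation-observable} when, additionally for conserved
#' elements, the partner's class-defining mark survived both replicates
#' at >= 1 genome-B stage.  Within the observable set, any residual
#' error is attributable to the pipeline (jitter handling, overlap
#' rules, liftover), which is the property under test.
#'
#' @param sim a \linkS4class{SimulatedGenomePair}.
#' @param emission the \code{emission} table from
#'   \code{\link{simulatePeakReplicates}}.
#' @param elements classified genome-A elements (after
#'   \code{\link{classifyElements}}).
#' @param conservation conservation calls from
#'   \code{\link{conservedActivity}} (rows keyed by the classified
#'   \code{element_id}s).
#' @return A list: \code{perElement} (data.frame with planted truth,
#'   observability flags, calls and correctness), \code{classAccuracy},
#'   \code{conservationAccuracy}, \code{overallAccuracy} (all
#'   observable-conditional, as fractions), \code{detectionRate}
#'   (unconditional fraction of planted elements detected) and
#'   \code{unconditionalAccuracy}.
#' @export
evaluateRecovery <- function(sim, emission, elements, conservation) {
  truth <- sim@elementsA
  requiredMark <- ifelse(truth$true_class == "promoter", "H3K4me3",
    "H3K27ac")
  obsFor <- function(species, ids, marks) {
    em <- emission[emission$species == species &
      emission$element_id %in% ids, , drop = FALSE]
    byStage <- split(em, em$stage)
    # observable at >= 1 stage: the required mark emitted in all reps
    anyStage <- rep(FALSE, length(ids))
    for (st in names(byStage)) {
      e <- byStage[[st]]
      ok <- vapply(seq_along(ids), function(i) {
        rows <- e$element_id == ids[i] & e$mark == marks[i]
        sum(rows) > 0 && all(e$emitted[rows])
      }, logical(1))
      anyStage <- anyStage | ok
    }
    anyStage
  }
  classObs <- obsFor("A", truth$element_id, requiredMark)
  consObs <- rep(TRUE, length(truth))
  isCons <- truth$conservation == "conserved"
  consObs[isCons] <- obsFor("B", truth$element_id[isCons],
    requiredMark[isCons])

  hit <- GenomicRanges::findOverlaps(truth, elements, select = "first",
    ignore.strand = TRUE)
  calledClass <- rep(NA_character_, length(truth))
  calledCons <- rep(NA_character_, length(truth))
  ok <- !is.na(hit)
  calledClass[ok] <- elements$element_class[hit[ok]]
  cm <- match(elements$element_id[hit[ok]], conservation$element_id)
  calledCons[ok][!is.na(cm)] <- conservation$status[cm[!is.na(cm)]]
  truthCons <- ifelse(isCons, "conserved", "species_specific")

  classCorrect <- !is.na(calledClass) & calledClass == truth$true_class
  consCorrect <- !is.na(calledCons) & calledCons == truthCons
  perElement <- data.frame(
    element_id = truth$element_id, true_class = truth$true_class,
    conservation = truth$conservation, class_observable = classObs,
    conservation_observable = classObs & consObs,
    detected = ok, called_class = calledClass,
    called_conservation = calledCons, class_correct = classCorrect,
    conservation_correct = consCorrect, stringsAsFactors = FALSE)
  bothObs <- classObs & consObs
  list(perElement = perElement,
    classAccuracy = mean(classCorrect[classObs]),
    conservationAccuracy = mean(consCorrect[bothObs]),
    overallAccuracy = mean((classCorrect & consCorrect)[bothObs]),
    detectionRate = mean(ok),
    unconditionalAccuracy = mean(classCorrect & consCorrect))
}
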