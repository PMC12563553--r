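# Motif scanning and GC/length-matched background enrichment.

.seqToInt <- function(s) {
  v <- match(strsplit(toupper(as.character(s)), "")[[1L]],
    c("A", "C", "G", "T"))
  v
}

#' Sample GC- and length-matched background sequences
#'
#' Emits one random background sequence per foreground sequence with the
#' same length and a GC content matched to within rounding (the number of
#' G/C bases is \code{round(gc * length)}, so the per-sequence GC
#' fraction deviates by at most 0.5/length), well inside the +/- 2
#' percentage-point tolerance required of a matched background.
#'
#' @param seqs foreground sequences
#'   (\link[Biostrings]{DNAStringSet} or character vector over ACGT).
#' @param seed integer seed.
#' @return A \code{DNAStringSet} of matched background sequences.
#' @export
sampleMatchedBackground <- function(seqs, seed = 1L) {
  seqs <- Biostrings::DNAStringSet(seqs)
  set.seed(.streamSeed(seed, "matched_background"))
  gc <- Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE)[, 1L]
  len <- Biostrings::width(seqs)
  out <- vapply(seq_along(seqs), function(i) {
    nGC <- round(gc[i] * len[i])
    bases <- c(sample(c("G", "C"), nGC, replace = TRUE),
      sample(c("A", "T"), len[i] - nGC, replace = TRUE))
    paste(sample(bases), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(out)
}

#' Scan sequences for a motif with log-odds PWM scores
#'
#' Scores every window of every sequence, on both strands, with the
#' log-odds matrix \code{log2((pwm + eps) / bg)} where \code{bg} is the
#' background base composition.  A sequence is a hit when any window
#' score reaches \code{thresholdFrac} of the maximal achievable score
#' (zero-or-one occurrence per sequence counting).
#'
#' @param seqs \code{DNAStringSet} or character vector.
#' @param motif a \linkS4class{MotifModel}.
#' @param bgFreq background base frequencies (named A/C/G/T, summing to
#'   1); default uniform.
#' @param thresholdFrac fraction of the maximal log-odds score required
#'   for a hit; default 0.8.
#' @param eps pseudo-probability added to PWM entries before the log;
#'   default 1e-4.
#' @return A list: \code{hit} (logical per sequence), \code{maxScore}
#'   (best window score per sequence; -Inf when the sequence is shorter
#'   than the motif) and \code{threshold}.
#' @export
scanMotif <- function(seqs, motif, bgFreq = NULL, thresholdFrac = 0.8,
    eps = 1e-4) {
  .checkFraction(thresholdFrac, "thresholdFrac")
  pwm <- motifMatrix(motif)
  if (is.null(bgFreq)) bgFreq <- c(A = .25, C = .25, G = .25, T = .25)
  bgFreq <- bgFreq[c("A", "C", "G", "T")]
  lom <- log2((pwm + eps) / as.numeric(bgFreq))
  W <- ncol(lom)
  maxAchievable <- sum(apply(lom, 2L, max))
  threshold <- thresholdFrac * maxAchievable
  seqs <- as.character(Biostrings::DNAStringSet(seqs))
  scoreOne <- function(v) {
    L <- length(v)
    if (L < W) return(-Inf)
    nWin <- L - W + 1L
    sc <- numeric(nWin)
    ok <- !logical(nWin)
    for (j in seq_len(W)) {
      col <- lom[, j][v[j:(j + nWin - 1L)]]
      nas <- is.na(col)
      col[nas] <- 0
      ok <- ok & !nas
      sc <- sc + col
    }
    sc[!ok] <- -Inf  # windows containing non-ACGT bases never hit
    max(sc)
  }
  maxScore <- vapply(seqs, function(s) {
    v <- .seqToInt(s)
    fwd <- scoreOne(v)
    rc <- rev(5L - v)  # reverse complement in integer code (NA stays NA)
    max(fwd, scoreOne(rc))
  }, numeric(1), USE.NAMES = FALSE)
  list(hit = maxScore >= threshold, maxScore = maxScore,
    threshold = threshold)
}

#' Motif enrichment against a GC/length-matched background
#'
#' Scans foreground and background sequences for each motif
#' (\code{\link{scanMotif}}; both strands, zero-or-one occurrence per
#' sequence), builds the 2x2 table of per-sequence hit counts, tests
#' enrichment one-sided (foreground over background) with the
#' hypergeometric tail, and adjusts across motifs with
#' Benjamini-Hochberg.  Sequences with more than 10\% non-ACGT bases are
#' excluded with a warning.  The log-odds background composition is the
#' base composition of the background set.
#'
#' @param fgSeqs foreground sequences (\code{DNAStringSet} or
#'   character).
#' @param motifs list of \linkS4class{MotifModel} (see
#'   \code{\link{readMotifs}}).
#' @param bgSeqs background sequences; by default drawn with
#'   \code{\link{sampleMatchedBackground}} under \code{seed}.
#' @param fdr significance threshold on the adjusted p; default 0.01.
#' @param thresholdFrac hit threshold as a fraction of the maximal
#'   log-odds score; default 0.8.
#' @param seed seed for the default background sampler.
#' @return A data.frame per motif: \code{motif_id}, \code{fg_hits},
#'   \code{fg_n}, \code{bg_hits}, \code{bg_n}, \code{odds_ratio},
#'   \code{p}, \code{p_adj}, \code{significant}.
#' @export
motifEnrichment <- function(fgSeqs, motifs, bgSeqs = NULL, fdr = 0.01,
    thresholdFrac = 0.8, seed = 1L) {
  fgSeqs <- Biostrings::DNAStringSet(fgSeqs)
  badFrac <- 1 - Biostrings::letterFrequency(fgSeqs, "ACGT",
    as.prob = TRUE)[, 1L]
  if (any(badFrac > 0.1)) {
    warning(sprintf("%d sequence(s) with > 10%% non-ACGT bases excluded",
      sum(badFrac > 0.1)))
    fgSeqs <- fgSeqs[badFrac <= 0.1]
  }
  if (is.null(bgSeqs)) bgSeqs <- sampleMatchedBackground(fgSeqs, seed)
  bgSeqs <- Biostrings::DNAStringSet(bgSeqs)
  comp <- colSums(Biostrings::alphabetFrequency(bgSeqs)[, c("A", "C",
    "G", "T"), drop = FALSE])
  bgFreq <- comp / sum(comp)
  rows <- lapply(motifs, function(mo) {
    fg <- scanMotif(fgSeqs, mo, bgFreq, thresholdFrac)
    bg <- scanMotif(bgSeqs, mo, bgFreq, thresholdFrac)
    a <- sum(fg$hit)
    b <- length(fgSeqs) - a
    cc <- sum(bg$hit)
    d <- length(bgSeqs) - cc
    # one-sided over-representation of hits among foreground sequences
    p <- stats::phyper(a - 1, a + cc, b + d, length(fgSeqs),
      lower.tail = FALSE)
    orCells <- if (any(c(a, b, cc, d) == 0)) c(a, b, cc, d) + 0.5
      else c(a, b, cc, d)
    data.frame(motif_id = motifId(mo), fg_hits = a,
      fg_n = length(fgSeqs), bg_hits = cc, bg_n = length(bgSeqs),
      odds_ratio = (orCells[1L] * orCells[4L]) /
        (orCells[2L] * orCells[3L]),
      p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$p_adj <- bhAdjust(res$p)
  res$significant <- res$p_adj < fdr
  res
}
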