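# Independent brute-force oracles and fixture builders.  Everything here
# is written as plain-loop reference code, deliberately sharing no
# internals with the package implementations it checks.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# --- fixture builders ---------------------------------------------------

randomPeaksDF <- function(n, chroms = c("chr1", "chr2"), span = 5000,
    maxw = 400) {
  chrom <- sample(chroms, n, replace = TRUE)
  s <- sample.int(span, n, replace = TRUE)
  w <- sample.int(maxw, n, replace = TRUE) + 20L
  data.frame(chrom = chrom, start0 = s, end1 = s + w,
    fold = round(runif(n, 1, 10), 3), summit = w %/% 2L,
    stringsAsFactors = FALSE)
}

dfToGR <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$start0 + 1L, df$end1))
  gr$signalValue <- df$fold
  gr$peak <- df$summit
  gr
}

# tiny standalone union-find (independent of the package's)
bfComponents <- function(n, edges) {
  lab <- seq_len(n)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    if (nrow(edges)) for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) {
        lab[lab == lab[a] | lab == lab[b]] <- m
        changed <- TRUE
      }
    }
  }
  lab
}

ovlLen <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

# --- consensus-peak oracle ---------------------------------------------

bfReproducible <- function(r1, r2, minFrac) {
  n1 <- nrow(r1); n2 <- nrow(r2)
  all <- rbind(r1, r2)
  edges <- matrix(0L, 0, 2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (r1$chrom[i] != r2$chrom[j]) next
    ow <- ovlLen(r1$start0[i], r1$end1[i], r2$start0[j], r2$end1[j])
    if (ow >= minFrac * (r1$end1[i] - r1$start0[i]) &&
        ow >= minFrac * (r2$end1[j] - r2$start0[j]))
      edges <- rbind(edges, c(i, n1 + j))
  }
  lab <- bfComponents(n1 + n2, edges)
  keep <- lab %in% lab[duplicated(lab)]
  out <- NULL
  for (l in unique(lab[keep])) {
    idx <- which(lab == l)
    out <- rbind(out, data.frame(chrom = all$chrom[idx[1]],
      start0 = min(all$start0[idx]), end1 = max(all$end1[idx]),
      support = length(idx), meanFold = mean(all$fold[idx]),
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) return(data.frame(chrom = character(0),
    start0 = integer(0), end1 = integer(0), support = integer(0),
    meanFold = numeric(0)))
  out[order(out$chrom, out$start0, out$end1), , drop = FALSE]
}

consensusToDF <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
    start0 = start(gr) - 1L, end1 = end(gr), support = gr$support,
    meanFold = gr$signalValue, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start0, df$end1), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- classification oracle ---------------------------------------------

bfClassify <- function(k4, k27, recipFrac) {
  n4 <- nrow(k4); n27 <- nrow(k27)
  all <- rbind(k4, k27)
  isK4 <- c(rep(TRUE, n4), rep(FALSE, n27))
  edges <- matrix(0L, 0, 2)
  anyOvl <- rep(FALSE, n4 + n27)
  for (i in seq_len(n4)) for (j in seq_len(n27)) {
    if (k4$chrom[i] != k27$chrom[j]) next
    ow <- ovlLen(k4$start0[i], k4$end1[i], k27$start0[j], k27$end1[j])
    if (ow > 0) { anyOvl[i] <- TRUE; anyOvl[n4 + j] <- TRUE }
    if (ow >= recipFrac * (k4$end1[i] - k4$start0[i]) &&
        ow >= recipFrac * (k27$end1[j] - k27$start0[j]))
      edges <- rbind(edges, c(i, n4 + j))
  }
  lab <- bfComponents(n4 + n27, edges)
  merged <- unique(c(edges))
  out <- NULL
  for (l in unique(lab[merged])) {
    idx <- which(lab == l)
    out <- rbind(out, data.frame(chrom = all$chrom[idx[1]],
      start0 = min(all$start0[idx]), end1 = max(all$end1[idx]),
      class = "promoter", stringsAsFactors = FALSE))
  }
  for (i in setdiff(seq_len(n4 + n27), which(lab %in% lab[merged]))) {
    cls <- if (anyOvl[i]) "ambiguous"
      else if (isK4[i]) "promoter" else "enhancer"
    out <- rbind(out, data.frame(chrom = all$chrom[i],
      start0 = all$start0[i], end1 = all$end1[i], class = cls,
      stringsAsFactors = FALSE))
  }
  out[order(out$chrom, out$start0, out$end1, out$class), , drop = FALSE]
}

elementsToDF <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
    start0 = start(gr) - 1L, end1 = end(gr), class = gr$element_class,
    stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start0, df$end1, df$class), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- base-by-base liftover oracle --------------------------------------

bfProject <- function(chrom, s0, e1, chains, minMatch) {
  chains <- as.list(chains)
  cand <- Filter(function(ch) ch@tName == chrom &&
    ch@tStart < e1 && ch@tEnd > s0, chains)
  if (!length(cand))
    return(list(status = "unmapped", frac = 0))
  sc <- vapply(cand, function(ch) ch@score, numeric(1))
  id <- vapply(cand, function(ch) ch@id, integer(1))
  ch <- cand[[order(-sc, id)[1]]]
  qpos <- integer(0)
  for (p in s0:(e1 - 1)) {
    tb <- ch@tStart
    qb <- ch@qStart
    b <- ch@blocks
    for (r in seq_len(nrow(b))) {
      if (p >= tb && p < tb + b[r, 1]) {
        q <- qb + (p - tb)
        if (ch@qStrand == "-") q <- ch@qSize - 1 - q
        qpos <- c(qpos, q)
        break
      }
      tb <- tb + b[r, 1] + b[r, 2]
      qb <- qb + b[r, 1] + b[r, 3]
    }
  }
  frac <- length(qpos) / (e1 - s0)
  if (length(qpos) == 0 || frac < minMatch)
    return(list(status = "unmapped", frac = frac))
  list(status = "mapped", frac = frac, chrom = ch@qName,
    start0 = min(qpos), end1 = max(qpos) + 1L,
    strand = ch@qStrand)
}

# --- set-intersection oracle -------------------------------------------

bfIntersections <- function(sets) {
  un <- unique(unlist(sets))
  sig <- vapply(un, function(el)
    paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
      collapse = "&"), character(1))
  as.list(table(sig))
}

# --- exact 2x2 enumeration oracle --------------------------------------

bfFisherP <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  tabProb <- function(x) {
    # P(table with first cell x) under fixed margins, via choose()
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }
  xs <- max(0, k - n):min(k, m)
  ps <- vapply(xs, tabProb, numeric(1))
  sum(ps[ps <= tabProb(a) * (1 + 1e-7)])
}
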