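# Internal helpers shared across modules.

# format numbers for tab-delimited writers: plain decimal notation, no
# padding, no trailing zeros, element-wise (format() pads vectors).
.fmtNum <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(v, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
  }, character(1))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.checkFraction <- function(x, name, lowerOpen = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be a single number", name)
  lowOk <- if (lowerOpen) x > 0 else x >= 0
  if (!lowOk || x > 1)
    .stopf("'%s' must be in %s0, 1]", name, if (lowerOpen) "(" else "[")
  invisible(x)
}

# deterministic per-stream seed derivation: one named pseudo-random stream
# per generated output, all driven by one user seed.  Kept < 2^31.
.streamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 2654435.0 + h * 97.0) %% 2147483587)
}

# union-find over n nodes given an edge matrix (2 columns of node indices);
# returns a component id per node (components numbered by first member).
.components <- function(n, edges) {
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      a <- findRoot(edges[r, 1L])
      b <- findRoot(edges[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), findRoot, integer(1))
}

# GRanges from 0-based half-open coordinates
.grFromBed <- function(chrom, start0, end1, strand = "*") {
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1L, end = end1),
    strand = strand)
}

.bedStart <- function(gr) GenomicRanges::start(gr) - 1L
.bedEnd <- function(gr) GenomicRanges::end(gr)
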