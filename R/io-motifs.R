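#' Read motif matrices from JASPAR-style PFM or MEME minimal files
#'
#' JASPAR format: records starting with \code{>id name} followed by four
#' lines \code{A [ counts... ]}, \code{C [...]}, \code{G [...]},
#' \code{T [...]} (brackets optional).  MEME minimal format: \code{MOTIF}
#' records with a \code{letter-probability matrix} block (rows are
#' positions, columns A C G T).  Count matrices are normalized to
#' probabilities column-wise.
#'
#' @param path path to the motif file.
#' @param format \code{"auto"} (detected from content), \code{"jaspar"}
#'   or \code{"meme"}.
#' @return A named list of \linkS4class{MotifModel} objects.
#' @export
readMotifs <- function(path, format = c("auto", "jaspar", "meme")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto")
    format <- if (any(grepl("^MEME version", lines))) "meme" else "jaspar"
  motifs <- list()
  if (format == "jaspar") {
    hdr <- grep("^>", lines)
    if (!length(hdr)) .stopf("no JASPAR records found in '%s'", path)
    for (k in seq_along(hdr)) {
      id <- sub("^>\\s*", "", lines[hdr[k]])
      id <- strsplit(id, "[ \t]+")[[1L]][1L]
      rows <- lines[(hdr[k] + 1L):(hdr[k] + 4L)]
      parseRow <- function(ln) {
        ln <- gsub("^[ACGT]\\s*|\\[|\\]", "", ln)
        as.numeric(strsplit(trimws(ln), "[ \t]+")[[1L]])
      }
      m <- do.call(rbind, lapply(rows, parseRow))
      rownames(m) <- c("A", "C", "G", "T")
      motifs[[id]] <- motifModel(id, m)
    }
  } else {
    starts <- grep("^MOTIF", lines)
    if (!length(starts)) .stopf("no MEME MOTIF records found in '%s'", path)
    for (s in starts) {
      id <- strsplit(trimws(lines[s]), "[ \t]+")[[1L]][2L]
      lp <- grep("^letter-probability matrix", lines)
      lp <- lp[lp > s][1L]
      if (is.na(lp)) .stopf("motif '%s' lacks a letter-probability matrix", id)
      w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[lp])
      w <- as.integer(w)
      rows <- lines[(lp + 1L):(lp + w)]
      m <- t(vapply(rows, function(ln)
        as.numeric(strsplit(trimws(ln), "[ \t]+")[[1L]]), numeric(4)))
      m <- t(m)
      rownames(m) <- c("A", "C", "G", "T")
      motifs[[id]] <- motifModel(id, m)
    }
  }
  motifs
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' \code{set_id<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path path to the GMT file.
#' @return A named list of character vectors of gene ids.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      .stopf("GMT record '%s' has fewer than 3 fields", f[1L])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets
}
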