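#' Read precomputed alignments (PSL or BLAST tabular)
#'
#' Lets external aligner output stand in for the built-in aligners.  PSL rows
#' keep their block lists; 12-column BLAST tabular rows (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore) become
#' blockless records: aligned columns are recovered from the span accounting
#' (`qspan + sspan - length`), gap columns as the remainder, so only
#' coverage/identity/gap statistics are available, not block structure.
#' All coordinates are normalised to 0-based half-open.
#'
#' @param path Path to the alignment file.
#' @param dialect `"psl"` or `"blast-tab"`.
#' @param queryLengths,targetLengths Optional named integer vectors supplying
#'   full sequence lengths for BLAST tabular records (the format does not
#'   carry them); coverage is `NA` without them.
#' @return A list of [PairwiseHit-class] records, in file order.
#' @export
readAlignments <- function(path, dialect = c("psl", "blast-tab"),
                           queryLengths = NULL, targetLengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (dialect == "psl") .readPsl(lines) else
    .readBlastTab(lines, queryLengths, targetLengths)
}

.readPsl <- function(lines) {
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 21L)
      stop(sprintf("PSL line %d: expected 21 columns, got %d", i, length(f)),
           call. = FALSE)
    num <- function(j) as.integer(f[j])
    sizes <- as.integer(strsplit(f[19], ",", fixed = TRUE)[[1]])
    qs <- as.integer(strsplit(f[20], ",", fixed = TRUE)[[1]])
    ts <- as.integer(strsplit(f[21], ",", fixed = TRUE)[[1]])
    if (length(sizes) != num(18))
      stop(sprintf("PSL line %d: blockCount disagrees with blockSizes", i),
           call. = FALSE)
    out[[i]] <- PairwiseHit(
      queryId = f[10], targetId = f[14],
      queryLen = num(11), targetLen = num(15),
      strand = substr(f[9], 1L, 1L),
      blocks = cbind(qStart = qs, tStart = ts, length = sizes),
      matches = num(1) + num(3), mismatches = num(2),
      gapColumns = num(6) + num(8), units = "nt")
  }
  out
}

.readBlastTab <- function(lines, queryLengths, targetLengths) {
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 12L)
      stop(sprintf("blast-tab line %d: expected 12 columns, got %d",
                   i, length(f)), call. = FALSE)
    len <- as.integer(f[4]); mm <- as.integer(f[5])
    qs <- as.integer(f[7]); qe <- as.integer(f[8])
    ss <- as.integer(f[9]); se <- as.integer(f[10])
    strand <- if (se < ss) "-" else "+"
    qspan <- abs(qe - qs) + 1L
    sspan <- abs(se - ss) + 1L
    cols <- qspan + sspan - len          # matches + mismatches
    gaps <- max(0L, len - cols)
    matches <- max(0L, cols - mm)
    ql <- if (!is.null(queryLengths)) unname(queryLengths[f[1]]) else NA_integer_
    tl <- if (!is.null(targetLengths)) unname(targetLengths[f[2]]) else NA_integer_
    out[[i]] <- PairwiseHit(
      queryId = f[1], targetId = f[2],
      queryLen = ifelse(is.na(ql), NA_integer_, ql),
      targetLen = ifelse(is.na(tl), NA_integer_, tl),
      strand = strand,
      blocks = matrix(integer(0), ncol = 3L),
      matches = matches, mismatches = mm, gapColumns = gaps,
      evalue = as.numeric(f[11]), blockless = TRUE, units = "nt")
  }
  out
}

#' Write alignment records as PSL
#'
#' Inverse of `readAlignments(..., dialect = "psl")` for block-bearing
#' records; blockless records cannot be exported as PSL.
#'
#' @param hits List of [PairwiseHit-class] records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePsl <- function(hits, path) {
  rows <- vapply(hits, function(h) {
    if (h@blockless) stop("cannot write blockless records as PSL", call. = FALSE)
    b <- h@blocks
    qe <- b[, "qStart"] + b[, "length"]
    te <- b[, "tStart"] + b[, "length"]
    ## split gap columns between the axes from the block geometry
    qg <- if (nrow(b) > 1L) b[-1L, "qStart"] - qe[-nrow(b)] else integer(0)
    tg <- if (nrow(b) > 1L) b[-1L, "tStart"] - te[-nrow(b)] else integer(0)
    paste(h@matches, h@mismatches, 0L, 0L,
          sum(qg > 0L), sum(qg), sum(tg > 0L), sum(tg),
          h@strand, h@queryId, h@queryLen, min(b[, "qStart"]), max(qe),
          h@targetId, h@targetLen, min(b[, "tStart"]), max(te),
          nrow(b),
          paste0(paste(b[, "length"], collapse = ","), ","),
          paste0(paste(b[, "qStart"], collapse = ","), ","),
          paste0(paste(b[, "tStart"], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
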