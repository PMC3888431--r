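#' Translate a nucleotide string in a given frame
#'
#' Standard genetic code ([Biostrings::GENETIC_CODE]); codons containing `N`
#' translate to `X`, stop codons to `*`, and 1-2 trailing nucleotides are
#' ignored.
#'
#' @param dna Nucleotide string over A, C, G, T, N.
#' @param frame Frame offset 0, 1 or 2 from the 5' end.
#' @return The amino-acid string.
#' @examples
#' translateDna("ATGAAATAA", 0)  # "MK*"
#' @export
translateDna <- function(dna, frame = 0L) {
  stopifnot(length(dna) == 1L, frame %in% 0:2)
  if (grepl("[^ACGTN]", dna))
    stop("invalid character in nucleotide sequence", call. = FALSE)
  n <- nchar(dna)
  if (n - frame < 3L) return("")
  starts <- seq.int(frame + 1L, by = 3L, length.out = (n - frame) %/% 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## Scan one oriented sequence (3 frames) for maximal ORFs: per stop-bounded
## frame segment, the 5'-most ATG opens the single reported ORF.  Coordinates
## are 0-based half-open on the scanned (oriented) sequence; the caller maps
## minus-strand spans back to forward-transcript coordinates.
.scanOrfsOneStrand <- function(seq, minLenNt, allowOpen3prime) {
  n <- nchar(seq)
  res <- list()
  for (frame in 0:2) {
    nCodon <- (n - frame) %/% 3L
    if (nCodon < 1L) next
    starts <- seq.int(frame + 1L, by = 3L, length.out = nCodon)
    codons <- substring(seq, starts, starts + 2L)
    isStop <- codons %in% c("TAA", "TAG", "TGA")
    isAtg <- codons == "ATG"
    ## segment index: stops close segments
    stopIdx <- which(isStop)
    segEnd <- c(stopIdx, if (allowOpen3prime) nCodon else integer(0))
    segStart <- c(1L, stopIdx + 1L)[seq_along(segEnd)]
    for (s in seq_along(segEnd)) {
      lo <- segStart[s]; hi <- segEnd[s]
      if (lo > hi) next
      closed <- length(stopIdx) >= s && segEnd[s] == stopIdx[s]
      ## 5'-most ATG in the coding part of the segment (stop codon included
      ## in the span when closed)
      codLo <- lo
      codHi <- if (closed) hi - 1L else hi
      if (codHi < codLo) next
      m <- which(isAtg[codLo:codHi])
      if (!length(m)) next
      a <- codLo + m[1L] - 1L
      spanStart <- starts[a] - 1L                  # 0-based
      spanEnd <- starts[hi] + 2L                   # half-open end
      if (!closed) spanEnd <- starts[hi] + 2L
      len <- spanEnd - spanStart
      if (len < minLenNt) next
      aaSeq <- paste(ifelse(is.na(Biostrings::GENETIC_CODE[codons[a:codHi]]),
                            "X", Biostrings::GENETIC_CODE[codons[a:codHi]]),
                     collapse = "")
      res[[length(res) + 1L]] <- list(frame = frame, start = spanStart,
                                      end = spanEnd, hasStop = closed,
                                      aa = aaSeq)
    }
  }
  res
}

#' Find open reading frames in a transcript
#'
#' Reports every maximal ATG-to-stop span (and, optionally, ATG-to-end spans
#' lacking a stop) of at least `minLenNt` nucleotides across the three frames
#' of each requested strand.  "Maximal" means the 5'-most ATG of each
#' stop-bounded frame segment defines the one reported ORF; nested ATGs are
#' strict sub-ORFs and are not reported.  The stop codon is included in the
#' span but excluded from the translation.
#'
#' @param seq A nucleotide string, or a length-1 named character/DNAStringSet
#'   element; the name (or `id`) identifies the transcript.
#' @param id Transcript identifier used in the output.
#' @param minLenNt Minimum ORF length in nucleotides (stop codon included);
#'   must be at least 3.
#' @param bothStrands Scan the reverse complement as well (default `TRUE`;
#'   de novo contigs are unoriented).
#' @param allowOpen3prime Report ORFs running off the 3' end without a stop
#'   (default `TRUE`; assemblies contain truncated transcripts).
#' @return A data.frame with columns `transcriptId`, `strand`, `frame`,
#'   `start`, `end` (0-based half-open on the forward transcript sequence),
#'   `lengthNt`, `hasStop`, `aa`, sorted by decreasing length with ties
#'   broken by strand (`+` first) then smaller start.
#' @export
findOrfs <- function(seq, id = "transcript", minLenNt = 200L,
                     bothStrands = TRUE, allowOpen3prime = TRUE) {
  if (methods::is(seq, "XStringSet")) {
    if (!is.null(names(seq))) id <- names(seq)[1L]
    seq <- as.character(seq[[1L]])
  } else if (!is.null(names(seq))) id <- names(seq)[1L]
  seq <- toupper(seq)
  if (minLenNt < 3L) stop("minLenNt must be >= 3", call. = FALSE)
  .assertDna(stats::setNames(seq, id))
  n <- nchar(seq)
  rows <- list()
  addRows <- function(hits, strand) {
    for (h in hits) {
      if (strand == "+") { st <- h$start; en <- h$end }
      else { st <- n - h$end; en <- n - h$start }
      rows[[length(rows) + 1L]] <<- data.frame(
        transcriptId = id, strand = strand, frame = h$frame,
        start = st, end = en, lengthNt = h$end - h$start,
        hasStop = h$hasStop, aa = h$aa, stringsAsFactors = FALSE)
    }
  }
  addRows(.scanOrfsOneStrand(seq, minLenNt, allowOpen3prime), "+")
  if (bothStrands)
    addRows(.scanOrfsOneStrand(revcomp(seq), minLenNt, allowOpen3prime), "-")
  if (!length(rows)) {
    return(data.frame(transcriptId = character(0), strand = character(0),
                      frame = integer(0), start = integer(0), end = integer(0),
                      lengthNt = integer(0), hasStop = logical(0),
                      aa = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  o <- order(-out$lengthNt, out$strand != "+", out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Longest ORF of a transcript
#'
#' The first row of `findOrfs(seq, minLenNt = 3)` under its deterministic
#' sort order (longest first; ties broken towards the `+` strand, then the
#' leftmost start), or `NULL` when the transcript contains no ORF.  This is
#' the package's CDS predictor.
#'
#' @inheritParams findOrfs
#' @return A one-row data.frame as in [findOrfs()], or `NULL`.
#' @export
longestOrf <- function(seq, id = "transcript", bothStrands = TRUE,
                       allowOpen3prime = TRUE) {
  o <- findOrfs(seq, id = id, minLenNt = 3L, bothStrands = bothStrands,
                allowOpen3prime = allowOpen3prime)
  if (nrow(o) == 0L) NULL else o[1L, , drop = FALSE]
}

#' Extract the CDS-oriented sequence of an ORF
#'
#' @param seq The forward transcript sequence the ORF was found in.
#' @param orf A one-row ORF data.frame from [findOrfs()].
#' @return The nucleotide sequence of the ORF, reading-strand oriented
#'   (starts with ATG).
#' @export
orfSequence <- function(seq, orf) {
  s <- substr(toupper(seq), orf$start + 1L, orf$end)
  if (orf$strand == "-") s <- revcomp(s)
  s
}

#' Materialise the spliced sequence of a transcript model
#'
#' Concatenates the exon substrings of the model's contig in genomic order
#' and reverse-complements the result for minus-strand models.
#'
#' @param models A [TranscriptModels-class] object.
#' @param genome A named `DNAStringSet` (or named character vector) of
#'   contigs.
#' @return A named character vector of spliced transcript sequences, one per
#'   model.
#' @export
splicedSequence <- function(models, genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  ids <- transcriptIds(models)
  ex <- exonRanges(models)
  ctg <- contigOf(models)
  str <- strandOf(models)
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    if (!ctg[i] %in% names(genome))
      stop(sprintf("contig %s of transcript %s not in genome", ctg[i], ids[i]),
           call. = FALSE)
    g <- genome[[ctg[i]]]
    st <- GenomicRanges::start(ex[[i]]); en <- GenomicRanges::end(ex[[i]])
    if (any(st < 1L) || any(en > nchar(g)))
      stop(sprintf("exon out of contig bounds for transcript %s (exon %d)",
                   ids[i], which(st < 1L | en > nchar(g))[1L]), call. = FALSE)
    s <- paste(substring(g, st, en), collapse = "")
    if (str[i] == "-") s <- revcomp(s)
    out[i] <- s
  }
  stats::setNames(out, ids)
}
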