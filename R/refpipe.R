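## Reference-branch filters: mapping coverage, canonical splice sites, and
## the longest-ORF-per-locus fraction rule.  All thresholds are inclusive on
## the keep side ("less than X removed"), each filter partitions its input
## and is idempotent.

#' Mapping-coverage filter
#'
#' Keeps a transcript model iff its spliced (aligned) length is at least
#' `minCov` of the originating transcript length (`sourceLength`).  Models
#' aligning only partially to the genome are discarded.
#'
#' @param models A [TranscriptModels-class] object with `sourceLength` set.
#' @param minCov Minimum spliced-length / source-length fraction (default
#'   0.90, boundary kept).
#' @return A list with `kept` and `removed` (both `TranscriptModels`) and a
#'   `coverage` vector.
#' @export
filterMappingCoverage <- function(models, minCov = 0.90) {
  ids <- transcriptIds(models)
  sl <- sourceLength(models)
  if (anyNA(sl))
    stop(sprintf("sourceLength missing for transcript %s",
                 ids[is.na(sl)][1L]), call. = FALSE)
  cov <- splicedLength(models) / sl
  keep <- cov >= minCov
  list(kept = subsetModels(models, ids[keep]),
       removed = subsetModels(models, ids[!keep]),
       coverage = cov)
}

#' Canonical splice-site filter
#'
#' Reads the donor and acceptor dinucleotides of every intron on the
#' transcript's strand and keeps the model iff every intron matches a
#' canonical pair.  Single-exon models are always kept.  The default
#' canonical set is GT-AG only (the strictest reading of "non-canonical");
#' GC-AG and AT-AC may be added.
#'
#' @param models A [TranscriptModels-class] object.
#' @param genome Named `DNAStringSet` or character vector of contigs.
#' @param canonicalPairs Character vector of `"donor-acceptor"` pairs.
#' @return A list with `kept`, `removed` and a per-transcript `canonical`
#'   logical vector.
#' @export
filterCanonicalSplice <- function(models, genome, canonicalPairs = "GT-AG") {
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  ids <- transcriptIds(models)
  ex <- exonRanges(models)
  ctg <- contigOf(models)
  str <- strandOf(models)
  ok <- logical(length(ids))
  for (i in seq_along(ids)) {
    st <- GenomicRanges::start(ex[[i]]); en <- GenomicRanges::end(ex[[i]])
    if (length(st) < 2L) { ok[i] <- TRUE; next }
    if (!ctg[i] %in% names(genome))
      stop(sprintf("contig %s not in genome", ctg[i]), call. = FALSE)
    g <- genome[[ctg[i]]]
    iStart <- en[-length(en)] + 1L      # first intron base (1-based)
    iEnd <- st[-1L] - 1L                # last intron base
    if (any(iEnd - iStart + 1L < 4L))
      stop(sprintf("intron shorter than 4 nt in transcript %s", ids[i]),
           call. = FALSE)
    left <- substring(g, iStart, iStart + 1L)
    right <- substring(g, iEnd - 1L, iEnd)
    pairs <- if (str[i] == "+") paste0(left, "-", right) else {
      vapply(seq_along(left), function(j)
        paste0(revcomp(right[j]), "-", revcomp(left[j])), character(1))
    }
    ok[i] <- all(pairs %in% canonicalPairs)
  }
  list(kept = subsetModels(models, ids[ok]),
       removed = subsetModels(models, ids[!ok]),
       canonical = stats::setNames(ok, ids))
}

#' Group transcript models into gene loci
#'
#' Two models belong to the same locus iff they are on the same contig and
#' strand and share at least one base of exonic overlap; loci are the
#' connected components of this relation.  Locus identifiers are
#' deterministic: the lexicographically smallest member transcript id.
#'
#' @param models A [TranscriptModels-class] object.
#' @return A named character vector mapping transcript id to locus id.
#' @export
groupLoci <- function(models) {
  ids <- transcriptIds(models)
  if (!length(ids)) return(stats::setNames(character(0), character(0)))
  ex <- exonRanges(models)
  flat <- unlist(ex, use.names = FALSE)
  txOf <- rep(seq_along(ids), lengths(ex))
  red <- GenomicRanges::reduce(flat, ignore.strand = FALSE, min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(flat, red, ignore.strand = FALSE)
  ## union-find over (transcript, reduced-range) bipartite edges
  nT <- length(ids); nR <- length(red)
  edges <- cbind(txOf[S4Vectors::queryHits(ov)],
                 nT + S4Vectors::subjectHits(ov))
  comp <- .ufComponents(nT + nR, edges)[seq_len(nT)]
  stats::setNames(.componentLabels(ids, comp), ids)
}

#' Longest-ORF locus filter
#'
#' Within each gene locus (computed by [groupLoci()]), keeps a transcript
#' iff its longest-ORF nucleotide length is at least `minFraction` of the
#' longest ORF in the locus.  Transcripts without any ORF are removed
#' whenever another locus member has one.
#'
#' @param models A [TranscriptModels-class] object.
#' @param genome Named `DNAStringSet` or character vector of contigs.
#' @param minFraction Minimum fraction of the locus-maximal ORF length
#'   (default 0.75, boundary kept).
#' @param orfLengths Optional precomputed named vector of longest-ORF
#'   lengths (nt) per transcript, to avoid recomputation.
#' @return A list with `kept`, `removed`, the locus assignment `loci` and
#'   the `orfLength` vector used.
#' @export
filterOrfFraction <- function(models, genome, minFraction = 0.75,
                              orfLengths = NULL) {
  ids <- transcriptIds(models)
  loci <- groupLoci(models)
  if (is.null(orfLengths)) {
    seqs <- splicedSequence(models, genome)
    orfLengths <- vapply(ids, function(id) {
      o <- longestOrf(seqs[[id]], id = id)
      if (is.null(o)) 0L else o$lengthNt
    }, integer(1))
  }
  orfLengths <- orfLengths[ids]
  keep <- logical(length(ids))
  for (loc in unique(loci)) {
    member <- which(loci == loc)
    L <- max(orfLengths[member])
    keep[member] <- if (L == 0L) TRUE else orfLengths[member] >= minFraction * L
  }
  list(kept = subsetModels(models, ids[keep]),
       removed = subsetModels(models, ids[!keep]),
       loci = loci, orfLength = orfLengths)
}

#' Run the reference-branch filter pipeline
#'
#' Applies the mapping-coverage, canonical-splice and longest-ORF-fraction
#' filters in that order and reports per-stage counts.
#'
#' @param models A [TranscriptModels-class] object (already consolidated
#'   transcript models, e.g. from a GTF).
#' @param genome Named `DNAStringSet` or character vector of contigs.
#' @param minCov,canonicalPairs,minOrfFraction Stage thresholds; see the
#'   individual filters.
#' @return A list with `models` (the surviving `TranscriptModels`), `loci`
#'   (locus assignment of the survivors), `report` (per-stage data.frame
#'   with input/kept/removed counts) and `removedIds` (list of removed ids
#'   per stage).
#' @export
runRefPipeline <- function(models, genome, minCov = 0.90,
                           canonicalPairs = "GT-AG", minOrfFraction = 0.75) {
  s1 <- filterMappingCoverage(models, minCov = minCov)
  s2 <- filterCanonicalSplice(s1$kept, genome, canonicalPairs = canonicalPairs)
  s3 <- filterOrfFraction(s2$kept, genome, minFraction = minOrfFraction)
  report <- data.frame(
    stage = c("mapping_coverage", "canonical_splice", "orf_fraction"),
    input = c(length(models), length(s1$kept), length(s2$kept)),
    kept = c(length(s1$kept), length(s2$kept), length(s3$kept)),
    removed = c(length(s1$removed), length(s2$removed), length(s3$removed)),
    stringsAsFactors = FALSE)
  loci <- groupLoci(s3$kept)
  list(models = s3$kept, loci = loci, report = report,
       removedIds = list(mapping_coverage = transcriptIds(s1$removed),
                         canonical_splice = transcriptIds(s2$removed),
                         orf_fraction = transcriptIds(s3$removed)))
}
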