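#' Construct a TranscriptModels object
#'
#' @param exons A named [GenomicRanges::GRangesList], one element per
#'   transcript (1-based closed genomic coordinates, sorted, non-overlapping,
#'   single contig and strand per transcript).
#' @param sourceLength Optional named integer vector giving the nucleotide
#'   length of each originating transcript sequence; recycled with `NA` for
#'   transcripts not named.
#' @return A [TranscriptModels-class] object.
#' @examples
#' gr <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200), "+"))
#' TranscriptModels(gr)
#' @export
TranscriptModels <- function(exons, sourceLength = NULL) {
  exons <- methods::as(exons, "CompressedGRangesList")
  ids <- names(exons)
  sl <- rep(NA_integer_, length(exons))
  names(sl) <- ids
  if (!is.null(sourceLength)) {
    sourceLength <- stats::setNames(as.integer(round(sourceLength)),
                                    names(sourceLength))
    if (is.null(names(sourceLength)))
      stop("sourceLength must be named by transcript id")
    hit <- intersect(names(sourceLength), ids)
    sl[hit] <- sourceLength[hit]
  }
  methods::new("TranscriptModels", exons = exons, sourceLength = sl)
}

#' @describeIn TranscriptModels Transcript identifiers.
#' @param x,object A `TranscriptModels` object.
#' @export
transcriptIds <- function(x) names(x@exons)

#' @describeIn TranscriptModels Exon `GRangesList`, named by transcript.
#' @export
exonRanges <- function(x) x@exons

#' @describeIn TranscriptModels Source (pre-mapping) transcript lengths.
#' @export
sourceLength <- function(x) x@sourceLength

#' @describeIn TranscriptModels Spliced (summed exon) length per transcript.
#' @export
splicedLength <- function(x) {
  stats::setNames(sum(GenomicRanges::width(x@exons)), transcriptIds(x))
}

#' @describeIn TranscriptModels Contig of each transcript.
#' @export
contigOf <- function(x) {
  vapply(as.list(S4Vectors::runValue(GenomicRanges::seqnames(x@exons))),
         function(v) as.character(v)[1L], character(1))
}

#' @describeIn TranscriptModels Strand of each transcript.
#' @export
strandOf <- function(x) {
  vapply(as.list(S4Vectors::runValue(GenomicRanges::strand(x@exons))),
         function(v) as.character(v)[1L], character(1))
}

#' Subset transcript models by transcript id
#'
#' @param x A [TranscriptModels-class] object.
#' @param ids Character vector of transcript ids to keep (order respected).
#' @return A `TranscriptModels` restricted to `ids`.
#' @export
subsetModels <- function(x, ids) {
  stopifnot(all(ids %in% transcriptIds(x)))
  methods::new("TranscriptModels", exons = x@exons[ids],
               sourceLength = x@sourceLength[ids])
}

setMethod("show", "TranscriptModels", function(object) {
  n <- length(object@exons)
  cat(sprintf("TranscriptModels with %d transcript(s)\n", n))
  if (n) {
    nex <- lengths(object@exons)
    cat(sprintf("  contigs: %d | exons per transcript: %d-%d | %d with source length\n",
                length(unique(contigOf(object))), min(nex), max(nex),
                sum(!is.na(object@sourceLength))))
  }
})

setMethod("length", "TranscriptModels", function(x) length(x@exons))
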