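#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end width
#' @importFrom IRanges IRanges
NULL

#' Transcript models on a genome
#'
#' An exon-chain representation of transcripts placed on genome contigs.
#' Exons are stored per transcript as a [GenomicRanges::GRangesList] (1-based
#' closed coordinates, the Bioconductor convention); each transcript has a
#' single contig and strand, exons sorted in genomic order and pairwise
#' non-overlapping.  The optional `sourceLength` records the nucleotide length
#' of the originating (pre-mapping) transcript sequence, the denominator of
#' the mapping-coverage filter.
#'
#' @slot exons A named `GRangesList`, one element per transcript.
#' @slot sourceLength Named integer vector parallel to `exons`; `NA` when the
#'   originating transcript length is unknown.
#' @export
setClass("TranscriptModels",
  representation(exons = "CompressedGRangesList", sourceLength = "integer"))

setValidity("TranscriptModels", function(object) {
  ex <- object@exons
  if (length(ex) == 0L) return(TRUE)
  ids <- names(ex)
  if (is.null(ids)) return("exons must be named by transcript id")
  if (any(!nzchar(ids))) return("empty transcript id")
  if (anyDuplicated(ids)) return("duplicate transcript ids")
  if (length(object@sourceLength) != length(ex))
    return("sourceLength must be parallel to exons")
  if (!identical(names(object@sourceLength), ids))
    return("sourceLength names must match transcript ids")
  if (length(ex) == 0L) return(TRUE)
  nContig <- lengths(unique(GenomicRanges::seqnames(ex)))
  if (any(nContig != 1L))
    return(sprintf("transcript(s) with exons on multiple contigs: %s",
                   paste(utils::head(ids[nContig != 1L], 3L), collapse = ", ")))
  str1 <- unique(GenomicRanges::strand(ex))
  if (any(lengths(str1) != 1L) ||
      !all(unlist(S4Vectors::runValue(GenomicRanges::strand(ex))) %in% c("+", "-")))
    return("each transcript needs one strand, '+' or '-'")
  st <- GenomicRanges::start(ex)
  en <- GenomicRanges::end(ex)
  ok <- vapply(seq_along(ex), function(i) {
    s <- st[[i]]; e <- en[[i]]
    all(diff(s) > 0) && all(s[-1L] > e[-length(e)]) && all(e >= s)
  }, logical(1))
  if (!all(ok))
    return(sprintf("unsorted or overlapping exons in: %s",
                   paste(utils::head(ids[!ok], 3L), collapse = ", ")))
  TRUE
})

#' Pairwise alignment record
#'
#' A block-chain alignment between a query and a target sequence, the common
#' currency of every filter and metric in the package.  Blocks are ungapped
#' aligned segments, 0-based half-open, monotone on both axes; unaligned
#' residues between consecutive blocks (on either axis) are counted as
#' `gapColumns`.  For protein-vs-nucleotide alignments all coordinates and
#' lengths are in amino-acid units of the aligned frame; `targetLen` is then
#' the nucleotide length of the target and coverage accounts for the factor 3.
#'
#' @slot queryId,targetId Sequence identifiers.
#' @slot queryLen,targetLen Full sequence lengths, each in its own unit.
#' @slot strand `"+"` or `"-"` (orientation of the query for nt-nt
#'   alignments, of the target frame for protein-nt).
#' @slot frame Reading frame 0..2 for protein-nt alignments, `NA` otherwise.
#' @slot blocks Integer matrix with columns `qStart`, `tStart`, `length`
#'   (0-based starts); zero rows for blockless records.
#' @slot matches,mismatches,gapColumns Column counts.
#' @slot score Alignment score (matches - mismatches - gap columns at
#'   unit scoring); the ranking used wherever a best hit is chosen.
#' @slot evalue E-value when the record came from BLAST tabular input, else
#'   `NA` (never computed internally).
#' @slot blockless `TRUE` for records whose per-block structure is unknown
#'   (BLAST tabular input); such records support coverage/identity/gap
#'   accounting but not block-level operations.
#' @export
setClass("PairwiseHit",
  representation(queryId = "character", targetId = "character",
                 queryLen = "integer", targetLen = "integer",
                 strand = "character", frame = "integer",
                 blocks = "matrix",
                 matches = "integer", mismatches = "integer",
                 gapColumns = "integer", score = "numeric",
                 evalue = "numeric", blockless = "logical"))

setValidity("PairwiseHit", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  if (object@matches < 0L || object@mismatches < 0L || object@gapColumns < 0L)
    return("negative column counts")
  b <- object@blocks
  if (!object@blockless) {
    if (nrow(b) == 0L) return("non-blockless record needs >= 1 block")
    if (sum(b[, "length"]) != object@matches + object@mismatches)
      return("block lengths must sum to matches + mismatches")
    if (nrow(b) > 1L) {
      qe <- b[, "qStart"] + b[, "length"]
      te <- b[, "tStart"] + b[, "length"]
      if (any(b[-1L, "qStart"] < qe[-nrow(b)]) ||
          any(b[-1L, "tStart"] < te[-nrow(b)]))
        return("blocks must be monotone on both axes")
    }
  }
  TRUE
})
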