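## PairwiseHit constructor and derived quantities.  The derived quantities
## are defined once here and used by every filter and metric:
##   alignment_length = matches + mismatches + gap_columns
##   percent_identity = 100 * matches / (matches + mismatches)
##   query_coverage   = aligned query residues / query length (query units)
##   gap_fraction     = gap_columns / alignment_length

#' Construct a pairwise alignment record
#'
#' @param queryId,targetId Sequence identifiers.
#' @param queryLen,targetLen Full lengths of the two sequences, each in its
#'   own unit (amino acids for a protein query, nucleotides for a nucleotide
#'   target).
#' @param strand Orientation, `"+"` or `"-"`.
#' @param blocks Integer matrix with columns `qStart`, `tStart`, `length`
#'   (0-based half-open starts).
#' @param matches,mismatches,gapColumns Column counts; gap columns are the
#'   unaligned residues between consecutive blocks summed over both axes.
#' @param frame Reading frame (0..2) for protein-vs-nucleotide alignments.
#' @param evalue E-value when known (BLAST tabular input only).
#' @param blockless `TRUE` when per-block structure is unknown.
#' @param units `"nt"` when both sequences are nucleotide, `"aa"` when block
#'   coordinates are amino-acid units over a nucleotide target (coverage then
#'   multiplies by 3 on the target axis), `"aa-aa"` for protein-protein.
#' @return A [PairwiseHit-class] object.
#' @export
PairwiseHit <- function(queryId, targetId, queryLen, targetLen, strand,
                        blocks, matches, mismatches, gapColumns = 0L,
                        frame = NA_integer_, evalue = NA_real_,
                        blockless = FALSE, units = c("nt", "aa", "aa-aa")) {
  units <- match.arg(units)
  if (is.null(dim(blocks))) blocks <- matrix(blocks, ncol = 3L)
  colnames(blocks) <- c("qStart", "tStart", "length")
  storage.mode(blocks) <- "integer"
  h <- methods::new("PairwiseHit",
    queryId = queryId, targetId = targetId,
    queryLen = as.integer(queryLen), targetLen = as.integer(targetLen),
    strand = strand, frame = as.integer(frame), blocks = blocks,
    matches = as.integer(matches), mismatches = as.integer(mismatches),
    gapColumns = as.integer(gapColumns),
    score = as.numeric(matches) - as.numeric(mismatches) -
      as.numeric(gapColumns),
    evalue = as.numeric(evalue), blockless = blockless)
  attr(h, "units") <- units
  h
}

.hitUnits <- function(h) {
  u <- attr(h, "units")
  if (is.null(u)) "nt" else u
}

#' Derived alignment statistics
#'
#' Accessors for the derived quantities of a [PairwiseHit-class]:
#' `alignmentLength()` (matches + mismatches + gap columns),
#' `percentIdentity()` (100 * matches / aligned columns), `queryCoverage()`
#' and `targetCoverage()` (aligned residues over full length, in each
#' sequence's own unit), `gapFraction()` (gap columns over alignment length)
#' and `isUngapped()` (no gap columns and a single block).
#'
#' @param h A `PairwiseHit`.
#' @return A numeric scalar (logical for `isUngapped`).
#' @name hit-stats
NULL

#' @rdname hit-stats
#' @export
alignmentLength <- function(h) h@matches + h@mismatches + h@gapColumns

#' @rdname hit-stats
#' @export
percentIdentity <- function(h) 100 * h@matches / (h@matches + h@mismatches)

#' @rdname hit-stats
#' @export
queryCoverage <- function(h) (h@matches + h@mismatches) / h@queryLen

#' @rdname hit-stats
#' @export
targetCoverage <- function(h) {
  aligned <- h@matches + h@mismatches
  if (.hitUnits(h) == "aa") aligned <- 3L * aligned
  aligned / h@targetLen
}

#' @rdname hit-stats
#' @export
gapFraction <- function(h) {
  al <- alignmentLength(h)
  if (al == 0L) return(0)
  h@gapColumns / al
}

#' @rdname hit-stats
#' @export
isUngapped <- function(h) h@gapColumns == 0L && (h@blockless || nrow(h@blocks) == 1L)

#' @rdname hit-stats
#' @export
hitScore <- function(h) h@score

#' @rdname hit-stats
#' @export
hitEvalue <- function(h) h@evalue

setMethod("show", "PairwiseHit", function(object) {
  cat(sprintf(
    "PairwiseHit %s -> %s [%s%s]: %d block(s), id %.1f%%, qcov %.3f, gapfrac %.4f%s\n",
    object@queryId, object@targetId, object@strand,
    if (is.na(object@frame)) "" else paste0("/f", object@frame),
    max(1L, nrow(object@blocks)), percentIdentity(object),
    queryCoverage(object), gapFraction(object),
    if (object@blockless) " (blockless)" else ""))
})
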