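#' Read transcript models from a GTF file
#'
#' Parses exon features (via [rtracklayer::import()]) into a
#' [TranscriptModels-class] object.  Exons are grouped by their
#' `transcript_id` attribute and sorted in genomic order; each transcript must
#' lie on a single contig and strand.  An optional `source_length` attribute
#' on exon lines carries the nucleotide length of the originating transcript
#' sequence (used by the mapping-coverage filter) and is picked up when
#' present.
#'
#' @param path Path to a GTF file with exon features.
#' @return A [TranscriptModels-class] object.
#' @export
readGtf <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    return(TranscriptModels(GenomicRanges::GRangesList()))
  }
  tid <- gr$transcript_id
  if (is.null(tid) || anyNA(tid) || any(!nzchar(tid))) {
    bad <- if (is.null(tid)) seq_along(gr) else which(is.na(tid) | !nzchar(tid))
    stop(sprintf("exon feature(s) without transcript_id (feature %s)",
                 paste(utils::head(bad, 3L), collapse = ", ")), call. = FALSE)
  }
  o <- order(tid, as.integer(GenomicRanges::start(gr)))
  gr <- gr[o]
  tid <- tid[o]
  sl <- NULL
  if (!is.null(gr$source_length)) {
    sl <- vapply(split(gr$source_length, tid),
                 function(v) suppressWarnings(as.integer(v[1L])), integer(1))
  }
  keep <- intersect(c("transcript_id", "gene_id"), colnames(S4Vectors::mcols(gr)))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep, drop = FALSE]
  grl <- GenomicRanges::GRangesList(split(gr, factor(tid, levels = unique(tid))))
  TranscriptModels(grl, sourceLength = sl)
}

#' Write transcript models to a GTF file
#'
#' The inverse of [readGtf()]: emits one exon line per exon with
#' `transcript_id` and `gene_id` attributes (gene id defaults to the
#' transcript id), plus a `source_length` attribute when known.
#'
#' @param models A [TranscriptModels-class] object.
#' @param path Output path.
#' @param geneId Optional named character vector mapping transcript id to
#'   gene id.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(models, path, geneId = NULL) {
  ex <- exonRanges(models)
  if (length(ex) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- unlist(ex, use.names = FALSE)
  tid <- rep(names(ex), lengths(ex))
  gid <- if (is.null(geneId)) tid else unname(geneId[tid])
  gid[is.na(gid)] <- tid[is.na(gid)]
  sl <- sourceLength(models)[tid]
  S4Vectors::mcols(gr) <- NULL
  gr$source <- "TxConsolidate"
  gr$type <- "exon"
  gr$gene_id <- gid
  gr$transcript_id <- tid
  if (any(!is.na(sl))) gr$source_length <- as.character(sl)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
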