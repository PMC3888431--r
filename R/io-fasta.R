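#' Read a FASTA file of nucleotide or protein sequences
#'
#' Thin, validating wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()].  Sequences are uppercased, ids must be
#' unique and non-empty, and nucleotide sequences are restricted to
#' A, C, G, T, N.  The record id is the first whitespace-delimited token of
#' the header; the remainder is kept in the `description` metadata column.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] (or [Biostrings::AAStringSet]) named
#'   by record id, with a `description` column in `mcols()`.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  .finishFasta(x, dna = TRUE)
}

#' @rdname readFasta
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  .finishFasta(x, dna = FALSE)
}

.finishFasta <- function(x, dna) {
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  .checkIds(ids)
  seqs <- toupper(as.character(x))
  if (any(nchar(seqs) == 0L))
    stop(sprintf("zero-length sequence for id %s", ids[nchar(seqs) == 0L][1L]),
         call. = FALSE)
  names(seqs) <- ids
  if (dna) {
    .assertDna(seqs, "FASTA sequence")
    out <- Biostrings::DNAStringSet(seqs)
  } else {
    bad <- grepl(sprintf("[^%s]", paste0(gsub("\\*", "\\\\*", AA_ALPHABET),
                                         collapse = "")), seqs)
    if (any(bad))
      stop(sprintf("protein sequence with invalid characters: %s",
                   ids[bad][1L]), call. = FALSE)
    out <- Biostrings::AAStringSet(seqs)
  }
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = unname(desc))
  out
}

#' Write sequences to FASTA
#'
#' @param records A named `DNAStringSet`/`AAStringSet` (or named character
#'   vector); a `description` metadata column, if present, is appended to the
#'   header.
#' @param path Output path.
#' @param lineWidth Sequence line width (default 60).
#' @return `path`, invisibly.  Re-reading the file yields identical records.
#' @export
writeFasta <- function(records, path, lineWidth = 60L) {
  if (is.character(records)) records <- Biostrings::BStringSet(records)
  ids <- names(records)
  .checkIds(ids)
  desc <- S4Vectors::mcols(records)$description
  if (!is.null(desc) && any(nzchar(desc))) {
    names(records) <- ifelse(nzchar(desc), paste(ids, desc), ids)
  }
  Biostrings::writeXStringSet(records, filepath = path, width = lineWidth)
  invisible(path)
}
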