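## Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper around
#' [Biostrings::reverseComplement()]; accepts and returns `character`.
#'
#' @param x Single nucleotide string over A, C, G, T, N.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.assertDna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, paste(utils::head(names(x)[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

.checkIds <- function(ids, what = "record") {
  if (any(!nzchar(ids))) stop(sprintf("empty %s id", what), call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s id(s): %s", what,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

## Minimal union-find; used for locus grouping and k-mer clustering.
.ufNew <- function(n) seq_len(n)

.ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

.ufComponents <- function(n, edges) {
  parent <- .ufNew(n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- .ufFind(parent, edges[r, 1L])
      b <- .ufFind(parent, edges[r, 2L])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), function(i) .ufFind(parent, i), integer(1))
}

## Deterministic component labels: lexicographically smallest member id.
.componentLabels <- function(ids, comp) {
  lab <- vapply(split(ids, comp), function(m) sort(m)[1L], character(1))
  unname(lab[as.character(comp)])
}

## All k-mers of a string (character vector, possibly with duplicates).
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

## Canonical k-mers: lexicographic min of k-mer and its reverse complement.
.canonicalKmers <- function(seq, k) {
  km <- unique(.kmers(seq, k))
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (!length(km)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

## Maximal-scoring contiguous run of a +1/-1 score vector (Kadane via prefix
## sums).  Returns NULL when no positive-scoring run exists, else a list with
## 1-based [from, to] within the vector.  Leftmost optimum on ties.
## Positive-scoring runs by recursive Kadane decomposition: the best run,
## the left/right remainders, and -- for runs bridging a deep internal
## valley of mismatches -- the sub-runs on either side of the deepest
## valley, so a chainer can choose between the coarse bridging run and its
## fine parts.  Duplicates are removed.
.positiveRuns <- function(score, minScore = 1L, valleyDepth = 4L) {
  out <- list()
  seen <- character(0)
  emit <- function(lo, hi) {
    if (hi < lo) return(invisible())
    r <- .bestRun(score[lo:hi])
    if (is.null(r) || r$score < minScore) return(invisible())
    from <- lo + r$from - 1L
    to <- lo + r$to - 1L
    key <- paste(from, to)
    if (!(key %in% seen)) {
      seen <<- c(seen, key)
      out[[length(out) + 1L]] <<- list(from = from, to = to, score = r$score)
    }
    emit(lo, from - 1L)
    emit(to + 1L, hi)
    if (to - from >= 3L) {
      v <- .bestRun(-score[(from + 1L):(to - 1L)])
      if (!is.null(v) && v$score >= valleyDepth) {
        emit(from, from + v$from - 1L)
        emit(from + v$to + 1L, to)
      }
    }
    invisible()
  }
  emit(1L, length(score))
  out
}

.bestRun <- function(score) {
  cs <- cumsum(score)
  prefix <- c(0, cs[-length(cs)])
  lo <- cummin(prefix)
  gain <- cs - lo
  best <- max(gain)
  if (best <= 0) return(NULL)
  to <- which.max(gain)
  from <- which(prefix[seq_len(to)] == lo[to])[1L]
  list(from = from, to = to, score = best)
}
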