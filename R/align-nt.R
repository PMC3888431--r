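## Ungapped nucleotide containment aligner: the substrate of the
## cd-hit-est-style dedup stage and of the cross-branch merge rules.

.seedDiagonals <- function(qk, tk) {
  ## candidate diagonals (0-based tStart - qStart) sharing an exact k-mer
  keep <- !grepl("N", tk, fixed = TRUE)
  tki <- which(keep)
  if (!length(tki)) return(integer(0))
  common <- intersect(unique(qk[!grepl("N", qk, fixed = TRUE)]), tk[tki])
  if (!length(common)) return(integer(0))
  qpos <- which(qk %in% common)
  tpl <- split(tki, tk[tki])
  sel <- tpl[qk[qpos]]
  unique(unlist(sel, use.names = FALSE) - rep(qpos, lengths(sel)))
}

## Evaluate one diagonal: maximal-scoring ungapped run (match +1, mismatch
## -1, N never matches).  rq/rt are raw byte vectors; d is tStart - qStart
## (0-based).  Returns NULL or c(qStart, tStart, cols, matches).
.scoreDiagonal <- function(rq, rt, okq, okt, d) {
  m <- length(rq); n <- length(rt)
  qs0 <- max(0L, -d); qe0 <- min(m, n - d)
  if (qe0 - qs0 < 1L) return(NULL)
  qi <- (qs0 + 1L):qe0
  ti <- qi + d
  eq <- (rq[qi] == rt[ti]) & okq[qi] & okt[ti]
  run <- .bestRun(2L * eq - 1L)
  if (is.null(run)) return(NULL)
  cols <- run$to - run$from + 1L
  matches <- sum(eq[run$from:run$to])
  c(qStart = qs0 + run$from - 1L, tStart = qs0 + run$from - 1L + d,
    cols = cols, matches = matches)
}

#' Ungapped nucleotide alignment of a query against a target
#'
#' Seeds shared exact k-mers in both orientations of the query, extends each
#' seeded diagonal without gaps to its maximal-scoring run (match +1,
#' mismatch -1; `N` never matches anything), and returns the single-block
#' record with the most aligned columns among runs reaching
#' `minIdentityPct`.  Ties are broken towards higher identity, then the `+`
#' orientation, then the smallest target start.  For minus-orientation hits
#' the query block coordinates refer to the reverse-complemented query (PSL
#' convention).
#'
#' @param query,target Nucleotide strings (or length-1 named
#'   character/DNAStringSet); names supply the record ids.
#' @param k Seed k-mer length (>= 4).
#' @param minIdentityPct Minimum percent identity of the returned run.
#' @param queryId,targetId Identifier overrides.
#' @param exhaustiveFallback When seeding yields no qualifying run, rescore
#'   every diagonal so the result is exactly the optimum over all ungapped
#'   placements (default `TRUE`).  Bulk callers that only need
#'   containment-grade alignments (which always carry seed words) disable
#'   it for speed.
#' @return A [PairwiseHit-class] with one block, or `NULL` if no qualifying
#'   run exists.
#' @export
ungappedAlignNt <- function(query, target, k = 12L, minIdentityPct = 90,
                            queryId = NULL, targetId = NULL,
                            exhaustiveFallback = TRUE) {
  if (k < 4L) stop("k must be >= 4", call. = FALSE)
  qc <- .asSeq(query, queryId, "query")
  tc <- .asSeq(target, targetId, "target")
  q <- qc$seq; t <- tc$seq
  m <- nchar(q); n <- nchar(t)
  if (m < 1L || n < 1L) stop("sequences must be non-empty", call. = FALSE)
  rt <- charToRaw(t)
  okt <- rt != charToRaw("N")
  tk <- .kmers(t, k)
  scanDiags <- function(seeded) {
    best <- NULL
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") q else revcomp(q)
      rq <- charToRaw(qs)
      okq <- rq != charToRaw("N")
      diags <- if (seeded) {
        if (m >= k && n >= k) sort(.seedDiagonals(.kmers(qs, k), tk))
        else integer(0)
      } else (-(m - 1L)):(n - 1L)
      for (d in diags) {
        cand <- .scoreDiagonal(rq, rt, okq, okt, d)
        if (is.null(cand)) next
        idPct <- 100 * cand[["matches"]] / cand[["cols"]]
        if (idPct < minIdentityPct) next
        key <- c(cand[["cols"]], idPct, strand == "+", -cand[["tStart"]],
                 -cand[["qStart"]])
        if (is.null(best) || .keyGreater(key, best$key)) {
          best <- list(key = key, strand = strand, cand = cand)
        }
      }
    }
    best
  }
  best <- scanDiags(seeded = TRUE)
  if (is.null(best) && exhaustiveFallback) best <- scanDiags(seeded = FALSE)
  if (is.null(best)) return(NULL)
  cand <- best$cand
  PairwiseHit(
    queryId = qc$id, targetId = tc$id, queryLen = m, targetLen = n,
    strand = best$strand,
    blocks = cbind(qStart = cand[["qStart"]], tStart = cand[["tStart"]],
                   length = cand[["cols"]]),
    matches = cand[["matches"]], mismatches = cand[["cols"]] - cand[["matches"]],
    gapColumns = 0L, units = "nt")
}

.asSeq <- function(x, id, fallback) {
  if (methods::is(x, "XStringSet")) {
    if (is.null(id) && !is.null(names(x))) id <- names(x)[1L]
    x <- as.character(x[[1L]])
  } else if (methods::is(x, "XString")) {
    x <- as.character(x)
  } else if (!is.null(names(x))) {
    if (is.null(id)) id <- names(x)[1L]
    x <- unname(x[1L])
  }
  list(seq = toupper(x), id = if (is.null(id)) fallback else id)
}

## lexicographic "greater than" over numeric keys
.keyGreater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}
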