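## Dynamic-programming label oracle used by the synthetic-data generator:
## expected evaluation classes are computed from optimal local alignments
## (Biostrings::pairwiseAlignment, unit match/mismatch scoring, linear gap
## penalty) rather than hand-asserted, so truth labels track the thresholds
## in force.  The production classifier travels a different route (word
## seeding + ungapped extension + chaining), which is exactly why the
## generator labels are an independent check on it.

.unitAAMatrix <- function() {
  letters <- AA_ALPHABET
  m <- matrix(-1, nrow = length(letters), ncol = length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m["X", "X"] <- -1   # ambiguous residues never match
  m["*", "*"] <- -1
  m
}

#' Optimal local protein alignment statistics (DP oracle)
#'
#' Smith-Waterman local alignment of two amino-acid strings under unit
#' match/mismatch scoring and a linear gap penalty, via
#' [Biostrings::pairwiseAlignment()].  The default penalty of 4 per gap
#' residue tolerates genuine small in-frame indels (flanked by enough
#' matches to pay for them) while suppressing spurious gap bridging into
#' unrelated sequence.
#'
#' @param q,t Amino-acid strings (query, target).
#' @param gapPenalty Linear per-residue gap penalty.
#' @return A list with `matches`, `mismatches`, `gaps` (gap columns summed
#'   over both axes), `identity` (percent), `queryCoverage`,
#'   `targetCoverage` and `score` (matches - mismatches - gap columns,
#'   the unit-score ranking used throughout).
#' @export
dpAlignProtein <- function(q, t, gapPenalty = 4) {
  pw <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(t), type = "local",
    substitutionMatrix = .unitAAMatrix(),
    gapOpening = 0, gapExtension = gapPenalty)
  mat <- Biostrings::nmatch(pw)
  mis <- Biostrings::nmismatch(pw)
  ins <- sum(IRanges::width(Biostrings::insertion(pw)[[1L]]))
  del <- sum(IRanges::width(Biostrings::deletion(pw)[[1L]]))
  cols <- mat + mis
  list(matches = mat, mismatches = mis, gaps = ins + del,
       identity = if (cols > 0) 100 * mat / cols else 0,
       queryCoverage = cols / nchar(q),
       targetCoverage = cols / nchar(t),
       score = mat - mis - (ins + del))
}

.defaultClassifyThresholds <- function() {
  list(minOrfNt = 200L, word = 5L, refCov = 0.90, queryCov = 0.90,
       maxGapFraction = 0.01, minIdentityPct = 90, minMatches = 33L,
       gapPenalty = 4)
}

#' Oracle classification of one transcript
#'
#' The generator-side twin of the production classifier: enumerates the
#' transcript's ORFs, aligns their translations against candidate
#' reference proteins with the DP oracle ([dpAlignProtein()]) and applies
#' the correct/incomplete/false rules to the best significant hit, using
#' identical significance and threshold conventions.
#'
#' @param seq Nucleotide transcript sequence.
#' @param proteins Named character vector of reference proteins.
#' @param index Optional precomputed word index over `proteins`.
#' @param thresholds Overrides of the default threshold list.
#' @return The class string: `correct`, `incomplete`, `false` or `no_hit`.
#' @export
oracleClassify <- function(seq, proteins, index = NULL, thresholds = list()) {
  th <- utils::modifyList(.defaultClassifyThresholds(), thresholds)
  if (is.null(index)) index <- .wordIndex(proteins, word = th$word)
  orfs <- findOrfs(seq, minLenNt = th$minOrfNt)
  best <- NULL
  if (nrow(orfs)) {
    for (r in seq_len(nrow(orfs))) {
      cand <- .wordCandidates(orfs$aa[r], index, word = th$word)
      for (pid in sort(cand)) {
        a <- dpAlignProtein(orfs$aa[r], proteins[[pid]],
                            gapPenalty = th$gapPenalty)
        if (a$identity < th$minIdentityPct || a$matches < th$minMatches) next
        key <- list(score = a$score, tid = pid)
        if (is.null(best) || a$score > best$a$score ||
            (a$score == best$a$score && pid < best$tid)) {
          best <- list(a = a, tid = pid)
        }
      }
    }
  }
  if (is.null(best)) return("no_hit")
  a <- best$a
  gf <- if (a$matches + a$mismatches + a$gaps > 0)
    a$gaps / (a$matches + a$mismatches + a$gaps) else 0
  if (a$targetCoverage >= th$refCov && gf <= th$maxGapFraction) "correct"
  else if (gf <= th$maxGapFraction && a$targetCoverage < th$refCov &&
           a$queryCoverage >= th$queryCov) "incomplete"
  else "false"
}

#' @rdname oracleClassify
#' @param seqs Named character vector of transcripts.
#' @return For `oracleClassifySet`: a named character vector of classes.
#' @export
oracleClassifySet <- function(seqs, proteins, thresholds = list()) {
  th <- utils::modifyList(.defaultClassifyThresholds(), thresholds)
  index <- .wordIndex(proteins, word = th$word)
  vapply(seqs, oracleClassify, character(1), proteins = proteins,
         index = index, thresholds = thresholds)
}
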