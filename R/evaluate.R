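## Reference-proteome evaluation statistics: the correct/incomplete/false
## classifier, the u80 completeness metric with gap classes, the presence
## test and the cluster-vs-locus paralog contingency table.
##
## Significance without e-values: rules stated as e-value cutoffs are
## applied verbatim when records carry e-values (BLAST tabular input); for
## internal unit-score alignments they are replaced by a minimum-matches
## proxy (~ the information content of the corresponding e-value at unit
## scoring): 33 matched residues for the 1e-20 classification cutoff, 16
## for the 1e-5 presence cutoff.  Both are configurable.

.isSignificant <- function(h, minIdentityPct, maxEvalue, minMatches) {
  if (!is.na(minIdentityPct) && percentIdentity(h) < minIdentityPct)
    return(FALSE)
  if (!is.na(h@evalue)) h@evalue <= maxEvalue else h@matches >= minMatches
}

.bestHit <- function(hits) {
  if (!length(hits)) return(NULL)
  key <- vapply(hits, function(h) h@score, numeric(1))
  tid <- vapply(hits, function(h) h@targetId, character(1))
  o <- order(-key, tid)
  hits[[o[1L]]]
}

## inverted word index over a set of protein sequences
.wordIndex <- function(aaSeqs, word = 5L) {
  w <- lapply(aaSeqs, function(s) {
    ww <- unique(.kmers(s, word))
    ww[!grepl("[X*]", ww)]
  })
  split(rep(names(aaSeqs), lengths(w)), unlist(w, use.names = FALSE))
}

.wordCandidates <- function(aaSeq, index, word = 5L) {
  ww <- unique(.kmers(aaSeq, word))
  ww <- ww[!grepl("[X*]", ww)]
  unique(unlist(index[intersect(ww, names(index))], use.names = FALSE))
}

## all amino-acid words seen in the six-frame translation of a transcript
.sixFrameWords <- function(seq, word = 5L) {
  out <- character(0)
  for (s in c(seq, revcomp(seq))) {
    for (f in 0:2) {
      aa <- translateDna(s, f)
      if (nchar(aa) >= word) out <- c(out, .kmers(aa, word))
    }
  }
  ww <- unique(out)
  ww[!grepl("[X*]", ww)]
}

#' Classify a transcript from its protein hits
#'
#' Applies the correct/incomplete/false rules to the best significant hit
#' among `hits` (alignments of the transcript's translated ORFs, as query,
#' against reference proteins, as target).  A hit is significant when its
#' identity reaches `minIdentityPct` and it passes the e-value cutoff
#' (`maxEvalue` when an e-value is known, else at least `minMatches` matched
#' residues).  The best significant hit (highest score; ties towards the
#' first target id) is classified: reference protein covered at least
#' `refCov` with gap fraction at most `maxGapFraction` is `correct`;
#' reference under-covered but the query (translated ORF) covered at least
#' `queryCov` with the same gap limit is `incomplete`; any other significant
#' hit is `false`; no significant hit is `no_hit`.
#'
#' @param hits List of [PairwiseHit-class] records (query = translated ORF,
#'   target = reference protein).
#' @param refCov,queryCov Coverage thresholds (default 0.90 each).
#' @param maxGapFraction Gap tolerance (default 0.01).
#' @param minIdentityPct Identity floor for significance (default 90).
#' @param maxEvalue,minMatches Significance cutoff and its internal proxy.
#' @return A list with `class` (one of `correct`, `incomplete`, `false`,
#'   `no_hit`) and `best` (the classified hit, or `NULL`).
#' @export
classifyTranscript <- function(hits, refCov = 0.90, queryCov = 0.90,
                               maxGapFraction = 0.01, minIdentityPct = 90,
                               maxEvalue = 1e-20, minMatches = 33L) {
  sig <- Filter(function(h) .isSignificant(h, minIdentityPct, maxEvalue,
                                           minMatches), hits)
  best <- .bestHit(sig)
  if (is.null(best)) return(list(class = "no_hit", best = NULL))
  gf <- gapFraction(best)
  tc <- targetCoverage(best)
  qc <- queryCoverage(best)
  cls <- if (tc >= refCov && gf <= maxGapFraction) "correct"
    else if (gf <= maxGapFraction && tc < refCov && qc >= queryCov) "incomplete"
    else "false"
  list(class = cls, best = best)
}

#' Classify a transcript set against a reference proteome
#'
#' For each transcript, finds all ORFs of at least `minOrfNt`, aligns their
#' translations against candidate reference proteins (exact-word prefilter,
#' then [proteinAlign()]), and classifies the transcript from its pooled
#' hits with [classifyTranscript()].  Fractions are computed over the
#' transcripts with a significant hit (the `no_hit` class is excluded from
#' the denominator, and fractions are `NA` when no transcript has a hit).
#'
#' @param transcripts Named `DNAStringSet` or named character vector.
#' @param proteins Named `AAStringSet` or named character vector of
#'   reference proteins.
#' @param minOrfNt Minimum ORF length screened (default 200 nt).
#' @param word Prefilter/seed word size.
#' @inheritParams classifyTranscript
#' @return A list with `fractions` (named numeric: correct, incomplete,
#'   false), `classes` (per-transcript data.frame with class and best-hit
#'   evidence) and `nWithHit`.
#' @export
classifySet <- function(transcripts, proteins, minOrfNt = 200L, word = 5L,
                        refCov = 0.90, queryCov = 0.90,
                        maxGapFraction = 0.01, minIdentityPct = 90,
                        maxEvalue = 1e-20, minMatches = 33L) {
  ts <- if (methods::is(transcripts, "XStringSet"))
    stats::setNames(as.character(transcripts), names(transcripts)) else transcripts
  pr <- if (methods::is(proteins, "XStringSet"))
    stats::setNames(as.character(proteins), names(proteins)) else proteins
  index <- .wordIndex(pr, word = word)
  rows <- list()
  for (id in names(ts)) {
    orfs <- findOrfs(ts[[id]], id = id, minLenNt = minOrfNt)
    hits <- list()
    if (nrow(orfs)) {
      for (r in seq_len(nrow(orfs))) {
        cand <- .wordCandidates(orfs$aa[r], index, word = word)
        for (pid in sort(cand)) {
          h <- proteinAlign(orfs$aa[r], pr[[pid]], word = word,
                            minIdentityPct = 0,
                            queryId = paste0(id, ".orf", r), targetId = pid)
          if (!is.null(h)) hits[[length(hits) + 1L]] <- h
        }
      }
    }
    cl <- classifyTranscript(hits, refCov = refCov, queryCov = queryCov,
                             maxGapFraction = maxGapFraction,
                             minIdentityPct = minIdentityPct,
                             maxEvalue = maxEvalue, minMatches = minMatches)
    b <- cl$best
    rows[[id]] <- data.frame(
      transcriptId = id, class = cl$class,
      bestProtein = if (is.null(b)) NA_character_ else b@targetId,
      identity = if (is.null(b)) NA_real_ else percentIdentity(b),
      refCoverage = if (is.null(b)) NA_real_ else targetCoverage(b),
      orfCoverage = if (is.null(b)) NA_real_ else queryCoverage(b),
      gapFraction = if (is.null(b)) NA_real_ else gapFraction(b),
      stringsAsFactors = FALSE)
  }
  classes <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(transcriptId = character(0), class = character(0))
  nWithHit <- sum(classes$class != "no_hit")
  fr <- if (nWithHit == 0L) c(correct = NA_real_, incomplete = NA_real_,
                              false = NA_real_)
  else c(correct = sum(classes$class == "correct") / nWithHit,
         incomplete = sum(classes$class == "incomplete") / nWithHit,
         false = sum(classes$class == "false") / nWithHit)
  list(fractions = fr, classes = classes, nWithHit = nWithHit)
}

#' The u80 reference-proteome completeness metric
#'
#' Aligns each reference protein against the transcript set
#' ([translatedAlign()], six frames) and keeps alignments covering at least
#' `minCov` of the protein.  A protein counts towards u80 iff at least one
#' coverage-qualified alignment is ungapped (a single gap-free alignment
#' must cover it; multiple transcripts may not jointly cover a protein).
#' Every protein is also assigned its best gap class among qualified
#' alignments -- `ungapped`, `gap_le_5pct` (gap fraction at most 5% of the
#' alignment length), `gap_gt_5pct` -- or `uncovered`.
#'
#' @param proteins Named `AAStringSet` or named character vector.
#' @param transcripts Named `DNAStringSet` or named character vector.
#' @param minCov Minimum protein coverage (default 0.80, boundary counted).
#' @param word,maxJoinGap,minIdentityPct Aligner parameters (identity floor
#'   70, the stringency the metric was designed with).
#' @return A list with `u80` (count), `u80Ids` (protein ids), `gapClass`
#'   (named character vector over all proteins) and `classCounts`.
#' @export
u80Metric <- function(proteins, transcripts, minCov = 0.80, word = 5L,
                      maxJoinGap = 30L, minIdentityPct = 70) {
  pr <- if (methods::is(proteins, "XStringSet"))
    stats::setNames(as.character(proteins), names(proteins)) else proteins
  ts <- if (methods::is(transcripts, "XStringSet"))
    stats::setNames(as.character(transcripts), names(transcripts)) else transcripts
  ## prefilter: protein words against six-frame transcript words
  tw <- lapply(ts, .sixFrameWords, word = word)
  inv <- split(rep(names(ts), lengths(tw)), unlist(tw, use.names = FALSE))
  gapClass <- stats::setNames(rep("uncovered", length(pr)), names(pr))
  rank <- c(ungapped = 3L, gap_le_5pct = 2L, gap_gt_5pct = 1L, uncovered = 0L)
  for (pid in names(pr)) {
    cand <- .wordCandidates(pr[[pid]], inv, word = word)
    for (tid in sort(cand)) {
      h <- translatedAlign(pr[[pid]], ts[[tid]], word = word,
                           maxJoinGap = maxJoinGap,
                           minIdentityPct = minIdentityPct,
                           queryId = pid, targetId = tid)
      if (is.null(h) || queryCoverage(h) < minCov) next
      cls <- if (isUngapped(h)) "ungapped"
        else if (gapFraction(h) <= 0.05) "gap_le_5pct" else "gap_gt_5pct"
      if (rank[cls] > rank[gapClass[pid]]) gapClass[pid] <- cls
      if (cls == "ungapped") break
    }
  }
  u80Ids <- names(pr)[gapClass == "ungapped"]
  counts <- vapply(names(rank), function(cl) sum(gapClass == cl), integer(1))
  list(u80 = length(u80Ids), u80Ids = u80Ids, gapClass = gapClass,
       classCounts = counts)
}

#' Proteins unique to one transcript set's u80
#'
#' Runs [u80Metric()] on each set and counts, per set, the reference
#' proteins that fall into that set's u80 and no other's.
#'
#' @param proteins Named `AAStringSet` or named character vector.
#' @param transcriptSets Named list of at least two transcript sets.
#' @param ... Passed to [u80Metric()].
#' @return A list with `uniqueCounts` (named integer per set) and
#'   `u80Ids` (per-set protein id lists).
#' @export
uniqueU80 <- function(proteins, transcriptSets, ...) {
  if (length(transcriptSets) < 2L)
    stop("need at least two transcript sets", call. = FALSE)
  ids <- lapply(transcriptSets, function(ts) u80Metric(proteins, ts, ...)$u80Ids)
  all <- unlist(ids, use.names = FALSE)
  once <- names(table(all))[table(all) == 1L]
  uniq <- vapply(ids, function(x) length(intersect(x, once)), integer(1))
  list(uniqueCounts = uniq, u80Ids = ids)
}

#' Protein presence test across merging
#'
#' A reference protein is present in the combined (pre-merge) set iff it
#' has a significant hit there; it is retained in the final set iff it has
#' a significant final hit whose percent identity is not more than
#' `maxIdentityDropPoints` below the identity of its best combined hit.
#' Hits are six-frame [translatedAlign()] alignments; significance uses the
#' relaxed presence cutoff (e-value 1e-5, or its internal minimum-matches
#' proxy).
#'
#' @param proteins Named `AAStringSet` or named character vector.
#' @param combined,final Transcript sets (named, nucleotide).
#' @param maxIdentityDropPoints Tolerated identity drop, percentage points
#'   (default 5).
#' @param minMatches Internal significance proxy for the 1e-5 cutoff.
#' @param word,minIdentityPct Aligner parameters.
#' @return A list with `presentInCombined`, `presentInFinal`, `missing`
#'   (protein id vectors) and a per-protein `table` of best identities.
#' @export
presenceTest <- function(proteins, combined, final,
                         maxIdentityDropPoints = 5, minMatches = 16L,
                         word = 5L, minIdentityPct = 0) {
  pr <- if (methods::is(proteins, "XStringSet"))
    stats::setNames(as.character(proteins), names(proteins)) else proteins
  bestIdentity <- function(ts) {
    ts <- if (methods::is(ts, "XStringSet"))
      stats::setNames(as.character(ts), names(ts)) else ts
    tw <- lapply(ts, .sixFrameWords, word = word)
    inv <- split(rep(names(ts), lengths(tw)), unlist(tw, use.names = FALSE))
    out <- stats::setNames(rep(NA_real_, length(pr)), names(pr))
    for (pid in names(pr)) {
      cand <- .wordCandidates(pr[[pid]], inv, word = word)
      hits <- list()
      for (tid in sort(cand)) {
        h <- translatedAlign(pr[[pid]], ts[[tid]], word = word,
                             minIdentityPct = minIdentityPct,
                             queryId = pid, targetId = tid)
        if (!is.null(h) && h@matches >= minMatches)
          hits[[length(hits) + 1L]] <- h
      }
      b <- .bestHit(hits)
      if (!is.null(b)) out[pid] <- percentIdentity(b)
    }
    out
  }
  idC <- bestIdentity(combined)
  idF <- bestIdentity(final)
  presentC <- names(pr)[!is.na(idC)]
  presentF <- names(pr)[!is.na(idF) & !is.na(idC) &
                          idF >= idC - maxIdentityDropPoints]
  presentF <- union(presentF, names(pr)[!is.na(idF) & is.na(idC)])
  missing <- setdiff(presentC, presentF)
  list(presentInCombined = presentC, presentInFinal = presentF,
       missing = missing,
       table = data.frame(proteinId = names(pr),
                          identityCombined = unname(idC),
                          identityFinal = unname(idF),
                          stringsAsFactors = FALSE))
}

#' Cluster-versus-locus paralog contingency table
#'
#' Cross-tabulates sequence clusters against gene loci.  Each cluster falls
#' in column `single_locus` (its members map to exactly one locus),
#' `multiple_loci` (more than one; candidate paralog families) or
#' `no_locus` (no member maps).  A cluster is counted in row
#' `multiple_cluster` iff it shares at least one locus with a different
#' cluster, else `unique_cluster`.
#'
#' @param clusters Named list mapping cluster id to member transcript ids
#'   (as from [clusterKmer()]).
#' @param loci Named character vector mapping transcript id to locus id,
#'   `NA` for transcripts without a locus (as from [groupLoci()], possibly
#'   extended with `NA`s).
#' @return A 2x3 integer matrix with the row/column layout above.
#' @export
paralogTable <- function(clusters, loci) {
  member <- unlist(clusters, use.names = FALSE)
  if (!all(member %in% names(loci)))
    stop(sprintf("transcript(s) in clusters but not in loci: %s",
                 paste(utils::head(setdiff(member, names(loci)), 3L),
                       collapse = ", ")), call. = FALSE)
  lociOf <- lapply(clusters, function(m) unique(loci[m][!is.na(loci[m])]))
  colOf <- vapply(lociOf, function(l)
    if (length(l) == 0L) "no_locus" else if (length(l) == 1L) "single_locus"
    else "multiple_loci", character(1))
  locusUsers <- split(rep(names(clusters), lengths(lociOf)),
                      unlist(lociOf, use.names = FALSE))
  sharedClusters <- unique(unlist(locusUsers[lengths(locusUsers) > 1L],
                                  use.names = FALSE))
  rowOf <- ifelse(names(clusters) %in% sharedClusters,
                  "multiple_cluster", "unique_cluster")
  tab <- matrix(0L, nrow = 2L, ncol = 3L,
                dimnames = list(c("unique_cluster", "multiple_cluster"),
                                c("single_locus", "multiple_loci", "no_locus")))
  for (i in seq_along(clusters)) {
    tab[rowOf[i], colOf[i]] <- tab[rowOf[i], colOf[i]] + 1L
  }
  tab
}
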