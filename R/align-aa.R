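## Protein chain aligner: seeds exact amino-acid words, extends each seeded
## diagonal without gaps (match +1, mismatch -1; X and * never match), then
## chains co-diagonal-compatible blocks.  Used directly for protein-protein
## comparison and per reading frame for protein-vs-translated-nucleotide.

.aaSeedDiagonals <- function(q, t, word) {
  if (nchar(q) < word || nchar(t) < word) return(integer(0))
  qk <- .kmers(q, word)
  tk <- .kmers(t, word)
  drop <- function(x) grepl("[X*]", x)
  tki <- which(!drop(tk))
  if (!length(tki)) return(integer(0))
  common <- intersect(unique(qk[!drop(qk)]), tk[tki])
  if (!length(common)) return(integer(0))
  qpos <- which(qk %in% common)
  tpl <- split(tki, tk[tki])
  sel <- tpl[qk[qpos]]
  unique(unlist(sel, use.names = FALSE) - rep(qpos, lengths(sel)))
}

## Returns a list(blocks, matches, mismatches, gapColumns) or NULL.
## Blocks are 0-based (qStart, tStart, length) in amino-acid units.
##
## Chaining allows candidate runs from neighbouring diagonals to overlap by
## a few columns (runs extend past an indel junction whenever the flanking
## columns happen to match on both diagonals); an overlapping link trims the
## junction, splitting the overlapped columns between the two blocks so
## that the chained match count is maximal -- the same local optimum a
## banded DP would pick.
.chainAlignAA <- function(q, t, word = 5L, maxJoinGap = 30L) {
  diags <- .aaSeedDiagonals(q, t, word)
  if (!length(diags)) return(NULL)
  rq <- charToRaw(q); rt <- charToRaw(t)
  okq <- !(rq %in% charToRaw("X*")); okt <- !(rt %in% charToRaw("X*"))
  qS <- tS <- cols <- mats <- integer(0)
  eqs <- list()
  for (d in sort(diags)) {
    m <- length(rq); n <- length(rt)
    qs0 <- max(0L, -d); qe0 <- min(m, n - d)
    if (qe0 - qs0 < 1L) next
    qi <- (qs0 + 1L):qe0
    eq <- (rq[qi] == rt[qi + d]) & okq[qi] & okt[qi + d]
    ## a diagonal can carry several blocks (e.g. a deletion followed by a
    ## compensating insertion); decompose it into all strong positive runs
    for (run in .positiveRuns(2L * eq - 1L, minScore = min(word, qe0 - qs0))) {
      k <- length(qS) + 1L
      qS[k] <- qs0 + run$from - 1L
      tS[k] <- qS[k] + d
      cols[k] <- run$to - run$from + 1L
      mats[k] <- sum(eq[run$from:run$to])
      eqs[[k]] <- eq[run$from:run$to]
    }
  }
  if (!length(qS)) return(NULL)
  o <- order(qS, tS)
  qS <- qS[o]; tS <- tS[o]; cols <- cols[o]; mats <- mats[o]; eqs <- eqs[o]
  nb <- length(qS)
  qE <- qS + cols
  tE <- tS + cols
  headM <- lapply(eqs, function(e) c(0L, cumsum(e)))   # matches in first x cols
  ## DP over blocks: maximise chained matches; tie-break towards fewer gap
  ## columns.  linkTrim[j -> i]: columns removed at the junction, split as
  ## (s from the end of j, ov - s from the start of i).
  sc <- mats
  gp <- integer(nb)
  prev <- rep(0L, nb)
  trimJ <- trimI <- rep(0L, nb)      # trims applied at the link into block i
  for (i in seq_len(nb)[-1]) {
    for (j in seq_len(i - 1L)) {
      ov <- max(0L, qE[j] - qS[i], tE[j] - tS[i])
      if (ov > cols[j] - 1L + cols[i] - 1L) next
      qg <- qS[i] + ov - qE[j]
      tg <- tS[i] + ov - tE[j]
      if (qg < 0L || tg < 0L || qg > maxJoinGap || tg > maxJoinGap) next
      availJ <- cols[j] - 1L - if (prev[j] > 0L) trimI[j] else 0L
      sLo <- max(0L, ov - (cols[i] - 1L))
      sHi <- min(ov, availJ)
      if (sHi < sLo) next
      ss <- sLo:sHi
      ## matches kept = sc[j] - tail_j(s) + mats[i] - head_i(ov - s)
      kept <- -(headM[[j]][cols[j] + 1L] - headM[[j]][cols[j] + 1L - ss]) -
        headM[[i]][ov - ss + 1L]
      w <- which.max(kept)
      s <- sc[j] + mats[i] + kept[w]
      g <- gp[j] + qg + tg
      if (s > sc[i] || (s == sc[i] && g < gp[i])) {
        sc[i] <- s; gp[i] <- g; prev[i] <- j
        trimJ[i] <- ss[w]; trimI[i] <- ov - ss[w]
      }
    }
  }
  i <- which(sc == max(sc))
  i <- i[which.min(gp[i])][1L]
  chain <- integer(0)
  while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
  ## materialise the chain with junction trims applied
  nB <- length(chain)
  bq <- qS[chain]; bt <- tS[chain]; bl <- cols[chain]
  cut0 <- integer(nB)                 # columns trimmed from each block start
  for (p in seq_len(nB)[-1]) {
    i <- chain[p]
    bl[p - 1L] <- bl[p - 1L] - trimJ[i]
    bq[p] <- bq[p] + trimI[i]
    bt[p] <- bt[p] + trimI[i]
    bl[p] <- bl[p] - trimI[i]
    cut0[p] <- trimI[i]
  }
  matches <- 0L
  for (p in seq_len(nB)) {
    e <- eqs[[chain[p]]]
    matches <- matches + sum(e[(cut0[p] + 1L):(cut0[p] + bl[p])])
  }
  colsTot <- sum(bl)
  gaps <- if (nB > 1L) {
    sum(bq[-1L] - (bq[-nB] + bl[-nB])) + sum(bt[-1L] - (bt[-nB] + bl[-nB]))
  } else 0L
  list(blocks = cbind(qStart = bq, tStart = bt, length = bl),
       matches = matches, mismatches = colsTot - matches, gapColumns = gaps)
}

#' Align a protein query to a nucleotide target via six-frame translation
#'
#' Translates the target in all six frames, seeds exact protein words,
#' extends ungapped on amino-acid identity (+1/-1 unit scoring, no
#' substitution matrix -- every downstream rule consumes only
#' coverage/identity/gap thresholds) and chains co-frame blocks whose
#' inter-block offsets on either axis are at most `maxJoinGap` residues,
#' counting the offsets as gap columns.  Returns the chain with maximal
#' matches subject to `minIdentityPct`, with deterministic tie-breaks
#' (higher identity, `+` strand, lower frame, smaller target start).
#'
#' @param protein Amino-acid string (or length-1 named character/AAStringSet).
#' @param target Nucleotide string (likewise).
#' @param word Exact-word seed length in amino acids.
#' @param maxJoinGap Maximum inter-block offset, in residues, joined into one
#'   chain.
#' @param minIdentityPct Minimum percent identity of the returned chain.
#' @param queryId,targetId Identifier overrides.
#' @return A [PairwiseHit-class] in amino-acid units (target coverage
#'   accounts for the factor 3), or `NULL`.
#' @export
translatedAlign <- function(protein, target, word = 5L, maxJoinGap = 30L,
                            minIdentityPct = 70, queryId = NULL,
                            targetId = NULL) {
  qc <- .asSeq(protein, queryId, "protein")
  tc <- .asSeq(target, targetId, "target")
  n <- nchar(tc$seq)
  best <- NULL
  for (strand in c("+", "-")) {
    ts <- if (strand == "+") tc$seq else revcomp(tc$seq)
    for (frame in 0:2) {
      taa <- translateDna(ts, frame)
      if (nchar(taa) < 1L) next
      ch <- .chainAlignAA(qc$seq, taa, word = word, maxJoinGap = maxJoinGap)
      if (is.null(ch)) next
      idPct <- 100 * ch$matches / (ch$matches + ch$mismatches)
      if (idPct < minIdentityPct) next
      key <- c(ch$matches, idPct, strand == "+", -frame, -ch$blocks[1L, "tStart"])
      if (is.null(best) || .keyGreater(key, best$key)) {
        best <- list(key = key, strand = strand, frame = frame, ch = ch)
      }
    }
  }
  if (is.null(best)) return(NULL)
  ch <- best$ch
  PairwiseHit(queryId = qc$id, targetId = tc$id,
              queryLen = nchar(qc$seq), targetLen = n,
              strand = best$strand, frame = best$frame,
              blocks = ch$blocks, matches = ch$matches,
              mismatches = ch$mismatches, gapColumns = ch$gapColumns,
              units = "aa")
}

#' Align two protein sequences with the chain aligner
#'
#' The protein-protein counterpart of [translatedAlign()] (one "frame"):
#' exact-word seeding, ungapped unit-score extension, block chaining with
#' offsets counted as gap columns.
#'
#' @param query,target Amino-acid strings (or length-1 named
#'   character/AAStringSet).
#' @inheritParams translatedAlign
#' @return A [PairwiseHit-class] in amino-acid units on both axes, or `NULL`.
#' @export
proteinAlign <- function(query, target, word = 5L, maxJoinGap = 30L,
                         minIdentityPct = 70, queryId = NULL,
                         targetId = NULL) {
  qc <- .asSeq(query, queryId, "query")
  tc <- .asSeq(target, targetId, "target")
  ch <- .chainAlignAA(qc$seq, tc$seq, word = word, maxJoinGap = maxJoinGap)
  if (is.null(ch)) return(NULL)
  idPct <- 100 * ch$matches / (ch$matches + ch$mismatches)
  if (idPct < minIdentityPct) return(NULL)
  PairwiseHit(queryId = qc$id, targetId = tc$id,
              queryLen = nchar(qc$seq), targetLen = nchar(tc$seq),
              strand = "+", blocks = ch$blocks, matches = ch$matches,
              mismatches = ch$mismatches, gapColumns = ch$gapColumns,
              units = "aa-aa")
}
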