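## De novo branch: containment redundancy removal (cd-hit-est analogue),
## canonical-k-mer single-linkage clustering (wcd analogue) and per-cluster
## forward-only gap-free overlap-consensus assembly (CAP3 -r 0 analogue).

## k-mer prescreen: candidate pairs must share at least one canonical k-mer.
## A containment at >= minIdentityPct over >= minOverlap bases shares one
## with overwhelming probability; this only prunes hopeless pairs.
.kmerPairIndex <- function(seqs, k = 12L) {
  ids <- names(seqs)
  km <- lapply(seqs, .canonicalKmers, k = k)
  inv <- split(rep(seq_along(ids), lengths(km)),
               unlist(km, use.names = FALSE))
  inv[lengths(inv) > 1L]
}

#' Containment redundancy removal
#'
#' Iterates transcripts by decreasing length (ties by id) and removes a
#' transcript iff an ungapped alignment against some already-kept transcript
#' covers at least `minCov` of the shorter (current) sequence at
#' `minIdentityPct` or better: such transcripts are wholly included in a
#' longer sequence.
#'
#' @param transcripts Named `DNAStringSet` or named character vector.
#' @param minCov Minimum coverage of the shorter sequence (default 0.90,
#'   boundary removed).
#' @param minIdentityPct Minimum percent identity of the containment
#'   alignment (default 95).
#' @param k Seed k-mer length for the ungapped aligner.
#' @return A list with `kept` and `removed` (same class as the input) and an
#'   `evidence` data.frame (removedId, keptId, coverage, identity).
#' @export
dedupeContainment <- function(transcripts, minCov = 0.90, minIdentityPct = 95,
                              k = 12L) {
  isXS <- methods::is(transcripts, "XStringSet")
  seqs <- if (isXS) stats::setNames(as.character(transcripts), names(transcripts))
          else transcripts
  .checkIds(names(seqs), "transcript")
  ids <- names(seqs)[order(-nchar(seqs), names(seqs))]
  inv <- .kmerPairIndex(seqs, k = k)
  idIndex <- stats::setNames(seq_along(seqs), names(seqs))
  ## candidate partner ids per transcript from the inverted k-mer index
  partners <- vector("list", length(seqs))
  for (grp in inv) {
    for (i in grp) partners[[i]] <- c(partners[[i]], grp)
  }
  partners <- lapply(partners, function(p) unique(setdiff(p, NA)))
  keptIds <- character(0)
  keptSet <- logical(length(seqs))
  removed <- character(0)
  ev <- list()
  for (id in ids) {
    i <- idIndex[[id]]
    cand <- partners[[i]]
    cand <- cand[keptSet[cand]]
    hitKept <- NULL
    for (j in cand) {
      kid <- names(seqs)[j]
      h <- ungappedAlignNt(seqs[[id]], seqs[[kid]], k = k,
                           minIdentityPct = minIdentityPct,
                           queryId = id, targetId = kid,
                           exhaustiveFallback = FALSE)
      if (!is.null(h) && queryCoverage(h) >= minCov) {
        hitKept <- h
        break
      }
    }
    if (is.null(hitKept)) {
      keptIds <- c(keptIds, id)
      keptSet[i] <- TRUE
    } else {
      removed <- c(removed, id)
      ev[[length(ev) + 1L]] <- data.frame(
        removedId = id, keptId = hitKept@targetId,
        coverage = queryCoverage(hitKept),
        identity = percentIdentity(hitKept), stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(removedId = character(0), keptId = character(0),
               coverage = numeric(0), identity = numeric(0))
  keep <- names(seqs)[names(seqs) %in% keptIds]
  drop <- names(seqs)[names(seqs) %in% removed]
  list(kept = transcripts[keep], removed = transcripts[drop],
       evidence = evidence)
}

#' Single-linkage k-mer clustering
#'
#' Links two transcripts iff their shared canonical k-mers amount to at
#' least `minSharedFraction` of the smaller k-mer set (canonical k-mers make
#' the criterion orientation-free); clusters are the connected components of
#' this relation.  Cluster ids are the lexicographically smallest member id.
#'
#' @param transcripts Named `DNAStringSet` or named character vector.
#' @param k K-mer length (>= 8).
#' @param minSharedFraction Linkage threshold on
#'   `|shared| / min(|kmers a|, |kmers b|)`.
#' @return A named list mapping cluster id to member transcript ids (each
#'   input transcript in exactly one cluster); the per-transcript assignment
#'   is in `attr(, "assignment")`.
#' @export
clusterKmer <- function(transcripts, k = 14L, minSharedFraction = 0.30) {
  if (k < 8L) stop("k must be >= 8", call. = FALSE)
  seqs <- if (methods::is(transcripts, "XStringSet"))
    stats::setNames(as.character(transcripts), names(transcripts)) else transcripts
  .checkIds(names(seqs), "transcript")
  ids <- names(seqs)
  n <- length(ids)
  if (!n) {
    out <- list()
    attr(out, "assignment") <- stats::setNames(character(0), character(0))
    return(out)
  }
  km <- lapply(seqs, .canonicalKmers, k = k)
  sizes <- lengths(km)
  ## count shared k-mers per co-occurring pair via the inverted index
  inv <- split(rep(seq_len(n), sizes), unlist(km, use.names = FALSE))
  inv <- inv[lengths(inv) > 1L]
  allKeys <- unlist(lapply(inv, function(grp) {
    cmb <- utils::combn(sort(grp), 2L)
    paste(cmb[1L, ], cmb[2L, ], sep = ":")
  }), use.names = FALSE)
  edges <- matrix(integer(0), ncol = 2L)
  if (length(allKeys)) {
    tab <- table(allKeys)
    ab <- do.call(rbind, strsplit(names(tab), ":", fixed = TRUE))
    a <- as.integer(ab[, 1L]); b <- as.integer(ab[, 2L])
    shared <- as.integer(tab)
    denom <- pmin(sizes[a], sizes[b])
    link <- denom > 0L & shared / denom >= minSharedFraction
    edges <- cbind(a[link], b[link])
  }
  comp <- .ufComponents(n, edges)
  lab <- .componentLabels(ids, comp)
  out <- split(ids, lab)
  out <- out[order(names(out))]
  attr(out, "assignment") <- stats::setNames(lab, ids)
  out
}

## Full-window ungapped identity between a suffix/containment diagonal of a
## and b.  Returns candidate overlaps (a-suffix to b-prefix, or b contained
## in a) as rows: shift, window length, identity.
.forwardOverlaps <- function(a, b, minOverlap, minIdentityPct, k = 12L) {
  na <- nchar(a); nb <- nchar(b)
  if (na < minOverlap || nb < minOverlap) return(NULL)
  ka <- .kmers(a, min(k, minOverlap))
  kb <- .kmers(b, min(k, minOverlap))
  keep <- !grepl("N", kb, fixed = TRUE)
  common <- intersect(unique(ka[!grepl("N", ka, fixed = TRUE)]), kb[keep])
  if (!length(common)) return(NULL)
  apos <- which(ka %in% common)
  bpl <- split(which(keep), kb[keep])
  sel <- bpl[ka[apos]]
  shifts <- unique(rep(apos, lengths(sel)) - unlist(sel, use.names = FALSE))
  ra <- charToRaw(a); rb <- charToRaw(b)
  oka <- ra != charToRaw("N"); okb <- rb != charToRaw("N")
  res <- list()
  for (s in sort(shifts)) {
    ## b aligned starting at a position s (0-based offset of b[1] on a)
    aFrom <- max(0L, s); aTo <- min(na, s + nb)
    L <- aTo - aFrom
    if (L < minOverlap) next
    bFrom <- aFrom - s
    ia <- (aFrom + 1L):aTo
    ib <- (bFrom + 1L):(bFrom + L)
    eq <- (ra[ia] == rb[ib]) & oka[ia] & okb[ib]
    idPct <- 100 * sum(eq) / L
    if (idPct < minIdentityPct) next
    ## qualifies as suffix-prefix overlap or containment only if the window
    ## reaches the facing sequence ends
    contained <- s >= 0L && s + nb <= na
    suffixPrefix <- s >= 0L && s + nb > na && aTo == na && bFrom == 0L
    if (!contained && !suffixPrefix) next
    res[[length(res) + 1L]] <- data.frame(
      shift = s, length = L, identity = idPct, contained = contained,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) NULL else do.call(rbind, res)
}

#' Forward-only overlap-consensus assembly of a cluster
#'
#' Greedy gap-free assembler: computes all pairwise forward-orientation
#' suffix-prefix overlaps and containments of at least `minOverlapNt` at
#' `minIdentityPct` or better, repeatedly merges the highest-scoring pair
#' (score = overlap length x identity; ties broken by id pair) into a
#' consensus (majority base per column, ties resolved towards the longer
#' parent) and stops when no overlap qualifies.  Reverse-complement overlaps
#' are never considered, which prevents chimeric joins, and no gaps are ever
#' introduced, which prevents new frame shifts.  Members are expected to be
#' CDS-oriented (see [runDenovoPipeline()]).
#'
#' @param members Named `DNAStringSet` or named character vector of cluster
#'   members.
#' @param minOverlapNt Minimum overlap window (nt).
#' @param minIdentityPct Minimum ungapped identity of the overlap window.
#' @return Named character vector of contigs; `attr(, "memberOf")` maps each
#'   member id to the contig id containing it.
#' @export
assembleCluster <- function(members, minOverlapNt = 40L, minIdentityPct = 98) {
  seqs <- if (methods::is(members, "XStringSet"))
    stats::setNames(as.character(members), names(members)) else members
  if (!length(seqs)) stop("members must be non-empty", call. = FALSE)
  .checkIds(names(seqs), "member")
  contigs <- as.list(seqs)
  constituents <- stats::setNames(as.list(names(seqs)), names(seqs))
  repeat {
    idsNow <- names(contigs)
    if (length(idsNow) < 2L) break
    best <- NULL
    for (i in seq_along(idsNow)) {
      for (j in seq_along(idsNow)) {
        if (i == j) next
        a <- idsNow[i]; b <- idsNow[j]
        ## only consider (a, b) with a the longer (or tie-earlier) so each
        ## unordered pair is scored once per role; containment needs a >= b
        if (nchar(contigs[[a]]) < nchar(contigs[[b]])) next
        if (nchar(contigs[[a]]) == nchar(contigs[[b]]) && a > b) next
        for (role in list(c(a, b), c(b, a))) {
          tab <- .forwardOverlaps(contigs[[role[1L]]], contigs[[role[2L]]],
                                  minOverlapNt, minIdentityPct)
          if (is.null(tab)) next
          ## containment is only scored with the longer sequence first
          if (role[1L] == b) tab <- tab[!tab$contained, , drop = FALSE]
          if (!nrow(tab)) next
          w <- which.max(tab$length * tab$identity)
          key <- tab$length[w] * tab$identity[w]
          if (is.null(best) || key > best$key + 1e-9 ||
              (abs(key - best$key) <= 1e-9 &&
               paste(role[1L], role[2L]) < paste(best$first, best$second))) {
            best <- list(key = key, first = role[1L], second = role[2L],
                         row = tab[w, , drop = FALSE])
          }
        }
      }
    }
    if (is.null(best)) break
    a <- best$first; b <- best$second
    merged <- .mergeConsensus(contigs[[a]], contigs[[b]], best$row$shift)
    la <- nchar(contigs[[a]]); lb <- nchar(contigs[[b]])
    keepId <- if (la > lb || (la == lb && a <= b)) a else b
    newConstituents <- c(constituents[[a]], constituents[[b]])
    contigs[[a]] <- NULL; contigs[[b]] <- NULL
    constituents[[a]] <- NULL; constituents[[b]] <- NULL
    contigs[[keepId]] <- merged
    constituents[[keepId]] <- newConstituents
  }
  out <- unlist(contigs)
  memberOf <- stats::setNames(
    rep(names(constituents), lengths(constituents)),
    unlist(constituents, use.names = FALSE))
  attr(out, "memberOf") <- memberOf[names(seqs)]
  out
}

## Merge b onto a at the given shift (0-based offset of b[1] on a), taking
## the majority base per overlap column; for two parents ties go to the
## longer parent (a when lengths tie).
.mergeConsensus <- function(a, b, shift) {
  na <- nchar(a); nb <- nchar(b)
  aFrom <- max(0L, shift); aTo <- min(na, shift + nb)
  bFrom <- aFrom - shift; bTo <- bFrom + (aTo - aFrom)
  ca <- strsplit(substr(a, aFrom + 1L, aTo), "")[[1]]
  cb <- strsplit(substr(b, bFrom + 1L, bTo), "")[[1]]
  longerIsA <- na >= nb
  cons <- ifelse(ca == cb, ca, if (longerIsA) ca else cb)
  paste0(substr(a, 1L, aFrom),
         paste(cons, collapse = ""),
         if (shift + nb > na) substr(b, bTo + 1L, nb) else
           substr(a, aTo + 1L, na))
}

#' Run the de novo consolidation pipeline
#'
#' Stage order: longest-ORF CDS extraction (transcripts without an ORF of at
#' least `minOrfNt` are dropped; surviving sequences are CDS-oriented so the
#' forward-only assembly rule is meaningful), containment dedup, k-mer
#' clustering, and per-cluster forward-only overlap-consensus assembly.
#'
#' @param transcripts Named `DNAStringSet` or named character vector.
#' @param minOrfNt Minimum longest-ORF length (nt) for a transcript to enter
#'   the pipeline (default 200).
#' @param dedupeCov,dedupeIdentityPct Containment-dedup thresholds.
#' @param clusterK,clusterMinShared Clustering parameters.
#' @param minOverlapNt,assembleIdentityPct Assembly parameters.
#' @return A list with `transcripts` (final contigs, named character
#'   vector), `clusters` (the [clusterKmer()] result on the deduped CDS
#'   set), `report` (per-stage counts) and `stages` (per-stage details).
#' @export
runDenovoPipeline <- function(transcripts, minOrfNt = 200L,
                              dedupeCov = 0.90, dedupeIdentityPct = 95,
                              clusterK = 14L, clusterMinShared = 0.30,
                              minOverlapNt = 40L, assembleIdentityPct = 98) {
  seqs <- if (methods::is(transcripts, "XStringSet"))
    stats::setNames(as.character(transcripts), names(transcripts)) else transcripts
  nIn <- length(seqs)
  ## stage 1: CDS extraction, orientation normalised to the ORF strand
  cds <- character(0)
  for (id in names(seqs)) {
    o <- longestOrf(seqs[[id]], id = id)
    if (!is.null(o) && o$lengthNt >= minOrfNt) {
      cds[id] <- orfSequence(seqs[[id]], o)
    }
  }
  dd <- if (length(cds)) dedupeContainment(cds, minCov = dedupeCov,
                                           minIdentityPct = dedupeIdentityPct)
        else list(kept = character(0), removed = character(0),
                  evidence = data.frame())
  kept <- dd$kept
  cl <- clusterKmer(kept, k = clusterK, minSharedFraction = clusterMinShared)
  contigs <- character(0)
  memberOf <- character(0)
  for (cid in names(cl)) {
    asm <- assembleCluster(kept[cl[[cid]]], minOverlapNt = minOverlapNt,
                           minIdentityPct = assembleIdentityPct)
    contigs <- c(contigs, asm)
    memberOf <- c(memberOf, attr(asm, "memberOf"))
  }
  report <- data.frame(
    stage = c("cds_extraction", "dedupe_containment", "cluster", "assemble"),
    input = c(nIn, length(cds), length(kept), length(kept)),
    kept = c(length(cds), length(kept), length(cl), length(contigs)),
    removed = c(nIn - length(cds), length(cds) - length(kept), NA, NA),
    stringsAsFactors = FALSE)
  list(transcripts = contigs, clusters = cl, report = report,
       stages = list(cds = cds, dedupe = dd, memberOf = memberOf))
}
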