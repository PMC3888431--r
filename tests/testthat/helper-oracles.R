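## Independent oracles and fixture builders used across the suite.  Each
## oracle takes the brute-force or reference-implementation route (full
## enumeration, Smith-Waterman DP, igraph connected components) so that
## agreement with the package's seeded/greedy implementations is a real
## cross-check, not a tautology.

randDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randCodons <- function(nCodon) {
  nonstop <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  sample(nonstop, nCodon, replace = TRUE)
}

mutateBases <- function(s, positions) {
  ch <- strsplit(s, "")[[1]]
  for (i in positions) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

## ---- ORF enumeration oracle -------------------------------------------
## Enumerates every ATG, scans to the next in-frame stop, then keeps the
## 5'-most ATG per (strand, frame, stop) so the result is comparable to the
## maximal-ORF convention.
orfOracle <- function(seq, minLenNt = 3, bothStrands = TRUE,
                      allowOpen3prime = TRUE) {
  stops <- c("TAA", "TAG", "TGA")
  scan1 <- function(s, strand, n) {
    rows <- list()
    for (i in seq_len(max(0L, nchar(s) - 2L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      j <- i + 3L
      stopAt <- NA_integer_
      while (j + 2L <= nchar(s)) {
        if (substr(s, j, j + 2L) %in% stops) { stopAt <- j; break }
        j <- j + 3L
      }
      if (!is.na(stopAt)) {
        st <- i - 1L; en <- stopAt + 2L; has <- TRUE
      } else if (allowOpen3prime) {
        nc <- (nchar(s) - i + 1L) %/% 3L
        st <- i - 1L; en <- i - 1L + nc * 3L; has <- FALSE
      } else next
      if (en - st < max(3L, minLenNt)) next
      if (strand == "-") { f <- st; st <- n - en; en <- n - f }
      rows[[length(rows) + 1L]] <- data.frame(
        strand = strand, start = st, end = en, lengthNt = en - st,
        hasStop = has, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  n <- nchar(seq)
  out <- scan1(seq, "+", n)
  if (bothStrands) out <- rbind(out, scan1(revcomp(seq), "-", n))
  if (is.null(out) || !nrow(out)) return(out)
  ## maximal ORFs: per (strand, stop-end or open-end), keep the 5'-most ATG
  keyEnd <- ifelse(out$strand == "+", out$end, out$start)
  key <- paste(out$strand, keyEnd, out$lengthNt %% 3L)
  keep <- unlist(lapply(split(seq_len(nrow(out)), key), function(ix) {
    ix[which.max(out$lengthNt[ix])]
  }), use.names = FALSE)
  out <- out[keep, , drop = FALSE]
  out[order(-out$lengthNt, out$strand != "+", out$start), , drop = FALSE]
}

## ---- all-diagonal ungapped alignment oracle ---------------------------
## Scores every diagonal of both orientations (no seeding) and returns the
## best single ungapped run under the same selection rules as the aligner.
diagOracle <- function(q, t, minIdentityPct = 90) {
  best <- NULL
  bN <- utf8ToInt("N")
  bt <- utf8ToInt(t)
  n <- length(bt)
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") q else revcomp(q)
    bq <- utf8ToInt(qs)
    m <- length(bq)
    for (d in (-(m - 1L)):(n - 1L)) {
      lo <- max(0L, -d); hi <- min(m, n - d)
      if (hi - lo < 1L) next
      qi <- (lo + 1L):hi
      eq <- (bq[qi] == bt[qi + d]) & bq[qi] != bN & bt[qi + d] != bN
      sc <- 2L * eq - 1L
      cs <- cumsum(sc)
      pre <- c(0L, cs[-length(cs)])
      gain <- cs - cummin(pre)
      g <- max(gain)
      if (g <= 0L) next
      to <- which.max(gain)
      from <- which(pre[seq_len(to)] == cummin(pre)[to])[1L]
      cols <- to - from + 1L
      matches <- sum(eq[from:to])
      idPct <- 100 * matches / cols
      if (idPct < minIdentityPct) next
      cand <- list(cols = cols, identity = idPct, strand = strand,
                   tStart = lo + from - 1L + d, qStart = lo + from - 1L)
      better <- is.null(best) ||
        cand$cols > best$cols ||
        (cand$cols == best$cols && cand$identity > best$identity) ||
        (cand$cols == best$cols && cand$identity == best$identity &&
           best$strand == "-" && cand$strand == "+") ||
        (cand$cols == best$cols && cand$identity == best$identity &&
           cand$strand == best$strand && cand$tStart < best$tStart)
      if (better) best <- cand
    }
  }
  best
}

## ---- DP protein alignment oracle (Smith-Waterman via Biostrings) ------
unitAAMat <- local({
  letters <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m["X", "X"] <- -1; m["*", "*"] <- -1
  m
})

dpOracleAA <- function(qaa, taa, gapPenalty = 4) {
  pw <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qaa), Biostrings::AAString(taa), type = "local",
    substitutionMatrix = unitAAMat, gapOpening = 0, gapExtension = gapPenalty)
  mat <- Biostrings::nmatch(pw); mis <- Biostrings::nmismatch(pw)
  gaps <- sum(IRanges::width(Biostrings::insertion(pw)[[1]])) +
    sum(IRanges::width(Biostrings::deletion(pw)[[1]]))
  list(matches = mat, mismatches = mis, gaps = gaps,
       coverage = (mat + mis) / nchar(qaa))
}

## six-frame DP oracle for translatedAlign fixtures
dpOracleTranslated <- function(protein, target, gapPenalty = 4) {
  best <- NULL
  for (s in c(target, revcomp(target))) {
    for (f in 0:2) {
      taa <- translateDna(s, f)
      if (nchar(taa) < 1) next
      a <- dpOracleAA(protein, taa, gapPenalty)
      sc <- a$matches - a$mismatches - a$gaps
      if (is.null(best) || sc > best$sc) best <- c(a, list(sc = sc))
    }
  }
  best
}

## ---- connected-component oracles (igraph) -----------------------------
componentsOracle <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

## canonical partition form for label-free comparison
partitionOf <- function(ids, membership) {
  unname(lapply(split(ids, membership), sort))
}

samePartition <- function(a, b) {
  setequal(vapply(a, paste, character(1), collapse = "|"),
           vapply(b, paste, character(1), collapse = "|"))
}

## independent canonical k-mer sets (chartr-based revcomp)
oracleCanonicalKmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- unique(substring(s, 1:(n - k + 1), k:n))
  km <- km[!grepl("N", km, fixed = TRUE)]
  rc <- vapply(km, function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = ""),
    character(1))
  unique(pmin(km, unname(rc)))
}

## small planted-containment transcript set for dedupe checks
makeContainmentSet <- function(nBase = 20, nContained = 10, seed = 1) {
  set.seed(seed)
  base <- stats::setNames(
    vapply(seq_len(nBase), function(i) randDna(sample(500:1200, 1)),
           character(1)),
    sprintf("base%02d", seq_len(nBase)))
  contained <- character(0)
  for (i in seq_len(nContained)) {
    src <- sample(names(base), 1)
    L <- nchar(base[[src]])
    fl <- sample(round(L * 0.3):round(L * 0.6), 1)
    fs <- sample(seq_len(L - fl + 1), 1)
    frag <- substr(base[[src]], fs, fs + fl - 1)
    nMut <- sample(0:max(1, round(fl * 0.01)), 1)
    if (nMut > 0) frag <- mutateBases(frag, sample(nchar(frag), nMut))
    contained[sprintf("cont%02d", i)] <- frag
  }
  c(base, contained)
}

## planted in-frame indel fixture for the translated-alignment oracle suite:
## a protein and a transcript carrying its CDS with 0-2 in-frame indels of
## 1-5 codons, each anchored at least 30 codons from the CDS ends and 25
## codons from each other so both alignment objectives resolve identically
makeIndelFixture <- function(nC = NULL, nIndel = NULL) {
  if (is.null(nIndel)) nIndel <- sample(0:2, 1)
  if (is.null(nC)) nC <- sample((80 + 60 * (nIndel == 2)):200, 1)
  codons <- randCodons(nC)
  prot <- paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  segs <- codons
  if (nIndel > 0) {
    pos <- if (nIndel == 2) {
      p1 <- sample(seq(30, nC - 60), 1)
      c(p1, sample(seq(p1 + 25, nC - 30), 1))
    } else sample(seq(30, nC - 30), 1)
    for (p in rev(pos)) {
      w <- sample(1:5, 1)
      if (stats::runif(1) < 0.5) {
        segs <- segs[-(p:(p + w - 1))]
      } else {
        segs <- append(segs, randCodons(w), after = p)
      }
    }
  }
  tx <- paste0(randDna(9), paste(segs, collapse = ""), randDna(9))
  list(prot = prot, tx = tx, nIndel = nIndel)
}
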