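## Seeded simulator of toy genomes, multi-exon genes with exon-skipping
## isoforms, proteomes, and corrupted / decoy-laden transcript sets with
## machine-readable truth labels.  Everything is deterministic given the
## seed; generated objects are internally audited (spliced models reproduce
## the stored mature transcripts) at every generation.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

.randDna <- function(n, gc = 0.42) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.STOPS <- c("TAA", "TAG", "TGA")

.randCds <- function(lenNt) {
  stopifnot(lenNt %% 3L == 0L, lenNt >= 9L)
  nonstop <- setdiff(names(Biostrings::GENETIC_CODE), .STOPS)
  paste(c("ATG", sample(nonstop, lenNt / 3L - 2L, replace = TRUE),
          sample(.STOPS, 1L)), collapse = "")
}

.defaultGenomeParams <- function() {
  list(exonCountRange = c(2L, 9L), exonLenRange = c(150L, 400L),
       intronLenRange = c(60L, 800L), isoformRange = c(1L, 4L),
       gc = 0.42, utrRange = c(15L, 40L), flankLen = 100L,
       minMatureLen = 540L)
}

.checkGenomeParams <- function(p) {
  bad <- function(r, lo, hi) r[1L] > r[2L] || r[1L] < lo || r[2L] > hi
  if (bad(p$exonCountRange, 2L, 12L)) stop("exonCountRange must be within 2-12")
  if (bad(p$exonLenRange, 100L, 400L)) stop("exonLenRange must be within 100-400")
  if (bad(p$intronLenRange, 60L, 2000L)) stop("intronLenRange must be within 60-2000")
  if (bad(p$isoformRange, 1L, 4L)) stop("isoformRange must be within 1-4")
  if (p$gc <= 0 || p$gc >= 1) stop("gc must be in (0,1)")
  invisible(p)
}

#' Generate a toy genome with multi-exon genes, isoforms and a proteome
#'
#' Each gene lives on its own contig, has 2-9 exons with GT..AG introns on
#' the coding strand, a CDS (ATG..stop, at least 60 percent of the mature
#' transcript) flanked by short UTRs (the 5' UTR is ATG-free so the CDS is
#' the longest ORF), and 1-4 isoforms built by skipping an internal exon.
#' Only skips that leave the isoform's longest ORF intact (at least 75
#' percent of the primary ORF, stop retained) are accepted, so clean
#' isoform sets pass the longest-ORF locus filter.  The proteome contains
#' one protein per isoform: the translation of that isoform's longest ORF.
#' Output is fully deterministic given the seed, which is recorded in the
#' result.
#'
#' @param nGenes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param params Optional list overriding the defaults: `exonCountRange`
#'   (within 2-12), `exonLenRange` (nt, within 100-400), `intronLenRange`
#'   (nt, within 60-2000), `isoformRange` (within 1-4), `gc`, `utrRange`,
#'   `flankLen`, `minMatureLen`.
#' @return A list: `genome` (named character, one contig per gene),
#'   `models` ([TranscriptModels-class], one entry per isoform,
#'   `sourceLength` = mature length), `mature` (named character),
#'   `proteome` (named character), `txInfo` (per-isoform data.frame),
#'   `genes` (per-gene data.frame), `geneStructs` (internal structures used
#'   by the decoy generators) and `seed`.
#' @export
makeGenome <- function(nGenes, seed, params = list()) {
  stopifnot(nGenes >= 1L)
  p <- utils::modifyList(.defaultGenomeParams(), params)
  .checkGenomeParams(p)
  .withSeed(seed, {
    genome <- character(0)
    mature <- character(0)
    proteome <- character(0)
    grl <- list()
    srcLen <- integer(0)
    txRows <- list()
    geneRows <- list()
    geneStructs <- list()
    for (g in seq_len(nGenes)) {
      gid <- sprintf("g%03d", g)
      ctg <- paste0("ctg_", gid)
      strand <- sample(c("+", "-"), 1L)
      nEx <- sample(p$exonCountRange[1L]:p$exonCountRange[2L], 1L)
      exLens <- sample(p$exonLenRange[1L]:p$exonLenRange[2L], nEx, replace = TRUE)
      if (nEx > 2L) {
        ## internal exons frame-preserving (length a multiple of 3) so exon
        ## skipping can yield intact-ORF isoforms, as symmetric exons do
        idx <- 2:(nEx - 1L)
        exLens[idx] <- pmax(p$exonLenRange[1L], exLens[idx] - exLens[idx] %% 3L)
      }
      M <- sum(exLens)
      if (M < p$minMatureLen) {
        exLens[nEx] <- exLens[nEx] + (p$minMatureLen - M)
        M <- p$minMatureLen
      }
      u5 <- sample(p$utrRange[1L]:p$utrRange[2L], 1L)
      u3raw <- sample(p$utrRange[1L]:p$utrRange[2L], 1L)
      cdsLen <- M - u5 - u3raw
      cdsLen <- cdsLen - cdsLen %% 3L
      u3 <- M - u5 - cdsLen
      cds <- .randCds(cdsLen)
      repeat {
        u5seq <- .randDna(u5, p$gc)
        if (!grepl("ATG", u5seq, fixed = TRUE)) break
      }
      u3seq <- .randDna(u3, p$gc)
      matureSeq <- paste0(u5seq, cds, u3seq)
      txEnds <- cumsum(exLens)
      txStarts <- c(1L, utils::head(txEnds, -1L) + 1L)
      intLens <- if (nEx > 1L)
        sample(p$intronLenRange[1L]:p$intronLenRange[2L], nEx - 1L, replace = TRUE)
        else integer(0)
      intronSeqs <- vapply(intLens, function(L)
        paste0("GT", .randDna(L - 4L, p$gc), "AG"), character(1))
      parts <- character(0)
      for (j in seq_len(nEx)) {
        parts <- c(parts, substr(matureSeq, txStarts[j], txEnds[j]),
                   if (j < nEx) intronSeqs[j])
      }
      region <- paste0(.randDna(p$flankLen, p$gc), paste(parts, collapse = ""),
                       .randDna(p$flankLen, p$gc))
      regionLen <- nchar(region)
      pos <- p$flankLen
      gS <- integer(nEx); gE <- integer(nEx)
      for (j in seq_len(nEx)) {
        gS[j] <- pos + 1L
        gE[j] <- pos + exLens[j]
        pos <- gE[j] + if (j < nEx) intLens[j] else 0L
      }
      if (strand == "-") {
        contig <- revcomp(region)
        newS <- regionLen - gE + 1L
        newE <- regionLen - gS + 1L
        gS <- newS; gE <- newE       # still in tx-exon order (descending)
      } else contig <- region
      genome[ctg] <- contig
      gs <- list(geneId = gid, ctg = ctg, strand = strand, nEx = nEx,
                 exLens = exLens, txStarts = txStarts, txEnds = txEnds,
                 gStart = gS, gEnd = gE, u5 = u5, u3 = u3, cdsLen = cdsLen,
                 matureLen = M, mature = matureSeq)
      geneStructs[[gid]] <- gs
      ## isoforms: primary keeps all exons; extras skip one internal exon
      nIso <- sample(p$isoformRange[1L]:p$isoformRange[2L], 1L)
      skipChoices <- if (nEx > 2L) {
        int <- 2:(nEx - 1L)
        int[order(exLens[int], int)]       # short exons pass the ORF rule most often
      } else integer(0)
      skips <- c(NA_integer_)
      for (cand in skipChoices) {
        if (length(skips) >= nIso) break
        isoSeq <- paste0(substr(matureSeq, 1L, txStarts[cand] - 1L),
                         substr(matureSeq, txEnds[cand] + 1L, M))
        lo <- longestOrf(isoSeq)
        if (!is.null(lo) && lo$strand == "+" && lo$hasStop &&
            lo$lengthNt >= 0.75 * cdsLen) {
          skips <- c(skips, cand)
        }
      }
      for (k in seq_along(skips)) {
        tid <- sprintf("%s.t%d", gid, k)
        skip <- skips[k]
        keepEx <- if (is.na(skip)) seq_len(nEx) else setdiff(seq_len(nEx), skip)
        isoSeq <- if (is.na(skip)) matureSeq else
          paste0(substr(matureSeq, 1L, txStarts[skip] - 1L),
                 substr(matureSeq, txEnds[skip] + 1L, M))
        lo <- longestOrf(isoSeq, id = tid)
        gr <- GenomicRanges::GRanges(
          ctg, IRanges::IRanges(sort(gS[keepEx]), sort(gE[keepEx])), strand)
        gr$gene_id <- gid
        grl[[tid]] <- gr
        mature[tid] <- isoSeq
        srcLen[tid] <- nchar(isoSeq)
        pid <- paste0(tid, "_p")
        proteome[pid] <- lo$aa
        txRows[[tid]] <- data.frame(
          txId = tid, geneId = gid, contig = ctg, strand = strand,
          isoform = k, skippedExon = skip, matureLen = nchar(isoSeq),
          orfLenNt = lo$lengthNt, proteinId = pid, stringsAsFactors = FALSE)
      }
      geneRows[[gid]] <- data.frame(
        geneId = gid, contig = ctg, strand = strand, nExons = nEx,
        matureLen = M, cdsLen = cdsLen, u5 = u5, u3 = u3,
        nIsoforms = length(skips), stringsAsFactors = FALSE)
    }
    models <- TranscriptModels(GenomicRanges::GRangesList(grl),
                               sourceLength = srcLen)
    ## generation audit: models + genome must reproduce the mature set
    rebuilt <- splicedSequence(models, genome)
    stopifnot(identical(unname(rebuilt[names(mature)]), unname(mature)))
    list(genome = genome, models = models, mature = mature,
         proteome = proteome,
         txInfo = do.call(rbind, c(txRows, list(make.row.names = FALSE))),
         genes = do.call(rbind, c(geneRows, list(make.row.names = FALSE))),
         geneStructs = geneStructs, seed = seed)
  })
}

## Map a transcript-coordinate window [from, to] (1-based) of a gene's
## primary transcript onto genomic exon ranges (ascending).
.txWindowToRanges <- function(gs, from, to) {
  st <- integer(0); en <- integer(0)
  for (i in seq_len(gs$nEx)) {
    a <- max(from, gs$txStarts[i]); b <- min(to, gs$txEnds[i])
    if (a > b) next
    if (gs$strand == "+") {
      st <- c(st, gs$gStart[i] + (a - gs$txStarts[i]))
      en <- c(en, gs$gStart[i] + (b - gs$txStarts[i]))
    } else {
      st <- c(st, gs$gEnd[i] - (b - gs$txStarts[i]))
      en <- c(en, gs$gEnd[i] - (a - gs$txStarts[i]))
    }
  }
  o <- order(st)
  IRanges::IRanges(st[o], en[o])
}

## Donor-acceptor pair of the intron between two genomic exon ranges,
## read on the transcript's strand.
.splicePair <- function(contig, intronStart, intronEnd, strand) {
  left <- substr(contig, intronStart, intronStart + 1L)
  right <- substr(contig, intronEnd - 1L, intronEnd)
  if (strand == "+") paste0(left, "-", right)
  else paste0(revcomp(right), "-", revcomp(left))
}

#' Corrupt a transcript set with labelled assembly artefacts
#'
#' Applies truncation, chimera joins, heavy point mutation, internal
#' deletion or strand flips to assigned fractions of a mature transcript
#' set, and computes each record's expected evaluation class (`correct`,
#' `incomplete`, `false`, `no_hit`) by running the dynamic-programming
#' label oracle ([oracleClassify()]) against the bundle's proteome under
#' the thresholds in force -- labels are computed, never hand-asserted, so
#' they remain sound if thresholds change.
#'
#' @param bundle A [makeGenome()] result.
#' @param corruptionSpec Named fractions over
#'   `none`, `truncation`, `chimera`, `heavy_mutation`,
#'   `internal_deletion`, `strand_flip`; must sum to at most 1 (remainder
#'   goes to `none`).
#' @param seed Integer seed.
#' @param truncateTo Retained 5' fraction for truncations (default 0.7).
#' @param mutationRate Per-base substitution rate for heavy mutation
#'   (default 0.15, far past the 90 percent identity significance floor).
#' @param deletionFrac Fraction of length removed by internal deletion.
#' @param thresholds Classification thresholds passed to the label oracle
#'   (defaults match [classifySet()]).
#' @return A list with `transcripts` (named character) and `truth`
#'   (data.frame: transcriptId, sourceGene, corruption, partnerGene,
#'   expectedClass).
#' @export
corruptTranscripts <- function(bundle,
                               corruptionSpec = c(none = 0.4, truncation = 0.3,
                                                  chimera = 0.2,
                                                  heavy_mutation = 0.1),
                               seed = 1L, truncateTo = 0.7,
                               mutationRate = 0.15, deletionFrac = 0.2,
                               thresholds = list()) {
  known <- c("none", "truncation", "chimera", "heavy_mutation",
             "internal_deletion", "strand_flip")
  if (!all(names(corruptionSpec) %in% known))
    stop("unknown corruption type(s): ",
         paste(setdiff(names(corruptionSpec), known), collapse = ", "))
  if (sum(corruptionSpec) > 1 + 1e-9)
    stop("corruption fractions must sum to at most 1")
  .withSeed(seed, {
    ids <- names(bundle$mature)
    n <- length(ids)
    shuffled <- sample(ids)
    cnt <- floor(corruptionSpec * n)
    cnt["none"] <- if ("none" %in% names(cnt))
      cnt[["none"]] + (n - sum(cnt)) else n - sum(cnt)
    assign <- rep(names(cnt), cnt)[seq_len(n)]
    geneOf <- stats::setNames(bundle$txInfo$geneId, bundle$txInfo$txId)
    out <- character(0)
    rows <- list()
    for (i in seq_len(n)) {
      tid <- shuffled[i]
      type <- assign[i]
      s <- bundle$mature[[tid]]
      partner <- NA_character_
      s2 <- switch(type,
        none = s,
        truncation = substr(s, 1L, max(3L, round(nchar(s) * truncateTo))),
        chimera = {
          others <- ids[geneOf[ids] != geneOf[tid]]
          ptid <- sample(others, 1L)
          partner <- geneOf[[ptid]]
          ps <- bundle$mature[[ptid]]
          paste0(substr(s, 1L, nchar(s) %/% 2L),
                 substr(ps, nchar(ps) %/% 2L + 1L, nchar(ps)))
        },
        heavy_mutation = .mutateSeq(s, mutationRate),
        internal_deletion = {
          dl <- max(1L, round(nchar(s) * deletionFrac))
          from <- sample(seq_len(nchar(s) - dl - 1L)[-1L], 1L)
          paste0(substr(s, 1L, from - 1L), substr(s, from + dl, nchar(s)))
        },
        strand_flip = revcomp(s))
      out[tid] <- s2
      rows[[tid]] <- data.frame(
        transcriptId = tid, sourceGene = geneOf[[tid]], corruption = type,
        partnerGene = partner, stringsAsFactors = FALSE)
    }
    out <- out[ids]
    rows <- rows[ids]
    truth <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    truth$expectedClass <- oracleClassifySet(out, bundle$proteome,
                                             thresholds = thresholds)[truth$transcriptId]
    list(transcripts = out, truth = truth)
  })
}

.mutateSeq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Build the two pipeline input branches with planted decoys
#'
#' Produces the reference-branch transcript models (all true isoforms plus
#' planted low-mapping-coverage, non-canonical-splice and short-ORF decoys,
#' each constructed to fail exactly its own filter stage) and the de novo
#' branch (one CDS per gene plus planted containment fragments).  All
#' plants are logged so filter removal lists can be checked against them
#' exactly.
#'
#' @param bundle A [makeGenome()] result.
#' @param seed Integer seed.
#' @param nLowCov,nNonCanonical,nShortOrf,nContain Number of planted decoys
#'   of each kind (each drawn from a distinct gene).
#' @return A list: `refModels` ([TranscriptModels-class]), `decoys` (lists
#'   of planted ids per stage), `denovo` (named character),
#'   `containments` (planted containment ids).
#' @export
makeTwoBranchInputs <- function(bundle, seed, nLowCov = 10L,
                                nNonCanonical = 10L, nShortOrf = 10L,
                                nContain = 15L) {
  gsAll <- bundle$geneStructs
  need <- nLowCov + nNonCanonical + nShortOrf
  if (need > length(gsAll))
    stop("not enough genes for the requested decoys")
  .withSeed(seed, {
    geneIds <- sample(names(gsAll))
    gLow <- geneIds[seq_len(nLowCov)]
    gNc <- geneIds[nLowCov + seq_len(nNonCanonical)]
    gShort <- geneIds[nLowCov + nNonCanonical + seq_len(nShortOrf)]
    ex <- as.list(exonRanges(bundle$models))
    src <- sourceLength(bundle$models)
    decoyLow <- decoyNc <- decoyShort <- character(0)
    for (g in gLow) {
      gs <- gsAll[[g]]
      id <- paste0("decoy_lowcov_", g)
      gr <- ex[[paste0(g, ".t1")]]
      ex[[id]] <- gr
      src[id] <- as.integer(ceiling(sum(GenomicRanges::width(gr)) / 0.7))
      decoyLow <- c(decoyLow, id)
    }
    for (g in gNc) {
      gs <- gsAll[[g]]
      id <- paste0("decoy_noncanon_", g)
      gr <- sort(ex[[paste0(g, ".t1")]])
      st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
      done <- FALSE
      for (j in seq_len(length(gr) - 1L)) {
        for (delta in 2:6) {
          newEn <- en
          newEn[j] <- en[j] + delta
          iS <- newEn[j] + 1L; iE <- st[j + 1L] - 1L
          if (iE - iS + 1L < 4L) next
          pair <- .splicePair(bundle$genome[[gs$ctg]], iS, iE, gs$strand)
          if (pair != "GT-AG") {
            gr2 <- GenomicRanges::GRanges(gs$ctg,
                     IRanges::IRanges(st, newEn), gs$strand)
            gr2$gene_id <- g
            ex[[id]] <- gr2
            src[id] <- as.integer(sum(GenomicRanges::width(gr2)))
            done <- TRUE
            break
          }
        }
        if (done) break
      }
      stopifnot(done)
      decoyNc <- c(decoyNc, id)
    }
    for (g in gShort) {
      gs <- gsAll[[g]]
      id <- paste0("decoy_shortorf_", g)
      cut <- 0.65
      repeat {
        q0 <- gs$u5 + ceiling(gs$cdsLen * cut)
        rng <- .txWindowToRanges(gs, q0 + 1L, gs$matureLen)
        gr2 <- GenomicRanges::GRanges(gs$ctg, rng, gs$strand)
        gr2$gene_id <- g
        m1 <- TranscriptModels(GenomicRanges::GRangesList(tmp = gr2))
        sp <- splicedSequence(m1, bundle$genome)[[1]]
        lo <- longestOrf(sp)
        if (is.null(lo) || lo$lengthNt < 0.7 * 0.75 * gs$cdsLen) break
        cut <- cut + 0.1
        stopifnot(cut < 0.95)
      }
      ex[[id]] <- gr2
      src[id] <- as.integer(sum(GenomicRanges::width(gr2)))
      decoyShort <- c(decoyShort, id)
    }
    refModels <- TranscriptModels(GenomicRanges::GRangesList(ex),
                                  sourceLength = src)
    ## de novo branch: primary CDS per gene + planted containments
    dn <- character(0)
    for (g in names(gsAll)) {
      gs <- gsAll[[g]]
      dn[paste0("dn_", g)] <- substr(gs$mature, gs$u5 + 1L,
                                     gs$u5 + gs$cdsLen)
    }
    gContain <- sample(names(gsAll), nContain)
    contain <- character(0)
    for (g in gContain) {
      gs <- gsAll[[g]]
      cdsSeq <- dn[[paste0("dn_", g)]]
      fl <- round(gs$cdsLen * stats::runif(1L, 0.5, 0.7))
      fs <- sample(seq_len(gs$cdsLen - fl + 1L), 1L)
      id <- paste0("dn_contain_", g)
      dn[id] <- substr(cdsSeq, fs, fs + fl - 1L)
      contain <- c(contain, id)
    }
    list(refModels = refModels,
         decoys = list(lowCoverage = decoyLow, nonCanonical = decoyNc,
                       shortOrf = decoyShort),
         denovo = dn, containments = contain)
  })
}

#' Generate a cross-branch merge scenario with planted redundancies
#'
#' Builds a reference set (primary mature transcripts), a de novo set with
#' three kinds of members -- redundant CDS copies of reference genes
#' (removed by the merge coverage rule), diverged paralog copies whose only
#' transcript is collapsed onto the host gene's reference transcript during
#' merging (their proteins then fail the 5-point presence test), and
#' de novo-only genes that survive -- plus the protein panel to evaluate
#' against.
#'
#' @param bundle A [makeGenome()] result with enough genes.
#' @param seed Integer seed.
#' @param nRedundant Planted redundant de novo copies.
#' @param nParalogLoss Planted paralog-collapse genes.
#' @param nDenovoOnly Genes represented only in the de novo branch.
#' @param codonMutFrac Fraction of interior codons mutated
#'   (non-synonymously) in each paralog copy; default 0.12 puts the
#'   post-merge identity drop well past 5 points while nucleotide identity
#'   stays above the merge rule's floor.
#' @return A list with `ref`, `denovo`, `proteins`, `plantedRemoved`
#'   (de novo ids the merge must remove), `lossProteins` (protein ids the
#'   presence test must report missing) and `truth` notes.
#' @export
makeMergeScenario <- function(bundle, seed, nRedundant = 15L,
                              nParalogLoss = 5L, nDenovoOnly = 5L,
                              codonMutFrac = 0.12) {
  gsAll <- bundle$geneStructs
  need <- nRedundant + nParalogLoss + nDenovoOnly
  if (need > length(gsAll)) stop("not enough genes in bundle")
  .withSeed(seed, {
    geneIds <- sample(names(gsAll))
    gOnly <- geneIds[seq_len(nDenovoOnly)]
    gHost <- geneIds[nDenovoOnly + seq_len(nParalogLoss)]
    gRed <- geneIds[nDenovoOnly + nParalogLoss + seq_len(nRedundant)]
    cdsOf <- function(g) {
      gs <- gsAll[[g]]
      substr(gs$mature, gs$u5 + 1L, gs$u5 + gs$cdsLen)
    }
    ref <- character(0)
    for (g in setdiff(geneIds, gOnly)) ref[paste0("ref_", g)] <- gsAll[[g]]$mature
    dn <- character(0)
    proteins <- character(0)
    for (g in geneIds) {
      proteins[paste0(g, "_p")] <- bundle$proteome[[paste0(g, ".t1_p")]]
    }
    for (g in gRed) dn[paste0("dn_red_", g)] <- cdsOf(g)
    for (g in gOnly) dn[paste0("dn_only_", g)] <- cdsOf(g)
    lossProteins <- character(0)
    for (g in gHost) {
      cds <- cdsOf(g)
      codons <- substring(cds, seq(1L, nchar(cds) - 2L, 3L),
                          seq(3L, nchar(cds), 3L))
      k <- length(codons)
      interior <- 16L:(k - 15L)
      mut <- sample(interior, max(1L, round(codonMutFrac * length(interior))))
      for (ci in mut) {
        old <- codons[ci]
        repeat {
          pos <- sample(3L, 1L)
          nt <- sample(setdiff(c("A", "C", "G", "T"),
                               substr(old, pos, pos)), 1L)
          cand <- old
          substr(cand, pos, pos) <- nt
          if (!cand %in% .STOPS &&
              Biostrings::GENETIC_CODE[[cand]] != Biostrings::GENETIC_CODE[[old]]) {
            codons[ci] <- cand
            break
          }
        }
      }
      parCds <- paste(codons, collapse = "")
      dn[paste0("dn_par_", g)] <- parCds
      pid <- paste0("par_", g, "_p")
      proteins[pid] <- sub("\\*$", "", translateDna(parCds, 0L))
      lossProteins <- c(lossProteins, pid)
    }
    plantedRemoved <- c(paste0("dn_red_", gRed), paste0("dn_par_", gHost))
    list(ref = ref, denovo = dn, proteins = proteins,
         plantedRemoved = plantedRemoved, lossProteins = lossProteins,
         genes = list(denovoOnly = gOnly, hosts = gHost, redundant = gRed))
  })
}

#' Fragment CDSs into overlapping forward tilings
#'
#' Cuts each selected CDS into 4-8 error-free forward fragments with
#' overlaps of at least `minOverlap` nt between neighbours, the input shape
#' the per-cluster overlap-consensus assembler must reconstruct exactly.
#'
#' @param bundle A [makeGenome()] result.
#' @param seed Integer seed.
#' @param nGenes Number of CDSs to tile (longest CDSs first).
#' @param nFragRange Range of fragments per CDS.
#' @param minOverlap Minimum overlap between consecutive fragments (nt).
#' @return A named list per gene: `members` (named character fragments,
#'   5'-to-3') and `truth` (the full CDS).
#' @export
makeTilingFragments <- function(bundle, seed, nGenes = 20L,
                                nFragRange = c(4L, 8L), minOverlap = 60L) {
  gsAll <- bundle$geneStructs
  cdsLens <- vapply(gsAll, function(x) x$cdsLen, integer(1))
  pick <- names(sort(cdsLens, decreasing = TRUE))[seq_len(min(nGenes, length(gsAll)))]
  .withSeed(seed, {
    out <- list()
    for (g in pick) {
      gs <- gsAll[[g]]
      cds <- substr(gs$mature, gs$u5 + 1L, gs$u5 + gs$cdsLen)
      L <- nchar(cds)
      nf <- sample(nFragRange[1L]:nFragRange[2L], 1L)
      ## fragment starts spread over the CDS; each fragment runs past the
      ## next start by at least minOverlap
      starts <- round(seq(1L, L, length.out = nf + 1L))[seq_len(nf)]
      jit <- c(0L, sample(-10:10, nf - 1L, replace = TRUE))
      starts <- pmax(1L, pmin(starts + jit, L - minOverlap))
      starts <- sort(starts)
      ends <- c(pmin(starts[-1L] + minOverlap +
                       sample(0:40, nf - 1L, replace = TRUE), L), L)
      frags <- substring(cds, starts, ends)
      names(frags) <- sprintf("%s_f%02d", g, seq_len(nf))
      out[[g]] <- list(members = frags, truth = cds)
    }
    out
  })
}
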