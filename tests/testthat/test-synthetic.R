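test_that("genome generation is deterministic and parameter-checked", {
  b1 <- makeGenome(4, seed = 701)
  b2 <- makeGenome(4, seed = 701)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$mature, b2$mature)
  expect_identical(b1$proteome, b2$proteome)
  b3 <- makeGenome(4, seed = 702)
  expect_false(identical(b1$genome, b3$genome))
  expect_error(makeGenome(2, 1, params = list(exonCountRange = c(2L, 20L))),
               "exonCountRange")
  expect_error(makeGenome(2, 1, params = list(intronLenRange = c(10L, 50L))),
               "intronLenRange")
})

test_that("every generated intron is GT..AG on the transcript strand", {
  b <- makeGenome(8, seed = 703)
  ex <- exonRanges(b$models)
  ctg <- contigOf(b$models)
  str <- strandOf(b$models)
  nIntron <- 0L
  for (i in seq_along(ex)) {
    st <- GenomicRanges::start(ex[[i]]); en <- GenomicRanges::end(ex[[i]])
    if (length(st) < 2) next
    g <- b$genome[[ctg[i]]]
    for (j in seq_len(length(st) - 1)) {
      iS <- en[j] + 1L; iE <- st[j + 1] - 1L
      donor <- substr(g, iS, iS + 1L)
      acceptor <- substr(g, iE - 1L, iE)
      pair <- if (str[i] == "+") paste0(donor, "-", acceptor)
        else paste0(revcomp(acceptor), "-", revcomp(donor))
      expect_identical(pair, "GT-AG")
      nIntron <- nIntron + 1L
    }
  }
  expect_gt(nIntron, 0L)
})

test_that("models, mature transcripts and proteome are mutually consistent", {
  b <- makeGenome(8, seed = 704)
  expect_identical(splicedSequence(b$models, b$genome), b$mature)
  for (tid in names(b$mature)) {
    lo <- longestOrf(b$mature[[tid]], id = tid)
    expect_identical(lo$aa, unname(b$proteome[[paste0(tid, "_p")]]))
  }
  ## CDS spans at least 60% of every primary mature transcript
  prim <- b$txInfo[b$txInfo$isoform == 1, ]
  expect_true(all(prim$orfLenNt / prim$matureLen >= 0.6))
})

test_that("corruption assigns labels via the oracle, not by construction", {
  b <- makeGenome(12, seed = 705)
  allNone <- corruptTranscripts(b, corruptionSpec = c(none = 1), seed = 706)
  expect_identical(allNone$transcripts, b$mature)
  expect_true(all(allNone$truth$expectedClass == "correct"))

  cr <- corruptTranscripts(b, seed = 707)
  expect_identical(sort(names(cr$transcripts)), sort(names(b$mature)))
  expect_true(all(cr$truth$expectedClass %in%
                    c("correct", "incomplete", "false", "no_hit")))
  ## determinism
  cr2 <- corruptTranscripts(b, seed = 707)
  expect_identical(cr$transcripts, cr2$transcripts)
  expect_identical(cr$truth, cr2$truth)
  expect_error(corruptTranscripts(b, corruptionSpec = c(nope = 1)), "unknown")
  expect_error(corruptTranscripts(b, corruptionSpec = c(none = 0.9,
                                                        chimera = 0.4)),
               "sum")
})

test_that("strand flips and internal deletions corrupt as advertised", {
  b <- makeGenome(10, seed = 708)
  cr <- corruptTranscripts(b, corruptionSpec = c(strand_flip = 0.5,
                                                 internal_deletion = 0.5),
                           seed = 709)
  flips <- cr$truth$transcriptId[cr$truth$corruption == "strand_flip"]
  for (tid in flips) {
    expect_identical(cr$transcripts[[tid]], revcomp(b$mature[[tid]]))
    ## both-strand ORF scanning makes a flipped transcript classify intact
    expect_identical(cr$truth$expectedClass[cr$truth$transcriptId == tid],
                     "correct")
  }
  dels <- cr$truth$transcriptId[cr$truth$corruption == "internal_deletion"]
  expect_true(all(nchar(cr$transcripts[dels]) < nchar(b$mature[dels])))
})

test_that("two-branch bundles are deterministic with all plants logged", {
  b <- makeGenome(20, seed = 710)
  t1 <- makeTwoBranchInputs(b, seed = 711, nLowCov = 3, nNonCanonical = 3,
                            nShortOrf = 3, nContain = 5)
  t2 <- makeTwoBranchInputs(b, seed = 711, nLowCov = 3, nNonCanonical = 3,
                            nShortOrf = 3, nContain = 5)
  expect_identical(t1$denovo, t2$denovo)
  expect_identical(exonRanges(t1$refModels), exonRanges(t2$refModels))
  expect_identical(t1$decoys, t2$decoys)
  expect_length(t1$decoys$lowCoverage, 3)
  expect_length(t1$containments, 5)
  ## zero decoys means the branches are clean truth
  t0 <- makeTwoBranchInputs(b, seed = 712, nLowCov = 0, nNonCanonical = 0,
                            nShortOrf = 0, nContain = 0)
  expect_setequal(transcriptIds(t0$refModels), transcriptIds(b$models))
  expect_error(makeTwoBranchInputs(b, seed = 1, nLowCov = 50,
                                   nNonCanonical = 0, nShortOrf = 0),
               "not enough genes")
})

test_that("label soundness: the production classifier recovers truth labels", {
  b <- makeGenome(15, seed = 713)
  cr <- corruptTranscripts(b, seed = 714)
  cls <- classifySet(cr$transcripts, b$proteome)
  got <- stats::setNames(cls$classes$class, cls$classes$transcriptId)
  expect_identical(unname(got[cr$truth$transcriptId]),
                   cr$truth$expectedClass)
})
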