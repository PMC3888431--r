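mkModels <- function(spec) {
  ## spec: list of list(id, ctg, strand, exons = matrix(start, end), src)
  grl <- list()
  src <- integer(0)
  for (m in spec) {
    gr <- GenomicRanges::GRanges(m$ctg,
      IRanges::IRanges(m$exons[, 1], m$exons[, 2]), m$strand)
    grl[[m$id]] <- gr
    src[m$id] <- if (is.null(m$src)) NA_integer_ else m$src
  }
  TranscriptModels(GenomicRanges::GRangesList(grl), sourceLength = src)
}

test_that("mapping-coverage filter keeps the 90% boundary inclusive", {
  m <- mkModels(list(
    list(id = "a", ctg = "c", strand = "+",
         exons = cbind(1, 900), src = 1000L),
    list(id = "b", ctg = "c", strand = "+",
         exons = cbind(1, 899), src = 1000L)))
  r <- filterMappingCoverage(m)
  expect_identical(transcriptIds(r$kept), "a")
  expect_identical(transcriptIds(r$removed), "b")

  bad <- mkModels(list(list(id = "x", ctg = "c", strand = "+",
                            exons = cbind(1, 10))))
  expect_error(filterMappingCoverage(bad), "sourceLength missing.*x")
})

test_that("mapping-coverage filter equals per-item predicate evaluation", {
  set.seed(401)
  spec <- lapply(1:100, function(i) {
    len <- sample(200:1000, 1)
    list(id = sprintf("t%03d", i), ctg = "c", strand = "+",
         exons = cbind((i - 1) * 2000 + 1, (i - 1) * 2000 + len),
         src = as.integer(round(len / stats::runif(1, 0.5, 1.3))))
  })
  m <- mkModels(spec)
  r <- filterMappingCoverage(m, minCov = 0.9)
  want <- vapply(spec, function(s)
    (s$exons[, 2] - s$exons[, 1] + 1) / s$src >= 0.9, logical(1))
  expect_setequal(transcriptIds(r$kept),
                  vapply(spec, `[[`, "", "id")[want])
  ## idempotence
  r2 <- filterMappingCoverage(r$kept, minCov = 0.9)
  expect_length(transcriptIds(r2$removed), 0)
})

test_that("canonical splice filter reads donor/acceptor on the right strand", {
  intron1 <- paste0("GT", randDna(56, seed = 402), "AG")
  genome <- c(c = paste0(randDna(100), intron1, randDna(100)))
  plus <- mkModels(list(list(id = "p", ctg = "c", strand = "+",
                             exons = cbind(c(50, 161), c(100, 200)))))
  expect_identical(transcriptIds(filterCanonicalSplice(plus, genome)$kept), "p")

  ## same intron read on the minus strand is CT..AC: removed
  minus <- mkModels(list(list(id = "m", ctg = "c", strand = "-",
                              exons = cbind(c(50, 161), c(100, 200)))))
  expect_identical(transcriptIds(filterCanonicalSplice(minus, genome)$removed),
                   "m")
  ## a genuine minus-strand intron (revcomp geometry: CT..AC on plus)
  intron2 <- paste0("CT", randDna(56), "AC")
  genome2 <- c(c = paste0(randDna(100), intron2, randDna(100)))
  minus2 <- mkModels(list(list(id = "m2", ctg = "c", strand = "-",
                               exons = cbind(c(50, 161), c(100, 200)))))
  expect_identical(transcriptIds(filterCanonicalSplice(minus2, genome2)$kept),
                   "m2")
  ## single-exon models always pass
  single <- mkModels(list(list(id = "s", ctg = "c", strand = "+",
                               exons = cbind(10, 60))))
  expect_identical(transcriptIds(filterCanonicalSplice(single, genome)$kept),
                   "s")
  ## GC-AG passes only when added to the canonical set
  intron3 <- paste0("GC", randDna(56), "AG")
  genome3 <- c(c = paste0(randDna(100), intron3, randDna(100)))
  gcag <- mkModels(list(list(id = "g", ctg = "c", strand = "+",
                             exons = cbind(c(50, 161), c(100, 200)))))
  expect_identical(transcriptIds(filterCanonicalSplice(gcag, genome3)$removed),
                   "g")
  expect_identical(
    transcriptIds(filterCanonicalSplice(gcag, genome3,
      canonicalPairs = c("GT-AG", "GC-AG"))$kept), "g")
})

test_that("splice filter removals equal the generator's corrupted plants", {
  b <- makeGenome(12, seed = 403)
  tb <- makeTwoBranchInputs(b, seed = 404, nLowCov = 0, nNonCanonical = 5,
                            nShortOrf = 0, nContain = 0)
  r <- filterCanonicalSplice(tb$refModels, b$genome)
  expect_setequal(transcriptIds(r$removed), tb$decoys$nonCanonical)
})

test_that("locus grouping is connected components of exonic overlap", {
  m <- mkModels(list(
    list(id = "a", ctg = "c", strand = "+", exons = cbind(1, 100)),
    list(id = "b", ctg = "c", strand = "+", exons = cbind(100, 200)),
    list(id = "c", ctg = "c", strand = "-", exons = cbind(1, 100)),
    list(id = "d", ctg = "c", strand = "+", exons = cbind(300, 400))))
  loci <- groupLoci(m)
  expect_equal(unname(loci["a"]), unname(loci["b"]))   # 1 bp overlap links
  expect_false(loci[["a"]] == loci[["c"]])             # strand separates
  expect_false(loci[["a"]] == loci[["d"]])
  ## abutting exons (no shared base) stay apart
  m2 <- mkModels(list(
    list(id = "x", ctg = "c", strand = "+", exons = cbind(1, 100)),
    list(id = "y", ctg = "c", strand = "+", exons = cbind(101, 200))))
  l2 <- groupLoci(m2)
  expect_false(l2[["x"]] == l2[["y"]])
})

test_that("locus grouping equals the igraph component oracle", {
  set.seed(405)
  for (rep in 1:60) {
    n <- sample(5:25, 1)
    spec <- lapply(seq_len(n), function(i) {
      st <- sample(1:2000, 1)
      list(id = sprintf("t%02d", i), ctg = sample(c("c1", "c2"), 1),
           strand = sample(c("+", "-"), 1),
           exons = cbind(st, st + sample(50:400, 1)))
    })
    m <- mkModels(spec)
    loci <- groupLoci(m)
    ids <- vapply(spec, `[[`, "", "id")
    edges <- matrix(integer(0), ncol = 2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- spec[[i]]; b <- spec[[j]]
      if (a$ctg == b$ctg && a$strand == b$strand &&
          a$exons[, 1] <= b$exons[, 2] && b$exons[, 1] <= a$exons[, 2])
        edges <- rbind(edges, c(i, j))
    }
    want <- componentsOracle(n, edges)
    expect_true(samePartition(partitionOf(ids, loci[ids]),
                              partitionOf(ids, want)))
  }
})

test_that("longest-ORF locus filter applies the inclusive 75% rule", {
  ## three overlapping single-exon models whose spliced sequences carry
  ## open ORFs of 900, 675 and 600 nt (ATG at contig position 101)
  cds <- paste0("ATG", paste(randCodons(300), collapse = ""))
  genome <- c(c = paste0(randDna(100, seed = 406), cds, randDna(50)))
  m <- mkModels(list(
    list(id = "full", ctg = "c", strand = "+", exons = cbind(101, 1000)),
    list(id = "ok", ctg = "c", strand = "+", exons = cbind(101, 775)),
    list(id = "short", ctg = "c", strand = "+", exons = cbind(101, 700))))
  r <- filterOrfFraction(m, genome)
  expect_setequal(transcriptIds(r$kept), c("full", "ok"))     # 675 >= 0.75*900
  expect_identical(transcriptIds(r$removed), "short")         # 600 < 675
  ## idempotent on the kept set
  r2 <- filterOrfFraction(r$kept, genome)
  expect_length(transcriptIds(r2$removed), 0)
})

test_that("reference pipeline removes exactly the planted decoys per stage", {
  b <- makeGenome(30, seed = 407)
  tb <- makeTwoBranchInputs(b, seed = 408, nLowCov = 4, nNonCanonical = 4,
                            nShortOrf = 4, nContain = 0)
  r <- runRefPipeline(tb$refModels, b$genome)
  expect_setequal(r$removedIds$mapping_coverage, tb$decoys$lowCoverage)
  expect_setequal(r$removedIds$canonical_splice, tb$decoys$nonCanonical)
  expect_setequal(r$removedIds$orf_fraction, tb$decoys$shortOrf)
  expect_equal(r$report$input[1], length(tb$refModels))
  expect_true(all(r$report$kept + r$report$removed == r$report$input))
  ## clean truth set passes untouched
  rClean <- runRefPipeline(b$models, b$genome)
  expect_length(unlist(rClean$removedIds), 0)
  ## empty input
  r0 <- runRefPipeline(TranscriptModels(GenomicRanges::GRangesList()),
                       b$genome)
  expect_equal(length(r0$models), 0L)
  expect_true(all(r0$report$input == 0))
})

test_that("filters commute with input order", {
  b <- makeGenome(10, seed = 409)
  tb <- makeTwoBranchInputs(b, seed = 410, nLowCov = 2, nNonCanonical = 2,
                            nShortOrf = 2, nContain = 0)
  ids <- transcriptIds(tb$refModels)
  set.seed(411)
  perm <- sample(ids)
  r1 <- runRefPipeline(tb$refModels, b$genome)
  r2 <- runRefPipeline(subsetModels(tb$refModels, perm), b$genome)
  expect_setequal(transcriptIds(r1$models), transcriptIds(r2$models))
})
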