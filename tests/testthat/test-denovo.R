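test_that("containment dedup removes duplicates and boundary containments", {
  set.seed(501)
  full <- randDna(1000)
  ## equal-length duplicates iterate in id order: "aFirst" is kept
  ts <- c(aFirst = full, bDup = full,
          frag = substr(full, 201, 500), lone = randDna(600))
  r <- dedupeContainment(ts)
  expect_setequal(names(r$kept), c("aFirst", "lone"))
  expect_setequal(r$evidence$removedId, c("bDup", "frag"))
  expect_true(all(r$evidence$keptId == "aFirst"))

  ## 100-nt transcript matching over exactly 90 of its 100 nt: removed
  target <- randDna(1000)
  q <- paste0(substr(target, 101, 190), randDna(10))
  r2 <- dedupeContainment(c(big = target, small = q))
  expect_identical(r2$evidence$removedId, "small")
  expect_gte(r2$evidence$coverage[1], 0.90)
})

test_that("containment dedup equals the all-pairs predicate oracle", {
  ts <- makeContainmentSet(nBase = 25, nContained = 12, seed = 502)
  r <- dedupeContainment(ts)
  ## oracle: iterate by descending length, apply the predicate over all
  ## already-kept sequences with the exhaustive aligner
  ids <- names(ts)[order(-nchar(ts), names(ts))]
  kept <- character(0)
  removedOracle <- character(0)
  for (id in ids) {
    hit <- FALSE
    for (kid in kept) {
      h <- ungappedAlignNt(ts[[id]], ts[[kid]], minIdentityPct = 95)
      if (!is.null(h) && queryCoverage(h) >= 0.90) { hit <- TRUE; break }
    }
    if (hit) removedOracle <- c(removedOracle, id) else kept <- c(kept, id)
  }
  expect_setequal(r$evidence$removedId, removedOracle)
  ## idempotence: the kept set is containment-free
  r2 <- dedupeContainment(r$kept)
  expect_length(names(r2$removed), 0)
})

test_that("k-mer clustering links isoforms and separates unrelated sequences", {
  set.seed(503)
  s <- randDna(1000)
  cl <- clusterKmer(c(x = s, y = s, z = randDna(1000)))
  expect_length(cl, 2)
  expect_setequal(cl[[which(vapply(cl, length, 1L) == 2)]], c("x", "y"))

  ## two isoforms sharing most exons cluster together
  b <- makeGenome(8, seed = 504, params = list(isoformRange = c(2L, 4L)))
  multi <- names(which(table(sub("[.].*", "", names(b$mature))) > 1))
  if (length(multi)) {
    g <- multi[1]
    members <- names(b$mature)[startsWith(names(b$mature), paste0(g, "."))]
    cl2 <- clusterKmer(b$mature[members])
    expect_length(cl2, 1)
  }
  expect_error(clusterKmer(c(a = "ACGT"), k = 6), "k must be")
})

test_that("k-mer clustering equals the single-linkage component oracle", {
  set.seed(505)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    pool <- lapply(1:3, function(i) randDna(sample(400:900, 1)))
    seqs <- stats::setNames(vapply(seq_len(n), function(i) {
      src <- sample(pool, 1)[[1]]
      L <- sample(250:nchar(src), 1)
      fs <- sample(seq_len(nchar(src) - L + 1), 1)
      s <- substr(src, fs, fs + L - 1)
      if (stats::runif(1) < 0.3) s <- revcomp(s)
      s
    }, character(1)), sprintf("s%02d", seq_len(n)))
    cl <- clusterKmer(seqs, k = 14, minSharedFraction = 0.30)
    km <- lapply(seqs, oracleCanonicalKmers, k = 14)
    edges <- matrix(integer(0), ncol = 2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      shared <- length(intersect(km[[i]], km[[j]]))
      if (shared / min(length(km[[i]]), length(km[[j]])) >= 0.30)
        edges <- rbind(edges, c(i, j))
    }
    want <- componentsOracle(n, edges)
    expect_true(samePartition(partitionOf(names(seqs), attr(cl, "assignment")),
                              partitionOf(names(seqs), want)))
  }
})

test_that("overlap assembly reconstructs fragmented sequences exactly", {
  set.seed(506)
  full <- randDna(2000)
  f1 <- substr(full, 1, 1100)
  f2 <- substr(full, 1001, 2000)
  asm <- assembleCluster(c(f1 = f1, f2 = f2))
  expect_length(asm, 1)
  expect_equal(unname(asm[[1]]), full)
  expect_setequal(names(attr(asm, "memberOf")), c("f1", "f2"))

  ## reverse-complemented partner is never merged (forward-only rule)
  asm2 <- assembleCluster(c(f1 = f1, f2 = revcomp(f2)))
  expect_length(asm2, 2)

  ## contained members are absorbed; contig at least as long as any member
  asm3 <- assembleCluster(c(a = full, mid = substr(full, 400, 900)))
  expect_length(asm3, 1)
  expect_equal(unname(asm3[[1]]), full)
  expect_error(assembleCluster(character(0)), "non-empty")
})

test_that("assembly output preserves members as ungapped sub-alignments", {
  b <- makeGenome(10, seed = 507, params = list(exonCountRange = c(4L, 9L)))
  tf <- makeTilingFragments(b, seed = 508, nGenes = 5)
  for (g in names(tf)) {
    asm <- assembleCluster(tf[[g]]$members)
    expect_length(asm, 1)
    expect_equal(unname(asm[[1]]), tf[[g]]$truth)
    expect_gte(nchar(asm[[1]]), max(nchar(tf[[g]]$members)))
    for (mem in tf[[g]]$members) {
      h <- ungappedAlignNt(mem, asm[[1]], minIdentityPct = 98)
      expect_false(is.null(h))
      expect_equal(queryCoverage(h), 1.0)
    }
  }
})

test_that("de novo pipeline runs stage order with faithful reporting", {
  r0 <- runDenovoPipeline(character(0))
  expect_length(r0$transcripts, 0)

  ## transcripts without a long ORF are dropped at stage one
  set.seed(509)
  noOrf <- stats::setNames(replicate(4, randDna(150)), paste0("n", 1:4))
  r1 <- runDenovoPipeline(noOrf)
  expect_length(r1$transcripts, 0)
  expect_equal(r1$report$removed[1], 4)

  b <- makeGenome(10, seed = 510)
  tb <- makeTwoBranchInputs(b, seed = 511, nLowCov = 0, nNonCanonical = 0,
                            nShortOrf = 0, nContain = 4)
  r2 <- runDenovoPipeline(tb$denovo)
  ## one contig per gene: containments removed, the rest distinct genes
  expect_equal(length(r2$transcripts), 10)
  expect_setequal(r2$stages$dedupe$evidence$removedId, tb$containments)
  expect_true(all(r2$report$input[1] == length(tb$denovo)))
})
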