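mkHit <- function(targetId, qLen, tLen, matches, mismatches = 0L, gaps = 0L,
                  evalue = NA_real_) {
  PairwiseHit(queryId = "q", targetId = targetId,
              queryLen = qLen, targetLen = tLen, strand = "+",
              blocks = cbind(0L, 0L, matches + mismatches),
              matches = matches, mismatches = mismatches, gapColumns = gaps,
              evalue = evalue, blockless = gaps > 0, units = "aa-aa")
}

test_that("merge removes covered de novo transcripts, reference first", {
  set.seed(601)
  ref <- c(r1 = randDna(1500), r2 = randDna(1200))
  dnRed <- substr(ref[["r1"]], 101, 1100)          # coverage 1.0 by r1
  dn <- c(d1 = dnRed, d2 = randDna(800))
  r <- mergeSets(ref, dn)
  expect_setequal(names(r$final), c("r1", "r2", "d2"))
  expect_equal(r$log$removedId, "d1")
  expect_equal(r$log$rule, "denovo_covered_by_ref")

  ## precedence: identical sequences survive as the reference copy
  eq <- randDna(900)
  r2 <- mergeSets(c(refEq = eq), c(dnEq = eq))
  expect_identical(names(r2$final), "refEq")

  expect_error(mergeSets(c(a = "ACGTACGTACGT"), c(a = "ACGTACGTACGT")),
               "duplicate")
})

test_that("reference transcripts fall only to complete ungapped coverage", {
  set.seed(602)
  dnLong <- randDna(2000)
  refIn <- substr(dnLong, 301, 1100)       # ref wholly inside a de novo
  refPart <- paste0(substr(dnLong, 1200, 1800), randDna(200))  # partial
  r <- mergeSets(c(rIn = refIn, rPart = refPart), c(dBig = dnLong))
  expect_setequal(names(r$final), c("rPart", "dBig"))
  expect_equal(r$log$removedId[r$log$rule == "ref_covered_by_denovo"], "rIn")
})

test_that("merge scenario removals and audit match the generator plants", {
  b <- makeGenome(30, seed = 603)
  sc <- makeMergeScenario(b, seed = 604, nRedundant = 10, nParalogLoss = 3,
                          nDenovoOnly = 3)
  r <- mergeSets(sc$ref, sc$denovo)
  expect_setequal(r$log$removedId, sc$plantedRemoved)
  ## post-condition audit: no surviving de novo transcript still satisfies
  ## the removal predicate against a kept reference transcript
  for (d in names(r$keptDenovo)) {
    for (rid in names(r$keptRef)) {
      h <- ungappedAlignNt(r$keptDenovo[[d]], r$keptRef[[rid]])
      expect_true(is.null(h) || queryCoverage(h) < 0.95)
    }
  }
})

test_that("classification follows the best-significant-hit rules", {
  ## correct: reference covered 95% with 0.5% gaps
  h1 <- mkHit("p1", qLen = 100L, tLen = 100L, matches = 95L)
  expect_equal(classifyTranscript(list(h1))$class, "correct")
  ## incomplete: reference 60% covered, query 95% covered, no gaps
  h2 <- mkHit("p1", qLen = 100L, tLen = 160L, matches = 95L)
  expect_equal(classifyTranscript(list(h2))$class, "incomplete")
  ## false: both sides under-covered
  h3 <- mkHit("p1", qLen = 160L, tLen = 160L, matches = 96L)
  expect_equal(classifyTranscript(list(h3))$class, "false")
  ## gaps above 1% forbid both correct and incomplete
  h4 <- mkHit("p1", qLen = 100L, tLen = 100L, matches = 95L, gaps = 3L)
  expect_equal(classifyTranscript(list(h4))$class, "false")
  ## below the identity floor or the match proxy: no hit at all
  h5 <- mkHit("p1", qLen = 100L, tLen = 100L, matches = 80L, mismatches = 15L)
  expect_equal(classifyTranscript(list(h5))$class, "no_hit")
  h6 <- mkHit("p1", qLen = 100L, tLen = 100L, matches = 20L)
  expect_equal(classifyTranscript(list(h6))$class, "no_hit")
  ## e-values, when present, replace the match-count proxy
  h7 <- mkHit("p1", qLen = 100L, tLen = 100L, matches = 20L, evalue = 1e-30)
  expect_equal(classifyTranscript(list(h7))$class, "false")  # tCov 0.2
  expect_equal(classifyTranscript(list())$class, "no_hit")
  ## best hit by score, ties by target id
  hA <- mkHit("pA", qLen = 100L, tLen = 200L, matches = 95L)
  hB <- mkHit("pB", qLen = 100L, tLen = 100L, matches = 95L)
  cl <- classifyTranscript(list(hA, hB))
  expect_equal(cl$best@targetId, "pA")
})

test_that("set classification recovers constructed class fractions", {
  set.seed(605)
  codons <- lapply(1:6, function(i) randCodons(sample(120:200, 1)))
  prots <- stats::setNames(
    vapply(codons, function(cs)
      paste(Biostrings::GENETIC_CODE[cs], collapse = ""), character(1)),
    paste0("p", 1:6))
  full <- vapply(codons, function(cs)
    paste(c("ATG", cs, "TAA"), collapse = ""), character(1))
  ts <- stats::setNames(full, paste0("t", 1:6))
  r <- classifySet(ts, prots)
  expect_equal(unname(r$fractions["correct"]), 1.0)

  ## truncations to 60% become incomplete
  tsTrunc <- stats::setNames(
    substr(full, 1, floor(nchar(full) * 0.6)), paste0("tr", 1:6))
  r2 <- classifySet(c(ts, tsTrunc), prots)
  expect_equal(unname(r2$fractions["incomplete"]), 0.5)
  expect_equal(r2$nWithHit, 12)

  r3 <- classifySet(character(0), prots)
  expect_true(all(is.na(r3$fractions)))
})

test_that("u80 counts single ungapped alignments at the 80% boundary", {
  set.seed(606)
  codons <- c("ATG", randCodons(99))
  prot <- sub("[*]$", "", translateDna(paste(codons, collapse = ""), 0))
  expect_equal(nchar(prot), 100L)
  t80 <- paste(codons[1:80], collapse = "")
  t79 <- paste(codons[1:79], collapse = "")
  tGap <- paste(c(codons[1:60], codons[64:100]), collapse = "")
  r <- u80Metric(c(p = prot), c(t = t80))
  expect_equal(r$u80, 1L)
  expect_equal(unname(r$gapClass), "ungapped")
  r2 <- u80Metric(c(p = prot), c(t = t79))
  expect_equal(r2$u80, 0L)
  expect_equal(unname(r2$gapClass), "uncovered")
  ## two-block chain, coverage 0.97, gap fraction 0.03: qualified but gapped
  r3 <- u80Metric(c(p = prot), c(t = tGap))
  expect_equal(r3$u80, 0L)
  expect_equal(unname(r3$gapClass), "gap_le_5pct")
  expect_equal(sum(r3$classCounts), 1L)
})

test_that("u80 is monotone under set growth and union beats branches", {
  b <- makeGenome(12, seed = 607)
  ts <- b$mature
  full <- u80Metric(b$proteome, ts)
  set.seed(608)
  for (i in 1:5) {
    sub <- sample(ts, sample(3:8, 1))
    expect_lte(u80Metric(b$proteome, sub)$u80, full$u80)
  }
  ## three branch subsets: the union's u80 is at least every branch's
  parts <- split(names(ts), rep_len(1:3, length(ts)))
  u <- vapply(parts, function(ids) u80Metric(b$proteome, ts[ids])$u80,
              integer(1))
  expect_gte(full$u80, max(u))
})

test_that("unique-u80 counts proteins seen in exactly one set", {
  b <- makeGenome(9, seed = 609)
  ts <- b$mature
  same <- uniqueU80(b$proteome, list(a = ts, b = ts))
  expect_true(all(same$uniqueCounts == 0))
  ## give one gene only to the first set
  g1tx <- names(ts)[startsWith(names(ts), "g001.")]
  setA <- ts
  setB <- ts[setdiff(names(ts), g1tx)]
  r <- uniqueU80(b$proteome, list(a = setA, b = setB))
  expect_gte(r$uniqueCounts[["a"]], 1L)
  expect_true(any(startsWith(setdiff(r$u80Ids$a, r$u80Ids$b), "g001.")))
  expect_error(uniqueU80(b$proteome, list(a = ts)), "two")
})

test_that("presence test applies the 5-point identity-drop rule", {
  set.seed(610)
  cs <- randCodons(120)
  prot <- paste(Biostrings::GENETIC_CODE[cs], collapse = "")
  exact <- paste(cs, collapse = "")
  mutAt <- function(nAA) {
    idx <- sample(20:100, nAA)
    out <- cs
    for (i in idx) {
      repeat {
        cand <- sample(randCodons(1), 1)
        if (Biostrings::GENETIC_CODE[[cand]] != Biostrings::GENETIC_CODE[[out[i]]]) {
          out[i] <- cand; break
        }
      }
    }
    paste(out, collapse = "")
  }
  drop4 <- mutAt(5)    # ~95.8% identity vs 100%: within 5 points
  drop8 <- mutAt(10)   # ~91.7%: beyond 5 points... vs 100
  pr <- c(P = prot)
  r1 <- presenceTest(pr, combined = c(cA = exact), final = c(fA = drop4))
  expect_identical(r1$presentInCombined, "P")
  expect_length(r1$missing, 0)
  r2 <- presenceTest(pr, combined = c(cA = exact), final = c(fA = drop8))
  expect_identical(r2$missing, "P")
  ## a protein absent from the combined set is not reported missing
  other <- stats::setNames(paste(randCodons(150), collapse = ""), "far")
  r3 <- presenceTest(c(P = prot, Q = paste(Biostrings::GENETIC_CODE[randCodons(100)], collapse = "")),
                     combined = c(cA = exact), final = c(fA = exact))
  expect_identical(r3$missing, character(0))
})

test_that("presence test missing set equals the generator's planted losses", {
  b <- makeGenome(24, seed = 611)
  sc <- makeMergeScenario(b, seed = 612, nRedundant = 8, nParalogLoss = 3,
                          nDenovoOnly = 3)
  mg <- mergeSets(sc$ref, sc$denovo)
  pt <- presenceTest(sc$proteins, c(sc$ref, sc$denovo), mg$final)
  expect_setequal(pt$missing, sc$lossProteins)
})

test_that("paralog table cross-tabulates clusters against loci", {
  clusters <- list(c1 = c("t1", "t2"), c2 = "t3", c3 = "t4", c4 = "t5")
  loci <- c(t1 = "L1", t2 = "L1", t3 = "L1", t4 = "L2", t5 = NA)
  tab <- paralogTable(clusters, loci)
  ## c1 and c2 share locus L1: both multiple_cluster, single locus each
  expect_equal(tab["multiple_cluster", "single_locus"], 2L)
  expect_equal(tab["unique_cluster", "single_locus"], 1L)
  expect_equal(tab["unique_cluster", "no_locus"], 1L)
  expect_equal(sum(tab), length(clusters))

  cl2 <- list(cA = c("t1", "t4"))
  expect_equal(paralogTable(cl2, loci)["unique_cluster", "multiple_loci"], 1L)
  expect_error(paralogTable(list(x = "zz"), loci), "not in loci")
})

test_that("paralog table equals direct tabulation on generator families", {
  b <- makeGenome(15, seed = 613, params = list(isoformRange = c(1L, 3L)))
  cl <- clusterKmer(b$mature)
  loci <- groupLoci(b$models)
  tab <- paralogTable(cl, loci)
  ## oracle: recount from scratch
  lociOf <- lapply(cl, function(m) unique(stats::na.omit(loci[m])))
  nLoci <- lengths(lociOf)
  shared <- table(unlist(lociOf))
  isMulti <- vapply(lociOf, function(l) any(shared[l] > 1), logical(1))
  for (rn in c(FALSE, TRUE)) {
    expect_equal(tab[rn + 1L, "single_locus"],
                 sum(nLoci == 1 & isMulti == rn))
    expect_equal(tab[rn + 1L, "multiple_loci"],
                 sum(nLoci > 1 & isMulti == rn))
    expect_equal(tab[rn + 1L, "no_locus"],
                 sum(nLoci == 0 & isMulti == rn))
  }
  expect_equal(sum(tab), length(cl))
})
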