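test_that("hit-track scores match exhaustive enumeration on a tiny model", {
  pfm <- rbind(c(0.8, 0.1, 0.05, 0.05), c(0.05, 0.8, 0.1, 0.05))
  m <- buildTFFM(pfm, "order1", bgToMotifProb = 0.1)
  set.seed(3)
  for (rep in 1:5) {
    s <- randomDnaString(6)
    tr <- hitTrack(m, s, bothStrands = FALSE)
    oracle <- enumPosterior(m@hmm, s)
    want <- rowSums(oracle$gamma[, finalStates(m), drop = FALSE])
    expect_lt(max(abs(tr$plus - want)), 1e-10)
  }
})

test_that("no-entry limit: tiny bgToMotifProb drives all scores to ~0", {
  m <- buildTFFM(testPfm(), "order1", bgToMotifProb = 1e-12)
  tr <- hitTrack(m, randomDnaString(60))
  expect_lt(max(tr$plus), 1e-6)
})

test_that("strand symmetry: a sequence and its reverse complement", {
  m <- buildTFFM(testPfm(), "order1")
  set.seed(17)
  for (rep in 1:5) {
    s <- randomDnaString(70)
    rc <- revcomp(s)
    expect_equal(bestHit(m, s)$score, bestHit(m, rc)$score,
                 tolerance = 1e-12)
    # the multiset of track scores over both strands is shared by the pair
    t1 <- hitTrack(m, s)
    t2 <- hitTrack(m, rc)
    expect_equal(sort(c(t1$plus, t1$minus)), sort(c(t2$plus, t2$minus)),
                 tolerance = 1e-12)
  }
})

test_that("planted consensus is recovered on both strands", {
  pfm <- testPfm()
  m <- buildTFFM(pfm, "order1")
  cons <- consensusOf(pfm)
  set.seed(29)
  bgl <- paste(sample(c("A", "T"), 30, TRUE), collapse = "")
  bgr <- paste(sample(c("A", "T"), 30, TRUE), collapse = "")
  h <- bestHit(m, paste0(bgl, cons, bgr))
  expect_equal(c(h$start, h$end), c(30, 40))
  hm <- bestHit(m, paste0(bgl, revcomp(cons), bgr))
  expect_equal(c(hm$start, hm$end), c(30, 40))
  expect_equal(hm$strand, "-")
  expect_equal(hm$siteSeq, cons)
})

test_that("best hit equals the track maximum and satisfies the contract", {
  m <- buildTFFM(testPfm(), "order1")
  s <- randomDnaString(101)
  tr <- hitTrack(m, s)
  h <- bestHit(m, s)
  expect_equal(h$score, max(c(tr$plus, tr$minus)), tolerance = 1e-12)
  expect_true(h$end - h$start >= lengthRange(m)[1])
  expect_true(h$end - h$start <= lengthRange(m)[2])
  expect_true(h$start >= 0 && h$end <= 101)
})

test_that("flexible-model hits report the maximum-posterior width", {
  pfm <- testPfm()
  gen <- applyFlexEdit(buildTFFM(pfm, "order1"),
                       flexEdit("skip_position", at = 5, prob = 0.5))
  cons <- consensusOf(pfm)
  short <- paste0(substr(cons, 1, 3), substr(cons, 5, 10))  # drop position 4
  # well-separated site contexts
  h_long <- bestHit(gen, paste0(strrep("T", 20), cons, strrep("T", 20)))
  expect_equal(h_long$width, 10L)
  h_short <- bestHit(gen, paste0(strrep("T", 20), short, strrep("T", 20)))
  expect_equal(h_short$width, 9L)
  expect_equal(h_short$siteSeq, short)
})

test_that("pocc follows its defining identities", {
  m <- buildTFFM(testPfm(), "order1")
  s <- randomDnaString(101)
  tr <- hitTrack(m, s)
  p <- pocc(m, s)
  expect_equal(p, 1 - prod(1 - c(tr$plus, tr$minus)), tolerance = 1e-12)
  expect_gte(p, max(c(tr$plus, tr$minus)))
  expect_gte(p, bestHit(m, s)$score)
  # single strand variant multiplies over the forward track only
  p1 <- pocc(m, s, bothStrands = FALSE)
  expect_equal(p1, 1 - prod(1 - tr$plus), tolerance = 1e-12)
  # no-entry limit gives pocc ~ 0
  m0 <- buildTFFM(testPfm(), "order1", bgToMotifProb = 1e-12)
  expect_lt(pocc(m0, s), 1e-4)
})

test_that("pocc closed form: P = (0.5, 0.5) gives 0.75", {
  # direct identity on the formula, via a crafted two-position product
  expect_equal(1 - prod(1 - c(0.5, 0.5)), 0.75)
  # monotonicity in each P_t
  p <- c(0.2, 0.4, 0.1)
  for (i in seq_along(p)) {
    q <- p; q[i] <- q[i] + 0.3
    expect_gt(1 - prod(1 - q), 1 - prod(1 - p))
  }
})

test_that("too-short sequences are rejected", {
  m <- buildTFFM(testPfm(), "order1")
  expect_error(hitTrack(m, "ACGT"), "shorter")
  expect_error(bestHit(m, "ACGT"), "shorter")
})

test_that("hits serialize to data frame and BED", {
  m <- buildTFFM(testPfm(), "order1")
  hits <- lapply(1:3, function(i) bestHit(m, randomDnaString(60)))
  df <- hitsToDataFrame(hits)
  expect_equal(nrow(df), 3L)
  f <- withr::local_tempfile(fileext = ".bed")
  writeHitsBed(hits, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(ncol(bed), 6L)
  expect_true(all(bed$V5 >= 0 & bed$V5 <= 1000))
})

test_that("batched scoring equals per-sequence scoring", {
  m <- buildTFFM(testPfm(), "order1")
  set.seed(8)
  seqs <- vapply(1:6, function(i) randomDnaString(80), "")
  b <- unname(motifHMM:::.batchSiteScores(m, seqs, "best"))
  p <- unname(motifHMM:::.batchSiteScores(m, seqs, "pocc"))
  for (i in 1:6) {
    expect_equal(b[i], bestHit(m, seqs[i])$score, tolerance = 1e-12)
    expect_equal(p[i], pocc(m, seqs[i]), tolerance = 1e-12)
  }
})
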