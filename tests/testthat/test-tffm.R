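test_that("pfmFromSites matches closed-form counts", {
  expect_equal(unname(pfmFromSites(c("ACG", "ACG", "ACG", "ACG"))),
               rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0)))
  expect_equal(unname(pfmFromSites(c("AA", "CC"))[1, ]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(pfmFromSites("A", pseudocount = 1)[1, ]),
               c(2, 1, 1, 1) / 5)
  expect_error(pfmFromSites(c("AC", "A")), "equal length")
})

test_that("order0/order1 topology is built as specified", {
  pfm <- rbind(c(0.7, 0.1, 0.1, 0.1),
               c(0.1, 0.7, 0.1, 0.1),
               c(0.1, 0.1, 0.7, 0.1))
  p <- 0.02
  for (kind in c("order0", "order1")) {
    m <- buildTFFM(pfm, kind, bgToMotifProb = p)
    A <- transitionMatrix(m)
    expect_equal(nStates(m), 4L)
    expect_equal(unname(A["bg", "m1"]), p)
    expect_equal(unname(A["bg", "bg"]), 1 - p)
    expect_equal(unname(A["m1", "m2"]), 1)
    expect_equal(unname(A["m2", "m3"]), 1)
    expect_equal(unname(A["m3", "bg"]), 1)
    expect_equal(lengthRange(m), c(3L, 3L))
    # emissions initialized from the PFM rows for every prev context
    for (prev in 1:4) {
      expect_equal(unname(emissionArray(m)[2, prev, ]), pfm[1, ])
    }
  }
  o0 <- buildTFFM(pfm, "order0")
  o1 <- buildTFFM(pfm, "order1")
  expect_true(all(o0@hmm@tied))
  expect_false(any(o1@hmm@tied))
})

test_that("detailed topology uses indicator emissions and PFM transitions", {
  pfm <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1))
  m <- buildTFFM(pfm, "detailed", bgToMotifProb = 0.01)
  expect_equal(nStates(m), 12L)  # 4 bg + 4 per position
  em <- emissionArray(m)
  # each state emits exactly its own nucleotide
  for (s in 1:12) {
    nt <- (s - 1) %% 4 + 1
    for (prev in 1:4) {
      expect_equal(unname(em[s, prev, ]),
                   as.numeric(seq_len(4) == nt))
    }
  }
  A <- transitionMatrix(m)
  # bg.x -> m1.y carries p * pfm[1, y]; position 1 -> 2 carries pfm[2, ]
  expect_equal(unname(A["bg.C", "m1.A"]), 0.01 * 0.7)
  expect_equal(unname(A["m1.A", "m2.C"]), 0.7)
  expect_equal(unname(A["m2.G", "bg.T"]), 0.25)
})

test_that("0-order site likelihood equals the PFM product under forced entry", {
  pfm <- testPfm()
  m <- buildTFFM(pfm, "order0")
  site <- consensusOf(pfm)
  code <- encode(site)
  em <- emissionArray(m)
  siteL <- prod(vapply(seq_along(code), function(i) {
    em[1 + i, 1, code[i]]
  }, numeric(1)))
  expect_equal(siteL, prod(pfm[cbind(seq_along(code), code)]),
               tolerance = 1e-12)
})

test_that("an immediate scan finds the PFM consensus", {
  pfm <- testPfm()
  m <- buildTFFM(pfm, "order1")
  win <- paste0(strrep("T", 40), consensusOf(pfm), strrep("T", 40))
  h <- bestHit(m, win)
  expect_equal(h$start, 40)
  expect_equal(h$end, 50)
  expect_equal(h$siteSeq, consensusOf(pfm))
})

test_that("flexible edits rewire topology with the declared width ranges", {
  pfm <- testPfm()  # L = 10
  m1 <- buildTFFM(pfm, "order1")
  md <- buildTFFM(pfm, "detailed")

  pathWidths <- function(m) {
    sort(unique(vapply(motifHMM:::.sitePaths(m), `[[`, integer(1), "width")))
  }

  for (base in list(m1, md)) {
    sk <- applyFlexEdit(base, flexEdit("skip_position", at = 5, prob = 0.5))
    expect_equal(lengthRange(sk), c(9L, 10L))
    expect_equal(pathWidths(sk), c(9L, 10L))

    gp <- applyFlexEdit(base, flexEdit("gap_insert", at = 5, prob = 0.5))
    expect_equal(lengthRange(gp), c(10L, 11L))
    expect_equal(pathWidths(gp), c(10L, 11L))

    fe <- applyFlexEdit(base, flexEdit("flexible_edge", at = 8, prob = 0.5))
    expect_equal(lengthRange(fe), c(8L, 10L))
    expect_equal(pathWidths(fe), c(8L, 10L))

    ac <- applyFlexEdit(base, flexEdit(
      "alternative_core", at = 5, to = 5, prob = 0.5,
      altPfm = rbind(c(0, 1, 0, 0), c(0, 0, 1, 0))))
    expect_equal(lengthRange(ac), c(10L, 11L))
    expect_equal(pathWidths(ac), c(10L, 11L))

    # every edited model still satisfies all stochastic invariants
    for (m in list(sk, gp, fe, ac)) expect_true(validObject(m@hmm))
  }
})

test_that("edited transition rows remain stochastic at the edit sites", {
  m <- buildTFFM(testPfm(), "order1")
  sk <- applyFlexEdit(m, flexEdit("skip_position", at = 5, prob = 0.5))
  A <- transitionMatrix(sk)
  expect_equal(unname(sum(A["m4", ])), 1, tolerance = 1e-12)
  expect_equal(unname(A["m4", "m5"]), 0.5)
  expect_equal(unname(A["m4", "m6"]), 0.5)
})

test_that("same edit list gives the same width range on order1 and detailed", {
  edits <- list(flexEdit("gap_insert", at = 3, prob = 0.4),
                flexEdit("skip_position", at = 7, prob = 0.6))
  apply_all <- function(kind) {
    m <- buildTFFM(testPfm(), kind)
    for (e in edits) m <- applyFlexEdit(m, e)
    lengthRange(m)
  }
  expect_equal(apply_all("order1"), apply_all("detailed"))
})

test_that("edit misuse is rejected", {
  m <- buildTFFM(testPfm(), "order1")
  expect_error(flexEdit("skip_position", at = 5, prob = 0), "strictly")
  expect_error(applyFlexEdit(m, flexEdit("skip_position", at = 1)), "interior")
  expect_error(applyFlexEdit(m, flexEdit("gap_insert", at = 10)), "last")
  sk <- applyFlexEdit(m, flexEdit("skip_position", at = 5))
  expect_error(applyFlexEdit(sk, flexEdit("skip_position", at = 5)),
               "already")
})

test_that("bgToMotifProb must lie strictly inside (0, 1)", {
  expect_error(buildTFFM(testPfm(), "order1", bgToMotifProb = 0))
  expect_error(buildTFFM(testPfm(), "order1", bgToMotifProb = 1))
})
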