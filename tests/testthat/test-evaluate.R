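test_that("cross-validation plans partition the data correctly", {
  set.seed(2)
  sv <- runif(1800)
  plan <- makePlan(sv, initSize = 600, k = 10, seed = 4)
  expect_length(plan$initSet, 600)
  rest <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_length(rest, 1200)
  expect_length(intersect(plan$initSet, rest), 0)
  # fold tests partition the remainder; train is 9x test
  expect_equal(sort(rest), setdiff(seq_len(1800), plan$initSet))
  for (f in plan$folds) {
    expect_length(f$test, 120)
    expect_length(f$train, 1080)
    expect_length(intersect(f$train, f$test), 0)
  }
  # init set takes the top signal values, ties by input order
  expect_true(min(sv[plan$initSet]) >= max(sv[rest]))

  plan2 <- makePlan(rep(1, 10), initSize = 0, k = 2, seed = 1)
  expect_equal(lengths(lapply(plan2$folds, `[[`, "test")),
               c(5L, 5L), ignore_attr = TRUE)
  expect_error(makePlan(runif(100), initSize = 95, k = 10), "too few")
})

test_that("tied signal values at the boundary resolve by input order", {
  sv <- c(5, 5, 5, 1, 1)
  plan <- makePlan(sv, initSize = 2, k = 3, seed = 1)
  expect_equal(plan$initSet, c(1L, 2L))
})

test_that("Markov background reproduces training composition", {
  gen <- markovBackground(rep(strrep("A", 500), 3))
  s <- sampleMarkovBackground(gen, 5, 50, seed = 2)
  # up to pseudocount leakage, sampled sequences are essentially all A
  expect_gt(unname(gen$trans["A", "A"]), 0.99)
  expect_gt(mean(strsplit(paste(s, collapse = ""), "")[[1]] == "A"), 0.9)

  set.seed(6)
  train <- vapply(1:30, function(i) randomDnaString(200), "")
  gen2 <- markovBackground(train)
  big <- sampleMarkovBackground(gen2, 1, 100000, seed = 3)
  code <- encode(big)
  emp <- matrix(0, 4, 4)
  tab <- table(code[-length(code)], code[-1])
  emp[as.integer(rownames(tab)), as.integer(colnames(tab))] <- tab
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - gen2$trans)), 0.01)

  expect_identical(sampleMarkovBackground(gen2, 3, 20, seed = 9),
                   sampleMarkovBackground(gen2, 3, 20, seed = 9))
  expect_error(markovBackground(character(0)), "empty")
})

test_that("GC-matched subsampling matches bins without replacement", {
  fg <- c(strrep("G", 50), strrep("C", 50))              # 100% GC
  pool <- c(strrep("A", 50), strrep("GC", 25), strrep("C", 50),
            strrep("T", 50))
  out <- gcMatchedSubsample(pool, fg, seed = 1)
  expect_length(out, 2)
  expect_true(all(grepl("^[GC]+$", out)))

  # pool == foreground gives a permutation of the foreground
  set.seed(4)
  fg2 <- vapply(1:20, function(i) randomDnaString(40), "")
  perm <- gcMatchedSubsample(fg2, fg2, seed = 2)
  expect_setequal(unname(perm), unname(fg2))

  # exhausted bin errors, naming the bin
  expect_error(gcMatchedSubsample(strrep("A", 20), c(fg, fg), seed = 1),
               "exhausted")
})

test_that("ROC/AUC matches the pairwise Mann-Whitney oracle", {
  expect_equal(rocAuc(rep(1, 5), rep(0, 5))$auc, 1)
  same <- c(0.1, 0.5, 0.9)
  expect_equal(rocAuc(same, same)$auc, 0.5)

  set.seed(12)
  for (rep in 1:40) {
    fg <- round(runif(sample(3:20, 1)), 1)  # coarse grid forces ties
    bg <- round(runif(sample(3:20, 1)), 1)
    expect_equal(rocAuc(fg, bg)$auc, pairwiseAuc(fg, bg),
                 tolerance = 1e-12)
  }
  expect_error(rocAuc(numeric(0), 1), "non-empty")
})

test_that("ROC curves are monotone and agree with an independent package", {
  set.seed(14)
  fg <- rnorm(60, 1)
  bg <- rnorm(60)
  r <- rocAuc(fg, bg)
  expect_true(all(diff(r$sensitivity) >= 0))
  expect_true(all(diff(1 - r$specificity) >= 0))
  skip_if_not_installed("pROC")
  ref <- pROC::roc(response = rep(c(1, 0), each = 60),
                   predictor = c(fg, bg), quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("method comparison statistics behave at their anchors", {
  auc <- cbind(a = runif(20, 0.7, 0.9))
  auc <- cbind(auc, b = auc[, 1])
  cmp <- compareMethods(auc)
  expect_equal(cmp$padj["a", "b"], 1)
  expect_true(all(cmp$ratios == 1))

  set.seed(15)
  base <- runif(20, 0.7, 0.9)
  cmp2 <- compareMethods(cbind(a = base, b = base + 0.05))
  expect_lt(cmp2$padj["a", "b"], 0.01)

  # ratio similarity threshold arithmetic
  cmp3 <- compareMethods(cbind(a = c(0.90), b = c(0.95)))
  expect_equal(unname(cmp3$ratios[1, "a"]), 0.90 / 0.95)
  expect_false(cmp3$similar[1, "a"])
  expect_true(cmp3$similar[1, "b"])
})

test_that("method comparison is invariant to column order", {
  set.seed(16)
  auc <- cbind(a = runif(12, 0.6, 0.95), b = runif(12, 0.6, 0.95),
               c = runif(12, 0.6, 0.95))
  c1 <- compareMethods(auc)
  c2 <- compareMethods(auc[, c("c", "a", "b")])
  for (i in c("a", "b", "c")) for (j in c("a", "b", "c")) {
    if (i != j) expect_equal(c1$padj[i, j], c2$padj[i, j])
  }
})

test_that("signal-score correlation handles monotone, null and degenerate", {
  sig <- 1:100
  expect_equal(signalScoreCorrelation(sig, sqrt(sig))$rho, 1)

  set.seed(18)
  nullRes <- signalScoreCorrelation(runif(200), runif(200))
  expect_lt(abs(nullRes$rho), 0.5)
  expect_gt(nullRes$slopePValue, 0.05)

  degen <- signalScoreCorrelation(runif(40), rep(0.5, 40))
  expect_true(degen$degenerate)
  expect_equal(degen$rho, 0)
  expect_error(signalScoreCorrelation(1:10, 1:10), "at least 20")
})

test_that("cross-validation never leaks the init set and is reproducible", {
  pfm <- testPfm()
  gen <- buildTFFM(pfm, "order1")
  sim <- simulateDataset(simConfig(nSequences = 80, plantedModel = gen,
                                   seed = 3))
  cv1 <- crossValidate(sim$sequences, sim$signals, pfm, method = "pwm",
                       initSize = 20, k = 5, seed = 2)
  cv2 <- crossValidate(sim$sequences, sim$signals, pfm, method = "pwm",
                       initSize = 20, k = 5, seed = 2)
  expect_identical(cv1$pooledAuc, cv2$pooledAuc)
  tested <- unlist(lapply(cv1$plan$folds, unlist))
  expect_length(intersect(cv1$plan$initSet, tested), 0)
  expect_length(cv1$fgScores, 60)
  expect_length(cv1$bgScores, 60)
})
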