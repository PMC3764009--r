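test_that("log-likelihood matches closed forms", {
  # single state, uniform unconditional emissions
  hmm <- condHMM(1, matrix(1, 1, 1), matrix(0.25, 1, 4))
  expect_equal(logLikelihood(hmm, "ACG"), c(seq1 = log(1 / 64)))

  # one-base sequence with sentinel A on a conditional one-state model
  em <- array(0, c(1, 4, 4))
  for (p in 1:4) em[1, p, ] <- c(0.1, 0.2, 0.3, 0.4) [c(p, p %% 4 + 1, 1, 2)]
  for (p in 1:4) em[1, p, ] <- em[1, p, ] / sum(em[1, p, ])
  h1 <- condHMM(1, matrix(1, 1, 1), em, tied = FALSE)
  expect_equal(unname(logLikelihood(h1, "A")), log(em[1, 1, 1]))
})

test_that("likelihood and posteriors match exhaustive enumeration", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    T_ <- sample(3:6, 1)
    hmm <- randomCondHMM(n)
    s <- randomDnaString(T_)
    oracle <- enumPosterior(hmm, s)
    expect_equal(unname(logLikelihood(hmm, s)), oracle$loglik,
                 tolerance = 1e-10)
    g <- posteriorDecode(hmm, s)
    expect_lt(max(abs(unname(g) - oracle$gamma)), 1e-10)
    expect_equal(rowSums(g), rep(1, T_), tolerance = 1e-9)
  }
})

test_that("one-state decoding is the identity and zero-emission states get 0", {
  hmm <- condHMM(1, matrix(1, 1, 1), matrix(0.25, 1, 4))
  expect_equal(unname(posteriorDecode(hmm, "ACGTACGT")[, 1]), rep(1, 8))

  # state 2 cannot emit T: gamma at a T position must be exactly 0
  B <- rbind(c(0.25, 0.25, 0.25, 0.25), c(1 / 3, 1 / 3, 1 / 3, 0))
  hmm2 <- condHMM(c(0.5, 0.5),
                  rbind(c(0.5, 0.5), c(0.5, 0.5)), B)
  g <- posteriorDecode(hmm2, "ATA")
  expect_equal(unname(g[2, 2]), 0)
})

test_that("order-0 degenerate model equals a plain unconditional HMM", {
  set.seed(11)
  n <- 3
  init <- runif(n); init <- init / sum(init)
  A <- matrix(runif(n * n), n); A <- A / rowSums(A)
  B <- matrix(runif(n * 4), n); B <- B / rowSums(B)
  hmm <- condHMM(init, A, B)  # unconditional rows, replicated internally
  for (s in c("ACGTAC", "TTTT", "GATTACA")) {
    expect_equal(unname(logLikelihood(hmm, s)),
                 plainForwardLL(init, A, B, encode(s)), tolerance = 1e-10)
  }
})

test_that("forward scaling is stable on long sequences", {
  hmm <- randomCondHMM(3, seed = 5)
  s <- randomDnaString(100000)
  ll <- unname(logLikelihood(hmm, s))
  expect_true(is.finite(ll))
  expect_lt(ll / 100000, 0)  # per-base log-prob is negative and finite
})

test_that("invalid residues are rejected, N is tolerated in scanning ops", {
  hmm <- randomCondHMM(2, seed = 2)
  expect_error(logLikelihood(hmm, "ACXG"), "invalid residue")
  expect_true(is.finite(logLikelihood(hmm, "ACNNG")))
})

test_that("Baum-Welch trace is non-decreasing and preserves structure", {
  set.seed(21)
  pfm <- testPfm()
  m <- buildTFFM(pfm, "order1")
  gen <- sampleHMM(m@hmm, length = 60, seed = 3, n = 40)
  seqs <- vapply(gen, `[[`, character(1), "seq")
  fit <- baumWelch(m@hmm, seqs, trainConfig(maxIterations = 15))
  expect_true(all(diff(fit$trace) >= -1e-9))
  # structural zeros never resurrected, no negative probabilities
  expect_true(all(fit$hmm@transitions[transitionMatrix(m) == 0] == 0))
  expect_true(all(fit$hmm@transitions >= 0))
  expect_true(all(fit$hmm@emissions >= 0))
  # stochasticity preserved (validity already enforces this)
  expect_equal(unname(rowSums(fit$hmm@transitions)),
               rep(1, nStates(m)), tolerance = 1e-9)
})

test_that("training data from the init model is near a fixed point", {
  m <- buildTFFM(testPfm(), "order1")
  gen <- sampleHMM(m@hmm, length = 101, seed = 9, n = 150)
  seqs <- vapply(gen, `[[`, character(1), "seq")
  fit <- baumWelch(m@hmm, seqs, trainConfig(maxIterations = 30))
  # near a fixed point (up to sampling noise): the cumulative gain beyond
  # the first step stays small and late steps are at the noise floor
  gain <- diff(fit$trace) / 150
  expect_lt(sum(gain[-1]), 0.5)
  expect_lt(max(utils::tail(gain, 10)), 0.01)
})

test_that("frozen parameter blocks are left untouched", {
  m <- buildTFFM(testPfm(), "detailed")
  gen <- sampleHMM(m@hmm, length = 50, seed = 4, n = 25)
  seqs <- vapply(gen, `[[`, character(1), "seq")
  fit <- baumWelch(m@hmm, seqs, trainConfig(maxIterations = 5),
                   frozen = "emissions")
  expect_identical(fit$hmm@emissions, m@hmm@emissions)
  expect_false(identical(fit$hmm@transitions, m@hmm@transitions))
})

test_that("degenerate training inputs error", {
  hmm <- randomCondHMM(2, seed = 1)
  expect_error(baumWelch(hmm, character(0)), "empty")
  expect_error(baumWelch(hmm, c("ANNA")), "N")
})

test_that("sampling is seeded, deterministic and matches its model", {
  hmm <- randomCondHMM(1, seed = 33)  # one-state order-1 chain
  a <- sampleHMM(hmm, length = 2000, seed = 7)
  b <- sampleHMM(hmm, length = 2000, seed = 7)
  expect_identical(a$seq, b$seq)

  # empirical conditional dinucleotide frequencies approach e(n|m)
  big <- sampleHMM(hmm, length = 100000, seed = 8)
  code <- encode(big$seq)
  emp <- matrix(0, 4, 4)
  tab <- table(code[-length(code)], code[-1])
  emp[as.integer(rownames(tab)), as.integer(colnames(tab))] <- tab
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - emissionArray(hmm)[1, , ])), 0.01)
})

test_that("deterministic cyclic model emits its exact cycle", {
  # two states, forced alternation, each emitting a fixed base
  A <- rbind(c(0, 1), c(1, 0))
  B <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  hmm <- condHMM(c(1, 0), A, B)
  out <- sampleHMM(hmm, length = 6, seed = 1)
  expect_equal(out$seq, "ACACAC")
  expect_equal(out$path, rep(c(1L, 2L), 3))
  expect_error(sampleHMM(hmm, length = 0), "length")
})

test_that("forward-backward invariant: sum_s alpha*beta is constant in t", {
  hmm <- randomCondHMM(4, seed = 55)
  X <- matrix(encode(randomDnaString(40)), nrow = 1)
  fb <- motifHMM:::.forwardBackward(hmm, X)
  tot <- vapply(seq_len(40), function(t) {
    sum(fb$alpha[[t]][1, ] * fb$beta[[t]][1, ])
  }, numeric(1))
  expect_lt(max(abs(tot - 1)), 1e-9)
})
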