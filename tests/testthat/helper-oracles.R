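# Shared fixtures and independent oracles, all built in code.

BASES <- c("A", "C", "G", "T")

encode <- function(x) match(strsplit(x, "")[[1]], c(BASES, "N"))
decode <- function(code) paste(c(BASES, "N")[code], collapse = "")
revcomp <- function(x) {
  code <- encode(x)
  decode(ifelse(rev(code) == 5L, 5L, 5L - rev(code)))
}

# random valid conditional-emission HMM
randomCondHMM <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  init <- runif(n) + 0.05
  init <- init / sum(init)
  A <- matrix(runif(n * n) + 0.05, n)
  A <- A / rowSums(A)
  em <- array(runif(n * 16) + 0.05, c(n, 4, 4))
  for (s in seq_len(n)) for (p in 1:4) em[s, p, ] <- em[s, p, ] / sum(em[s, p, ])
  condHMM(init, A, em)
}

randomDnaString <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

# ORACLE: exhaustive path enumeration of posteriors and likelihood.
# Sums the joint probability over all n^T state paths; independent of the
# forward-backward implementation.
enumPosterior <- function(hmm, seqChar, sentinel = 1L) {
  code <- encode(seqChar)
  n <- length(stateLabels(hmm))
  T_ <- length(code)
  A <- transitionMatrix(hmm)
  em <- emissionArray(hmm)
  init <- initialProbs(hmm)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T_)))
  prev <- c(sentinel, code[-T_])
  pr <- init[paths[, 1]]
  for (t in seq_len(T_)) {
    pr <- pr * em[cbind(paths[, t], prev[t], code[t])]
  }
  if (T_ > 1) {
    for (t in 2:T_) pr <- pr * A[cbind(paths[, t - 1], paths[, t])]
  }
  g <- matrix(0, T_, n)
  for (t in seq_len(T_)) {
    for (s in seq_len(n)) g[t, s] <- sum(pr[paths[, t] == s])
  }
  list(gamma = g / sum(pr), loglik = log(sum(pr)))
}

# ORACLE: forward algorithm for a plain unconditional-emission HMM
# (standard textbook recursion, no conditioning structure at all)
plainForwardLL <- function(init, A, B, code) {
  a <- init * B[, code[1]]
  ll <- 0
  for (t in seq_along(code)[-1]) {
    c1 <- sum(a)
    ll <- ll + log(c1)
    a <- as.numeric((a / c1) %*% A) * B[, code[t]]
  }
  ll + log(sum(a))
}

# ORACLE: tie-corrected Mann-Whitney AUC by direct pairwise comparison
pairwiseAuc <- function(fg, bg) {
  tot <- 0
  for (x in fg) tot <- tot + sum(x > bg) + 0.5 * sum(x == bg)
  tot / (length(fg) * length(bg))
}

# a strong 10-position test PFM and small helpers used across files
testPfm <- function() simulationMotif()

consensusOf <- function(pfm) {
  paste(BASES[apply(pfm, 1, which.max)], collapse = "")
}
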