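# The benchmarking protocol: seeding-set/fold construction, background
# sequence generation (order-1 Markov chain and %GC-matched pool
# subsampling), ROC/AUC, cross-validation, method-comparison statistics and
# score-signal correlation.

#' Cross-validation plan over a peak set
#'
#' Reserves the \code{initSize} sequences with the highest signal values
#' for model seeding (ties resolved by input order), then shuffles the
#' remainder and splits it into k disjoint folds; each fold tests on one
#' part and trains on the other k-1 (train 9x the size of test for the
#' default k = 10).
#'
#' @param signalValues per-sequence enrichment signal.
#' @param initSize number of top-signal sequences reserved for seeding
#'   (default 600).
#' @param k number of folds (default 10).
#' @param seed shuffle seed.
#' @return list of class \code{"CrossValPlan"}: \code{initSet} (indices)
#'   and \code{folds}, a list of \code{list(train, test)} index pairs.
#' @export
makePlan <- function(signalValues, initSize = 600L, k = 10L, seed = 1L) {
  n <- length(signalValues)
  if (n < initSize + k) {
    stop("too few sequences: need at least initSize + k = ", initSize + k)
  }
  ord <- order(signalValues, decreasing = TRUE)  # radix sort: stable
  initSet <- sort(ord[seq_len(initSize)])
  rest <- setdiff(seq_len(n), initSet)
  shuffled <- .withSeed(seed, sample(rest))
  # contiguous chunks of the shuffled remainder, sizes as equal as possible
  sizes <- diff(round(seq(0, length(rest), length.out = k + 1)))
  testSets <- split(shuffled, rep(seq_len(k), sizes))
  folds <- lapply(seq_len(k), function(i) {
    test <- sort(testSets[[i]])
    list(train = sort(unlist(testSets[-i], use.names = FALSE)), test = test)
  })
  structure(list(initSet = initSet, folds = folds, n = n),
            class = "CrossValPlan")
}

#' Order-1 Markov background generator
#'
#' Estimates a one-state first-order chain from all adjacent nucleotide
#' pairs of the training sequences (pseudocount 1 per dinucleotide), plus
#' the marginal first-position distribution, and samples background
#' sequences from it.
#'
#' @param trainSeqs character vector or \code{DNAStringSet}.
#' @return \code{markovBackground}: list of class \code{"MarkovBG"} with
#'   \code{trans} (4 x 4 conditional table, rows = previous nucleotide)
#'   and \code{init} (first-nucleotide distribution).
#' @export
markovBackground <- function(trainSeqs) {
  seqs <- .asSeqChar(trainSeqs)
  if (!length(seqs)) stop("empty training set")
  pair <- matrix(1, 4L, 4L, dimnames = list(.DNA_BASES, .DNA_BASES))
  first <- rep(1, 4L)
  for (s in seqs) {
    code <- .encodeSeq(s)
    code <- code[code != .N_CODE]
    if (length(code) < 1L) next
    first[code[1L]] <- first[code[1L]] + 1
    if (length(code) > 1L) {
      idx <- cbind(code[-length(code)], code[-1L])
      tab <- table(factor(idx[, 1], levels = 1:4),
                   factor(idx[, 2], levels = 1:4))
      pair <- pair + as.matrix(tab)
    }
  }
  structure(list(trans = pair / rowSums(pair), init = first / sum(first)),
            class = "MarkovBG")
}

#' @rdname markovBackground
#' @param gen a \code{"MarkovBG"}.
#' @param n number of sequences to draw.
#' @param lengths sequence lengths (recycled to n).
#' @param seed RNG seed; same seed gives an identical sample.
#' @return \code{sampleMarkovBackground}: character vector of n sequences.
#' @export
sampleMarkovBackground <- function(gen, n, lengths, seed = 1L) {
  stopifnot(inherits(gen, "MarkovBG"))
  lengths <- rep_len(as.integer(lengths), n)
  cum <- t(apply(gen$trans, 1, cumsum))
  cumInit <- cumsum(gen$init)
  .withSeed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      L <- lengths[i]
      code <- integer(L)
      code[1L] <- findInterval(stats::runif(1), cumInit,
                               rightmost.closed = TRUE) + 1L
      if (L > 1L) {
        u <- stats::runif(L - 1L)
        for (t in 2:L) {
          code[t] <- findInterval(u[t - 1L], cum[code[t - 1L], ],
                                  rightmost.closed = TRUE) + 1L
        }
      }
      out[i] <- .decodeSeq(pmin(code, 4L))
    }
    names(out) <- paste0("bg", seq_len(n))
    out
  })
}

#' %GC-matched background subsampling from a candidate pool
#'
#' For each foreground sequence, draws (without replacement) one pool
#' sequence from the same %GC bin (1-percentage-point bins), emulating
#' genomic background construction matched on GC composition.
#'
#' @param pool candidate background sequences.
#' @param foreground foreground sequences to match.
#' @param seed RNG seed.
#' @param binWidth GC-fraction bin width (default 0.01).
#' @return character vector, one background per foreground sequence.
#' @export
gcMatchedSubsample <- function(pool, foreground, seed = 1L,
                               binWidth = 0.01) {
  pool <- .asSeqChar(pool)
  foreground <- .asSeqChar(foreground)
  gc <- function(x) {
    vapply(x, function(s) {
      code <- .encodeSeq(s)
      code <- code[code != .N_CODE]
      mean(code == 2L | code == 3L)
    }, numeric(1))
  }
  binOf <- function(g) as.integer(floor(g / binWidth + 1e-9))
  poolBin <- binOf(gc(pool))
  fgBin <- binOf(gc(foreground))
  .withSeed(seed, {
    taken <- logical(length(pool))
    out <- character(length(foreground))
    for (i in seq_along(foreground)) {
      avail <- which(!taken & poolBin == fgBin[i])
      if (!length(avail)) {
        stop("background pool exhausted for GC bin [",
             fgBin[i] * binWidth, ", ", (fgBin[i] + 1) * binWidth, ")")
      }
      j <- if (length(avail) == 1L) avail else sample(avail, 1L)
      taken[j] <- TRUE
      out[i] <- pool[j]
    }
    names(out) <- paste0("bg", seq_along(out))
    out
  })
}

#' ROC curve and AUC from foreground and background scores
#'
#' Sweeps a threshold over the union of observed scores (ties grouped at
#' one threshold), records sensitivity and specificity at each threshold,
#' and integrates the curve (sensitivity vs 1 - specificity) by the
#' trapezoid rule. Equivalent to the tie-corrected Mann-Whitney
#' probability that a foreground score exceeds a background score.
#'
#' @param fgScores scores of true (foreground) sequences.
#' @param bgScores scores of background sequences.
#' @return list of class \code{"ROCResult"}: \code{thresholds},
#'   \code{sensitivity}, \code{specificity}, \code{auc}.
#' @export
rocAuc <- function(fgScores, bgScores) {
  if (!length(fgScores) || !length(bgScores)) {
    stop("both score lists must be non-empty")
  }
  thr <- sort(unique(c(fgScores, bgScores)), decreasing = TRUE)
  nf <- length(fgScores)
  nb <- length(bgScores)
  tp <- vapply(thr, function(s) sum(fgScores >= s), numeric(1))
  fp <- vapply(thr, function(s) sum(bgScores >= s), numeric(1))
  sens <- c(0, tp / nf)
  fpr <- c(0, fp / nb)
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens[-1],
                 specificity = 1 - fpr[-1], auc = auc),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Cross-validated discrimination of a model on a peak dataset
#'
#' Runs the full benchmarking protocol on one dataset: reserve the
#' top-signal seeding set, split the remainder into k folds; per fold,
#' initialize a model from the seed PFM, train it on the fold's training
#' sequences (TFFM kinds only; the PWM baseline is untrained), score the
#' fold's test sequences and an equal-size background with the best hit
#' per sequence (or the occupancy probability), and accumulate ROC curves.
#' The headline number is the pooled AUC over the concatenated fold
#' scores; per-fold AUCs are also returned.
#'
#' @param seqs dataset sequences (character vector or DNAStringSet).
#' @param signals per-sequence signal values (same length).
#' @param seedPfm L x 4 PFM seeding model initialization.
#' @param method \code{"order0"}, \code{"order1"}, \code{"detailed"} or
#'   \code{"pwm"}.
#' @param flexEdits optional list of [flexEdit()]s applied after building
#'   (TFFM kinds only).
#' @param background \code{"markov"} (order-1 chain fitted to each fold's
#'   test sequences) or \code{"pool"} (GC-matched subsample of
#'   \code{pool}).
#' @param pool candidate background pool when \code{background = "pool"}.
#' @param score \code{"bestHit"} or \code{"pocc"}.
#' @param initSize,k,seed plan parameters (see [makePlan()]).
#' @param config [trainConfig()] for Baum-Welch.
#' @param bgToMotifProb initial background-to-motif transition.
#' @return list of class \code{"CrossValResult"}: \code{pooledAuc},
#'   \code{pooledRoc}, \code{foldAuc}, \code{folds} (per-fold ROCResult),
#'   \code{fgScores}, \code{bgScores}, \code{plan}, \code{method}.
#' @export
crossValidate <- function(seqs, signals, seedPfm,
                          method = c("order1", "order0", "detailed", "pwm"),
                          flexEdits = list(),
                          background = c("markov", "pool"), pool = NULL,
                          score = c("bestHit", "pocc"),
                          initSize = 600L, k = 10L, seed = 1L,
                          config = trainConfig(),
                          bgToMotifProb = 1 / 101) {
  method <- match.arg(method)
  background <- match.arg(background)
  score <- match.arg(score)
  seqs <- .asSeqChar(seqs)
  stopifnot(length(seqs) == length(signals))
  plan <- makePlan(signals, initSize = initSize, k = k, seed = seed)
  stopifnot(!length(intersect(plan$initSet,
                              unlist(lapply(plan$folds, unlist)))))

  fgAll <- numeric(0)
  bgAll <- numeric(0)
  folds <- vector("list", k)
  foldAuc <- numeric(k)
  for (i in seq_len(k)) {
    fold <- plan$folds[[i]]
    trainSeqs <- seqs[fold$train]
    testFg <- seqs[fold$test]
    if (method == "pwm") {
      model <- buildPWM(seedPfm)
      scoreFun <- function(ss) vapply(seq_along(ss), function(j) {
        pwmBestHit(model, ss[j])$score
      }, numeric(1))
    } else {
      tffm <- buildTFFM(seedPfm, method, bgToMotifProb = bgToMotifProb)
      for (e in flexEdits) tffm <- applyFlexEdit(tffm, e)
      fit <- trainTFFM(tffm, trainSeqs, config = config)
      model <- fit$tffm
      mode <- if (score == "bestHit") "best" else "pocc"
      scoreFun <- function(ss) .batchSiteScores(model, ss, mode = mode)
    }
    testBg <- if (background == "markov") {
      gen <- markovBackground(testFg)
      sampleMarkovBackground(gen, length(testFg), nchar(testFg),
                             seed = seed + i)
    } else {
      if (is.null(pool)) stop("background = 'pool' needs a pool")
      gcMatchedSubsample(pool, testFg, seed = seed + i)
    }
    fg <- unname(scoreFun(testFg))
    bg <- unname(scoreFun(testBg))
    roc <- rocAuc(fg, bg)
    folds[[i]] <- roc
    foldAuc[i] <- roc$auc
    fgAll <- c(fgAll, fg)
    bgAll <- c(bgAll, bg)
  }
  pooled <- rocAuc(fgAll, bgAll)
  structure(list(pooledAuc = pooled$auc, pooledRoc = pooled,
                 foldAuc = foldAuc, folds = folds,
                 fgScores = fgAll, bgScores = bgAll,
                 plan = plan, method = method),
            class = "CrossValResult")
}

#' @export
print.CrossValResult <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s): pooled AUC = %.4f (folds %.3f-%.3f)\n",
              length(x$foldAuc), x$method, x$pooledAuc,
              min(x$foldAuc), max(x$foldAuc)))
  invisible(x)
}

#' Pairwise comparison of methods across datasets
#'
#' For each pair of methods, a two-paired-samples Wilcoxon signed-rank
#' test on the per-dataset AUC differences (null: differences symmetric
#' around 0), Benjamini-Hochberg corrected across all pairs. Also reports
#' each method's per-dataset ratio to the best AUC, with methods flagged
#' similar to the best when the ratio is at least 0.95.
#'
#' @param aucTable numeric matrix, datasets x methods (column names are
#'   method names).
#' @return list: \code{pvalues} and \code{padj} (method x method,
#'   symmetric), \code{ratios} (datasets x methods), \code{similar}
#'   (logical, ratio >= 0.95), \code{bestMethod} per dataset.
#' @export
compareMethods <- function(aucTable) {
  aucTable <- as.matrix(aucTable)
  if (ncol(aucTable) < 2L) stop("need at least two methods")
  if (is.null(colnames(aucTable))) {
    colnames(aucTable) <- paste0("method", seq_len(ncol(aucTable)))
  }
  methods <- colnames(aucTable)
  m <- length(methods)
  P <- matrix(NA_real_, m, m, dimnames = list(methods, methods))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      d <- aucTable[, i] - aucTable[, j]
      p <- if (all(d == 0)) 1 else {
        suppressWarnings(stats::wilcox.test(aucTable[, i], aucTable[, j],
                                            paired = TRUE)$p.value)
      }
      P[i, j] <- P[j, i] <- p
    }
  }
  raw <- P[upper.tri(P)]
  adj <- stats::p.adjust(raw, method = "BH")
  Padj <- P
  Padj[upper.tri(Padj)] <- adj
  Padj[lower.tri(Padj)] <- t(Padj)[lower.tri(Padj)]
  best <- apply(aucTable, 1, max)
  ratios <- sweep(aucTable, 1, best, "/")
  list(pvalues = P, padj = Padj, ratios = ratios,
       similar = ratios >= 0.95,
       bestMethod = methods[apply(aucTable, 1, which.max)])
}

#' Correlation between prediction scores and peak signal values
#'
#' Bins the sequences into twenty 5-percentile groups by signal value,
#' takes the median prediction score in each group, and reports the
#' Spearman rank correlation between the group rank (1..20) and the group
#' medians, together with the ordinary least-squares slope p-value on the
#' same 20 points (the probability of a regression slope that far from
#' horizontal under the null).
#'
#' @param signals per-sequence signal values (>= 20).
#' @param scores per-sequence prediction scores.
#' @return list: \code{rho}, \code{slopePValue}, \code{binMedians},
#'   \code{degenerate} (TRUE when the medians are constant, in which case
#'   rho is reported as 0).
#' @export
signalScoreCorrelation <- function(signals, scores) {
  n <- length(signals)
  stopifnot(length(scores) == n)
  if (n < 20L) stop("need at least 20 paired observations")
  bin <- ceiling(rank(signals, ties.method = "first") * 20 / n)
  bin[bin < 1L] <- 1L
  med <- vapply(split(scores, bin), stats::median, numeric(1))
  idx <- as.integer(names(med))
  if (length(unique(med)) == 1L) {
    return(list(rho = 0, slopePValue = NA_real_, binMedians = med,
                degenerate = TRUE))
  }
  rho <- suppressWarnings(
    stats::cor.test(idx, med, method = "spearman")$estimate)
  fit <- stats::lm(med ~ idx)
  slopeP <- summary(fit)$coefficients[2, 4]
  list(rho = unname(rho), slopePValue = slopeP, binMedians = med,
       degenerate = FALSE)
}
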