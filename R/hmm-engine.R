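# Forward-backward machinery for conditional-emission HMMs.
#
# All recursions are batched over sequences of equal length: alpha/beta are
# (n_seq x n_states) matrices updated by one matrix product per position,
# which keeps Baum-Welch training fast in plain R at the problem sizes this
# package targets (~100 nt windows, <= 64 states). Per-position scaling
# (Rabiner) keeps everything in linear space, stable to sequence lengths of
# 1e5 and beyond.

# Emission probability matrix at one position for a batch of sequences.
# prev/cur: integer codes (1..4, 5 = N) of length n_seq. N at the current
# position emits with the uniform background marginal (0.25) in every
# state; N at the previous position conditions on the mean of the four
# conditional rows. Training never sees N (N sequences are excluded).
#' @noRd
.emisAt <- function(em, prev, cur, n) {
  nseq <- length(prev)
  E <- matrix(0, nseq, n)
  curN <- cur == .N_CODE
  prevN <- prev == .N_CODE
  for (s in seq_len(n)) {
    es <- em[s, , ]
    v <- numeric(nseq)
    ok <- !curN & !prevN
    v[ok] <- es[cbind(prev[ok], cur[ok])]
    if (any(prevN & !curN)) {
      mrow <- colMeans(es)
      idx <- prevN & !curN
      v[idx] <- mrow[cur[idx]]
    }
    v[curN] <- 0.25
    E[, s] <- v
  }
  E
}

# Batched scaled forward-backward.
# X: integer matrix (n_seq x T) of coded sequences, all the same length.
# Returns alpha, beta, E as length-T lists of (n_seq x n) matrices (alpha
# scaled so rows sum to 1), per-position scale factors (n_seq x T) and
# per-sequence log-likelihoods.
#' @noRd
.forwardBackward <- function(hmm, X, sentinel = 1L, backward = TRUE) {
  n <- length(hmm@states)
  A <- hmm@transitions
  em <- hmm@emissions
  nseq <- nrow(X)
  T_ <- ncol(X)
  alpha <- vector("list", T_)
  E <- vector("list", T_)
  scale <- matrix(0, nseq, T_)

  prev <- rep.int(sentinel, nseq)
  for (t in seq_len(T_)) {
    Et <- .emisAt(em, prev, X[, t], n)
    E[[t]] <- Et
    if (t == 1L) {
      a <- Et * matrix(hmm@initial, nseq, n, byrow = TRUE)
    } else {
      a <- (alpha[[t - 1L]] %*% A) * Et
    }
    ct <- rowSums(a)
    if (any(ct <= 0)) {
      stop("sequence has probability zero under the model")
    }
    alpha[[t]] <- a / ct
    scale[, t] <- ct
    prev <- X[, t]
  }
  ll <- rowSums(log(scale))

  beta <- NULL
  if (backward) {
    beta <- vector("list", T_)
    beta[[T_]] <- matrix(1, nseq, n)
    if (T_ > 1L) {
      tA <- t(A)
      for (t in seq(T_ - 1L, 1L)) {
        beta[[t]] <- ((beta[[t + 1L]] * E[[t + 1L]]) %*% tA) / scale[, t + 1L]
      }
    }
  }
  list(alpha = alpha, beta = beta, scale = scale, E = E, loglik = ll)
}

#' @noRd
.codeMatrix <- function(seqs) {
  codes <- lapply(seqs, .encodeSeq)
  lens <- lengths(codes)
  list(codes = codes, lens = lens)
}

# split coded sequences into equal-length batches (indices by length)
#' @noRd
.lengthBatches <- function(lens) {
  split(seq_along(lens), lens)
}

#' Log-likelihood of sequences under a conditional-emission HMM
#'
#' Natural-log probability of each sequence under the model, computed with
#' the scaled forward algorithm. The emission at the first position is
#' conditioned on the fixed \code{sentinel} nucleotide.
#'
#' @param hmm a [CondHMM-class].
#' @param seqs a character vector or \code{DNAStringSet} of sequences over
#'   \{A,C,G,T,N\}.
#' @param sentinel nucleotide conditioning the first emission
#'   (default \code{"A"}).
#' @return numeric vector of log-likelihoods, one per sequence.
#' @examples
#' hmm <- condHMM(1, matrix(1, 1, 1), matrix(0.25, 1, 4))
#' logLikelihood(hmm, "ACG")  # log(1/64)
#' @export
logLikelihood <- function(hmm, seqs, sentinel = "A") {
  stopifnot(is(hmm, "CondHMM"))
  validObject(hmm)
  seqs <- .asSeqChar(seqs)
  sent <- match(toupper(sentinel), .DNA_BASES)
  if (is.na(sent)) stop("sentinel must be one of A, C, G, T")
  cm <- .codeMatrix(seqs)
  out <- numeric(length(seqs))
  for (idx in .lengthBatches(cm$lens)) {
    X <- do.call(rbind, cm$codes[idx])
    fb <- .forwardBackward(hmm, X, sentinel = sent, backward = FALSE)
    out[idx] <- fb$loglik
  }
  names(out) <- names(seqs)
  out
}

#' Posterior state probabilities (forward-backward decoding)
#'
#' Computes \eqn{\gamma_t(s) = P(\mathrm{state}~s~\mathrm{at}~t \mid
#' \mathrm{sequence})} for every position and state. Rows sum to 1.
#'
#' @inheritParams logLikelihood
#' @param seq a single sequence.
#' @return numeric matrix (sequence length x n_states) with state labels as
#'   column names.
#' @export
posteriorDecode <- function(hmm, seq, sentinel = "A") {
  stopifnot(is(hmm, "CondHMM"))
  validObject(hmm)
  seq <- .asSeqChar(seq)
  stopifnot(length(seq) == 1L)
  sent <- match(toupper(sentinel), .DNA_BASES)
  if (is.na(sent)) stop("sentinel must be one of A, C, G, T")
  X <- matrix(.encodeSeq(seq[[1]]), nrow = 1L)
  fb <- .forwardBackward(hmm, X, sentinel = sent)
  n <- length(hmm@states)
  T_ <- ncol(X)
  g <- matrix(0, T_, n, dimnames = list(NULL, hmm@states))
  for (t in seq_len(T_)) g[t, ] <- fb$alpha[[t]][1, ] * fb$beta[[t]][1, ]
  g
}

#' Baum-Welch training configuration
#'
#' @param pseudocount small positive value added to expected counts of
#'   structurally allowed parameters before renormalization; keeps
#'   numerically underflowed counts from creating new structural zeros.
#' @param maxIterations iteration cap.
#' @param llTolerance stop when the mean per-sequence log-likelihood
#'   improvement drops below this value.
#' @param seed seed for any randomized initialization.
#' @return a list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(pseudocount = 1e-4, maxIterations = 100L,
                        llTolerance = 1e-4, seed = 1L) {
  stopifnot(pseudocount > 0, maxIterations >= 1)
  structure(list(pseudocount = pseudocount,
                 maxIterations = as.integer(maxIterations),
                 llTolerance = llTolerance, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Baum-Welch parameter estimation
#'
#' Expectation-maximization training of a conditional-emission HMM.
#' Structural zeros (parameters exactly 0 at initialization) are preserved:
#' the topology of the model never changes. Tied (order-0) states keep
#' their four conditional rows identical by pooling expected counts across
#' the previous-nucleotide index. Parameter blocks named in \code{frozen}
#' (\code{"initial"}, \code{"transitions"}, \code{"emissions"}) are left
#' untouched, e.g. the definitional indicator emissions of a detailed TFFM.
#'
#' @inheritParams logLikelihood
#' @param seqs training sequences; sequences containing N are rejected.
#' @param config a [trainConfig()].
#' @param frozen character subset of
#'   \code{c("initial", "transitions", "emissions")}.
#' @return list with elements \code{hmm} (the trained model) and
#'   \code{trace} (total log-likelihood per iteration, non-decreasing).
#' @export
baumWelch <- function(hmm, seqs, config = trainConfig(), frozen = character(),
                      sentinel = "A") {
  stopifnot(is(hmm, "CondHMM"))
  validObject(hmm)
  seqs <- .asSeqChar(seqs)
  if (!length(seqs)) stop("empty training set")
  if (any(grepl("N", seqs, fixed = TRUE))) {
    if (all(grepl("N", seqs, fixed = TRUE))) {
      stop("all training sequences contain N")
    }
    stop("training sequences must not contain N; filter them first")
  }
  stopifnot(all(frozen %in% c("initial", "transitions", "emissions")))
  sent <- match(toupper(sentinel), .DNA_BASES)

  n <- length(hmm@states)
  pc <- config$pseudocount
  maskI <- hmm@initial > 0
  maskA <- hmm@transitions > 0
  maskE <- hmm@emissions > 0

  cm <- .codeMatrix(seqs)
  batches <- .lengthBatches(cm$lens)
  Xs <- lapply(batches, function(idx) do.call(rbind, cm$codes[idx]))

  cur <- hmm
  trace <- numeric(0)
  prevTotal <- -Inf
  for (iter in seq_len(config$maxIterations)) {
    A <- cur@transitions
    initC <- numeric(n)
    transC <- matrix(0, n, n)
    emisC <- array(0, dim = c(n, 4L, 4L))
    total <- 0

    for (X in Xs) {
      nseq <- nrow(X)
      T_ <- ncol(X)
      fb <- .forwardBackward(cur, X, sentinel = sent)
      total <- total + sum(fb$loglik)
      # previous observed nucleotide at each position
      P <- cbind(rep.int(sent, nseq),
                 X[, -T_, drop = FALSE])
      for (t in seq_len(T_)) {
        g <- fb$alpha[[t]] * fb$beta[[t]]
        if (t == 1L) initC <- initC + colSums(g)
        # emission expected counts grouped by (prev, cur) pair
        k <- (P[, t] - 1L) * 4L + X[, t]
        G <- rowsum(g, k)
        ks <- as.integer(rownames(G))
        for (j in seq_along(ks)) {
          pv <- (ks[j] - 1L) %/% 4L + 1L
          cv <- (ks[j] - 1L) %% 4L + 1L
          emisC[, pv, cv] <- emisC[, pv, cv] + G[j, ]
        }
        if (t < T_) {
          M <- (fb$E[[t + 1L]] * fb$beta[[t + 1L]]) / fb$scale[, t + 1L]
          transC <- transC + A * crossprod(fb$alpha[[t]], M)
        }
      }
    }

    trace <- c(trace, total)
    improve <- (total - prevTotal) / length(seqs)
    if (is.finite(prevTotal) && improve < config$llTolerance) break
    prevTotal <- total

    # ---- M step ----
    newInit <- cur@initial
    if (!"initial" %in% frozen) {
      v <- (initC + pc) * maskI
      if (sum(v) > 0) newInit <- v / sum(v)
    }
    newA <- cur@transitions
    if (!"transitions" %in% frozen) {
      for (s in seq_len(n)) {
        if (!any(maskA[s, ])) next
        v <- (transC[s, ] + pc) * maskA[s, ]
        if (sum(v) > 0) newA[s, ] <- v / sum(v)
      }
    }
    newE <- cur@emissions
    if (!"emissions" %in% frozen) {
      for (s in seq_len(n)) {
        if (cur@tied[s]) {
          cnt <- colSums(emisC[s, , ])
          v <- (cnt + pc) * maskE[s, 1L, ]
          if (sum(v) > 0) {
            row <- v / sum(v)
            for (prev in 1:4) newE[s, prev, ] <- row
          }
        } else {
          for (prev in 1:4) {
            if (!any(maskE[s, prev, ])) next
            v <- (emisC[s, prev, ] + pc) * maskE[s, prev, ]
            if (sum(v) > 0) newE[s, prev, ] <- v / sum(v)
          }
        }
      }
    }
    cur <- new("CondHMM", states = cur@states, initial = newInit,
               transitions = newA, emissions = newE, tied = cur@tied)
  }
  validObject(cur)
  list(hmm = cur, trace = trace)
}

#' Sample sequences from a conditional-emission HMM
#'
#' Ancestral sampling of the generative process: states follow the initial
#' and transition probabilities; each emitted nucleotide is drawn from the
#' current state's conditional row given the previously emitted nucleotide
#' (the sentinel for the first position).
#'
#' @inheritParams logLikelihood
#' @param length sequence length (>= 1).
#' @param seed integer seed; same seed gives identical output.
#' @param n number of sequences to draw.
#' @return for \code{n = 1} a list with \code{seq} (character) and
#'   \code{path} (integer state indices); for \code{n > 1} a list of such
#'   lists.
#' @export
sampleHMM <- function(hmm, length, seed = 1L, n = 1L, sentinel = "A") {
  stopifnot(is(hmm, "CondHMM"))
  validObject(hmm)
  if (length < 1L) stop("length must be >= 1")
  sent <- match(toupper(sentinel), .DNA_BASES)
  .withSeed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      path <- integer(length)
      emit <- integer(length)
      prev <- sent
      s <- sample.int(length(hmm@states), 1L, prob = hmm@initial)
      for (t in seq_len(length)) {
        if (t > 1L) s <- sample.int(length(hmm@states), 1L,
                                    prob = hmm@transitions[s, ])
        e <- sample.int(4L, 1L, prob = hmm@emissions[s, prev, ])
        path[t] <- s
        emit[t] <- e
        prev <- e
      }
      out[[i]] <- list(seq = .decodeSeq(emit), path = path)
    }
    if (n == 1L) out[[1]] else out
  })
}
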