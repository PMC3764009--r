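# PWM log-odds baseline for head-to-head comparison with the HMM models.

#' Log-odds position weight matrix
#'
#' Entry-wise \eqn{w_{i,n} = \log_2((p_{i,n} + pc) / (b_n + pc))} for PFM
#' probability p, background frequency b and pseudocount pc.
#'
#' @slot weights L x 4 log-odds matrix (columns A, C, G, T).
#' @slot background length-4 background frequencies.
#' @slot pseudocount the pseudocount used.
#' @seealso [buildPWM()], [pwmBestHit()]
#' @export
setClass("MotifPWM",
  representation(weights = "matrix", background = "numeric",
                 pseudocount = "numeric")
)

setValidity("MotifPWM", function(object) {
  msgs <- character()
  if (ncol(object@weights) != 4L) msgs <- c(msgs, "weights must have 4 columns")
  if (!all(is.finite(object@weights))) msgs <- c(msgs, "non-finite weights")
  m <- .checkProbVector(object@background, "background")
  if (!is.null(m)) msgs <- c(msgs, m)
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MotifPWM", function(object) {
  cat(sprintf("MotifPWM of length %d (max score %.3f bits)\n",
              nrow(object@weights), sum(apply(object@weights, 1, max))))
})

#' Build a log-odds PWM from a position frequency matrix
#'
#' @param pfm L x 4 probability matrix.
#' @param background length-4 background nucleotide frequencies
#'   (default uniform).
#' @param pseudocount added to both numerator and denominator probabilities
#'   (default 0.01); must be > 0 if any PFM entry is 0, otherwise the
#'   weight would be infinite.
#' @return a [MotifPWM-class].
#' @examples
#' pfm <- rbind(c(1, 0, 0, 0), c(0, 0.5, 0.5, 0))
#' buildPWM(pfm, pseudocount = 0.01)
#' @export
buildPWM <- function(pfm, background = rep(0.25, 4), pseudocount = 0.01) {
  pfm <- .checkPfm(pfm)
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0)) {
    stop("background must be a probability vector over A, C, G, T")
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(pfm == 0)) {
    stop("zero PFM entry with zero pseudocount gives an infinite weight")
  }
  W <- log2(sweep(pfm + pseudocount, 2, background + pseudocount, "/"))
  colnames(W) <- .DNA_BASES
  new("MotifPWM", weights = W, background = background,
      pseudocount = pseudocount)
}

# windowed PWM scores along one strand of a coded sequence; N scores as
# the background expectation of its column
#' @noRd
.pwmScores <- function(pwm, code) {
  W <- pwm@weights
  L <- nrow(W)
  T_ <- length(code)
  nWin <- T_ - L + 1L
  if (nWin < 1L) stop("sequence shorter than the matrix")
  bgExp <- as.numeric(W %*% pwm@background)
  sc <- numeric(nWin)
  for (i in seq_len(L)) {
    col <- code[i:(i + nWin - 1L)]
    v <- ifelse(col == .N_CODE, bgExp[i], W[i, pmin(col, 4L)])
    sc <- sc + v
  }
  sc
}

#' Best PWM hit in a sequence
#'
#' Maximal windowed sum of log-odds weights over all start positions and
#' both strands; ties broken by smaller start, then the forward strand.
#'
#' @param pwm a [MotifPWM-class].
#' @param seq one sequence.
#' @param bothStrands scan the reverse complement too (default TRUE).
#' @return a list of class \code{"Hit"} (same shape as [bestHit()], score
#'   in log-odds bits).
#' @export
pwmBestHit <- function(pwm, seq, bothStrands = TRUE) {
  stopifnot(is(pwm, "MotifPWM"))
  seq <- .asSeqChar(seq)
  stopifnot(length(seq) == 1L)
  code <- .encodeSeq(seq[[1]])
  L <- nrow(pwm@weights)
  T_ <- length(code)
  if (T_ < L) stop("sequence shorter than the matrix")
  plus <- .pwmScores(pwm, code)
  cand <- data.frame(score = plus, start1 = seq_along(plus), strand = "+",
                     stringsAsFactors = FALSE)
  if (bothStrands) {
    minus <- .pwmScores(pwm, .revCompCode(code))
    # rc window starting at j covers forward [T - j - L + 2, T - j + 1]
    cand <- rbind(cand, data.frame(
      score = minus, start1 = T_ - seq_along(minus) - L + 2L,
      strand = "-", stringsAsFactors = FALSE))
  }
  best <- max(cand$score)
  sel <- cand[cand$score >= best - 1e-12, , drop = FALSE]
  sel <- sel[order(sel$start1, sel$strand != "+"), , drop = FALSE]
  top <- sel[1L, ]
  site <- substr(seq[[1]], top$start1, top$start1 + L - 1L)
  if (top$strand == "-") site <- .revCompChar(site)
  structure(list(id = names(seq), start = top$start1 - 1L,
                 end = top$start1 - 1L + L, strand = top$strand,
                 score = top$score, width = L, siteSeq = site),
            class = "Hit")
}
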