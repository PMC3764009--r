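# Scanning sequences with a TFFM: per-position, per-strand posterior
# probabilities that a binding site ends there, best hit per sequence, and
# probability of occupancy.

#' @noRd
.scanOne <- function(tffm, code, sentinel = 1L) {
  X <- matrix(code, nrow = 1L)
  fb <- .forwardBackward(tffm@hmm, X, sentinel = sentinel)
  T_ <- length(code)
  n <- nStates(tffm)
  g <- matrix(0, T_, n)
  for (t in seq_len(T_)) g[t, ] <- fb$alpha[[t]][1, ] * fb$beta[[t]][1, ]
  list(fb = fb, final = rowSums(g[, tffm@finalStates, drop = FALSE]))
}

# final-state posterior P_t for a batch of equal-length coded sequences
# (n_seq x T matrix)
#' @noRd
.finalScoreMatrix <- function(tffm, X, sentinel = 1L) {
  fb <- .forwardBackward(tffm@hmm, X, sentinel = sentinel)
  T_ <- ncol(X)
  S <- matrix(0, nrow(X), T_)
  for (t in seq_len(T_)) {
    g <- fb$alpha[[t]] * fb$beta[[t]]
    S[, t] <- rowSums(g[, tffm@finalStates, drop = FALSE])
  }
  S
}

# batched per-sequence scores: the best-hit posterior (max over positions
# and strands) or the occupancy probability. Numerically identical to
# bestHit()$score / pocc() but one forward-backward per length batch.
#' @noRd
.batchSiteScores <- function(tffm, seqs, mode = c("best", "pocc"),
                             bothStrands = TRUE, sentinel = 1L) {
  mode <- match.arg(mode)
  seqs <- .asSeqChar(seqs)
  cm <- .codeMatrix(seqs)
  out <- numeric(length(seqs))
  for (idx in .lengthBatches(cm$lens)) {
    X <- do.call(rbind, cm$codes[idx])
    S <- .finalScoreMatrix(tffm, X, sentinel)
    Sr <- if (bothStrands) {
      Xr <- t(apply(X, 1L, .revCompCode))
      if (nrow(X) == 1L) Xr <- matrix(Xr, nrow = 1L)
      .finalScoreMatrix(tffm, Xr, sentinel)
    }
    v <- if (mode == "best") {
      b <- apply(S, 1L, max)
      if (bothStrands) b <- pmax(b, apply(Sr, 1L, max))
      b
    } else {
      q <- apply(1 - S, 1L, prod)
      if (bothStrands) q <- q * apply(1 - Sr, 1L, prod)
      1 - q
    }
    out[idx] <- v
  }
  names(out) <- names(seqs)
  out
}

#' Per-position binding-site posterior track
#'
#' Scores a sequence at every position and strand: the score at position t
#' is the posterior probability (forward-backward) of being in a final
#' match state, i.e. that a binding site ends at t. The reverse strand is
#' scanned on the reverse complement with the same model; its scores are
#' mapped back to forward coordinates, indexed by the forward-strand
#' position of the site's last base in its reading direction (the leftmost
#' base of the forward-coordinate interval).
#'
#' @param tffm a [TFFM-class].
#' @param seq one sequence (character or \code{DNAString(Set)}).
#' @param bothStrands scan the reverse strand too (default TRUE).
#' @param sentinel nucleotide conditioning the first emission.
#' @return a list of class \code{"HitTrack"}: \code{id}, \code{plus} and
#'   \code{minus} score vectors (minus all NA when \code{bothStrands} is
#'   FALSE), and \code{length}.
#' @export
hitTrack <- function(tffm, seq, bothStrands = TRUE, sentinel = "A") {
  stopifnot(is(tffm, "TFFM"))
  seq <- .asSeqChar(seq)
  stopifnot(length(seq) == 1L)
  code <- .encodeSeq(seq[[1]])
  T_ <- length(code)
  if (T_ < tffm@lengthRange[1]) {
    stop("sequence shorter than the minimum motif width")
  }
  sent <- match(toupper(sentinel), .DNA_BASES)
  fwd <- .scanOne(tffm, code, sent)
  minus <- rep(NA_real_, T_)
  if (bothStrands) {
    rcode <- .revCompCode(code)
    rev_ <- .scanOne(tffm, rcode, sent)
    # rc position t' -> forward position T - t' + 1
    minus[T_ - seq_len(T_) + 1L] <- rev_$final
  }
  structure(list(id = names(seq), plus = fwd$final, minus = minus,
                 length = T_), class = "HitTrack")
}

# posterior probability of each enumerated site path ending at position t
# (forward reading frame of `code`), using a cached forward-backward.
#' @noRd
.pathScoresAt <- function(tffm, scan, code, t, sentinel = 1L) {
  paths <- .sitePaths(tffm)
  hmm <- tffm@hmm
  A <- hmm@transitions
  em <- hmm@emissions
  n <- nStates(tffm)
  pos <- tffm@matchMap
  alpha <- scan$fb$alpha
  beta <- scan$fb$beta
  sc <- scan$fb$scale
  prevAt <- function(u) if (u <= 1L) sentinel else code[u - 1L]
  vapply(paths, function(pp) {
    w <- pp$width
    if (t - w < 0L) return(0)
    G1 <- pos[[pp$groups[1L]]]
    e1 <- .emisAt(em, prevAt(t - w + 1L), code[t - w + 1L], n)[1L, ]
    if (t - w > 0L) {
      entry <- as.numeric(alpha[[t - w]][1, tffm@bgStates] %*%
                            A[tffm@bgStates, G1, drop = FALSE])
    } else {
      entry <- hmm@initial[G1]
    }
    v <- entry * e1[G1]
    prevG <- G1
    if (w > 1L) {
      for (k in 2:w) {
        Gk <- pos[[pp$groups[k]]]
        u <- t - w + k
        ek <- .emisAt(em, prevAt(u), code[u], n)[1L, ]
        v <- as.numeric(v %*% A[prevG, Gk, drop = FALSE]) * ek[Gk]
        prevG <- Gk
      }
    }
    num <- sum(v * beta[[t]][1, prevG])
    num / prod(sc[1, (t - w + 1L):t])
  }, numeric(1))
}

#' Best-scoring binding site in a sequence
#'
#' The hit with the maximal per-position posterior over both strands, with
#' ties broken by smaller start then the forward strand. For
#' flexible-length models the hit width is the width of the site-path
#' variant with the highest posterior probability of ending at the chosen
#' position.
#'
#' @inheritParams hitTrack
#' @return a list of class \code{"Hit"}: \code{id}, \code{start},
#'   \code{end} (0-based half-open, forward coordinates), \code{strand},
#'   \code{score}, \code{width} and \code{siteSeq} (residues on the hit's
#'   strand).
#' @export
bestHit <- function(tffm, seq, bothStrands = TRUE, sentinel = "A") {
  stopifnot(is(tffm, "TFFM"))
  seq <- .asSeqChar(seq)
  stopifnot(length(seq) == 1L)
  code <- .encodeSeq(seq[[1]])
  T_ <- length(code)
  if (T_ < tffm@lengthRange[1]) {
    stop("sequence shorter than the minimum motif width")
  }
  sent <- match(toupper(sentinel), .DNA_BASES)
  flexible <- tffm@lengthRange[1] != tffm@lengthRange[2]
  L <- tffm@lengthRange[2]

  fwd <- .scanOne(tffm, code, sent)
  rcode <- NULL
  rev_ <- NULL
  if (bothStrands) {
    rcode <- .revCompCode(code)
    rev_ <- .scanOne(tffm, rcode, sent)
  }

  widthAt <- function(scan, cd, t) {
    if (!flexible) return(tffm@lengthRange[1])
    ps <- .pathScoresAt(tffm, scan, cd, t, sent)
    widths <- vapply(.sitePaths(tffm), `[[`, integer(1), "width")
    widths[which.max(ps)]
  }

  # candidates: (score, end position t in the scanning frame, strand)
  cand <- data.frame(score = fwd$final, t = seq_len(T_), strand = "+",
                     stringsAsFactors = FALSE)
  if (bothStrands) {
    cand <- rbind(cand,
                  data.frame(score = rev_$final, t = seq_len(T_),
                             strand = "-", stringsAsFactors = FALSE))
  }
  # work through score levels from the top; within a level, resolve widths
  # and keep only candidates whose full site fits inside the sequence
  # (relevant only for degenerate models — scores at impossible positions
  # are structurally zero otherwise)
  top <- NULL
  while (is.null(top) && nrow(cand)) {
    best <- max(cand$score)
    lvl <- cand$score >= best - 1e-15
    sel <- cand[lvl, , drop = FALSE]
    cand <- cand[!lvl, , drop = FALSE]
    sel$width <- NA_integer_
    sel$start1 <- NA_integer_
    for (i in seq_len(nrow(sel))) {
      if (sel$strand[i] == "+") {
        w <- widthAt(fwd, code, sel$t[i])
        sel$width[i] <- w
        sel$start1[i] <- sel$t[i] - w + 1L
      } else {
        w <- widthAt(rev_, rcode, sel$t[i])
        sel$width[i] <- w
        sel$start1[i] <- T_ - sel$t[i] + 1L
      }
    }
    ok <- sel$start1 >= 1L & (sel$start1 - 1L + sel$width) <= T_
    sel <- sel[ok, , drop = FALSE]
    if (nrow(sel)) {
      sel <- sel[order(sel$start1, sel$strand != "+"), , drop = FALSE]
      top <- sel[1L, ]
    }
  }
  if (is.null(top)) stop("no valid hit position in the sequence")
  start0 <- top$start1 - 1L
  end0 <- start0 + top$width
  site <- substr(seq[[1]], top$start1, top$start1 + top$width - 1L)
  if (top$strand == "-") site <- .revCompChar(site)
  structure(list(id = names(seq), start = start0, end = end0,
                 strand = top$strand, score = top$score,
                 width = top$width, siteSeq = site), class = "Hit")
}

#' Probability of occupancy
#'
#' Aggregates the per-position site posteriors \eqn{P_t} of a sequence into
#' the probability that the factor occupies the sequence at least once:
#' \deqn{P_{occ} = 1 - \prod_t (1 - P_t),}
#' the complement of the probability of no occupancy at any position. By
#' default the product runs over the positions of both strands.
#'
#' @inheritParams hitTrack
#' @return a single numeric in [0, 1].
#' @export
pocc <- function(tffm, seq, bothStrands = TRUE, sentinel = "A") {
  tr <- hitTrack(tffm, seq, bothStrands = bothStrands, sentinel = sentinel)
  p <- c(tr$plus, if (bothStrands) tr$minus)
  p <- p[!is.na(p)]
  1 - prod(1 - p)
}

#' @export
print.Hit <- function(x, ...) {
  cat(sprintf("Hit %s [%d, %d) %s score=%.4g site=%s\n",
              x$id, x$start, x$end, x$strand, x$score, x$siteSeq))
  invisible(x)
}

#' @export
print.HitTrack <- function(x, ...) {
  cat(sprintf("HitTrack %s: %d positions, max + %.4g, max - %.4g\n",
              x$id, x$length, max(x$plus),
              if (all(is.na(x$minus))) NA else max(x$minus, na.rm = TRUE)))
  invisible(x)
}

#' Convert hits to a data frame / write hits as BED6
#'
#' @param hits a list of \code{"Hit"} objects (or a single one).
#' @return \code{hitsToDataFrame}: data.frame with columns id, start, end,
#'   strand, score, width, siteSeq.
#' @export
hitsToDataFrame <- function(hits) {
  if (inherits(hits, "Hit")) hits <- list(hits)
  do.call(rbind, lapply(hits, function(h) {
    data.frame(id = h$id, start = h$start, end = h$end, strand = h$strand,
               score = h$score, width = h$width, siteSeq = h$siteSeq,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname hitsToDataFrame
#' @param path output file path.
#' @return \code{writeHitsBed}: the path, invisibly. Coordinates are
#'   0-based half-open (BED convention); the BED score column carries the
#'   posterior scaled to 0-1000.
#' @export
writeHitsBed <- function(hits, path) {
  df <- hitsToDataFrame(hits)
  bed <- data.frame(chrom = df$id, start = df$start, end = df$end,
                    name = paste0(df$id, "_site"),
                    score = round(1000 * pmin(pmax(df$score, 0), 1)),
                    strand = df$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-position score track as wiggle-like text
#'
#' @param track a \code{"HitTrack"}.
#' @param path output file path.
#' @export
writeTrack <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=posterior id=%s", track$id), con)
  writeLines(sprintf("%d\t%s\t%s", seq_len(track$length),
                     formatC(track$plus, format = "g", digits = 8),
                     ifelse(is.na(track$minus), ".",
                            formatC(track$minus, format = "g", digits = 8))),
             con)
  invisible(path)
}
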