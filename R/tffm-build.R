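# Construction of the three TFFM topologies from a seed position frequency
# matrix, and the declarative flexible-length edits (gap insertion, skippable
# position, alternative core, flexible edge).

#' Position frequency matrix from aligned sites
#'
#' @param sites character vector (or \code{DNAStringSet}) of aligned
#'   binding sites, all the same length.
#' @param pseudocount added to each nucleotide count:
#'   \code{(count + pc) / (N + 4 pc)}.
#' @return an L x 4 matrix with columns A, C, G, T; rows sum to 1.
#' @examples
#' pfmFromSites(c("ACG", "ACG", "ACG", "ACG"))
#' @export
pfmFromSites <- function(sites, pseudocount = 0) {
  sites <- .asSeqChar(sites)
  L <- unique(nchar(sites))
  if (length(L) != 1L) stop("all sites must have equal length")
  if (L < 1L) stop("sites must be non-empty")
  M <- do.call(rbind, lapply(sites, .encodeSeq))
  if (any(M == .N_CODE)) stop("sites must not contain N")
  probs <- matrix(0, L, 4L, dimnames = list(NULL, .DNA_BASES))
  N <- length(sites)
  for (i in seq_len(L)) {
    cnt <- tabulate(M[, i], nbins = 4L)
    probs[i, ] <- (cnt + pseudocount) / (N + 4 * pseudocount)
  }
  probs
}

#' @noRd
.checkPfm <- function(pfm) {
  if (!is.matrix(pfm) || ncol(pfm) != 4L || nrow(pfm) < 1L) {
    stop("a PFM must be an L x 4 matrix")
  }
  if (any(pfm < 0)) stop("PFM entries must be non-negative")
  if (any(abs(rowSums(pfm) - 1) > 1e-9)) {
    stop("each PFM row must sum to 1")
  }
  colnames(pfm) <- .DNA_BASES
  pfm
}

#' Build a TFFM from a seed position frequency matrix
#'
#' Constructs one of the three topologies:
#' \describe{
#'   \item{order0}{one background state plus one match state per motif
#'     position, with unconditional emissions initialized to the PFM rows —
#'     a PFM expressed as an HMM.}
#'   \item{order1}{the same state layout with conditional emissions; each
#'     match state starts with its four conditional rows equal to the PFM
#'     row, so dinucleotide dependencies are absent at initialization and
#'     emerge only through training.}
#'   \item{detailed}{four background states and four nucleotide-specific
#'     states per motif position, each emitting its own nucleotide with
#'     probability 1 (these indicator emissions are definitional and frozen
#'     during training). Dependencies live in the transitions: states of
#'     position i send four transition probabilities to the states of
#'     position i+1, initialized to the PFM row of position i+1, and the
#'     four background states each own their background-to-motif
#'     transitions, so a site can start with a probability depending on the
#'     last background nucleotide.}
#' }
#' In all topologies, consecutive within-motif transitions are 1, the last
#' position returns to the background with probability 1, the background
#' self-transition is \code{1 - bgToMotifProb}, and background emissions
#' start uniform. The initial state distribution equals the transition row
#' out of the background (mass \code{1 - bgToMotifProb} on the background,
#' \code{bgToMotifProb} on the first motif position): the scan window is
#' treated as preceded by background sequence, so a site starting at the
#' first window position is scoreable.
#'
#' @param pfm L x 4 matrix of per-position nucleotide probabilities.
#' @param kind \code{"order0"}, \code{"order1"} or \code{"detailed"}.
#' @param bgToMotifProb probability of entering the motif from the
#'   background; default 1/101 so that roughly one site is expected per
#'   101-nt scan window at initialization.
#' @return a [TFFM-class].
#' @examples
#' pfm <- pfmFromSites(c("TACGAT", "TACGTT", "TACGAT"), pseudocount = 1)
#' buildTFFM(pfm, "order1")
#' @export
buildTFFM <- function(pfm, kind = c("order1", "order0", "detailed"),
                      bgToMotifProb = 1 / 101) {
  kind <- match.arg(kind)
  pfm <- .checkPfm(pfm)
  L <- nrow(pfm)
  if (bgToMotifProb <= 0 || bgToMotifProb >= 1) {
    stop("bgToMotifProb must be in (0, 1)")
  }
  p <- bgToMotifProb

  if (kind %in% c("order0", "order1")) {
    n <- L + 1L
    states <- c("bg", paste0("m", seq_len(L)))
    A <- matrix(0, n, n, dimnames = list(states, states))
    A["bg", "bg"] <- 1 - p
    A["bg", "m1"] <- p
    for (i in seq_len(L - 1L)) A[i + 1L, i + 2L] <- 1
    A[n, "bg"] <- 1
    em <- array(0, dim = c(n, 4L, 4L))
    for (prev in 1:4) em[1L, prev, ] <- 0.25
    for (i in seq_len(L)) for (prev in 1:4) em[i + 1L, prev, ] <- pfm[i, ]
    tied <- rep(kind == "order0", n)
    init <- c(1 - p, p, numeric(L - 1L))
    hmm <- condHMM(init, A, em, states = states, tied = tied)
    mm <- as.list(1L + seq_len(L))
    names(mm) <- as.character(seq_len(L))
    tffm <- new("TFFM", hmm = hmm, kind = kind, matchMap = mm,
                bgStates = 1L, finalStates = n,
                lengthRange = c(L, L), edits = list())
  } else {
    n <- 4L * (L + 1L)
    states <- c(paste0("bg.", .DNA_BASES),
                paste0("m", rep(seq_len(L), each = 4L), ".",
                       rep(.DNA_BASES, L)))
    grp <- function(i) 4L * i + 1:4  # states of motif position i
    A <- matrix(0, n, n, dimnames = list(states, states))
    for (b in 1:4) {
      A[b, 1:4] <- (1 - p) * 0.25
      A[b, grp(1L)] <- p * pfm[1L, ]
    }
    for (i in seq_len(L - 1L)) {
      for (s in grp(i)) A[s, grp(i + 1L)] <- pfm[i + 1L, ]
    }
    for (s in grp(L)) A[s, 1:4] <- 0.25
    em <- array(0, dim = c(n, 4L, 4L))
    for (s in seq_len(n)) {
      nt <- (s - 1L) %% 4L + 1L
      for (prev in 1:4) em[s, prev, nt] <- 1
    }
    tied <- rep(TRUE, n)
    init <- c(rep((1 - p) / 4, 4L), p * pfm[1L, ], numeric(n - 8L))
    hmm <- condHMM(init, A, em, states = states, tied = tied)
    mm <- lapply(seq_len(L), grp)
    names(mm) <- as.character(seq_len(L))
    tffm <- new("TFFM", hmm = hmm, kind = kind, matchMap = mm,
                bgStates = 1:4, finalStates = grp(L),
                lengthRange = c(L, L), edits = list())
  }
  validObject(tffm)
  validObject(tffm@hmm)
  tffm
}

#' Train a TFFM with Baum-Welch
#'
#' Convenience wrapper around [baumWelch()] that freezes the definitional
#' indicator emissions of detailed models and carries the motif bookkeeping
#' over to the trained model. Sequences containing N are dropped with a
#' warning (their likelihood contribution would be ill-defined for
#' training).
#'
#' @param tffm a [TFFM-class].
#' @param seqs training sequences.
#' @param config a [trainConfig()].
#' @return list with \code{tffm} (trained) and \code{trace}
#'   (log-likelihood per iteration).
#' @export
trainTFFM <- function(tffm, seqs, config = trainConfig()) {
  stopifnot(is(tffm, "TFFM"))
  seqs <- .asSeqChar(seqs)
  hasN <- grepl("N", seqs, fixed = TRUE)
  if (any(hasN)) {
    warning(sum(hasN), " sequence(s) containing N excluded from training")
    seqs <- seqs[!hasN]
  }
  frozen <- if (tffm@kind == "detailed") "emissions" else character()
  fit <- baumWelch(tffm@hmm, seqs, config = config, frozen = frozen)
  out <- tffm
  out@hmm <- fit$hmm
  list(tffm = out, trace = fit$trace)
}

#' Declare a flexible-length edit
#'
#' Declarative description of a topology edit that makes a motif's length
#' variable, mirroring the constructions used for flexible binding-site
#' models:
#' \describe{
#'   \item{gap_insert}{a new uniform-emission position inserted between
#'     motif positions \code{at} and \code{at + 1}, used with probability
#'     \code{prob} and bypassed otherwise (STAT-like inserted gap;
#'     widens the width range by +1).}
#'   \item{skip_position}{position \code{at} becomes skippable: the
#'     transition from position \code{at - 1} to \code{at} is set to
#'     \code{prob}, and a new transition from \code{at - 1} to
#'     \code{at + 1} gets \code{1 - prob} (width range widens by -1).}
#'   \item{alternative_core}{positions \code{at..to} can be replaced by an
#'     alternative run of positions given by \code{altPfm}, entered with
#'     probability \code{prob} (e.g. a motif whose core is either one
#'     degenerate column or a two-nucleotide word).}
#'   \item{flexible_edge}{the motif may end at position \code{at}: a
#'     transition from \code{at} to the background is added with
#'     probability \code{prob}, and the continuing transition is scaled to
#'     \code{1 - prob}; position \code{at} joins the final states.}
#' }
#'
#' @param kind edit kind (see above).
#' @param at first (or only) motif position the edit refers to.
#' @param to last motif position of an \code{alternative_core} span.
#' @param prob initial branch probability, strictly in (0, 1); re-estimated
#'   by training.
#' @param altPfm K x 4 matrix for \code{alternative_core}: the emission
#'   rows of the alternative path (its length K may differ from the span).
#' @return a list of class \code{"FlexEdit"} consumed by
#'   [applyFlexEdit()].
#' @export
flexEdit <- function(kind = c("gap_insert", "skip_position",
                              "alternative_core", "flexible_edge"),
                     at, to = NULL, prob = 0.5, altPfm = NULL) {
  kind <- match.arg(kind)
  if (prob <= 0 || prob >= 1) stop("prob must be strictly between 0 and 1")
  at <- as.integer(at)
  if (kind == "alternative_core") {
    if (is.null(to) || is.null(altPfm)) {
      stop("alternative_core needs `to` and `altPfm`")
    }
    altPfm <- .checkPfm(altPfm)
    to <- as.integer(to)
    if (to < at) stop("`to` must be >= `at`")
  }
  structure(list(kind = kind, at = at, to = to, prob = prob,
                 altPfm = altPfm), class = "FlexEdit")
}

# helper: add states to a CondHMM, returning the enlarged model and the
# indices of the new states
#' @noRd
.addStates <- function(hmm, labels, emRows, tied) {
  n0 <- length(hmm@states)
  k <- length(labels)
  n <- n0 + k
  states <- c(hmm@states, labels)
  A <- matrix(0, n, n, dimnames = list(states, states))
  A[seq_len(n0), seq_len(n0)] <- hmm@transitions
  # provisional self-loops keep the enlarged model row-stochastic until the
  # caller rewires the new states (zeroing their rows first)
  for (j in seq_len(k)) A[n0 + j, n0 + j] <- 1
  em <- array(0, dim = c(n, 4L, 4L))
  em[seq_len(n0), , ] <- hmm@emissions
  for (j in seq_len(k)) for (prev in 1:4) em[n0 + j, prev, ] <- emRows[[j]]
  list(hmm = new("CondHMM", states = states,
                 initial = c(hmm@initial, numeric(k)),
                 transitions = A, emissions = em,
                 tied = c(hmm@tied, tied)),
       new = n0 + seq_len(k))
}

# positions (in matchMap order) as list of integer state groups
#' @noRd
.posGroups <- function(tffm) tffm@matchMap

# normalized average transition distribution from state group `from` to
# state group `to` (used to initialize newly created transitions)
#' @noRd
.groupDist <- function(A, from, to) {
  d <- colMeans(A[from, to, drop = FALSE])
  if (sum(d) <= 0) d <- rep(1 / length(to), length(to))
  d / sum(d)
}

#' Apply a flexible-length edit to a TFFM
#'
#' Rewires the model topology as declared by a [flexEdit()]. Edits act at
#' the state level for order-0/order-1 models and at the nucleotide
#' state-group level for detailed models; the same edit list applied to an
#' order-1 and a detailed model yields the same width range. All edited
#' transition rows remain stochastic and the result is validity-checked.
#'
#' @param tffm a [TFFM-class].
#' @param edit a [flexEdit()].
#' @return the edited [TFFM-class], with the edit recorded.
#' @examples
#' pfm <- matrix(rep(c(.7, .1, .1, .1), 11), ncol = 4, byrow = TRUE)
#' m <- buildTFFM(pfm, "order1")
#' skippable <- applyFlexEdit(m, flexEdit("skip_position", at = 5))
#' lengthRange(skippable)  # 10 11
#' @export
applyFlexEdit <- function(tffm, edit) {
  stopifnot(is(tffm, "TFFM"), inherits(edit, "FlexEdit"))
  pos <- .posGroups(tffm)
  L <- length(pos)
  detailed <- tffm@kind == "detailed"
  hmm <- tffm@hmm
  A <- hmm@transitions
  prob <- edit$prob
  mm <- tffm@matchMap
  lr <- tffm@lengthRange
  fin <- tffm@finalStates

  posIndex <- function(i) {
    if (i < 1L || i > L) stop("edit position ", i, " out of range 1..", L)
    pos[[i]]
  }

  if (edit$kind == "gap_insert") {
    pG <- posIndex(edit$at)
    if (edit$at >= L) stop("gap must be inserted before the last position")
    qG <- posIndex(edit$at + 1L)
    if (detailed) {
      labs <- paste0("g", edit$at, ".", .DNA_BASES)
      emRows <- lapply(1:4, function(nt) { r <- numeric(4); r[nt] <- 1; r })
      add <- .addStates(hmm, labs, emRows, tied = rep(TRUE, 4L))
      gap <- add$new
    } else {
      add <- .addStates(hmm, paste0("g", edit$at), list(rep(0.25, 4L)),
                        tied = tffm@kind == "order0")
      gap <- add$new
    }
    hmm <- add$hmm
    A2 <- hmm@transitions
    A2[gap, ] <- 0
    qDist <- .groupDist(A, pG, qG)
    for (u in pG) {
      w <- sum(A2[u, qG])
      A2[u, qG] <- A2[u, qG] * (1 - prob)
      # enter the gap with prob, spread uniformly over its states
      A2[u, gap] <- prob * w / length(gap)
    }
    for (g in gap) A2[g, qG] <- qDist
    hmm@transitions <- A2
    newEntry <- list(gap)
    names(newEntry) <- paste0("g", edit$at)
    mm <- append(mm, newEntry, after = edit$at)
    lr <- c(lr[1], lr[2] + 1L)
  } else if (edit$kind == "skip_position") {
    if (edit$at < 2L || edit$at >= L) {
      stop("skippable position must be an interior motif position")
    }
    prevG <- posIndex(edit$at - 1L)
    skipG <- posIndex(edit$at)
    nextG <- posIndex(edit$at + 1L)
    if (any(A[prevG, nextG] > 0)) {
      stop("position ", edit$at, " is already skippable")
    }
    nDist <- .groupDist(A, skipG, nextG)
    for (u in prevG) {
      w <- sum(A[u, skipG])
      A[u, skipG] <- A[u, skipG] * prob
      A[u, nextG] <- A[u, nextG] + (1 - prob) * w * nDist
    }
    hmm@transitions <- A
    lr <- c(lr[1] - 1L, lr[2])
  } else if (edit$kind == "flexible_edge") {
    if (edit$at >= L) stop("flexible edge must precede the last position")
    pG <- posIndex(edit$at)
    nextG <- posIndex(edit$at + 1L)
    if (any(A[pG, tffm@bgStates] > 0)) {
      stop("position ", edit$at, " already transitions to the background")
    }
    bg <- tffm@bgStates
    for (u in pG) {
      w <- sum(A[u, ])
      A[u, ] <- A[u, ] * (1 - prob)
      A[u, bg] <- A[u, bg] + prob * w / length(bg)
    }
    hmm@transitions <- A
    fin <- sort(unique(c(fin, pG)))
    lr <- c(min(lr[1], edit$at), lr[2])
  } else { # alternative_core
    if (edit$at < 2L) stop("alternative core must start after position 1")
    K <- nrow(edit$altPfm)
    span <- edit$to - edit$at + 1L
    prevG <- posIndex(edit$at - 1L)
    entryG <- posIndex(edit$at)
    afterBg <- edit$to == L
    exitG <- if (afterBg) tffm@bgStates else posIndex(edit$to + 1L)
    # create alternative path states
    altIdx <- vector("list", K)
    for (j in seq_len(K)) {
      if (detailed) {
        labs <- paste0("a", edit$at, ".", j, ".", .DNA_BASES)
        emRows <- lapply(1:4, function(nt) { r <- numeric(4); r[nt] <- 1; r })
        add <- .addStates(hmm, labs, emRows, tied = rep(TRUE, 4L))
      } else {
        add <- .addStates(hmm, paste0("a", edit$at, ".", j),
                          list(edit$altPfm[j, ]),
                          tied = tffm@kind == "order0")
      }
      hmm <- add$hmm
      altIdx[[j]] <- add$new
    }
    A2 <- hmm@transitions
    for (j in seq_len(K)) A2[altIdx[[j]], ] <- 0
    firstAlt <- altIdx[[1L]]
    for (u in prevG) {
      w <- sum(A2[u, entryG])
      A2[u, entryG] <- A2[u, entryG] * (1 - prob)
      if (detailed) {
        A2[u, firstAlt] <- prob * w * edit$altPfm[1L, ]
      } else {
        A2[u, firstAlt] <- prob * w
      }
    }
    for (j in seq_len(K - 1L)) {
      for (u in altIdx[[j]]) {
        if (detailed) {
          A2[u, altIdx[[j + 1L]]] <- edit$altPfm[j + 1L, ]
        } else {
          A2[u, altIdx[[j + 1L]]] <- 1
        }
      }
    }
    exitDist <- if (afterBg) {
      rep(1 / length(exitG), length(exitG))
    } else {
      .groupDist(A, posIndex(edit$to), exitG)
    }
    for (u in altIdx[[K]]) A2[u, exitG] <- exitDist
    hmm@transitions <- A2
    newEntries <- altIdx
    names(newEntries) <- paste0("a", edit$at, ".", seq_len(K))
    mm <- append(mm, newEntries, after = edit$to)
    if (afterBg) fin <- sort(unique(c(fin, altIdx[[K]])))
    delta <- K - span
    lr <- c(min(lr[1], lr[1] + delta), max(lr[2], lr[2] + delta))
  }

  out <- tffm
  out@hmm <- hmm
  out@matchMap <- mm
  out@finalStates <- fin
  out@lengthRange <- as.integer(lr)
  out@edits <- c(tffm@edits, list(unclass(edit)))
  validObject(out@hmm)
  validObject(out)
  out
}

# Enumerate all site paths: sequences of position groups from a
# background-entered group to a group that can return to the background.
# Works at the state-group level so detailed models stay tractable.
# Returns a list of lists(groups = integer vector of matchMap indices,
# width = path length).
#' @noRd
.sitePaths <- function(tffm, maxPaths = 1000L) {
  A <- tffm@hmm@transitions
  pos <- tffm@matchMap
  nPos <- length(pos)
  bg <- tffm@bgStates
  # group adjacency: g -> h if any state transition > 0
  adj <- lapply(seq_len(nPos), function(g) {
    which(vapply(seq_len(nPos), function(h) {
      any(A[pos[[g]], pos[[h]], drop = FALSE] > 0)
    }, logical(1)))
  })
  toBg <- vapply(seq_len(nPos), function(g) {
    any(A[pos[[g]], bg, drop = FALSE] > 0)
  }, logical(1))
  entry <- which(vapply(seq_len(nPos), function(g) {
    any(A[bg, pos[[g]], drop = FALSE] > 0)
  }, logical(1)))
  paths <- list()
  walk <- function(trail) {
    g <- trail[length(trail)]
    if (toBg[g]) paths[[length(paths) + 1L]] <<- trail
    if (length(paths) > maxPaths) stop("too many site paths to enumerate")
    for (h in adj[[g]]) {
      if (h %in% trail) stop("cycle detected among match positions")
      walk(c(trail, h))
    }
  }
  for (g in entry) walk(g)
  lapply(paths, function(tr) list(groups = tr, width = length(tr)))
}
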