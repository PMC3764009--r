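# Synthetic peak-like datasets with known ground truth: 101-nt windows
# drawn from an order-1 background chain, each optionally carrying one
# planted binding site sampled from a generative TFFM, plus a signal value
# that increases with the planted site's generative probability.

#' Default order-1 background composition
#'
#' A human-like background: ~41% GC with a depleted CpG (C followed by G)
#' dinucleotide, so that GC-matching code operates on meaningful
#' variation. Rows are the previous nucleotide, columns the next.
#'
#' @return 4 x 4 row-stochastic matrix.
#' @export
defaultBackground <- function() {
  marg <- c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)
  tr <- rbind(marg, marg, marg, marg)
  rownames(tr) <- .DNA_BASES
  # CpG depletion: most C->G mass moved off, mild TpA depletion
  tr["C", "G"] <- 0.04
  tr["T", "A"] <- 0.22
  tr <- tr / rowSums(tr)
  tr
}

#' Reference simulation motif
#'
#' A realistic ~12-bit motif for simulation studies, shaped like the
#' E-box motifs bound by the Max/Myc family: a strongly conserved
#' 7-nucleotide core (consensus CACGTGA, 95% consensus probability per
#' position) flanked by degenerate positions. Real TF motifs concentrate
#' their information in a near-deterministic core rather than spreading it
#' uniformly, and the simulated data inherit that structure. The default
#' core probability calibrates the total information content to
#' approximately 12 bits (11.9).
#'
#' @param coreProb consensus-base probability at each core position.
#' @return a 10 x 4 position frequency matrix.
#' @export
simulationMotif <- function(coreProb = 0.95) {
  stopifnot(coreProb > 0.25, coreProb < 1)
  core <- function(b) {
    r <- rep((1 - coreProb) / 3, 4)
    r[b] <- coreProb
    r
  }
  flank <- c(0.4, 0.3, 0.2, 0.1)
  rows <- c(list(flank),
            lapply(match(strsplit("CACGTGA", "")[[1]], .DNA_BASES), core),
            list(flank, flank[c(3, 4, 1, 2)]))
  pfm <- do.call(rbind, rows)
  colnames(pfm) <- .DNA_BASES
  pfm / rowSums(pfm)
}

#' Simulation configuration
#'
#' @param nSequences number of windows to generate.
#' @param windowLength window width (default 101, the summit-centered
#'   scan window).
#' @param background 4 x 4 order-1 conditional table for the background
#'   chain (default [defaultBackground()]).
#' @param plantedModel the generative site model: a [TFFM-class] (possibly
#'   with flexible-length edits) or an L x 4 PFM (sites drawn
#'   column-independently).
#' @param plantingProbability probability that a window receives a site.
#' @param sitePosition \code{"uniform"} over valid starts, or
#'   \code{"center"}: Gaussian around the window center (sd
#'   \code{centerSd}), clipped to valid starts — summit-proximal planting.
#' @param centerSd standard deviation for \code{"center"} planting.
#' @param strandProbability probability a site is planted on the forward
#'   strand (default 0.5, as in real peak sets; set to 1 for
#'   strand-identifiable parameter-recovery studies).
#' @param signalSlope a > 0 in \eqn{signal = \exp(a z + \epsilon)} where z
#'   is the standardized per-nucleotide generative log-probability of the
#'   planted site; makes signal increase monotonically with site strength.
#' @param signalNoiseSd sd of the log-normal signal noise.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nSequences, windowLength = 101L,
                      background = defaultBackground(),
                      plantedModel, plantingProbability = 1,
                      sitePosition = c("uniform", "center"),
                      centerSd = 10, strandProbability = 0.5,
                      signalSlope = 1,
                      signalNoiseSd = 0.25, seed = 1L) {
  sitePosition <- match.arg(sitePosition)
  stopifnot(nSequences >= 1, windowLength >= 1,
            plantingProbability >= 0, plantingProbability <= 1,
            strandProbability >= 0, strandProbability <= 1)
  if (is.matrix(plantedModel)) {
    plantedModel <- buildTFFM(.checkPfm(plantedModel), "order0")
  }
  stopifnot(is(plantedModel, "TFFM"))
  if (plantedModel@lengthRange[2] > windowLength) {
    stop("motif wider than the window")
  }
  if (!all(dim(background) == c(4L, 4L)) ||
      any(abs(rowSums(background) - 1) > 1e-9) || any(background < 0)) {
    stop("background must be a 4x4 row-stochastic table")
  }
  structure(list(nSequences = as.integer(nSequences),
                 windowLength = as.integer(windowLength),
                 background = background, plantedModel = plantedModel,
                 plantingProbability = plantingProbability,
                 sitePosition = sitePosition, centerSd = centerSd,
                 strandProbability = strandProbability,
                 signalSlope = signalSlope, signalNoiseSd = signalNoiseSd,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# sample one site from the TFFM's match-state chain, conditioning the
# first emission on prevNt; returns the coded site, its variant (site-path
# groups collapsed to a label), and its generative log-probability
# (emissions plus within-motif transition branches)
#' @noRd
.sampleSite <- function(tffm, prevNt) {
  A <- tffm@hmm@transitions
  em <- tffm@hmm@emissions
  bg <- tffm@bgStates
  # entry distribution: background -> match transitions, averaged over
  # background states, renormalized
  entry <- colMeans(A[bg, , drop = FALSE])
  entry[bg] <- 0
  entry <- entry / sum(entry)
  s <- sample.int(length(entry), 1L, prob = entry)
  logp <- 0
  code <- integer(0)
  prev <- prevNt
  repeat {
    e <- sample.int(4L, 1L, prob = em[s, prev, ])
    logp <- logp + log(em[s, prev, e])
    code <- c(code, e)
    prev <- e
    nxt <- sample.int(ncol(A), 1L, prob = A[s, ])
    if (nxt %in% bg) break
    logp <- logp + log(A[s, nxt] / (1 - sum(A[s, bg])))  # branch choice
    s <- nxt
  }
  list(code = code, width = length(code), logp = logp)
}

#' Generate a synthetic peak dataset with known ground truth
#'
#' Draws each window from the background chain; with the configured
#' probability, one site sampled from the planted model (including
#' flexible-width variants with their branch probabilities) overwrites the
#' window at a drawn position and strand. The site's first emission is
#' conditioned on the background nucleotide preceding it, so planted sites
#' are seamless order-1 insertions. Signal values increase with the
#' planted site's generative log-probability (log-normal noise);
#' unplanted windows get the weakest signal regime.
#'
#' @param config a [simConfig()].
#' @return list of class \code{"SimulatedDataset"}: \code{sequences}
#'   (named character), \code{truth} (data.frame: id, start, end [0-based
#'   half-open], strand, width, logp — one row per planted site),
#'   \code{signals}, \code{config}.
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$nSequences
  W <- config$windowLength
  tffm <- config$plantedModel
  cum <- t(apply(config$background, 1, cumsum))
  # stationary-ish start: marginal of the table
  margin <- colMeans(config$background)
  cumInit <- cumsum(margin / sum(margin))

  .withSeed(config$seed, {
    seqs <- character(n)
    ids <- sprintf("sim%04d", seq_len(n))
    rows <- list()
    strength <- rep(NA_real_, n)
    widths <- integer(0)
    for (i in seq_len(n)) {
      code <- integer(W)
      code[1L] <- findInterval(stats::runif(1), cumInit,
                               rightmost.closed = TRUE) + 1L
      for (t in 2:W) {
        code[t] <- findInterval(stats::runif(1), cum[code[t - 1L], ],
                                rightmost.closed = TRUE) + 1L
      }
      if (stats::runif(1) < config$plantingProbability) {
        strand <- if (stats::runif(1) < config$strandProbability) "+" else "-"
        # draw width first by sampling the site, then place it
        prevGuess <- 1L  # provisional; re-conditioned after placement
        site <- .sampleSite(tffm, prevGuess)
        w <- site$width
        maxStart <- W - w + 1L
        start1 <- if (config$sitePosition == "uniform") {
          sample.int(maxStart, 1L)
        } else {
          center <- (W - w) / 2 + 1
          s <- round(stats::rnorm(1, center, config$centerSd))
          min(max(s, 1L), maxStart)
        }
        # re-sample the site conditioned on the actual preceding base
        prevNt <- if (start1 > 1L) code[start1 - 1L] else 1L
        site <- .sampleSite(tffm, prevNt)
        while (site$width != w) site <- .sampleSite(tffm, prevNt)
        placed <- if (strand == "+") site$code else .revCompCode(site$code)
        code[start1:(start1 + w - 1L)] <- placed
        rows[[length(rows) + 1L]] <- data.frame(
          id = ids[i], start = start1 - 1L, end = start1 - 1L + w,
          strand = strand, width = w, logp = site$logp,
          stringsAsFactors = FALSE)
        strength[i] <- site$logp / w
        widths <- c(widths, w)
      }
      seqs[i] <- .decodeSeq(code)
    }
    names(seqs) <- ids
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = character(0), start = integer(0), end = integer(0),
                 strand = character(0), width = integer(0),
                 logp = numeric(0))
    # signal: exp(a * standardized per-nt site log-probability + noise);
    # unplanted windows sit below the weakest planted site
    z <- strength
    if (any(!is.na(z))) {
      mu <- mean(z, na.rm = TRUE)
      sd_ <- stats::sd(z, na.rm = TRUE)
      if (!is.finite(sd_) || sd_ == 0) sd_ <- 1
      z <- (z - mu) / sd_
      z[is.na(z)] <- min(z, na.rm = TRUE) - 1
    } else {
      z <- rep(0, n)
    }
    signals <- exp(config$signalSlope * z +
                     stats::rnorm(n, 0, config$signalNoiseSd))
    structure(list(sequences = seqs, truth = truth, signals = signals,
                   config = config),
              class = "SimulatedDataset")
  })
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA sequences, a truth BED of planted sites, a signal table,
#' and a faux narrowPeak file (windows laid out on a synthetic contig at
#' 1 kb spacing with the summit at the window center), so the standard
#' format readers can be exercised end-to-end on synthetic data.
#'
#' @param sim a [simulateDataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  stopifnot(inherits(sim, "SimulatedDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "sequences.fa")
  writeFastaSeqs(sim$sequences, fasta)
  bed <- file.path(dir, "truth.bed")
  utils::write.table(
    data.frame(sim$truth$id, sim$truth$start, sim$truth$end,
               "site", 0, sim$truth$strand),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  sig <- file.path(dir, "signals.tsv")
  utils::write.table(
    data.frame(id = names(sim$sequences), signalValue = sim$signals),
    sig, sep = "\t", quote = FALSE, row.names = FALSE)
  W <- sim$config$windowLength
  n <- length(sim$sequences)
  npk <- file.path(dir, "peaks.narrowPeak")
  starts <- (seq_len(n) - 1L) * 1000L
  utils::write.table(
    data.frame("chrS", starts, starts + W, names(sim$sequences), 0, ".",
               sim$signals, -1, -1, (W - 1L) %/% 2L),
    npk, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta, bed = bed, signals = sig, narrowPeak = npk))
}
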