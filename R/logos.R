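# Summary and dense sequence logos for TFFMs, and model information
# content. The dense logo is the dinucleotide-aware representation: one
# row per previous nucleotide, with row opacity encoding how likely that
# previous nucleotide is.

#' Logo tables of a fixed-length TFFM
#'
#' Computes, for each motif position i, the marginal nucleotide
#' probabilities \eqn{P_i(n) = \sum_m P_{i-1}(m) e_i(n|m)} (starting from
#' equiprobable A, C, G, T before the first position), the conditional
#' tables \eqn{P_i(n|m)} (emission tables for order-0/order-1 models;
#' normalized transition tables for detailed models), and the opacity
#' weights \eqn{w_i(m) = P_{i-1}(m)} used by the dense logo.
#'
#' @param tffm a fixed-length [TFFM-class]; flexible-length models are not
#'   representable in this layout and raise an error.
#' @return list of class \code{"LogoData"}: \code{marginal} (L x 4),
#'   \code{conditional} (L x 4 x 4, \code{[i, m, n]}), \code{opacity}
#'   (L x 4), \code{length}.
#' @export
logoData <- function(tffm) {
  stopifnot(is(tffm, "TFFM"))
  if (tffm@lengthRange[1] != tffm@lengthRange[2]) {
    stop("unsupported topology: logos are defined for fixed-length models")
  }
  L <- tffm@lengthRange[1]
  pos <- tffm@matchMap
  A <- tffm@hmm@transitions
  em <- tffm@hmm@emissions
  cond <- array(0, dim = c(L, 4L, 4L),
                dimnames = list(NULL, .DNA_BASES, .DNA_BASES))
  for (i in seq_len(L)) {
    g <- pos[[i]]
    if (tffm@kind == "detailed") {
      # transition rows from the previous position's nucleotide states
      # (the background group for i = 1) to this position's states
      src <- if (i == 1L) tffm@bgStates else pos[[i - 1L]]
      for (m in 1:4) {
        row <- A[src[m], g]
        cond[i, m, ] <- .normalizeRow(row)
      }
    } else {
      cond[i, , ] <- em[g[1L], , ]
    }
  }
  marginal <- matrix(0, L, 4L, dimnames = list(NULL, .DNA_BASES))
  opacity <- matrix(0, L, 4L, dimnames = list(NULL, .DNA_BASES))
  prev <- rep(0.25, 4L)
  for (i in seq_len(L)) {
    opacity[i, ] <- prev
    marginal[i, ] <- as.numeric(prev %*% cond[i, , ])
    prev <- marginal[i, ]
  }
  structure(list(marginal = marginal, conditional = cond,
                 opacity = opacity, length = L), class = "LogoData")
}

#' Information content of a TFFM, in bits
#'
#' \deqn{IC = \sum_i \left[2 + \sum_n P_i(n) \log_2 P_i(n)\right]}
#' with \eqn{0 \log 0 = 0}, using the marginal position probabilities of
#' [logoData()] (Schneider convention, 2 bits per position maximum).
#'
#' @inheritParams logoData
#' @return total information content in \eqn{[0, 2L]} bits.
#' @export
informationContent <- function(tffm) {
  ld <- logoData(tffm)
  sum(apply(ld$marginal, 1, .colIC))
}

#' @noRd
.colIC <- function(p) {
  nz <- p > 0
  2 + sum(p[nz] * log2(p[nz]))
}

# deterministic SVG assembly ------------------------------------------------

.LOGO_COLORS <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")

#' @noRd
.fmt <- function(x) formatC(x, format = "f", digits = 4)

# one stack of letters in a box of (w x h) px at (x, y); heights px must
# sum to <= h; letters drawn bottom-up in increasing height order
#' @noRd
.letterStack <- function(x, y, w, h, heights) {
  ord <- order(heights)
  top <- y + h
  parts <- character(0)
  for (j in ord) {
    hh <- heights[j]
    if (hh <= 1e-6) next
    top <- top - hh
    # glyph box: text scaled into w x hh; monospace glyph advance ~0.6em,
    # cap height ~0.7em at font-size 10
    sx <- w / 6
    sy <- hh / 7
    parts <- c(parts, sprintf(
      paste0('<text x="0" y="0" font-family="monospace" font-size="10" ',
             'fill="%s" transform="translate(%s,%s) scale(%s,%s)">%s</text>'),
      .LOGO_COLORS[j], .fmt(x), .fmt(top + hh), .fmt(sx), .fmt(sy),
      .DNA_BASES[j]))
  }
  parts
}

#' Render a TFFM logo as SVG text
#'
#' \code{logoSVG} builds the SVG document as a string; [renderLogos()]
#' writes it to a file. Two styles:
#' \describe{
#'   \item{summary}{one letter stack per position, total column height
#'     proportional to the position's information content and letter
#'     heights proportional to \eqn{P_i(n) \cdot IC_i}.}
#'   \item{dense}{a 4-row grid, one row per previous nucleotide m; the
#'     cell (m, i) draws the conditional distribution \eqn{P_i(\cdot|m)}
#'     probability-scaled, with cell opacity proportional to the
#'     previous-position probability \eqn{w_i(m)} (floored at 0.1 so all
#'     rows stay legible).}
#' }
#' Output is deterministic: the same LogoData renders byte-identically.
#'
#' @param data a [logoData()] result.
#' @param style \code{"summary"} or \code{"dense"}.
#' @return \code{logoSVG}: a single string holding a well-formed SVG
#'   document.
#' @export
logoSVG <- function(data, style = c("summary", "dense")) {
  style <- match.arg(style)
  stopifnot(inherits(data, "LogoData"))
  L <- data$length
  colW <- 30
  if (style == "summary") {
    H <- 100  # 2 bits
    width <- colW * L + 40
    height <- H + 30
    body <- character(0)
    for (i in seq_len(L)) {
      p <- data$marginal[i, ]
      ic <- .colIC(p)
      heights <- p * ic / 2 * H
      body <- c(body, .letterStack(40 + (i - 1) * colW, 10, colW, H, heights))
      body <- c(body, sprintf(
        '<text x="%s" y="%s" font-family="monospace" font-size="8">%d</text>',
        .fmt(40 + (i - 1) * colW + colW / 2 - 2), .fmt(H + 22), i))
    }
    axis <- c(
      sprintf('<line x1="38" y1="10" x2="38" y2="%s" stroke="black"/>',
              .fmt(10 + H)),
      '<text x="2" y="16" font-family="monospace" font-size="8">2 bits</text>',
      sprintf('<text x="2" y="%s" font-family="monospace" font-size="8">0</text>',
              .fmt(10 + H))
    )
  } else {
    cellH <- 30
    width <- colW * L + 40
    height <- 4 * cellH + 30
    body <- character(0)
    for (m in 1:4) {
      y0 <- 10 + (m - 1) * cellH
      body <- c(body, sprintf(
        paste0('<text x="2" y="%s" font-family="monospace" font-size="10" ',
               'fill="%s">%s</text>'),
        .fmt(y0 + cellH / 2 + 3), .LOGO_COLORS[m], .DNA_BASES[m]))
      for (i in seq_len(L)) {
        op <- max(0.1, data$opacity[i, m])
        heights <- data$conditional[i, m, ] * cellH
        cell <- .letterStack(40 + (i - 1) * colW, y0, colW, cellH, heights)
        body <- c(body,
                  sprintf('<g opacity="%s">', .fmt(op)), cell, "</g>")
      }
    }
    for (i in seq_len(L)) {
      body <- c(body, sprintf(
        '<text x="%s" y="%s" font-family="monospace" font-size="8">%d</text>',
        .fmt(40 + (i - 1) * colW + colW / 2 - 2), .fmt(4 * cellH + 22), i))
    }
    axis <- character(0)
  }
  paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height),
    axis, body, "</svg>"), collapse = "\n")
}

#' @rdname logoSVG
#' @param out output SVG file path.
#' @return \code{renderLogos}: the path, invisibly.
#' @export
renderLogos <- function(data, out, style = c("summary", "dense")) {
  svg <- logoSVG(data, style)
  con <- file(out, "wb")
  on.exit(close(con))
  writeBin(charToRaw(svg), con)
  invisible(out)
}

#' Dump logo tables as tab-separated text
#'
#' @param data a [logoData()] result.
#' @param path output path.
#' @export
writeLogoData <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# marginal probabilities (position x A C G T)", con)
  utils::write.table(data$marginal, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  writeLines("# conditional probabilities (position, prev -> A C G T)", con)
  for (i in seq_len(data$length)) {
    for (m in 1:4) {
      writeLines(paste(c(i, .DNA_BASES[m], data$conditional[i, m, ]),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
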