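# Standard formats: FASTA (via Biostrings), ENCODE narrowPeak, MEME
# minimal motif files, JASPAR-style PFMs, and lossless model JSON.
# Coordinates are 0-based half-open (BED convention) throughout.

#' Read DNA sequences from a FASTA file
#'
#' Wraps \code{Biostrings::readDNAStringSet} with the validation this
#' package needs: sequences are uppercased, must be over \{A,C,G,T,N\},
#' and empty files, malformed headers and zero-length records are parse
#' errors naming the offending line.
#'
#' @param path FASTA file.
#' @return a named \code{DNAStringSet}, records in file order.
#' @export
readFastaSeqs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty)) stop("FASTA parse error: file is empty")
  first <- nonEmpty[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("FASTA parse error at line ", first, ": expected a '>' header")
  }
  headers <- which(startsWith(trimws(lines), ">"))
  for (i in seq_along(headers)) {
    h <- headers[i]
    stopLine <- if (i < length(headers)) headers[i + 1] - 1 else length(lines)
    body <- gsub("\\s", "", paste(
      lines[seq.int(h + 1, length.out = max(0, stopLine - h))],
      collapse = ""))
    if (!nchar(body)) {
      stop("FASTA parse error at line ", h, ": zero-length sequence record")
    }
    if (grepl("[^ACGTNacgtn]", body)) {
      stop("invalid residues in record at line ", h, " (",
           trimws(lines[h]), "); alphabet is A, C, G, T, N")
    }
  }
  x <- tryCatch(Biostrings::readDNAStringSet(path), error = function(e) {
    stop("FASTA parse error: ", conditionMessage(e))
  })
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or \code{DNAStringSet}.
#' @param path output path.
#' @export
writeFastaSeqs <- function(seqs, path) {
  seqs <- .asSeqChar(seqs)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read peak-summit windows from an ENCODE narrowPeak file
#'
#' Parses the 10-column narrowPeak dialect of BED6+4 (tab-separated;
#' column 7 = signal value, column 10 = summit offset from the interval
#' start, -1 meaning absent) and returns, for each peak with a known
#' summit, the scan window of width \code{2 * flank + 1} centered on the
#' summit, paired with the peak's signal value. Records with summit -1 are
#' skipped with a warning giving the count. Windows that would extend
#' below coordinate 0 are clipped and flagged; clipped windows are
#' conventionally excluded from training.
#'
#' @param path narrowPeak file.
#' @param flank nucleotides kept on each side of the summit (default 50,
#'   giving 101-nt windows).
#' @param minPeaks if > 0, error when fewer usable peaks are found.
#' @return data.frame with columns chrom, start, end (0-based half-open
#'   window), name, signalValue, summit (genomic 0-based summit
#'   coordinate), clipped (logical).
#' @export
readNarrowpeakWindows <- function(path, flank = 50L, minPeaks = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) != 10L) {
    stop("narrowPeak format error: expected 10 columns, found ", ncol(df))
  }
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "signalValue", "pValue", "qValue", "peak")
  if (any(df$start >= df$end)) stop("narrowPeak format error: start >= end")
  absent <- df$peak < 0L
  if (any(absent)) {
    warning(sum(absent), " record(s) without a summit (peak = -1) skipped")
    df <- df[!absent, , drop = FALSE]
  }
  if (any(df$start + df$peak >= df$end)) {
    stop("narrowPeak format error: summit offset outside the interval")
  }
  summit <- df$start + df$peak
  start <- summit - flank
  end <- summit + flank + 1L
  clipped <- start < 0L
  start[clipped] <- 0L
  out <- data.frame(chrom = df$chrom, start = start, end = end,
                    name = if (all(df$name == ".")) {
                      paste0("peak", seq_len(nrow(df)))
                    } else df$name,
                    signalValue = df$signalValue, summit = summit,
                    clipped = clipped, stringsAsFactors = FALSE)
  if (minPeaks > 0L && nrow(out) < minPeaks) {
    stop("dataset too small: ", nrow(out), " usable peaks, need ", minPeaks)
  }
  out
}

#' Read motifs from a MEME minimal motif file
#'
#' Parses the MEME minimal text format (a version line, optional alphabet
#' and background lines, and one or more \code{MOTIF} blocks each with a
#' \code{letter-probability matrix} section) and returns one position
#' frequency matrix per motif, rows renormalized to sum to 1.
#'
#' @param path MEME minimal format file.
#' @return named list of L x 4 PFMs in file order.
#' @export
readMemeMinimal <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  motifStarts <- grep("^MOTIF\\b", lines)
  if (!length(motifStarts)) stop("MEME parse error: no MOTIF block found")
  out <- list()
  for (i in seq_along(motifStarts)) {
    s <- motifStarts[i]
    e <- if (i < length(motifStarts)) motifStarts[i + 1] - 1 else length(lines)
    block <- lines[s:e]
    name <- trimws(sub("^MOTIF", "", block[1]))
    if (!nzchar(name)) name <- paste0("motif", i)
    lp <- grep("^letter-probability matrix", block)
    if (!length(lp)) {
      stop("MEME parse error: motif '", name,
           "' has no letter-probability matrix")
    }
    header <- block[lp[1]]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", header))
    rows <- list()
    j <- lp[1] + 1
    while (length(rows) < ifelse(is.na(w), Inf, w) && j <= length(block)) {
      ln <- trimws(block[j])
      if (!nzchar(ln)) { if (is.na(w) && length(rows)) break else { j <- j + 1; next } }
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (anyNA(vals) || length(vals) != 4L) {
        if (is.na(w)) break
        stop("MEME parse error: bad matrix row for motif '", name, "'")
      }
      rows[[length(rows) + 1]] <- vals
      j <- j + 1
    }
    if (!length(rows) || (!is.na(w) && length(rows) != w)) {
      stop("MEME parse error: motif '", name, "' matrix is incomplete")
    }
    pfm <- do.call(rbind, rows)
    pfm <- pfm / rowSums(pfm)
    colnames(pfm) <- .DNA_BASES
    out[[name]] <- pfm
  }
  out
}

#' Read / write JASPAR-style PFM text
#'
#' The JASPAR flat format: a \code{>} header then four lines
#' \code{A [ 1 2 3 ]} ... with per-position counts or probabilities.
#'
#' @param path file path.
#' @return \code{readJasparPfm}: an L x 4 probability matrix (rows
#'   normalized).
#' @export
readJasparPfm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- grep("^[ACGT]\\s*\\[", lines, value = TRUE)
  if (length(rows) != 4L) stop("JASPAR parse error: need 4 A/C/G/T rows")
  base <- substr(trimws(rows), 1, 1)
  vals <- lapply(rows, function(r) {
    body <- sub(".*\\[", "", sub("\\].*", "", r))
    as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  })
  if (length(unique(lengths(vals))) != 1L) {
    stop("JASPAR parse error: rows of unequal length")
  }
  m <- do.call(cbind, vals[match(.DNA_BASES, base)])
  colnames(m) <- .DNA_BASES
  m / rowSums(m)
}

#' @rdname readJasparPfm
#' @param pfm L x 4 matrix of counts or probabilities.
#' @param name motif name written in the header.
#' @export
writeJasparPfm <- function(pfm, path, name = "motif") {
  stopifnot(is.matrix(pfm), ncol(pfm) == 4L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  for (j in 1:4) {
    writeLines(sprintf("%s [ %s ]", .DNA_BASES[j],
                       paste(formatC(pfm[, j], format = "g", digits = 10),
                             collapse = " ")), con)
  }
  invisible(path)
}

#' Serialize / deserialize a TFFM as JSON
#'
#' Models are written with explicit state labels and full-precision
#' probability tables, so files are self-describing for all three
#' topologies (including flexible-length edits) and a write/read roundtrip
#' reproduces every probability to within 1e-12. Reading re-validates all
#' stochastic constraints and errors on tampered files.
#'
#' @param tffm a [TFFM-class].
#' @param path JSON file path.
#' @export
writeTFFM <- function(tffm, path) {
  stopifnot(is(tffm, "TFFM"))
  validObject(tffm)
  hmm <- tffm@hmm
  emis <- lapply(seq_along(hmm@states), function(s) {
    m <- hmm@emissions[s, , ]
    dimnames(m) <- NULL
    m
  })
  names(emis) <- hmm@states
  obj <- list(
    format = "motifHMM-tffm",
    formatVersion = 1L,
    kind = tffm@kind,
    states = hmm@states,
    tied = hmm@tied,
    initial = unname(hmm@initial),
    transitions = unname(hmm@transitions),
    emissions = emis,
    matchMap = tffm@matchMap,
    bgStates = tffm@bgStates,
    finalStates = tffm@finalStates,
    lengthRange = tffm@lengthRange,
    edits = lapply(tffm@edits, function(e) e[!vapply(e, is.null, TRUE)])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTFFM
#' @return \code{readTFFM}: the deserialized [TFFM-class].
#' @export
readTFFM <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "motifHMM-tffm") {
    stop("model load error: not a motifHMM TFFM file")
  }
  n <- length(obj$states)
  asMatrix <- function(x, nr, nc, what) {
    if (!is.matrix(x)) {
      # list of rows (JSON arrays): bind row-wise
      if (!is.list(x) || length(x) != nr ||
          any(lengths(x) != nc)) {
        stop("model load error: ", what, " dimensions do not match")
      }
      x <- do.call(rbind, lapply(x, as.numeric))
    }
    if (!all(dim(x) == c(nr, nc))) {
      stop("model load error: ", what, " dimensions do not match")
    }
    x
  }
  A <- asMatrix(obj$transitions, n, n, "transition table")
  em <- array(0, dim = c(n, 4L, 4L))
  for (s in seq_len(n)) {
    m <- obj$emissions[[obj$states[s]]]
    if (is.null(m)) m <- obj$emissions[[s]]
    em[s, , ] <- asMatrix(m, 4L, 4L,
                          paste("emission table of state", obj$states[s]))
  }
  hmm <- tryCatch(
    condHMM(as.numeric(obj$initial), A, em, states = obj$states,
            tied = as.logical(obj$tied)),
    error = function(e) stop("model load error: ", conditionMessage(e))
  )
  mm <- lapply(obj$matchMap, as.integer)
  tffm <- tryCatch({
    t <- new("TFFM", hmm = hmm, kind = obj$kind, matchMap = mm,
             bgStates = as.integer(obj$bgStates),
             finalStates = as.integer(obj$finalStates),
             lengthRange = as.integer(obj$lengthRange),
             edits = if (length(obj$edits)) {
               if (is.data.frame(obj$edits)) {
                 lapply(seq_len(nrow(obj$edits)),
                        function(i) as.list(obj$edits[i, ]))
               } else as.list(obj$edits)
             } else list())
    validObject(t@hmm)
    validObject(t)
    t
  }, error = function(e) stop("model load error: ", conditionMessage(e)))
  tffm
}
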