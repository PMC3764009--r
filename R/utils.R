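# Internal helpers: DNA alphabet coding, reverse complement, seeded RNG.

.DNA_BASES <- c("A", "C", "G", "T")
.N_CODE <- 5L

#' @noRd
.encodeSeq <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  code <- match(chars, c(.DNA_BASES, "N"))
  if (anyNA(code)) {
    bad <- unique(chars[is.na(code)])
    stop("invalid residue(s) in sequence: ", paste(bad, collapse = ", "))
  }
  code
}

#' @noRd
.decodeSeq <- function(code) {
  paste(c(.DNA_BASES, "N")[code], collapse = "")
}

# integer-coded reverse complement (A<->T, C<->G, N fixed)
#' @noRd
.revCompCode <- function(code) {
  out <- rev(code)
  ifelse(out == .N_CODE, .N_CODE, 5L - out)
}

#' @noRd
.revCompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Run expr with a private RNG state; the caller's .Random.seed is untouched.
#' @noRd
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# coerce sequence input (character vector / DNAStringSet) to a named
# character vector, uppercased
#' @noRd
.asSeqChar <- function(seqs) {
  if (is(seqs, "XStringSet")) {
    out <- as.character(seqs)
  } else if (is.character(seqs)) {
    out <- seqs
  } else {
    stop("sequences must be a character vector or a DNAStringSet")
  }
  out <- toupper(out)
  if (!length(out)) return(out)
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    names(out) <- paste0("seq", seq_along(out))
  }
  out
}

#' @noRd
.checkProbVector <- function(p, what, tol = 1e-9) {
  if (any(p < -tol)) return(sprintf("%s has negative entries", what))
  if (abs(sum(p) - 1) > tol) {
    return(sprintf("%s sums to %.12g, not 1", what, sum(p)))
  }
  NULL
}

#' @noRd
.normalizeRow <- function(p) {
  s <- sum(p)
  if (s <= 0) stop("cannot normalize a non-positive row")
  p / s
}
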