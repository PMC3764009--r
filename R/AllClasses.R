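#' Discrete HMM over DNA with first-order conditional emissions
#'
#' A hidden Markov model over the alphabet \{A, C, G, T\} in which every
#' state emits a nucleotide with a probability that may depend on the
#' nucleotide observed at the previous sequence position. Emissions are
#' stored as one 4x4 row-stochastic table per state, indexed
#' \code{[previous, current]}. A state whose four rows are identical is an
#' order-0 (unconditional) state; the \code{tied} flag marks such states so
#' that training keeps their rows identical.
#'
#' The emission of the very first sequence position is conditioned on a
#' fixed sentinel nucleotide (\code{"A"} by default throughout the package),
#' so likelihoods are defined for every position.
#'
#' @slot states character vector of state labels.
#' @slot initial numeric vector of initial state probabilities (sums to 1).
#' @slot transitions row-stochastic state-by-state transition matrix.
#' @slot emissions numeric array \code{n_states x 4 x 4};
#'   \code{emissions[s, m, n]} is the probability that state \code{s} emits
#'   nucleotide \code{n} when the previous observed nucleotide was \code{m}.
#' @slot tied logical per state; \code{TRUE} for order-0 states whose four
#'   conditional rows are constrained to stay identical under training.
#'
#' @seealso [condHMM()], [logLikelihood()], [posteriorDecode()],
#'   [baumWelch()], [sampleHMM()]
#' @export
setClass("CondHMM",
  representation(
    states = "character",
    initial = "numeric",
    transitions = "matrix",
    emissions = "array",
    tied = "logical"
  )
)

setValidity("CondHMM", function(object) {
  n <- length(object@states)
  msgs <- character()
  if (n < 1L) msgs <- c(msgs, "model needs at least one state")
  if (anyDuplicated(object@states)) msgs <- c(msgs, "duplicate state labels")
  if (length(object@initial) != n) {
    msgs <- c(msgs, "initial vector length != number of states")
  }
  if (!all(dim(object@transitions) == c(n, n))) {
    msgs <- c(msgs, "transition matrix must be n_states x n_states")
  }
  if (!all(dim(object@emissions) == c(n, 4L, 4L))) {
    msgs <- c(msgs, "emissions must be an n_states x 4 x 4 array")
  }
  if (length(object@tied) != n) {
    msgs <- c(msgs, "tied flag vector length != number of states")
  }
  if (length(msgs)) return(msgs)
  m <- .checkProbVector(object@initial, "initial distribution")
  if (!is.null(m)) msgs <- c(msgs, m)
  for (s in seq_len(n)) {
    m <- .checkProbVector(object@transitions[s, ],
                          sprintf("transition row '%s'", object@states[s]))
    if (!is.null(m)) msgs <- c(msgs, m)
    for (prev in 1:4) {
      m <- .checkProbVector(object@emissions[s, prev, ],
                            sprintf("emission row '%s'|%s", object@states[s],
                                    .DNA_BASES[prev]))
      if (!is.null(m)) msgs <- c(msgs, m)
    }
    if (object@tied[s]) {
      e <- object@emissions[s, , ]
      if (max(abs(sweep(e, 2, e[1, ]))) > 1e-9) {
        msgs <- c(msgs, sprintf("state '%s' is tied but its rows differ",
                                object@states[s]))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CondHMM
#'
#' @param initial initial state probabilities.
#' @param transitions row-stochastic transition matrix.
#' @param emissions either an \code{n x 4 x 4} array of conditional emission
#'   tables, or an \code{n x 4} matrix of unconditional rows (replicated
#'   across the four previous-nucleotide rows, with \code{tied = TRUE}).
#' @param states state labels; defaults to \code{"s1"..."sn"}.
#' @param tied logical per state; defaults to \code{TRUE} when
#'   \code{emissions} was given unconditionally, else \code{FALSE}.
#' @return a validated [CondHMM-class] object.
#' @examples
#' hmm <- condHMM(
#'   initial = c(1, 0),
#'   transitions = rbind(c(0.9, 0.1), c(0.2, 0.8)),
#'   emissions = rbind(c(0.25, 0.25, 0.25, 0.25), c(0.7, 0.1, 0.1, 0.1))
#' )
#' @export
condHMM <- function(initial, transitions, emissions, states = NULL,
                    tied = NULL) {
  n <- length(initial)
  if (is.matrix(emissions)) {
    stopifnot(nrow(emissions) == n, ncol(emissions) == 4L)
    arr <- array(0, dim = c(n, 4L, 4L))
    for (s in seq_len(n)) for (prev in 1:4) arr[s, prev, ] <- emissions[s, ]
    emissions <- arr
    if (is.null(tied)) tied <- rep(TRUE, n)
  }
  if (is.null(tied)) tied <- rep(FALSE, n)
  if (is.null(states)) states <- paste0("s", seq_len(n))
  dimnames(emissions) <- list(states, .DNA_BASES, .DNA_BASES)
  dimnames(transitions) <- list(states, states)
  names(initial) <- states
  new("CondHMM", states = states, initial = initial,
      transitions = transitions, emissions = emissions, tied = tied)
}

#' Transcription factor flexible model (TFFM)
#'
#' A [CondHMM-class] together with the motif bookkeeping that makes it a
#' binding-site model: which states form the background, which represent
#' each motif position, which states end a site, and the range of site
#' widths the topology can emit.
#'
#' Three topologies are supported (see [buildTFFM()]): \code{"order0"}
#' (one background state plus one unconditional state per motif position —
#' essentially a PFM expressed as an HMM), \code{"order1"} (the same state
#' layout with first-order conditional emissions, capturing dinucleotide
#' dependencies), and \code{"detailed"} (four nucleotide-specific indicator
#' states per position; dependencies live in the transitions, and a site
#' can start with a probability depending on the last background
#' nucleotide).
#'
#' @slot hmm the underlying [CondHMM-class].
#' @slot kind one of \code{"order0"}, \code{"order1"}, \code{"detailed"}.
#' @slot matchMap named list mapping each motif position label to the
#'   integer indices of the state(s) representing it, in path order.
#' @slot bgStates integer indices of the background state(s).
#' @slot finalStates integer indices of the state(s) that end a site.
#' @slot lengthRange integer c(Lmin, Lmax) of realizable site widths.
#' @slot edits list of [flexEdit()] records applied to the model.
#'
#' @seealso [buildTFFM()], [applyFlexEdit()], [hitTrack()], [bestHit()]
#' @export
setClass("TFFM",
  representation(
    hmm = "CondHMM",
    kind = "character",
    matchMap = "list",
    bgStates = "integer",
    finalStates = "integer",
    lengthRange = "integer",
    edits = "list"
  )
)

setValidity("TFFM", function(object) {
  msgs <- character()
  if (!object@kind %in% c("order0", "order1", "detailed")) {
    msgs <- c(msgs, "kind must be order0, order1 or detailed")
  }
  n <- length(object@hmm@states)
  match_states <- sort(unique(unlist(object@matchMap)))
  if (length(intersect(object@bgStates, match_states))) {
    msgs <- c(msgs, "background and match states must be disjoint")
  }
  if (!setequal(c(object@bgStates, match_states), seq_len(n))) {
    msgs <- c(msgs, "background and match states must partition the states")
  }
  if (!length(object@finalStates)) {
    msgs <- c(msgs, "finalStates must be non-empty")
  }
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1] > object@lengthRange[2] ||
      object@lengthRange[1] < 1L) {
    msgs <- c(msgs, "lengthRange must be c(Lmin, Lmax) with 1 <= Lmin <= Lmax")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CondHMM-class number of states
#' @param object a CondHMM or TFFM
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @export
setMethod("nStates", "CondHMM", function(object) length(object@states))
#' @export
setMethod("nStates", "TFFM", function(object) nStates(object@hmm))

#' Accessors for CondHMM and TFFM objects
#'
#' \code{stateLabels}, \code{initialProbs}, \code{transitionMatrix} and
#' \code{emissionArray} expose the probability tables of a model;
#' \code{modelKind}, \code{lengthRange}, \code{finalStates},
#' \code{backgroundStates} and \code{matchMap} expose the TFFM motif
#' bookkeeping. Accessors are the supported way to inspect models; slots
#' are internal.
#'
#' @param object a [CondHMM-class] or [TFFM-class]
#' @name tffm-accessors
NULL

#' @rdname tffm-accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname tffm-accessors
#' @export
setMethod("stateLabels", "CondHMM", function(object) object@states)
#' @rdname tffm-accessors
#' @export
setMethod("stateLabels", "TFFM", function(object) object@hmm@states)

#' @rdname tffm-accessors
#' @export
setGeneric("initialProbs", function(object) standardGeneric("initialProbs"))
#' @rdname tffm-accessors
#' @export
setMethod("initialProbs", "CondHMM", function(object) object@initial)
#' @rdname tffm-accessors
#' @export
setMethod("initialProbs", "TFFM", function(object) object@hmm@initial)

#' @rdname tffm-accessors
#' @export
setGeneric("transitionMatrix",
           function(object) standardGeneric("transitionMatrix"))
#' @rdname tffm-accessors
#' @export
setMethod("transitionMatrix", "CondHMM", function(object) object@transitions)
#' @rdname tffm-accessors
#' @export
setMethod("transitionMatrix", "TFFM",
          function(object) object@hmm@transitions)

#' @rdname tffm-accessors
#' @export
setGeneric("emissionArray", function(object) standardGeneric("emissionArray"))
#' @rdname tffm-accessors
#' @export
setMethod("emissionArray", "CondHMM", function(object) object@emissions)
#' @rdname tffm-accessors
#' @export
setMethod("emissionArray", "TFFM", function(object) object@hmm@emissions)

#' @rdname tffm-accessors
#' @export
setGeneric("modelKind", function(object) standardGeneric("modelKind"))
#' @rdname tffm-accessors
#' @export
setMethod("modelKind", "TFFM", function(object) object@kind)

#' @rdname tffm-accessors
#' @export
setGeneric("lengthRange", function(object) standardGeneric("lengthRange"))
#' @rdname tffm-accessors
#' @export
setMethod("lengthRange", "TFFM", function(object) object@lengthRange)

#' @rdname tffm-accessors
#' @export
setGeneric("finalStates", function(object) standardGeneric("finalStates"))
#' @rdname tffm-accessors
#' @export
setMethod("finalStates", "TFFM", function(object) object@finalStates)

#' @rdname tffm-accessors
#' @export
setGeneric("backgroundStates",
           function(object) standardGeneric("backgroundStates"))
#' @rdname tffm-accessors
#' @export
setMethod("backgroundStates", "TFFM", function(object) object@bgStates)

#' @rdname tffm-accessors
#' @export
setGeneric("matchMap", function(object) standardGeneric("matchMap"))
#' @rdname tffm-accessors
#' @export
setMethod("matchMap", "TFFM", function(object) object@matchMap)

setMethod("show", "CondHMM", function(object) {
  cat(sprintf("CondHMM with %d states: %s\n", nStates(object),
              paste(utils::head(object@states, 8), collapse = ", ")))
  if (nStates(object) > 8) cat("  ...\n")
  cat(sprintf("  %d order-0 (tied) state(s)\n", sum(object@tied)))
})

setMethod("show", "TFFM", function(object) {
  lr <- object@lengthRange
  cat(sprintf("TFFM (%s): motif width %s, %d states (%d background)\n",
              object@kind,
              if (lr[1] == lr[2]) lr[1] else paste(lr[1], lr[2], sep = "-"),
              nStates(object), length(object@bgStates)))
  if (length(object@edits)) {
    kinds <- vapply(object@edits, function(e) e$kind, character(1))
    cat("  flexible-length edits:", paste(kinds, collapse = ", "), "\n")
  }
})
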