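#' @import methods
#' @importFrom stats kmeans cov pchisq p.adjust quantile rnorm runif ppois
#'   setNames aggregate
#' @importFrom utils write.table read.table head
NULL

.prob_tol <- 1e-6

#' Structural-alphabet hidden Markov model
#'
#' An `AlphabetModel` holds the state space of a structural alphabet: one
#' state ("structural letter") per four-residue backbone prototype, a
#' Gaussian emission distribution over the four inter-C-alpha descriptors
#' for each state, a state-to-state transition matrix encoding the
#' preferred successions of letters along the chain, and an initial state
#' distribution.
#'
#' @slot letters character vector of unique single-character state names,
#'   in canonical order (the full alphabet uses the 27 names `A`-`Z`, `a`).
#' @slot initial numeric vector of initial state probabilities (sums to 1).
#' @slot transitions row-stochastic matrix of transition probabilities.
#' @slot emissionMean numeric matrix, one row per state, one column per
#'   descriptor (angstroms).
#' @slot emissionCov numeric array `d x d x K` of per-state emission
#'   covariances (square angstroms); each slice symmetric positive definite.
#'
#' @seealso [readAlphabetModel()], [trainAlphabetModel()], [viterbiEncode()]
#' @export
setClass("AlphabetModel",
  representation(
    letters = "character",
    initial = "numeric",
    transitions = "matrix",
    emissionMean = "matrix",
    emissionCov = "array"
  )
)

setValidity("AlphabetModel", function(object) {
  K <- length(object@letters)
  msgs <- character()
  if (anyDuplicated(object@letters))
    msgs <- c(msgs, "state letters must be unique")
  if (length(object@initial) != K)
    msgs <- c(msgs, "initial distribution length differs from state count")
  if (abs(sum(object@initial) - 1) > .prob_tol || any(object@initial < 0))
    msgs <- c(msgs, "initial distribution must be non-negative and sum to 1")
  if (!all(dim(object@transitions) == c(K, K))) {
    msgs <- c(msgs, "transition matrix must be K x K")
  } else {
    rs <- rowSums(object@transitions)
    bad <- which(abs(rs - 1) > .prob_tol | apply(object@transitions < 0, 1, any))
    if (length(bad))
      msgs <- c(msgs, paste0("transition row for state '",
        object@letters[bad[1]], "' is not a probability distribution (sum = ",
        format(rs[bad[1]]), ")"))
  }
  d <- ncol(object@emissionMean)
  if (nrow(object@emissionMean) != K)
    msgs <- c(msgs, "emission mean matrix must have one row per state")
  if (!all(dim(object@emissionCov) == c(d, d, K))) {
    msgs <- c(msgs, "emission covariance array must be d x d x K")
  } else {
    for (k in seq_len(K)) {
      S <- object@emissionCov[, , k]
      if (max(abs(S - t(S))) > 1e-8 ||
          inherits(try(chol(S), silent = TRUE), "try-error")) {
        msgs <- c(msgs, paste0("emission covariance for state '",
          object@letters[k], "' is not symmetric positive definite"))
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' First-order Markov background over structural letters
#'
#' Maximum-likelihood background model for the loop letter corpus, used by
#' the exceptionality statistics: transition probabilities between letters,
#' an initial distribution over sequence-start letters, and bookkeeping
#' about the corpus the model was fitted on.
#'
#' @slot alphabet character vector of letters.
#' @slot order integer Markov order (currently 1).
#' @slot transitions row-stochastic transition matrix.
#' @slot initial initial letter distribution.
#' @slot nSeq number of sequences in the source corpus.
#' @slot totalLetters total letter count of the source corpus.
#' @slot lengths integer vector of sequence lengths of the source corpus.
#'
#' @seealso [fitBackground()], [wordPvalue()]
#' @export
setClass("BackgroundModel",
  representation(
    alphabet = "character",
    order = "integer",
    transitions = "matrix",
    initial = "numeric",
    nSeq = "integer",
    totalLetters = "integer",
    lengths = "integer"
  )
)

setValidity("BackgroundModel", function(object) {
  K <- length(object@alphabet)
  msgs <- character()
  if (object@order != 1L)
    msgs <- c(msgs, "only first-order backgrounds are supported")
  if (!all(dim(object@transitions) == c(K, K)) ||
      max(abs(rowSums(object@transitions) - 1)) > .prob_tol ||
      any(object@transitions < 0))
    msgs <- c(msgs, "transitions must be a K x K row-stochastic matrix")
  if (length(object@initial) != K || abs(sum(object@initial) - 1) > .prob_tol ||
      any(object@initial < 0))
    msgs <- c(msgs, "initial must be a probability vector over the alphabet")
  if (length(msgs)) msgs else TRUE
})

#' Cluster of seven-residue fragments sharing one structural word
#'
#' All fragments of the loop bank whose letter substring equals one
#' structural word. Coordinates, amino-acid sequences and B-factors are
#' carried so that per-word statistics (RMSD, Z-score profiles, B-factor
#' flags) can be computed from the cluster alone.
#'
#' @slot word the structural word (k letters).
#' @slot fragments data.frame with at least `loop_id` and `position`
#'   (1-based position of the word within the loop letters).
#' @slot coords list of `(k+3) x 3` C-alpha coordinate matrices, one per
#'   member (may be empty when clusters come from letter strings only).
#' @slot sequences character vector of `(k+3)`-residue amino-acid sequences
#'   (one-letter codes), one per member (may be empty).
#' @slot bfactors numeric vector of per-fragment mean C-alpha B-factors.
#'
#' @seealso [clusterWords()], [intraWordRMSD()], [zscoreProfile()]
#' @export
setClass("WordCluster",
  representation(
    word = "character",
    fragments = "data.frame",
    coords = "list",
    sequences = "character",
    bfactors = "numeric"
  )
)

setValidity("WordCluster", function(object) {
  n <- nrow(object@fragments)
  msgs <- character()
  if (length(object@word) != 1L || !nzchar(object@word))
    msgs <- c(msgs, "word must be a single non-empty string")
  if (length(object@coords) && length(object@coords) != n)
    msgs <- c(msgs, "coords must be empty or have one matrix per fragment")
  if (length(object@sequences) && length(object@sequences) != n)
    msgs <- c(msgs, "sequences must be empty or have one entry per fragment")
  if (length(object@bfactors) && length(object@bfactors) != n)
    msgs <- c(msgs, "bfactors must be empty or have one value per fragment")
  if (length(msgs)) msgs else TRUE
})

#' Positional amino-acid Z-score profile of a structural word
#'
#' Z-scores comparing, for each of the `k+3` fragment positions and each of
#' the 20 amino acids, the observed count within the word's cluster with
#' the count expected from the whole fragment bank, under a Poisson
#' standardization. Cells whose expected count is 5 or less are masked
#' invalid and never contribute to the summaries.
#'
#' @slot word the structural word.
#' @slot z numeric matrix, positions x amino acids.
#' @slot valid logical matrix of the same shape (expected count > 5).
#' @slot expected numeric matrix of expected counts.
#' @slot observed numeric matrix of observed counts.
#' @slot zMax maximum Z-score over valid cells (`NA` if none valid).
#' @slot nbPosSig number of positions with at least one valid Z-score at or
#'   above the significance cutoff.
#' @slot cutoff significance cutoff on Z (default 4).
#'
#' @seealso [zscoreProfile()], [zscoreDistance()]
#' @export
setClass("ZProfile",
  representation(
    word = "character",
    z = "matrix",
    valid = "matrix",
    expected = "matrix",
    observed = "matrix",
    zMax = "numeric",
    nbPosSig = "integer",
    cutoff = "numeric"
  )
)

setValidity("ZProfile", function(object) {
  msgs <- character()
  if (!identical(dim(object@z), dim(object@valid)))
    msgs <- c(msgs, "z and valid must have identical dimensions")
  if (length(msgs)) msgs else TRUE
})

## ---- accessors -------------------------------------------------------

#' @describeIn AlphabetModel-class number of states
#' @param object,x an object of the documented class
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' Accessors for model and cluster objects
#'
#' `modelLetters()` returns the ordered state names of an [AlphabetModel]
#' or the alphabet of a [BackgroundModel]; `transitionMatrix()` and
#' `initialProbs()` return the transition matrix and initial distribution;
#' `emissionMeans()`/`emissionCovs()` the Gaussian emission parameters;
#' `wordOf()` and `clusterSize()` the word and member count of a
#' [WordCluster]; `zMatrix()` and `validMask()` the Z-score matrix and
#' validity mask of a [ZProfile].
#'
#' @param object an [AlphabetModel], [BackgroundModel], [WordCluster] or
#'   [ZProfile].
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelLetters", function(object) standardGeneric("modelLetters"))
#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("initialProbs", function(object) standardGeneric("initialProbs"))
#' @rdname accessors
#' @export
setGeneric("emissionMeans", function(object) standardGeneric("emissionMeans"))
#' @rdname accessors
#' @export
setGeneric("emissionCovs", function(object) standardGeneric("emissionCovs"))
#' @rdname accessors
#' @export
setGeneric("wordOf", function(object) standardGeneric("wordOf"))
#' @rdname accessors
#' @export
setGeneric("clusterSize", function(object) standardGeneric("clusterSize"))
#' @rdname accessors
#' @export
setGeneric("zMatrix", function(object) standardGeneric("zMatrix"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setMethod("modelLetters", "AlphabetModel", function(object) object@letters)
#' @rdname accessors
#' @export
setMethod("modelLetters", "BackgroundModel", function(object) object@alphabet)
#' @export
setMethod("nStates", "AlphabetModel", function(object) length(object@letters))
#' @rdname accessors
#' @export
setMethod("transitionMatrix", "AlphabetModel", function(object) object@transitions)
#' @rdname accessors
#' @export
setMethod("transitionMatrix", "BackgroundModel", function(object) object@transitions)
#' @rdname accessors
#' @export
setMethod("initialProbs", "AlphabetModel", function(object) object@initial)
#' @rdname accessors
#' @export
setMethod("initialProbs", "BackgroundModel", function(object) object@initial)
#' @rdname accessors
#' @export
setMethod("emissionMeans", "AlphabetModel", function(object) object@emissionMean)
#' @rdname accessors
#' @export
setMethod("emissionCovs", "AlphabetModel", function(object) object@emissionCov)
#' @rdname accessors
#' @export
setMethod("wordOf", "WordCluster", function(object) object@word)
#' @rdname accessors
#' @export
setMethod("wordOf", "ZProfile", function(object) object@word)
#' @rdname accessors
#' @export
setMethod("clusterSize", "WordCluster", function(object) nrow(object@fragments))
#' @rdname accessors
#' @export
setMethod("zMatrix", "ZProfile", function(object) object@z)
#' @rdname accessors
#' @export
setMethod("validMask", "ZProfile", function(object) object@valid)

## ---- show ------------------------------------------------------------

setMethod("show", "AlphabetModel", function(object) {
  cat("AlphabetModel with", nStates(object), "structural letters:",
      paste(object@letters, collapse = ""), "\n")
  cat("  descriptors:", ncol(object@emissionMean), "per four-residue fragment\n")
})

setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel (order ", object@order, ") over {",
      paste(object@alphabet, collapse = ""), "}\n", sep = "")
  cat("  fitted on ", object@nSeq, " sequences / ",
      object@totalLetters, " letters\n", sep = "")
})

setMethod("show", "WordCluster", function(object) {
  cat("WordCluster '", object@word, "': ", clusterSize(object),
      " fragments", sep = "")
  if (length(object@coords)) cat(", with coordinates")
  if (length(object@sequences)) cat(", with sequences")
  cat("\n")
})

setMethod("show", "ZProfile", function(object) {
  cat("ZProfile '", object@word, "': ", nrow(object@z), " positions x ",
      ncol(object@z), " amino acids; ", sum(object@valid),
      " valid cells\n", sep = "")
  cat("  Z_max = ", format(object@zMax, digits = 3),
      ", significant positions = ", object@nbPosSig,
      " (cutoff ", object@cutoff, ")\n", sep = "")
})
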