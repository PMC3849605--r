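#' @import methods
#' @importFrom stats plogis rbinom rgamma runif rnorm sd setNames
#' @importFrom utils combn head
#' @useDynLib CysBond, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Alphabetical one-letter codes of the 20 standard amino acids. Profile
#' matrices are indexed by this alphabet; any other residue letter is mapped
#' to `"X"` and carries no statistical weight.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## PSI-BLAST column order in ASCII PSSM files
.BLAST_AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

.checkTrue <- function(ok, msg) if (!isTRUE(ok)) msg else NULL

#' Annotated protein chain
#'
#' A protein chain together with (optionally) its per-position profile, its
#' disulfide pattern, and the set of cysteines excluded from statistics
#' (inter-chain bonded or structurally undetermined). All residue positions
#' are 1-based.
#'
#' @slot id single chain identifier.
#' @slot sequence amino-acid string over the 20-letter alphabet plus `X`.
#' @slot profile numeric matrix, one row per residue, 20 columns named by
#'   [AA_ALPHABET20]; each row sums to 1. A 0-row matrix means "no profile
#'   attached".
#' @slot bonds integer matrix with two columns (`i`, `j`), one disulfide
#'   bond per row, `i < j`, both positions cysteines; each cysteine appears
#'   in at most one bond.
#' @slot excludedCys integer vector of cysteine positions excluded from use.
#'
#' @seealso [annotatedChain()], [cysPositions()], [usableCys()]
#' @export
setClass("AnnotatedChain",
  representation(
    id = "character",
    sequence = "character",
    profile = "matrix",
    bonds = "matrix",
    excludedCys = "integer"
  )
)

setValidity("AnnotatedChain", function(object) {
  errs <- character(0)
  add <- function(e) if (!is.null(e)) errs <<- c(errs, e)
  add(.checkTrue(length(object@id) == 1L && nzchar(object@id), "id must be a single non-empty string"))
  add(.checkTrue(length(object@sequence) == 1L && nchar(object@sequence) >= 1L,
                 "sequence must be a single string of length >= 1"))
  L <- nchar(object@sequence)
  pr <- object@profile
  if (nrow(pr) > 0L) {
    add(.checkTrue(nrow(pr) == L, "profile rows must match sequence length"))
    add(.checkTrue(ncol(pr) == 20L, "profile must have 20 columns"))
    add(.checkTrue(all(abs(rowSums(pr) - 1) < 1e-6), "profile rows must sum to 1"))
    add(.checkTrue(all(pr >= -1e-12), "profile frequencies must be non-negative"))
  }
  cys <- cysPositions(object)
  b <- object@bonds
  if (nrow(b) > 0L) {
    add(.checkTrue(ncol(b) == 2L, "bonds must have two columns"))
    add(.checkTrue(all(b[, 1] < b[, 2]), "bond rows must satisfy i < j"))
    add(.checkTrue(all(b %in% cys), "bonded positions must be cysteines"))
    add(.checkTrue(!anyDuplicated(as.vector(b)), "each cysteine may appear in at most one bond"))
    add(.checkTrue(!any(as.vector(b) %in% object@excludedCys),
                   "bonded positions must be disjoint from excludedCys"))
  }
  if (length(object@excludedCys))
    add(.checkTrue(all(object@excludedCys %in% cys), "excludedCys must be cysteine positions"))
  if (length(errs)) errs else TRUE
})

#' Disulfide connectivity pattern
#'
#' A set of unordered cysteine-position pairs in which each position appears
#' at most once (a matching).
#'
#' @slot bonds integer matrix with columns `i`, `j` (`i < j`), rows sorted
#'   lexicographically.
#' @seealso [disulfidePattern()]
#' @export
setClass("DisulfidePattern", representation(bonds = "matrix"))

setValidity("DisulfidePattern", function(object) {
  b <- object@bonds
  errs <- character(0)
  if (ncol(b) != 2L) errs <- c(errs, "bonds must have two columns")
  if (nrow(b) > 0L) {
    if (!all(b[, 1] < b[, 2])) errs <- c(errs, "bond rows must satisfy i < j")
    if (anyDuplicated(as.vector(b))) errs <- c(errs, "each position may appear in at most one bond")
  }
  if (length(errs)) errs else TRUE
})

#' Profile-weighted neighbourhood statistics around cysteines
#'
#' Accumulated first- and second-order observed counts (profile-weighted
#' numerators and denominators) for cysteine bonding states
#' (`kind = "state"`, classes `bonded`/`free`) or for cysteine pairs
#' (`kind = "pair"`, classes `connected`/`unconnected`). Raw probabilities
#' are numerator/denominator; the reference state is the class sum.
#'
#' @slot kind `"state"` or `"pair"`.
#' @slot K odd statistics window size (residues spanned, centre included).
#' @slot classes the two class labels.
#' @slot firstNum per-class numerator matrix, 20 residues x first-order
#'   positions (offsets for states, slots for pairs).
#' @slot firstDen per-class denominator vector over first-order positions.
#' @slot secondNum per-class numerator array, 20 x 20 x second-order
#'   position pairs (offset pairs for states, slot-pair orbits for pairs).
#' @slot secondDen per-class denominator vector over second-order pairs.
#' @slot secondIndex data frame describing the second-order position pairs.
#' @slot composition corpus profile-weighted amino-acid composition
#'   (length-20 probability vector), the smoothing target downstream.
#' @slot classWeight accumulated profile mass per class.
#' @slot nChains number of chains accumulated.
#' @export
setClass("ContextStatistics",
  representation(
    kind = "character", K = "integer", classes = "character",
    firstNum = "list", firstDen = "list",
    secondNum = "list", secondDen = "list",
    secondIndex = "data.frame",
    composition = "numeric", classWeight = "numeric", nChains = "integer"
  )
)

setValidity("ContextStatistics", function(object) {
  errs <- character(0)
  if (!object@kind %in% c("state", "pair")) errs <- c(errs, "kind must be 'state' or 'pair'")
  if (object@K %% 2L != 1L || object@K < 3L) errs <- c(errs, "K must be odd and >= 3")
  if (length(object@classes) != 2L) errs <- c(errs, "exactly two classes required")
  for (cl in object@classes) {
    if (any(object@firstNum[[cl]] < -1e-12)) errs <- c(errs, "negative numerator")
    if (any(object@firstDen[[cl]] < -1e-12)) errs <- c(errs, "negative denominator")
  }
  if (length(errs)) errs else TRUE
})

#' Context-based mean-force potential tables
#'
#' First- and second-order mean-force potentials, in units of RT, derived
#' from a [ContextStatistics] object via the inverse-Boltzmann relation.
#'
#' @slot kind `"state"` or `"pair"` (inherited from the statistics).
#' @slot K statistics window size.
#' @slot classes the two class labels.
#' @slot first per-class 20 x positions matrix of first-order potentials.
#' @slot second per-class 20 x 20 x pairs array of second-order potentials.
#' @slot secondIndex data frame describing second-order position pairs.
#' @slot rt energy scale constant (RT); default 1.
#' @slot lambda pseudocount mass used when smoothing the statistics.
#' @slot composition smoothing target composition (carried for provenance).
#' @export
setClass("PotentialTable",
  representation(
    kind = "character", K = "integer", classes = "character",
    first = "list", second = "list", secondIndex = "data.frame",
    rt = "numeric", lambda = "numeric", composition = "numeric"
  )
)

setValidity("PotentialTable", function(object) {
  errs <- character(0)
  for (cl in object@classes) {
    if (!all(is.finite(object@first[[cl]]))) errs <- c(errs, "first-order potentials must be finite")
    if (!all(is.finite(object@second[[cl]]))) errs <- c(errs, "second-order potentials must be finite")
  }
  if (object@rt <= 0) errs <- c(errs, "rt must be positive")
  if (length(errs)) errs else TRUE
})

#' Single-hidden-layer feed-forward network
#'
#' Logistic hidden and output units, trained by backpropagation on
#' cross-entropy. Weights are seed-deterministic.
#'
#' @slot nIn,nHidden input and hidden layer sizes.
#' @slot W1,b1 hidden-layer weights (nHidden x nIn) and biases.
#' @slot W2,b2 output-layer weights (1 x nHidden) and bias.
#' @slot seed integer seed the initial weights and batch order derive from.
#' @slot history data frame of per-epoch training/validation loss.
#' @export
setClass("FeedForwardNet",
  representation(
    nIn = "integer", nHidden = "integer",
    W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
    seed = "integer", history = "data.frame"
  )
)

setValidity("FeedForwardNet", function(object) {
  errs <- character(0)
  if (!identical(dim(object@W1), c(object@nHidden, object@nIn))) errs <- c(errs, "W1 shape mismatch")
  if (length(object@b1) != object@nHidden) errs <- c(errs, "b1 length mismatch")
  if (!identical(dim(object@W2), c(1L, object@nHidden))) errs <- c(errs, "W2 shape mismatch")
  if (length(object@b2) != 1L) errs <- c(errs, "b2 length mismatch")
  if (length(errs)) errs else TRUE
})

#' Trained two-stage disulfide predictor
#'
#' Bundles everything [predictChain()] needs: the two potential tables, the
#' two networks, the encoding configuration and the score-standardisation
#' constants estimated on the training set.
#'
#' @slot stateNet,connNet the bonding-state and connectivity networks.
#' @slot stateTable,pairTable the potential tables both stages score with.
#' @slot cfg list: `nnWindow`, `K`, `stateThreshold`, `minBondProb`,
#'   `minSeparation`.
#' @slot stateScoreCenter,stateScoreScale standardisation of the two
#'   state context scores (bonded, free).
#' @slot pairScoreCenter,pairScoreScale standardisation of the two pair
#'   context scores (connected, unconnected).
#' @export
setClass("DisulfidePredictor",
  representation(
    stateNet = "FeedForwardNet", connNet = "FeedForwardNet",
    stateTable = "PotentialTable", pairTable = "PotentialTable",
    cfg = "list",
    stateScoreCenter = "numeric", stateScoreScale = "numeric",
    pairScoreCenter = "numeric", pairScoreScale = "numeric"
  )
)
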