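#' Construct an annotated protein chain
#'
#' @param id chain identifier.
#' @param sequence amino-acid string; letters outside the 20-letter alphabet
#'   are mapped to `X`.
#' @param profile optional numeric matrix (positions x 20). Columns may be
#'   named by amino acid; unnamed columns are taken in [AA_ALPHABET20] order.
#'   Rows are renormalised to sum to 1; an all-zero row becomes the one-hot
#'   distribution of the sequence residue (uniform for `X`).
#' @param bonds optional two-column matrix (or [DisulfidePattern]) of
#'   1-based cysteine position pairs.
#' @param excludedCys integer vector of cysteine positions to exclude from
#'   statistics (inter-chain bonded or structurally undetermined).
#' @return An [AnnotatedChain-class] object.
#' @examples
#' ch <- annotatedChain("demo", "ACDCG")
#' cysPositions(ch)
#' @export
annotatedChain <- function(id, sequence, profile = NULL, bonds = NULL,
                           excludedCys = integer(0)) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  letters20 <- strsplit(sequence, "")[[1]]
  letters20[!letters20 %in% c(AA_ALPHABET20, "X")] <- "X"
  sequence <- paste(letters20, collapse = "")
  if (is.null(profile)) {
    profile <- matrix(numeric(0), nrow = 0, ncol = 20,
                      dimnames = list(NULL, AA_ALPHABET20))
  } else {
    profile <- .normalizeProfile(as.matrix(profile), sequence)
  }
  if (is.null(bonds)) {
    bonds <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  } else {
    if (is(bonds, "DisulfidePattern")) bonds <- bonds@bonds
    bonds <- .canonicalBonds(bonds)
  }
  new("AnnotatedChain", id = as.character(id), sequence = sequence,
      profile = profile, bonds = bonds,
      excludedCys = sort(unique(as.integer(excludedCys))))
}

## order columns by alphabet, renormalize rows, one-hot fallback for zero rows
.normalizeProfile <- function(profile, sequence) {
  if (ncol(profile) != 20L) stop("profile must have 20 columns")
  if (!is.null(colnames(profile))) {
    if (!setequal(colnames(profile), AA_ALPHABET20))
      stop("profile column names must be the 20 standard amino acids")
    profile <- profile[, AA_ALPHABET20, drop = FALSE]
  } else {
    colnames(profile) <- AA_ALPHABET20
  }
  rs <- rowSums(profile)
  zero <- rs <= 0
  if (any(zero)) {
    letters20 <- strsplit(sequence, "")[[1]]
    for (i in which(zero)) {
      row <- numeric(20)
      if (letters20[i] %in% AA_ALPHABET20) row[match(letters20[i], AA_ALPHABET20)] <- 1
      else row[] <- 1 / 20
      profile[i, ] <- row
    }
    rs <- rowSums(profile)
  }
  profile / rs
}

.canonicalBonds <- function(bonds) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds)) {
    bonds <- t(apply(bonds, 1, sort))
    bonds <- matrix(as.integer(bonds), ncol = 2)
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  }
  dimnames(bonds) <- list(NULL, c("i", "j"))
  bonds
}

#' Construct a disulfide pattern
#'
#' @param pairs two-column matrix (or data frame / list of length-2 vectors)
#'   of 1-based position pairs; a matching (each position at most once).
#' @return A [DisulfidePattern-class] object.
#' @examples
#' disulfidePattern(rbind(c(4, 60), c(18, 29)))
#' @export
disulfidePattern <- function(pairs = NULL) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0) || length(pairs) == 0) {
    b <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  } else {
    if (is.list(pairs) && !is.data.frame(pairs)) pairs <- do.call(rbind, pairs)
    b <- .canonicalBonds(as.matrix(pairs))
    if (any(b[, 1] == b[, 2])) stop("a bond cannot pair a position with itself")
  }
  new("DisulfidePattern", bonds = b)
}

#' @describeIn annotatedChain positions of `C` residues (1-based, increasing).
#' @param x an `AnnotatedChain`.
#' @export
cysPositions <- function(x) {
  stopifnot(is(x, "AnnotatedChain"))
  which(strsplit(x@sequence, "")[[1]] == "C")
}

#' Usable cysteine positions of a chain
#'
#' Cysteine positions minus the excluded set (inter-chain bonded or
#' structurally undetermined cysteines carry no statistical weight).
#' @param x an [AnnotatedChain-class].
#' @return integer vector of 1-based positions.
#' @export
usableCys <- function(x) setdiff(cysPositions(x), x@excludedCys)

#' @rdname AnnotatedChain-class
#' @param x an `AnnotatedChain`.
#' @export
chainId <- function(x) x@id

#' @rdname AnnotatedChain-class
#' @export
chainSeq <- function(x) x@sequence

#' @rdname AnnotatedChain-class
#' @export
profileMatrix <- function(x) x@profile

#' @rdname AnnotatedChain-class
#' @export
hasProfile <- function(x) nrow(x@profile) > 0L

#' @rdname AnnotatedChain-class
#' @export
bondPattern <- function(x) new("DisulfidePattern", bonds = x@bonds)

#' @rdname AnnotatedChain-class
#' @export
excludedCys <- function(x) x@excludedCys

#' Replace a chain's profile
#' @param x an [AnnotatedChain-class].
#' @param value positions x 20 matrix.
#' @export
`profileMatrix<-` <- function(x, value) {
  x@profile <- .normalizeProfile(as.matrix(value), x@sequence)
  validObject(x)
  x
}

#' @rdname DisulfidePattern-class
#' @param x a `DisulfidePattern`.
#' @export
bonds <- function(x) {
  if (is(x, "AnnotatedChain")) return(x@bonds)
  x@bonds
}

#' @rdname DisulfidePattern-class
#' @export
nBonds <- function(x) nrow(bonds(x))

#' Bonding class of each cysteine
#'
#' @param chain an [AnnotatedChain-class].
#' @return named integer vector over [usableCys()]: 1 = bonded, 0 = free.
#' @export
cysLabels <- function(chain) {
  pos <- usableCys(chain)
  lab <- as.integer(pos %in% as.vector(chain@bonds))
  names(lab) <- pos
  lab
}

setMethod("show", "AnnotatedChain", function(object) {
  L <- nchar(object@sequence)
  cys <- cysPositions(object)
  cat(sprintf("AnnotatedChain '%s': %d residues, %d cysteines (%d usable), %d bonds, profile %s\n",
              object@id, L, length(cys), length(usableCys(object)),
              nrow(object@bonds),
              if (hasProfile(object)) "attached" else "absent"))
})

setMethod("show", "DisulfidePattern", function(object) {
  b <- object@bonds
  cat(sprintf("DisulfidePattern with %d bond(s)", nrow(b)))
  if (nrow(b)) cat(":", paste(sprintf("%d-%d", b[, 1], b[, 2]), collapse = ", "))
  cat("\n")
})

setMethod("show", "ContextStatistics", function(object) {
  cat(sprintf("ContextStatistics (%s): K = %d, classes %s, %d chains, class mass %s\n",
              object@kind, object@K, paste(object@classes, collapse = "/"),
              object@nChains,
              paste(sprintf("%.2f", object@classWeight), collapse = "/")))
})

setMethod("show", "PotentialTable", function(object) {
  cat(sprintf("PotentialTable (%s): K = %d, RT = %g, lambda = %g, %d second-order position pairs\n",
              object@kind, object@K, object@rt, object@lambda, nrow(object@secondIndex)))
})

setMethod("show", "FeedForwardNet", function(object) {
  cat(sprintf("FeedForwardNet: %d-%d-1 (logistic), seed %d, %d epochs trained\n",
              object@nIn, object@nHidden, object@seed, nrow(object@history)))
})

setMethod("show", "DisulfidePredictor", function(object) {
  cat(sprintf("DisulfidePredictor: state net %d-%d-1, connectivity net %d-%d-1, K = %d, NN window = %d\n",
              object@stateNet@nIn, object@stateNet@nHidden,
              object@connNet@nIn, object@connNet@nHidden,
              object@cfg$K, object@cfg$nnWindow))
})

#' Test two disulfide patterns for equality
#' @param a,b [DisulfidePattern-class] objects (or bond matrices).
#' @return logical.
#' @export
samePattern <- function(a, b) {
  ma <- if (is(a, "DisulfidePattern")) a@bonds else .canonicalBonds(a)
  mb <- if (is(b, "DisulfidePattern")) b@bonds else .canonicalBonds(b)
  isTRUE(all.equal(unname(ma), unname(mb)))
}
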