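## JSON (de)serialisation of statistics, potential tables and trained
## predictors. Flat JSON keeps model files text-only and diffable.

.arrayToJSON <- function(a) list(dim = dim(a), data = as.vector(a))
.arrayFromJSON <- function(x) array(as.numeric(unlist(x$data)), dim = as.integer(unlist(x$dim)))

#' Serialize context statistics to JSON
#'
#' The document records the window size, alphabet, class labels and every
#' accumulator, so potential tables rebuilt from it are reproducible.
#'
#' @param stats a [ContextStatistics-class].
#' @param path output path.
#' @return `statsFromJSON` returns the restored object.
#' @export
statsToJSON <- function(stats, path) {
  payload <- list(
    type = "ContextStatistics", kind = stats@kind, K = stats@K,
    alphabet = AA_ALPHABET20, classes = stats@classes,
    firstNum = lapply(stats@firstNum, .arrayToJSON),
    firstDen = stats@firstDen,
    secondNum = lapply(stats@secondNum, .arrayToJSON),
    secondDen = stats@secondDen,
    secondIndex = stats@secondIndex,
    composition = stats@composition,
    classWeight = as.list(stats@classWeight),
    nChains = stats@nChains)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname statsToJSON
#' @export
statsFromJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$type, "ContextStatistics")) stop("not a serialized ContextStatistics")
  fixFirst <- function(l) {
    m <- .arrayFromJSON(l)
    dimnames(m) <- list(AA_ALPHABET20, NULL)
    m
  }
  fixSecond <- function(l) {
    a <- .arrayFromJSON(l)
    dimnames(a) <- list(AA_ALPHABET20, AA_ALPHABET20, NULL)
    a
  }
  new("ContextStatistics", kind = x$kind, K = as.integer(x$K),
      classes = x$classes,
      firstNum = lapply(x$firstNum, fixFirst),
      firstDen = lapply(x$firstDen, as.numeric),
      secondNum = lapply(x$secondNum, fixSecond),
      secondDen = lapply(x$secondDen, as.numeric),
      secondIndex = as.data.frame(x$secondIndex),
      composition = setNames(as.numeric(x$composition), AA_ALPHABET20),
      classWeight = unlist(x$classWeight),
      nChains = as.integer(x$nChains))
}

.netToList <- function(net) list(
  nIn = net@nIn, nHidden = net@nHidden,
  W1 = .arrayToJSON(net@W1), b1 = net@b1,
  W2 = .arrayToJSON(net@W2), b2 = net@b2, seed = net@seed)

.netFromList <- function(x) new("FeedForwardNet",
  nIn = as.integer(x$nIn), nHidden = as.integer(x$nHidden),
  W1 = .arrayFromJSON(x$W1), b1 = as.numeric(x$b1),
  W2 = .arrayFromJSON(x$W2), b2 = as.numeric(x$b2),
  seed = as.integer(x$seed), history = data.frame())

.tableToList <- function(tab) list(
  kind = tab@kind, K = tab@K, classes = tab@classes,
  first = lapply(tab@first, .arrayToJSON),
  second = lapply(tab@second, .arrayToJSON),
  secondIndex = tab@secondIndex, rt = tab@rt, lambda = tab@lambda,
  composition = tab@composition)

.tableFromList <- function(x) {
  first <- lapply(x$first, function(l) {
    m <- .arrayFromJSON(l); dimnames(m) <- list(AA_ALPHABET20, NULL); m })
  second <- lapply(x$second, function(l) {
    a <- .arrayFromJSON(l); dimnames(a) <- list(AA_ALPHABET20, AA_ALPHABET20, NULL); a })
  new("PotentialTable", kind = x$kind, K = as.integer(x$K), classes = x$classes,
      first = first, second = second,
      secondIndex = as.data.frame(x$secondIndex),
      rt = as.numeric(x$rt), lambda = as.numeric(x$lambda),
      composition = setNames(as.numeric(x$composition), AA_ALPHABET20))
}

#' Serialize a trained predictor to a JSON model file
#'
#' Stores both networks, both potential tables, the encoding configuration
#' and the score-standardisation constants; [predictorFromJSON()] restores
#' a predictor whose predictions are bit-identical to the original's.
#'
#' @param predictor a [DisulfidePredictor-class].
#' @param path output path.
#' @return `predictorFromJSON` returns the restored predictor.
#' @export
predictorToJSON <- function(predictor, path) {
  payload <- list(
    type = "DisulfidePredictor",
    cfg = predictor@cfg,
    stateNet = .netToList(predictor@stateNet),
    connNet = .netToList(predictor@connNet),
    stateTable = .tableToList(predictor@stateTable),
    pairTable = .tableToList(predictor@pairTable),
    stateScoreCenter = predictor@stateScoreCenter,
    stateScoreScale = predictor@stateScoreScale,
    pairScoreCenter = predictor@pairScoreCenter,
    pairScoreScale = predictor@pairScoreScale)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname predictorToJSON
#' @export
predictorFromJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$type, "DisulfidePredictor")) stop("not a serialized DisulfidePredictor")
  cfg <- x$cfg
  cfg$K <- as.integer(cfg$K); cfg$nnWindow <- as.integer(cfg$nnWindow)
  cfg$minSeparation <- as.integer(cfg$minSeparation)
  new("DisulfidePredictor",
      stateNet = .netFromList(x$stateNet), connNet = .netFromList(x$connNet),
      stateTable = .tableFromList(x$stateTable),
      pairTable = .tableFromList(x$pairTable),
      cfg = cfg,
      stateScoreCenter = as.numeric(x$stateScoreCenter),
      stateScoreScale = as.numeric(x$stateScoreScale),
      pairScoreCenter = as.numeric(x$pairScoreCenter),
      pairScoreScale = as.numeric(x$pairScoreScale))
}
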