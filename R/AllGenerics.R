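## Generics, accessors and show methods.

#' Number of sequences in an alignment
#' @param x a [ProteinMSA-class]
#' @return integer
#' @export
setGeneric("nSeq", function(x) standardGeneric("nSeq"))

#' @rdname nSeq
#' @export
setMethod("nSeq", "ProteinMSA", function(x) nrow(x@chars))

#' Number of alignment columns
#' @param x a [ProteinMSA-class]
#' @return integer
#' @export
setGeneric("nCol", function(x) standardGeneric("nCol"))

#' @rdname nCol
#' @export
setMethod("nCol", "ProteinMSA", function(x) ncol(x@chars))

#' Character matrix of an alignment
#' @param x a [ProteinMSA-class]
#' @return character matrix
#' @export
setGeneric("alignmentChars", function(x) standardGeneric("alignmentChars"))

#' @rdname alignmentChars
#' @export
setMethod("alignmentChars", "ProteinMSA", function(x) {
  m <- x@chars
  dimnames(m) <- list(x@ids, x@columnLabels)
  m
})

#' Sequence identifiers
#' @param x a [ProteinMSA-class]
#' @return character vector
#' @export
setGeneric("sequenceIds", function(x) standardGeneric("sequenceIds"))

#' @rdname sequenceIds
#' @export
setMethod("sequenceIds", "ProteinMSA", function(x) x@ids)

#' Original column numbers
#' @param x a [ProteinMSA-class] or [LinkMatrix-class]
#' @return integer vector of original 1-based column numbers
#' @export
setGeneric("columnLabels", function(x) standardGeneric("columnLabels"))

#' @rdname columnLabels
#' @export
setMethod("columnLabels", "ProteinMSA", function(x) x@columnLabels)

#' @rdname columnLabels
#' @export
setMethod("columnLabels", "LinkMatrix", function(x) x@columnLabels)

#' Per-column molecule labels
#' @param x a [ProteinMSA-class]
#' @return integer vector (possibly empty)
#' @export
setGeneric("moleculeLabels", function(x) standardGeneric("moleculeLabels"))

#' @rdname moleculeLabels
#' @export
setMethod("moleculeLabels", "ProteinMSA", function(x) x@moleculeLabels)

#' Edge list of an interaction network
#' @param x an [InteractionNetwork-class]
#' @return two-column integer matrix (i < j)
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname edges
#' @export
setMethod("edges", "InteractionNetwork", function(x) x@edges)

#' Number of nodes
#' @param x an [InteractionNetwork-class] or [MRFModel-class]
#' @return integer
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "InteractionNetwork", function(x) x@nNodes)

#' @rdname nNodes
#' @export
setMethod("nNodes", "MRFModel", function(x) x@network@nNodes)

#' Score matrix of a LinkMatrix
#' @param x a [LinkMatrix-class]
#' @return symmetric numeric matrix
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname scores
#' @export
setMethod("scores", "LinkMatrix", function(x) {
  s <- x@scores
  dimnames(s) <- list(x@columnLabels, x@columnLabels)
  s
})

#' Scoring mode of a LinkMatrix
#' @param x a [LinkMatrix-class]
#' @return character scalar
#' @export
setGeneric("scoringMode", function(x) standardGeneric("scoringMode"))

#' @rdname scoringMode
#' @export
setMethod("scoringMode", "LinkMatrix", function(x) x@scoringMode)

setMethod("show", "ProteinMSA", function(object) {
  cat(sprintf("ProteinMSA: %d sequences x %d columns\n",
              nrow(object@chars), ncol(object@chars)))
  if (length(object@moleculeLabels))
    cat(sprintf("  two molecules: %d + %d columns\n",
                sum(object@moleculeLabels == 1L),
                sum(object@moleculeLabels == 2L)))
  gap <- mean(object@chars == "-")
  cat(sprintf("  gap fraction %.3f; columns %d..%d of original alignment\n",
              gap, min(object@columnLabels), max(object@columnLabels)))
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges (density parameter %.3g)\n",
              object@nNodes, nrow(object@edges), object@density))
})

setMethod("show", "MRFModel", function(object) {
  cat(sprintf(
    "MRFModel on %d nodes / %d edges; pPrefNode = %.3g, pPrefEdge = %.3g\n",
    object@network@nNodes, nrow(object@network@edges),
    object@pPrefNode, object@pPrefEdge))
})

setMethod("show", "CoefficientPath", function(object) {
  cat(sprintf("CoefficientPath for column %d: %d lambda values\n",
              object@responseColumn, length(object@lambdas)))
  if (object@degenerate) {
    cat("  degenerate (constant response): all-zero path\n")
  } else {
    cat(sprintf("  lambda %.4g .. %.4g; nonzero coefficients %d .. %d\n",
                max(object@lambdas), min(object@lambdas),
                min(object@nNonzero), max(object@nNonzero)))
  }
})

setMethod("show", "LinkMatrix", function(object) {
  p <- nrow(object@scores)
  ut <- object@scores[upper.tri(object@scores)]
  cat(sprintf("LinkMatrix (%s): %d columns, %d pairs, %d with score > 0\n",
              object@scoringMode, p, length(ut), sum(ut > 0)))
})

setMethod("show", "ContactMap", function(object) {
  n <- nrow(object@distances)
  ut <- object@distances[upper.tri(object@distances)]
  cat(sprintf("ContactMap: %d residues; %d/%d pairs within %.3g Angstrom\n",
              n, sum(ut <= object@contactCutoff), length(ut),
              object@contactCutoff))
})

setMethod("show", "InteractionModel", function(object) {
  cat(sprintf("InteractionModel (%s): %d column fits, pseudocount %.4g\n",
              object@maskMode, length(object@fits), object@pseudocount))
})
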