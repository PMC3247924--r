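## S4 classes for alignments, simulated networks, fitted paths and link maps.

#' ProteinMSA: a gapped protein multiple sequence alignment
#'
#' Characters are stored as an `n_seq x n_col` matrix over the 20 amino acids
#' and the gap symbol `-`. `columnLabels` carries the original 1-based column
#' numbers so that columns removed by [filterGapColumns()] can still be
#' reported against a structure. `moleculeLabels`, when set, partitions the
#' columns into two molecules (1 or 2) for inter/intra-molecular analyses.
#'
#' @slot ids character, one identifier per sequence.
#' @slot chars character matrix of single characters.
#' @slot columnLabels integer, original 1-based column numbers.
#' @slot moleculeLabels integer of length 0, or one label (1 or 2) per column.
#' @exportClass ProteinMSA
setClass("ProteinMSA",
  representation(
    ids = "character",
    chars = "matrix",
    columnLabels = "integer",
    moleculeLabels = "integer"
  )
)

setValidity("ProteinMSA", function(object) {
  msgs <- character()
  if (nrow(object@chars) < 2L)
    msgs <- c(msgs, "an alignment needs at least 2 sequences")
  if (length(object@ids) != nrow(object@chars))
    msgs <- c(msgs, "length(ids) must equal the number of rows")
  if (length(object@columnLabels) != ncol(object@chars))
    msgs <- c(msgs, "columnLabels must have one entry per column")
  if (length(object@moleculeLabels) &&
      length(object@moleculeLabels) != ncol(object@chars))
    msgs <- c(msgs, "moleculeLabels must be empty or one per column")
  if (length(object@moleculeLabels) &&
      !all(object@moleculeLabels %in% c(1L, 2L)))
    msgs <- c(msgs, "moleculeLabels must be 1 or 2")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProteinMSA
#'
#' @param chars character matrix (sequences in rows) or character vector of
#'   equal-length strings.
#' @param ids sequence identifiers; defaults to `seq1..seqN`.
#' @param moleculeLabels optional per-column molecule tag (1 or 2).
#' @param columnLabels original 1-based column numbers; defaults to
#'   `1..n_col`.
#' @return A [ProteinMSA-class] object.
#' @examples
#' ProteinMSA(c("ACDE", "AC-E"))
#' @export
ProteinMSA <- function(chars, ids = NULL, moleculeLabels = integer(),
                       columnLabels = NULL) {
  if (is.character(chars) && !is.matrix(chars)) {
    lens <- nchar(chars)
    if (length(unique(lens)) != 1L)
      stop("sequences have unequal lengths")
    chars <- do.call(rbind, strsplit(chars, ""))
  }
  chars <- toupper(chars)
  chars[chars == "."] <- "-"
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(chars)))
  if (is.null(columnLabels)) columnLabels <- seq_len(ncol(chars))
  new("ProteinMSA", ids = ids, chars = unname(chars),
      columnLabels = as.integer(columnLabels),
      moleculeLabels = as.integer(moleculeLabels))
}

#' EncodedMSA: integer and indicator form of an alignment
#'
#' `A` holds integer codes 1..21 per cell (see [aaAlphabet()]); `M` is the
#' sparse `n_seq x (21 * n_col)` one-hot expansion in which every 21-wide row
#' block contains exactly one 1. `columnMap[[i]]` gives the 21 indicator
#' column indices of original column `i`.
#'
#' @slot A integer matrix of codes in 1..21.
#' @slot M sparse indicator matrix (`Matrix::dgCMatrix`).
#' @slot columnMap list of integer vectors, one per alignment column.
#' @slot aaOrder the character-to-integer mapping used.
#' @slot columnLabels original 1-based column numbers.
#' @exportClass EncodedMSA
setClass("EncodedMSA",
  representation(
    A = "matrix",
    M = "Matrix",
    columnMap = "list",
    aaOrder = "character",
    columnLabels = "integer"
  )
)

setValidity("EncodedMSA", function(object) {
  msgs <- character()
  if (!all(object@A %in% seq_len(21L)))
    msgs <- c(msgs, "A must contain integer codes in 1..21")
  if (ncol(object@M) != 21L * ncol(object@A))
    msgs <- c(msgs, "M must have 21 columns per alignment column")
  if (length(msgs)) msgs else TRUE
})

#' InteractionNetwork: ground-truth column-column interactions
#'
#' An undirected simple graph on `1..nNodes`; each node corresponds to an
#' alignment column in the simulator.
#'
#' @slot nNodes number of nodes.
#' @slot edges two-column integer matrix of node pairs with `i < j`.
#' @slot density the edge-inclusion probability used to generate the graph.
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  representation(nNodes = "integer", edges = "matrix", density = "numeric")
)

setValidity("InteractionNetwork", function(object) {
  e <- object@edges
  msgs <- character()
  if (ncol(e) != 2L) msgs <- c(msgs, "edges must have two columns")
  if (nrow(e)) {
    if (any(e[, 1L] >= e[, 2L])) msgs <- c(msgs, "edges must satisfy i < j")
    if (any(e < 1L) || any(e > object@nNodes))
      msgs <- c(msgs, "edge endpoints out of range")
    if (anyDuplicated(paste(e[, 1L], e[, 2L])))
      msgs <- c(msgs, "duplicate edges")
  }
  if (length(msgs)) msgs else TRUE
})

#' MRFModel: Markov random field over an interaction network
#'
#' Node potentials give each of the 21 characters a weight at each node (rows
#' sum to 1: one preferred character with weight `pPrefNode`, the rest share
#' the remainder equally). Each edge carries a 21 x 21 distribution over
#' character pairs in which every row has two preferred partner characters
#' (the 42 preferred cells sharing total mass `pPrefEdge`) against 399
#' background cells sharing `1 - pPrefEdge`; the tables act as clique
#' potentials in the Gibbs conditional, which renormalizes them.
#'
#' @slot network the [InteractionNetwork-class].
#' @slot nodePotentials `nNodes x 21` matrix, rows summing to 1.
#' @slot edgePotentials `21 x 21 x nEdges` array.
#' @slot pPrefNode preferred-character node weight.
#' @slot pPrefEdge preferred-pair edge weight.
#' @exportClass MRFModel
setClass("MRFModel",
  representation(
    network = "InteractionNetwork",
    nodePotentials = "matrix",
    edgePotentials = "array",
    pPrefNode = "numeric",
    pPrefEdge = "numeric"
  )
)

setValidity("MRFModel", function(object) {
  msgs <- character()
  np <- object@nodePotentials
  if (nrow(np) != object@network@nNodes || ncol(np) != 21L)
    msgs <- c(msgs, "nodePotentials must be nNodes x 21")
  if (any(abs(rowSums(np) - 1) > 1e-8))
    msgs <- c(msgs, "node potential rows must sum to 1")
  d <- dim(object@edgePotentials)
  if (length(d) != 3L || d[1L] != 21L || d[2L] != 21L ||
      d[3L] != nrow(object@network@edges))
    msgs <- c(msgs, "edgePotentials must be 21 x 21 x nEdges")
  if (length(msgs)) msgs else TRUE
})

#' FitConfig: tuning parameters for the per-column elastic-net path
#'
#' @slot alpha elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @slot nLambda number of penalty values on the path.
#' @slot lambdaMinRatio smallest lambda as a fraction of lambda_max; `NA`
#'   selects 0.01.
#' @slot standardize standardize predictors internally before fitting.
#' @slot maskMode `"all"` uses every other column as predictor;
#'   `"intermolecular"` restricts predictors to the partner molecule.
#' @exportClass FitConfig
setClass("FitConfig",
  representation(
    alpha = "numeric",
    nLambda = "integer",
    lambdaMinRatio = "numeric",
    standardize = "logical",
    maskMode = "character"
  )
)

setValidity("FitConfig", function(object) {
  msgs <- character()
  if (object@alpha < 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must lie in [0, 1]")
  if (object@nLambda < 1L) msgs <- c(msgs, "nLambda must be >= 1")
  if (!object@maskMode %in% c("all", "intermolecular"))
    msgs <- c(msgs, "maskMode must be 'all' or 'intermolecular'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FitConfig
#'
#' @param alpha elastic-net mixing parameter; the method's default is 0.99,
#'   i.e. almost pure lasso with a small ridge component that stabilizes
#'   groups of correlated predictors.
#' @param nLambda number of penalty values on the log-spaced path.
#' @param lambdaMinRatio ratio of the smallest to the largest lambda; `NA`
#'   picks 1/100 (the solver default whenever predictors outnumber
#'   observations, which alignment work guarantees in practice).
#' @param standardize standardize predictors to unit variance before
#'   fitting. Off by default: one-hot indicators already share a common
#'   scale, and standardizing inflates the influence of rare characters
#'   (an indicator with frequency q has variance q(1-q), so rare-character
#'   columns get amplified most), which measurably degrades link ranking.
#' @param maskMode `"all"` or `"intermolecular"` (two-molecule alignments).
#' @return A [FitConfig-class] object.
#' @examples
#' fitConfig(nLambda = 50)
#' @export
fitConfig <- function(alpha = 0.99, nLambda = 100L, lambdaMinRatio = NA_real_,
                      standardize = FALSE, maskMode = c("all", "intermolecular")) {
  new("FitConfig", alpha = alpha, nLambda = as.integer(nLambda),
      lambdaMinRatio = lambdaMinRatio, standardize = standardize,
      maskMode = match.arg(maskMode))
}

#' CoefficientPath: the regularization path of one response column
#'
#' Coefficients are stored per observed response class (classes absent from
#' the response column carry no coefficients); [pathCoefficients()] expands
#' any path entry to the full 21-row table.
#'
#' @slot responseColumn index of the response column in the (filtered)
#'   alignment.
#' @slot lambdas decreasing penalty sequence.
#' @slot beta list over observed classes of sparse `nPred x nLambda`
#'   coefficient matrices.
#' @slot intercepts `nObsClass x nLambda` matrix of unpenalized intercepts.
#' @slot obsClasses integer codes of the classes observed in the response.
#' @slot loglik multinomial log-likelihood at each lambda.
#' @slot nNonzero number of nonzero (non-intercept) coefficients per lambda.
#' @slot predictorColumns original column index of each predictor indicator
#'   column.
#' @slot nObs number of sequences used in the fit.
#' @slot degenerate TRUE when the response was constant and the path is the
#'   all-zero model.
#' @exportClass CoefficientPath
setClass("CoefficientPath",
  representation(
    responseColumn = "integer",
    lambdas = "numeric",
    beta = "list",
    intercepts = "matrix",
    obsClasses = "integer",
    loglik = "numeric",
    nNonzero = "integer",
    predictorColumns = "integer",
    nObs = "integer",
    degenerate = "logical"
  )
)

#' LinkMatrix: symmetric column-column interaction scores
#'
#' @slot scores symmetric nonnegative matrix with zero diagonal.
#' @slot scoringMode one of `"bic"`, `"path_sum"`, `"model_count"`,
#'   `"corrected_mi"`.
#' @slot columnLabels original 1-based alignment column numbers.
#' @exportClass LinkMatrix
setClass("LinkMatrix",
  representation(scores = "matrix", scoringMode = "character",
                 columnLabels = "integer")
)

setValidity("LinkMatrix", function(object) {
  s <- object@scores
  msgs <- character()
  if (nrow(s) != ncol(s)) msgs <- c(msgs, "scores must be square")
  if (!isTRUE(all.equal(s, t(s), tolerance = 1e-10)))
    msgs <- c(msgs, "scores must be symmetric")
  if (any(diag(s) != 0)) msgs <- c(msgs, "diagonal must be zero")
  if (any(s < 0)) msgs <- c(msgs, "scores must be nonnegative")
  if (length(object@columnLabels) != nrow(s))
    msgs <- c(msgs, "columnLabels must match the matrix dimension")
  if (length(msgs)) msgs else TRUE
})

#' ContactMap: residue-residue distances from a structure
#'
#' Distances are between Cbeta atoms (Calpha for glycine), in Angstrom.
#' `residueToColumn[r]` gives the (original, 1-based) alignment column of
#' structure residue `r`, or `NA` when unmapped.
#'
#' @slot distances symmetric distance matrix in Angstrom.
#' @slot contactCutoff distance (Angstrom) at or below which a pair is a
#'   contact.
#' @slot residueToColumn integer map from structure residues to alignment
#'   columns.
#' @exportClass ContactMap
setClass("ContactMap",
  representation(distances = "matrix", contactCutoff = "numeric",
                 residueToColumn = "integer")
)

setValidity("ContactMap", function(object) {
  d <- object@distances
  msgs <- character()
  if (nrow(d) != ncol(d)) msgs <- c(msgs, "distances must be square")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    msgs <- c(msgs, "distances must be symmetric")
  if (any(d < 0)) msgs <- c(msgs, "distances must be nonnegative")
  m <- object@residueToColumn[!is.na(object@residueToColumn)]
  if (anyDuplicated(m)) msgs <- c(msgs, "residueToColumn must be injective")
  if (length(msgs)) msgs else TRUE
})

#' InteractionModel: per-column BIC-selected fits for pair scoring
#'
#' Stores, for each alignment column, the minimum-BIC entry of its
#' elastic-net path, together with the metadata needed to score a new
#' aligned candidate sequence pair by summed per-column log-likelihood.
#'
#' @slot fits list, one element per column: beta (sparse), intercepts,
#'   obsClasses, predictorIndicators, lambda, bic.
#' @slot maskMode `"intermolecular_only"` or `"inter_and_intra"`.
#' @slot aaOrder character-to-integer mapping.
#' @slot columnLabels original column numbers of the training alignment.
#' @slot moleculeLabels per-column molecule tag of the training alignment.
#' @slot pseudocount additive probability floor used in scoring.
#' @exportClass InteractionModel
setClass("InteractionModel",
  representation(
    fits = "list",
    maskMode = "character",
    aaOrder = "character",
    columnLabels = "integer",
    moleculeLabels = "integer",
    pseudocount = "numeric"
  )
)
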