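## Benchmark generator: random interaction networks, MRF potentials, Gibbs
## sampling of alignments, and the noise / duplication perturbations.

#' Generate a random interaction network
#'
#' Each of the `nNodes*(nNodes-1)/2` candidate node pairs is included as an
#' edge independently with probability `density`.
#'
#' @param nNodes number of nodes (alignment columns); at least 2.
#' @param density edge inclusion probability in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return An [InteractionNetwork-class].
#' @examples
#' generateNetwork(10, 0.25, seed = 1)
#' @export
generateNetwork <- function(nNodes, density, seed = NULL) {
  if (nNodes < 2L) stop("nNodes must be at least 2")
  stopifnot(density >= 0, density <= 1)
  if (!is.null(seed)) set.seed(seed)
  pairs <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < density
  e <- pairs[keep, , drop = FALSE]
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  colnames(e) <- c("i", "j")
  new("InteractionNetwork", nNodes = as.integer(nNodes),
      edges = matrix(as.integer(e), ncol = 2L,
                     dimnames = list(NULL, c("i", "j"))),
      density = density)
}

#' Build MRF node and edge potentials for a network
#'
#' Every node gets one uniformly chosen preferred character of weight
#' `pPrefNode`; the other 20 characters share `(1 - pPrefNode)/20` each,
#' so each node row is a probability distribution. Every edge gets a
#' 21 x 21 table normalized the same way: for each character `a` (the
#' state of the lower-numbered endpoint), two partner characters are
#' chosen uniformly, and the resulting 42 preferred cells share the total
#' mass `pPrefEdge` (each `pPrefEdge/42`) while the 399 background cells
#' share `1 - pPrefEdge` (each `(1 - pPrefEdge)/399`), making the table a
#' distribution over character pairs. All 21 characters (including the
#' gap state) take part in partner selection and the table is used as-is,
#' without symmetrization; the Gibbs conditional renormalizes, so only
#' the preferred/background ratio matters.
#'
#' @param net an [InteractionNetwork-class].
#' @param pPrefNode node preference weight in (0, 1), e.g. 0.1 or 0.3.
#' @param pPrefEdge edge preference weight in (0, 1), e.g. 0.1 or 0.3.
#' @param seed optional RNG seed.
#' @return An [MRFModel-class].
#' @examples
#' net <- generateNetwork(5, 0.5, seed = 1)
#' buildPotentials(net, 0.3, 0.3, seed = 2)
#' @export
buildPotentials <- function(net, pPrefNode, pPrefEdge, seed = NULL) {
  stopifnot(is(net, "InteractionNetwork"),
            pPrefNode > 0, pPrefNode < 1, pPrefEdge > 0, pPrefEdge < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- net@nNodes
  m <- nrow(net@edges)
  nodePot <- matrix((1 - pPrefNode) / 20, n, .NSTATE)
  pref <- sample.int(.NSTATE, n, replace = TRUE)
  nodePot[cbind(seq_len(n), pref)] <- pPrefNode
  # 42 preferred cells share mass pPrefEdge, 399 background cells share
  # the rest: the table sums to 1
  edgePot <- array((1 - pPrefEdge) / (.NSTATE * .NSTATE - .NSTATE * 2),
                   dim = c(.NSTATE, .NSTATE, m))
  prefVal <- pPrefEdge / (.NSTATE * 2)
  for (e in seq_len(m)) {
    for (a in seq_len(.NSTATE)) {
      partners <- sample.int(.NSTATE, 2L)
      edgePot[a, partners, e] <- prefVal
    }
  }
  new("MRFModel", network = net, nodePotentials = nodePot,
      edgePotentials = edgePot, pPrefNode = pPrefNode, pPrefEdge = pPrefEdge)
}

#' Run the Gibbs chain and record selected sweeps
#'
#' Low-level interface to the compiled sampler: performs `nSweeps`
#' sequential full sweeps (nodes updated in order 1..n) and returns the
#' 1..21 state vectors recorded after the requested sweeps. Initial states
#' are drawn from the node potentials. The conditional for a node is
#' proportional to its node potential times the product of the incident
#' edge-table entries at the current neighbor states.
#'
#' @param model an [MRFModel-class].
#' @param nSweeps total number of full sweeps.
#' @param recordSweeps increasing 1-based sweep numbers to record.
#' @param seed optional RNG seed.
#' @param synchronous update all nodes from the previous sweep's state
#'   instead of the evolving state (see [gibbsSample()]).
#' @return Integer matrix, `length(recordSweeps) x nNodes`, values in 1..21.
#' @export
gibbsChain <- function(model, nSweeps, recordSweeps, seed = NULL,
                       synchronous = FALSE) {
  stopifnot(is(model, "MRFModel"))
  recordSweeps <- as.integer(recordSweeps)
  if (is.unsorted(recordSweeps, strictly = TRUE))
    stop("recordSweeps must be strictly increasing")
  if (max(recordSweeps) > nSweeps)
    stop("recordSweeps beyond nSweeps")
  if (!is.null(seed)) set.seed(seed)
  n <- nNodes(model)
  init <- vapply(seq_len(n), function(v)
    sample.int(.NSTATE, 1L, prob = model@nodePotentials[v, ]), 1L)
  # rescale edge slices so neighbor products stay near 1 (exact: the
  # conditional renormalizes)
  ep <- model@edgePotentials * (.NSTATE * .NSTATE)
  gibbs_chain_cpp(model@nodePotentials, model@network@edges - 1L,
                  as.numeric(ep), as.integer(nSweeps), recordSweeps,
                  as.integer(init), isTRUE(synchronous))
}

#' Gibbs-sample an alignment from an MRF model
#'
#' Runs `nIterations` full sweeps and keeps the last `nSamples` states
#' recorded every `thinning` sweeps (i.e. sweeps
#' `nIterations - (nSamples-1)*thinning, ..., nIterations`), mapping states
#' back to characters via [aaAlphabet()].
#'
#' @param model an [MRFModel-class].
#' @param nIterations total sweeps (default 100000).
#' @param thinning sweeps between recorded samples (default 50; 1 gives
#'   maximally correlated consecutive samples).
#' @param nSamples number of sequences to keep (e.g. 50, 500, 1000).
#' @param seed optional RNG seed.
#' @return A [ProteinMSA-class] with `nSamples` rows and `nNodes` columns.
#' @examples
#' m <- buildPotentials(generateNetwork(8, 0.3, seed = 1), 0.3, 0.3, seed = 2)
#' gibbsSample(m, nIterations = 500, thinning = 10, nSamples = 20, seed = 3)
#' @export
gibbsSample <- function(model, nIterations = 100000L, thinning = 50L,
                        nSamples = 500L, seed = NULL, synchronous = FALSE) {
  if (nSamples * thinning > nIterations)
    stop("nSamples * thinning must not exceed nIterations")
  rec <- seq.int(nIterations - (nSamples - 1L) * thinning, nIterations,
                 by = thinning)
  states <- gibbsChain(model, nIterations, rec, seed = seed,
                       synchronous = synchronous)
  statesToMSA(states)
}

#' Convert recorded Gibbs states to a ProteinMSA
#'
#' @param states integer matrix of 1..21 states (samples in rows).
#' @return A [ProteinMSA-class].
#' @export
statesToMSA <- function(states) {
  aa <- aaAlphabet()
  chars <- matrix(aa[states], nrow(states), ncol(states))
  ProteinMSA(chars, ids = sprintf("sample%04d", seq_len(nrow(states))))
}

#' Randomly mutate a fraction of alignment cells
#'
#' Exactly `round(rate * nSeq * nCol)` distinct cells are chosen uniformly
#' and each is replaced by a character drawn uniformly from the 20 amino
#' acids excluding the cell's current character; gaps are never introduced
#' (a mutated gap cell becomes a uniformly chosen amino acid).
#'
#' @param aln a [ProteinMSA-class].
#' @param rate fraction of cells to mutate, e.g. 0.1 or 0.25.
#' @param seed optional RNG seed.
#' @return A [ProteinMSA-class] of the same shape.
#' @export
addPositionNoise <- function(aln, rate, seed = NULL) {
  stopifnot(is(aln, "ProteinMSA"), rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  chars <- aln@chars
  aa <- aaAlphabet()
  ncells <- length(chars)
  k <- round(rate * ncells)
  if (k > 0) {
    idx <- sample.int(ncells, k)
    cur <- match(chars[idx], aa)
    isAA <- cur <= 20L
    new <- integer(k)
    # amino-acid cells: uniform over the 19 other amino acids
    u <- sample.int(19L, sum(isAA), replace = TRUE)
    new[isAA] <- u + (u >= cur[isAA])
    # gap (or collapsed ambiguity) cells: uniform over all 20 amino acids
    new[!isAA] <- sample.int(20L, sum(!isAA), replace = TRUE)
    chars[idx] <- aa[new]
  }
  new("ProteinMSA", ids = aln@ids, chars = chars,
      columnLabels = aln@columnLabels, moleculeLabels = aln@moleculeLabels)
}

#' Replace sequences by node-potential-only samples
#'
#' `round(rate * nSeq)` uniformly chosen rows are replaced by sequences
#' drawn independently per column from the model's node potentials (no edge
#' terms), mimicking sequences unrelated to the interaction structure.
#'
#' @param aln a [ProteinMSA-class] whose columns match the model's nodes.
#' @param model the [MRFModel-class] that generated the alignment.
#' @param rate fraction of sequences to replace.
#' @param seed optional RNG seed.
#' @return A [ProteinMSA-class] of the same shape.
#' @export
addSequenceNoise <- function(aln, model, rate, seed = NULL) {
  stopifnot(is(aln, "ProteinMSA"), is(model, "MRFModel"),
            rate >= 0, rate <= 1)
  if (ncol(aln@chars) != nNodes(model))
    stop("alignment columns and model nodes differ")
  if (!is.null(seed)) set.seed(seed)
  chars <- aln@chars
  aa <- aaAlphabet()
  k <- round(rate * nrow(chars))
  if (k > 0) {
    rows <- sample.int(nrow(chars), k)
    for (v in seq_len(ncol(chars))) {
      chars[rows, v] <- aa[sample.int(.NSTATE, k, replace = TRUE,
                                      prob = model@nodePotentials[v, ])]
    }
  }
  new("ProteinMSA", ids = aln@ids, chars = chars,
      columnLabels = aln@columnLabels, moleculeLabels = aln@moleculeLabels)
}

#' Append duplicate copies of one sequence
#'
#' One uniformly chosen row is appended `nCopies` times; originals keep
#' their order and the copies follow at the end.
#'
#' @param aln a [ProteinMSA-class].
#' @param nCopies number of copies to append (0 leaves the alignment
#'   unchanged).
#' @param seed optional RNG seed.
#' @return A [ProteinMSA-class] with `nSeq + nCopies` rows.
#' @export
addDuplicates <- function(aln, nCopies, seed = NULL) {
  stopifnot(is(aln, "ProteinMSA"), nCopies >= 0)
  if (nCopies == 0) return(aln)
  if (!is.null(seed)) set.seed(seed)
  r <- sample.int(nrow(aln@chars), 1L)
  chars <- rbind(aln@chars,
                 aln@chars[rep.int(r, nCopies), , drop = FALSE])
  ids <- c(aln@ids, sprintf("%s_dup%03d", aln@ids[r], seq_len(nCopies)))
  new("ProteinMSA", ids = ids, chars = chars,
      columnLabels = aln@columnLabels, moleculeLabels = aln@moleculeLabels)
}

#' Write a network edge list to TSV
#'
#' @param net an [InteractionNetwork-class].
#' @param path output path; columns `node_i`, `node_j` (1-based).
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  e <- net@edges
  write.table(data.frame(node_i = e[, 1L], node_j = e[, 2L]), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge list from TSV
#'
#' @param path TSV with two columns of 1-based node indices (header
#'   optional).
#' @param nNodes number of nodes; defaults to the largest index seen.
#' @return An [InteractionNetwork-class].
#' @export
readEdgeList <- function(path, nNodes = NULL) {
  first <- readLines(path, n = 1L)
  hasHeader <- !grepl("^[0-9]", trimws(first))
  d <- read.table(path, header = hasHeader, sep = "\t")
  e <- cbind(pmin(d[[1L]], d[[2L]]), pmax(d[[1L]], d[[2L]]))
  e <- unique(e[order(e[, 1L], e[, 2L]), , drop = FALSE])
  if (is.null(nNodes)) nNodes <- max(e)
  new("InteractionNetwork", nNodes = as.integer(nNodes),
      edges = matrix(as.integer(e), ncol = 2L,
                     dimnames = list(NULL, c("i", "j"))),
      density = nrow(e) / (nNodes * (nNodes - 1) / 2))
}
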