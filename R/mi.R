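## Mutual information baseline with joint-entropy correction.

#' Joint count statistics for a pair of alignment columns
#'
#' @param a,b integer vectors of codes in 1..21 (same length), or a
#'   [ProteinMSA-class] in `a` with column indices in `b`.
#' @return List with `joint` (21 x 21 count table), `marginals` (list of
#'   two 21-vectors) and `nSeq`.
#' @export
columnPairStats <- function(a, b) {
  if (is(a, "ProteinMSA")) {
    enc <- encodeAlignment(a)
    stopifnot(length(b) == 2L)
    ai <- enc@A[, b[1L]]; bi <- enc@A[, b[2L]]
  } else {
    ai <- as.integer(a); bi <- as.integer(b)
  }
  stopifnot(length(ai) == length(bi))
  joint <- matrix(tabulate((ai - 1L) * .NSTATE + bi, .NSTATE * .NSTATE),
                  .NSTATE, .NSTATE, byrow = TRUE)
  list(joint = joint,
       marginals = list(rowSums(joint), colSums(joint)),
       nSeq = length(ai))
}

# core computation on a count table; returns c(mi, hJoint), natural log
.miFromCounts <- function(joint) {
  n <- sum(joint)
  nz <- which(joint > 0)
  pj <- joint[nz] / n
  pa <- rowSums(joint) / n
  pb <- colSums(joint) / n
  rowIdx <- (nz - 1L) %% nrow(joint) + 1L
  colIdx <- (nz - 1L) %/% nrow(joint) + 1L
  mi <- sum(pj * log(pj / (pa[rowIdx] * pb[colIdx])))
  h <- -sum(pj * log(pj))
  c(mi = max(mi, 0), hJoint = h)
}

#' Mutual information between two alignment columns
#'
#' Plug-in MI `sum p(a,b) log[p(a,b) / (p(a) p(b))]` over cells with
#' positive joint probability.
#'
#' @param stats output of [columnPairStats()], or a 21 x 21 (or smaller)
#'   count table.
#' @param base logarithm base; natural log by default (use 2 for bits).
#' @return MI (nonnegative scalar).
#' @examples
#' s <- columnPairStats(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))
#' columnMI(s, base = 2)   # 1 bit
#' @export
columnMI <- function(stats, base = exp(1)) {
  joint <- if (is.list(stats)) stats$joint else stats
  unname(.miFromCounts(joint)[["mi"]] / log(base))
}

#' Entropy-corrected mutual information
#'
#' MI divided by the joint entropy of the pair, the normalization that
#' compensates MI's dependence on how variable the two columns are;
#' defined as 0 when the joint entropy is 0 (both columns conserved). The
#' log base cancels in the ratio. Always lies in `[0, 1]`.
#'
#' @param stats output of [columnPairStats()] or a count table.
#' @return Corrected MI in `[0, 1]`.
#' @examples
#' s <- columnPairStats(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))
#' correctedMI(s)   # 1: maximal dependence
#' @export
correctedMI <- function(stats) {
  joint <- if (is.list(stats)) stats$joint else stats
  v <- .miFromCounts(joint)
  if (v[["hJoint"]] <= 0) return(0)
  unname(min(v[["mi"]] / v[["hJoint"]], 1))
}

#' Mutual-information link matrix over all column pairs
#'
#' Pairwise entropy-corrected MI (or plain MI with `corrected = FALSE`,
#' kept for comparison; the corrected form performs better and is the
#' default everywhere).
#'
#' @param aln a gap-filtered [ProteinMSA-class].
#' @param corrected divide each pair's MI by its joint entropy.
#' @return A [LinkMatrix-class] with `scoringMode = "corrected_mi"` (or
#'   `"mi"`).
#' @examples
#' miMatrix(ProteinMSA(c("ACD", "ACE", "AFD", "AFE")))
#' @export
miMatrix <- function(aln, corrected = TRUE) {
  stopifnot(is(aln, "ProteinMSA"))
  enc <- encodeAlignment(aln)
  A <- enc@A
  p <- ncol(A)
  s <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) {
    ai21 <- (A[, i] - 1L) * .NSTATE
    for (j in seq.int(i + 1L, p)) {
      joint <- matrix(tabulate(ai21 + A[, j], .NSTATE * .NSTATE),
                      .NSTATE, .NSTATE, byrow = TRUE)
      s[i, j] <- s[j, i] <- if (corrected) correctedMI(joint)
        else columnMI(joint)
    }
  }
  new("LinkMatrix", scores = s,
      scoringMode = if (corrected) "corrected_mi" else "mi",
      columnLabels = enc@columnLabels)
}

#' Mean corrected MI over all unordered column pairs
#'
#' The alignment-level summary used for calibrating simulated alignments
#' against biological ones.
#'
#' @param aln a [ProteinMSA-class].
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
meanCorrectedMI <- function(aln) {
  s <- scores(miMatrix(aln))
  v <- s[upper.tri(s)]
  c(mean = mean(v), sd = stats::sd(v))
}
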