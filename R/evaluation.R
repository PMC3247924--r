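## Validation machinery: AUC against ground-truth networks, contact maps,
## CASP-style accuracy and Xd, F-score, distance enrichment.

# upper-triangle pair scores of a LinkMatrix as a vector plus index matrix
.pairScores <- function(links) {
  s <- links@scores
  ut <- which(upper.tri(s), arr.ind = TRUE)
  list(i = ut[, 1L], j = ut[, 2L], score = s[ut])
}

#' AUC of link scores against a ground-truth network
#'
#' Area under the ROC curve of the score ranking of all unordered column
#' pairs (self-pairs excluded) against the edge/non-edge labels, computed
#' by the rank-sum (Mann-Whitney) formulation, which handles tied scores
#' exactly: constant scores give 0.5.
#'
#' @param links a [LinkMatrix-class] whose `columnLabels` index the
#'   network's nodes.
#' @param truth an [InteractionNetwork-class].
#' @return AUC in `[0, 1]`.
#' @examples
#' net <- generateNetwork(10, 0.3, seed = 1)
#' s <- matrix(0, 10, 10); s[edges(net)] <- 1; s <- s + t(s)
#' links <- new("LinkMatrix", scores = s, scoringMode = "path_sum",
#'              columnLabels = 1:10)
#' aucLinks(links, net)   # 1: perfect ranking
#' @export
aucLinks <- function(links, truth) {
  stopifnot(is(links, "LinkMatrix"), is(truth, "InteractionNetwork"))
  ps <- .pairScores(links)
  lab_i <- links@columnLabels[ps$i]
  lab_j <- links@columnLabels[ps$j]
  key <- paste(pmin(lab_i, lab_j), pmax(lab_i, lab_j))
  e <- truth@edges
  isEdge <- key %in% paste(e[, 1L], e[, 2L])
  n1 <- sum(isEdge); n0 <- sum(!isEdge)
  if (n1 == 0L || n0 == 0L)
    stop("truth must contain both edge and non-edge pairs")
  r <- rank(ps$score)
  (sum(r[isEdge]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build a contact map from residue coordinates
#'
#' @param coords numeric matrix or data frame of one representative atom
#'   per residue: columns `x`, `y`, `z` (a matrix uses its three columns);
#'   rows in residue order.
#' @param cutoff contact distance in Angstrom (pairs at or below it are
#'   contacts); 8 for CASP-style evaluation.
#' @param residueToColumn optional integer map from structure residues to
#'   original alignment columns; defaults to identical indexing.
#' @return A [ContactMap-class].
#' @examples
#' xyz <- rbind(c(0, 0, 0), c(0, 0, 7.9), c(0, 0, 30))
#' contactMap(xyz, cutoff = 8)
#' @export
contactMap <- function(coords, cutoff = 8, residueToColumn = NULL) {
  if (is.data.frame(coords)) {
    stopifnot(all(c("x", "y", "z") %in% names(coords)))
    coords <- as.matrix(coords[, c("x", "y", "z")])
  }
  stopifnot(is.numeric(coords), ncol(coords) == 3L,
            all(is.finite(coords)))
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  if (is.null(residueToColumn)) residueToColumn <- seq_len(nrow(coords))
  new("ContactMap", distances = d, contactCutoff = cutoff,
      residueToColumn = as.integer(residueToColumn))
}

#' Contact map from a PDB file
#'
#' Uses one representative atom per residue: Cbeta, or Calpha for glycine
#' (and for any residue missing its Cbeta, with a warning). Requires the
#' bio3d package.
#'
#' @param path PDB file path.
#' @param cutoff contact distance in Angstrom.
#' @param chain optional chain identifier.
#' @param residueToColumn optional residue-to-column map.
#' @return A [ContactMap-class].
#' @export
contactMapFromPDB <- function(path, cutoff = 8, chain = NULL,
                              residueToColumn = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("contactMapFromPDB requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!is.null(chain)) at <- at[at$chain == chain, ]
  at <- at[at$type == "ATOM", ]
  resKey <- paste(at$chain, at$resno, at$insert)
  resIds <- unique(resKey)
  pick <- lapply(resIds, function(r) {
    rows <- at[resKey == r, ]
    w <- if (rows$resid[1L] == "GLY") which(rows$elety == "CA")
         else which(rows$elety == "CB")
    if (!length(w)) w <- which(rows$elety == "CA")
    if (!length(w)) return(NULL)
    rows[w[1L], c("x", "y", "z")]
  })
  ok <- !vapply(pick, is.null, TRUE)
  if (any(!ok))
    warning(sum(!ok), " residue(s) without CA/CB excluded from contact map")
  coords <- do.call(rbind, pick[ok])
  contactMap(as.matrix(coords), cutoff = cutoff,
             residueToColumn = residueToColumn)
}

# translate link scores onto structure residue pairs; returns data frame
# of (ri, rj, score, dist, sep) for mapped residue pairs i < j
.residuePairScores <- function(links, cmap) {
  map <- cmap@residueToColumn            # residue -> original column label
  colOf <- match(map, links@columnLabels)  # residue -> index in score matrix
  nres <- nrow(cmap@distances)
  ut <- which(upper.tri(cmap@distances), arr.ind = TRUE)
  ri <- ut[, 1L]; rj <- ut[, 2L]
  ci <- colOf[ri]; cj <- colOf[rj]
  ok <- !is.na(ci) & !is.na(cj)
  data.frame(ri = ri[ok], rj = rj[ok],
             score = links@scores[cbind(ci[ok], cj[ok])],
             dist = cmap@distances[cbind(ri[ok], rj[ok])],
             sep = rj[ok] - ri[ok])
}

# Xd: contrast of predicted-pair vs all-pair distance distributions over
# 15 bins of 4 Angstrom (0-60); positive when predictions are enriched in
# short distances
.xd <- function(predDist, allDist) {
  breaks <- seq(0, 60, by = 4)
  binf <- function(d) {
    d <- pmin(d, 59.999)
    tabulate(findInterval(d, breaks, rightmost.closed = TRUE), 15L) /
      max(length(d), 1L)
  }
  Pp <- binf(predDist)
  Pa <- binf(allDist)
  di <- breaks[-1L] / 60
  sum((Pp - Pa) / (15 * di))
}

#' CASP-style contact-prediction scores
#'
#' Candidate residue pairs separated by at least `minSeparation` along the
#' sequence are ranked by link score; the top `floor(L * topFraction)`
#' pairs are assessed for accuracy `TP / (TP + FP)` against the contact
#' map, and for `Xd`, which contrasts the distance distribution of the
#' predicted pairs with that of all candidate pairs (15 bins of 4 Angstrom
#' over 0-60; 0 means no enrichment toward short distances). Boundary ties
#' are broken by ascending pair index.
#'
#' @param links a [LinkMatrix-class].
#' @param cmap a [ContactMap-class] mapping structure residues to the
#'   link matrix's columns.
#' @param L domain length; defaults to the number of mapped residues.
#' @param topFraction fraction of `L` predictions to assess (1/5 or 1/10).
#' @param minSeparation minimum residue separation (default 24).
#' @return List with `accuracy`, `xd`, `nSelected`, `tp`, `fp`.
#' @export
caspScores <- function(links, cmap, L = NULL, topFraction = 1 / 5,
                       minSeparation = 24L) {
  d <- .residuePairScores(links, cmap)
  d <- d[d$sep >= minSeparation, ]
  if (is.null(L)) L <- sum(!is.na(match(cmap@residueToColumn,
                                        links@columnLabels)))
  nSel <- floor(L * topFraction)
  if (nrow(d) < nSel) {
    warning("only ", nrow(d), " candidate pairs available for ", nSel,
            " requested; evaluating all")
    nSel <- nrow(d)
  }
  d <- d[order(-d$score, d$ri, d$rj), ]
  top <- d[seq_len(nSel), ]
  tp <- sum(top$dist <= cmap@contactCutoff)
  list(accuracy = if (nSel > 0) tp / nSel else NA_real_,
       xd = .xd(top$dist, d$dist),
       nSelected = nSel, tp = tp, fp = nSel - tp)
}

#' Accuracy of the top n% of ranked pairs
#'
#' For each requested percentile `n`, the fraction of true contacts among
#' the top `n`% highest-scoring candidate pairs.
#'
#' @param links a [LinkMatrix-class].
#' @param cmap a [ContactMap-class].
#' @param percentiles fractions in `(0, 1]`, e.g. `c(0.01, 0.02, 0.05)`.
#' @param minSeparation minimum residue separation (default 0).
#' @return Data frame with `percentile`, `nPairs`, `accuracy`.
#' @export
accuracyVsPercentile <- function(links, cmap,
                                 percentiles = c(0.01, 0.02, 0.05),
                                 minSeparation = 0L) {
  d <- .residuePairScores(links, cmap)
  d <- d[d$sep >= minSeparation, ]
  d <- d[order(-d$score, d$ri, d$rj), ]
  isContact <- d$dist <= cmap@contactCutoff
  out <- lapply(percentiles, function(p) {
    k <- max(1L, floor(p * nrow(d)))
    data.frame(percentile = p, nPairs = k,
               accuracy = mean(isContact[seq_len(k)]))
  })
  do.call(rbind, out)
}

# canonical "i-j" keys for a two-column pair matrix
.pairKeys <- function(pairs) {
  pairs <- as.matrix(pairs)
  paste(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
}

#' F-score of a predicted pair set against true contacts
#'
#' Harmonic mean of precision `TP/(TP+FP)` and recall `TP/(TP+FN)`;
#' 0 when there are no true positives.
#'
#' @param predicted two-column matrix/data frame of predicted pairs.
#' @param contacts two-column matrix/data frame of true contact pairs.
#' @return F-score in `[0, 1]`.
#' @examples
#' fScore(rbind(c(1, 2), c(1, 3)), rbind(c(1, 2), c(4, 5)))
#' @export
fScore <- function(predicted, contacts) {
  pk <- unique(.pairKeys(predicted))
  ck <- unique(.pairKeys(contacts))
  if (!length(pk) || !length(ck)) return(0)
  tp <- sum(pk %in% ck)
  if (tp == 0L) return(0)
  precision <- tp / length(pk)
  recall <- tp / length(ck)
  2 * precision * recall / (precision + recall)
}

#' Short-distance enrichment of top-ranked links
#'
#' For each distance cutoff, the fraction of the `topN` highest-scoring
#' residue pairs with structural distance at or below the cutoff is
#' compared with the background fraction over all candidate pairs, with a
#' 2 x 2 chi-square test (predicted vs background, short vs long; no
#' continuity correction).
#'
#' @param links a [LinkMatrix-class].
#' @param cmap a [ContactMap-class].
#' @param topN number of top-ranked pairs to assess.
#' @param cutoffs distance cutoffs in Angstrom (default `c(5, 15)`).
#' @param minSeparation minimum residue separation (default 0).
#' @return Data frame with `cutoff`, `topFraction`, `backgroundFraction`,
#'   `pValue`.
#' @export
distanceEnrichment <- function(links, cmap, topN, cutoffs = c(5, 15),
                               minSeparation = 0L) {
  d <- .residuePairScores(links, cmap)
  d <- d[d$sep >= minSeparation, ]
  stopifnot(topN <= nrow(d))
  d <- d[order(-d$score, d$ri, d$rj), ]
  top <- d[seq_len(topN), ]
  out <- lapply(cutoffs, function(ct) {
    a <- sum(top$dist <= ct)
    bg <- sum(d$dist <= ct)
    tab <- rbind(c(a, topN - a), c(bg, nrow(d) - bg))
    p <- tryCatch(
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
      error = function(e) NA_real_)
    data.frame(cutoff = ct, topFraction = a / topN,
               backgroundFraction = bg / nrow(d), pValue = p)
  })
  do.call(rbind, out)
}
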