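linkMat <- function(s, labels = seq_len(nrow(s))) {
  s <- (s + t(s)) / 2
  s <- s - min(s)            # shift into the nonnegative range; AUC and
  diag(s) <- 0               # top-k selections only use the ranking
  new("LinkMatrix", scores = s, scoringMode = "path_sum",
      columnLabels = as.integer(labels))
}

test_that("AUC follows the rank-sum convention, including ties", {
  net <- generateNetwork(10, 0.3, seed = 1)
  s <- matrix(0, 10, 10); s[edges(net)] <- 1
  expect_equal(aucLinks(linkMat(s), net), 1)
  expect_equal(aucLinks(linkMat(matrix(0.7, 10, 10)), net), 0.5)
  # 5-column toy (10 pairs) against a brute-force concordance count
  set.seed(2)
  sc <- matrix(runif(25), 5, 5)
  sc[2, 4] <- sc[4, 2] <- sc[1, 3]   # force a tie across groups
  lm5 <- linkMat(sc)
  truth <- new("InteractionNetwork", nNodes = 5L,
               edges = rbind(c(1L, 3L), c(2L, 5L), c(4L, 5L)), density = 0.3)
  ut <- which(upper.tri(matrix(0, 5, 5)), arr.ind = TRUE)
  isE <- paste(ut[, 1], ut[, 2]) %in% paste(truth@edges[, 1], truth@edges[, 2])
  v <- scores(lm5)[ut]
  conc <- 0
  for (i in which(isE)) for (j in which(!isE))
    conc <- conc + (v[i] > v[j]) + 0.5 * (v[i] == v[j])
  expect_equal(aucLinks(lm5, truth), conc / (sum(isE) * sum(!isE)))
  # monotone transform invariance
  lm5b <- new("LinkMatrix", scores = lm5@scores^3,
              scoringMode = "path_sum", columnLabels = 1:5)
  expect_equal(aucLinks(lm5b, truth), aucLinks(lm5, truth))
  # degenerate truths are rejected
  full <- new("InteractionNetwork", nNodes = 3L,
              edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)), density = 1)
  expect_error(aucLinks(linkMat(matrix(1, 3, 3)), full), "edge and non-edge")
})

test_that("contact maps apply the distance cutoff inclusively", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 7.9), c(0, 0, 16.1))
  cm <- contactMap(xyz, cutoff = 8)
  expect_true(cm@distances[1, 2] <= cm@contactCutoff)    # 7.9: contact
  expect_false(cm@distances[1, 3] <= cm@contactCutoff)   # 16.1: not
  expect_false(cm@distances[2, 3] <= cm@contactCutoff)   # 8.2: not
  # exact boundary (integer coordinates): "within 8" includes 8
  cm2 <- contactMap(data.frame(x = c(0, 8), y = c(0, 0), z = c(0, 0),
                               residue = 1:2), cutoff = 8)
  expect_true(cm2@distances[1, 2] <= cm2@contactCutoff)
})

test_that("PDB reading uses Cbeta, with Calpha for glycine", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2       5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  N   GLY A   2       6.000   0.000   0.000  1.00  0.00           N",
    "END"), pdb)
  cm <- contactMapFromPDB(pdb, cutoff = 8)
  # ALA contributes its CB (x=2), GLY its CA (x=5): distance 3
  expect_equal(cm@distances[1, 2], 3)
})

test_that("CASP-style scoring selects floor(L * fraction) separated pairs", {
  nres <- 200L
  set.seed(3)
  coords <- cbind(cumsum(runif(nres, 1, 3)), 0, 0)
  cm <- contactMap(coords, cutoff = 8)
  # perfect predictor: score = -distance for |i-j| >= 24
  s <- -cm@distances
  res <- caspScores(linkMat(s), cm, topFraction = 1 / 10)
  expect_equal(res$nSelected, 20L)   # L/10 for a 200-residue domain
  expect_equal(res$accuracy, res$tp / 20)
  resL5 <- caspScores(linkMat(s), cm, topFraction = 1 / 5)
  expect_equal(resL5$nSelected, 40L)
  # a perfect predictor can only find contacts if any exist at >= 24
  d <- rmrcm:::.residuePairScores(linkMat(s), cm)
  cand <- d[d$sep >= 24, ]
  best <- sort(cand$dist)[1:20]
  expect_equal(res$tp, sum(best <= 8))
  # min separation can only shrink the candidate set
  resAll <- caspScores(linkMat(s), cm, topFraction = 1 / 10,
                       minSeparation = 0L)
  expect_gte(nrow(d), nrow(cand))
  expect_gte(resAll$accuracy, res$accuracy)
})

test_that("Xd is zero when predictions match the overall distance distribution", {
  set.seed(4)
  coords <- matrix(rnorm(3 * 60, sd = 12), 60, 3)
  cm <- contactMap(coords, cutoff = 8)
  s <- matrix(1, 60, 60)   # constant scores
  # request more pairs than exist: all candidates evaluated, Pp == Pa
  res <- suppressWarnings(caspScores(linkMat(s), cm, L = 60 * 60,
                                     topFraction = 1, minSeparation = 0L))
  expect_equal(res$xd, 0)
  # score inversely proportional to distance: enrichment toward short bins
  res2 <- caspScores(linkMat(-cm@distances), cm, topFraction = 1 / 5,
                     minSeparation = 0L)
  expect_gt(res2$xd, 0)
})

test_that("accuracy-vs-percentile reproduces a hand-counted toy ranking", {
  coords <- cbind(c(0, 1, 2, 30, 60, 100), 0, 0)
  cm <- contactMap(coords, cutoff = 8)
  s <- matrix(0, 6, 6)
  ut <- which(upper.tri(s), arr.ind = TRUE)
  s[ut] <- 15 - seq_len(15)   # rank pairs by index order: (1,2),(1,3),...
  lm <- linkMat(s)
  curve <- accuracyVsPercentile(lm, cm, percentiles = c(0.2, 1))
  # top 3 of 15 pairs in index order: (1,2),(1,3),(2,3) - all contacts
  expect_equal(curve$nPairs, c(3L, 15L))
  expect_equal(curve$accuracy[1L], 1)
  # 100% equals the overall contact density
  dvec <- cm@distances[upper.tri(cm@distances)]
  expect_equal(curve$accuracy[2L], mean(dvec <= 8))
})

test_that("F-score combines precision and recall as stated", {
  expect_equal(fScore(rbind(c(1, 2), c(3, 4)), rbind(c(2, 1), c(4, 3))), 1)
  expect_equal(fScore(rbind(c(1, 2)), rbind(c(3, 4))), 0)
  pred <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5))
  truth <- rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(2, 5), c(2, 6),
                 c(3, 4), c(3, 5))
  # TP = 2, FP = 2, FN = 6: precision 0.5, recall 0.25, F = 1/3
  expect_equal(fScore(pred, truth), 1 / 3)
})

test_that("distance enrichment reports fractions and a textbook chi-square", {
  set.seed(5)
  coords <- matrix(rnorm(3 * 40, sd = 10), 40, 3)
  cm <- contactMap(coords, cutoff = 5)
  lm <- linkMat(-cm@distances)
  res <- distanceEnrichment(lm, cm, topN = 25, cutoffs = c(5, 15))
  expect_equal(res$cutoff, c(5, 15))
  d <- cm@distances[upper.tri(cm@distances)]
  expect_equal(res$backgroundFraction, c(mean(d <= 5), mean(d <= 15)))
  # the closest-ranked pairs must be enriched in short distances
  expect_gte(res$topFraction[2L], res$backgroundFraction[2L])
  # p-value equals the hand-computed Pearson statistic's tail
  nAll <- length(d)
  for (k in 1:2) {
    ct <- res$cutoff[k]
    a <- res$topFraction[k] * 25
    bg <- res$backgroundFraction[k] * nAll
    tab <- rbind(c(a, 25 - a), c(bg, nAll - bg))
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    expect_equal(res$pValue[k], pchisq(stat, df = 1, lower.tail = FALSE))
  }
})
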